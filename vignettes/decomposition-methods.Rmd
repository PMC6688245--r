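---
title: "Decomposing urban–rural gaps in institutional delivery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing urban-rural gaps in institutional delivery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obdecomp)
```

## The problem

Institutional delivery — childbirth in a public or private health facility —
is strongly patterned by residence in much of sub-Saharan Africa: urban women
deliver in facilities at far higher rates than rural women. A raw gap of
40-odd percentage points, however, says nothing about *why*. Two mechanisms
are confounded: urban women are better endowed with the determinants of
facility birth (wealth, education, antenatal contact, proximity to
facilities), and the same endowments may convert into facility birth at
different rates across the two groups (better-equipped urban facilities,
better-quality urban schooling, favoritism and discrimination in access).
Decomposition methods separate the two.

`obdecomp` implements this separation for a binary outcome: group-wise
logit/probit/linear fits, the Oaxaca, Blinder, Reimers and Cotton weighting
schemes, a detailed allocation of the explained component across covariate
groups, a two-step Mills-ratio correction for selection into the birth
sample, and bootstrap inference — together with a synthetic survey generator
whose ground truth makes every step testable.

## Model and decomposition algebra

Each residence group `j ∈ {urban, rural}` gets its own index model
`P(y = 1 | x) = g⁻¹(x'β^j)` fitted by maximum likelihood on the group's rows
(ordinary least squares for the linear link). Decompositions are built from
counterfactual means `m(β, X) = mean(g⁻¹(Xβ))`: averages of predicted
probabilities when one group's rows are priced with some coefficient vector.

The three-fold algebra under the urban reference is

```
total       = m(β_U, X_U) − m(β_R, X_R)
explained   = m(β_U, X_U) − m(β_U, X_R)
unexplained = m(β_U, X_U) − m(β_R, X_U)
interaction = total − explained − unexplained
```

and the rural reference swaps the pricing. Written this way the components
sum to the total *identically*, for any link — the additive "cross term"
formulations that circulate in the applied literature double-count under a
non-linear link, whereas the counterfactual-mean formulation keeps the
adding-up identity exact (the test suite enforces it at 1e−10). The two
references are connected algebraically: the urban-reference explained minus
the rural-reference explained equals the rural-reference interaction.

The two-fold algebra blends the coefficient vectors,
`β* = ω β_U + (1 − ω) β_R`, and reads the unexplained part as deviations
from that pooled norm: urban *advantage* above it, rural *disadvantage*
below it. The schemes differ only in `ω`: Oaxaca 1, Blinder 0, Reimers 0.5,
Cotton the urban share of the estimation sample. Because all schemes share
one total, agreement of their explained components is a robustness check, not
a choice of truth.

### Link choice

The default link is logit. Its intercept score equation forces each group's
mean fitted probability to equal its observed outcome rate, so the
decomposition total equals the raw gap in observed means exactly; the same
holds for the linear link, while probit matches only approximately (the
discrepancy is the sum of the two groups' score residuals and is typically
below 1e−3 at survey scale). Probit is provided because the selection
machinery is exact in its latent-normal world; linear is provided because
every component then has a closed matrix-algebra form, which the oracle
tests exploit.

### Detailed decomposition

Only the explained component is decomposed per covariate. Each non-intercept
design column k receives the linearization weight
`W_k = Δx̄_k β*_k / Σ_j Δx̄_j β*_j`, and contributes `W_k × explained`;
dummies of one categorical variable are aggregated into a single group, and
the Mills ratio, when present, is its own group. Under the linear link this
collapses to the exact product `Δx̄_k β*_k`. Two caveats are inherent to the
method and documented rather than hidden: contributions of categorical
variables depend on the reference category (references are fixed — the first
canonical level — and recorded in `design_meta`), and the weights share the
non-linearity of the explained component among covariates proportionally,
which is a linearization, not an exact path integral. The residual of the
allocation is zero by construction and is reported for numerical audit.

When the endowment differences priced by `β*` sum to exactly zero the
weights are undefined; the function then returns all-zero contributions with
a warning rather than dividing by zero.

### Selection correction

Only women with a recent birth appear in the outcome sample. The two-step
correction fits a probit of the birth indicator on the full sample of women
(age, education, wealth, religion, ethnicity, marital status, residence,
contraceptive use — marital status and contraceptive use act as exclusion
restrictions, absent from the outcome equation), computes the inverse Mills
ratio `λ(z) = φ(z)/Φ(z)` at each selected woman's fitted index, and adds it
to the outcome equation as a regressor. This is deliberately the literal
two-step-with-Mills-regressor procedure, not a full-information bivariate
likelihood: with a binary second stage the two-step is an approximation that
reduces, but does not eliminate, selection bias — the simulation study in
the test suite measures exactly that (mean absolute coefficient bias over
100 replicates falls when the Mills term is added under strong selection,
and the correction is inert when selection is ignorable). The selection
probit is fitted on the pooled sample, with residence among its covariates,
rather than per group.

`inverse_mills` is computed as `exp(log φ(z) − log Φ(z))`, which stays
accurate far into the left tail where the naive ratio underflows to 0/0; it
is strictly positive, strictly decreasing, and satisfies `λ(z) > −z`.

### Inference

No analytic standard errors are attached to the components; the package uses
a nonparametric pairs bootstrap, stratified by residence (and by survey year
when several years are pooled) so that every replicate preserves the group
structure. Both group models are refitted per replicate and all components
recomputed, so replicate components inherit the adding-up identity exactly.
Standard errors are replicate standard deviations; intervals are percentile
intervals at 95%; the significance flag is "the interval excludes zero",
a 5% two-sided test without normality assumptions. `B` defaults to 1000;
the validation studies use B = 200, where percentile intervals for the
explained component achieve 96-97% empirical coverage at n = 2000.
Replicates whose fits fail (single-class or separated resamples) are dropped
and counted, with an error if more than 5% fail; a rare dummy that loses all
variation within one group of a resample is removed from both fits for that
replicate and its contribution recorded as zero.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. A
`population_spec` fixes the rural share of births, per-group covariate
distributions (categorical probability vectors; binary rates; parity as
1 + Poisson so every mother has at least one child; antenatal visits as
negative binomial), link-scale coefficient vectors per group, and an
optional probit selection stage whose latent error is correlated (`ρ`) with
the outcome error. For the probit link the selection structure is exactly
the textbook bivariate-normal model; for other links the outcome's latent
uniform is driven through a normal score so that `ρ = 0` reduces *exactly*
to the no-selection model — a property the tests rely on.

`default_ghana_spec()` calibrates the margins to the pooled Ghana DHS
2003/2008/2014 birth sample: 58.9% rural births; group-wise age, education,
wealth, ethnicity, religion, marital-status, complication, distance-barrier,
parity and antenatal margins; delivery rates of 43.1% (rural) and 84.7%
(urban). The antenatal negative-binomial size parameters were solved so each
group matches both its mean visit count and its share attending four or more
visits; the outcome intercepts were solved (by Monte-Carlo root-finding, once,
and frozen) so the group delivery rates hit their targets given the chosen
slopes. The slopes themselves are a documented, plausible choice — strong
wealth and education gradients, an antenatal-care effect, a distance
penalty, slightly more favourable urban coefficients — not estimates from
the real microdata, which are registration-gated.

What the generator does *not* emulate, deliberately: joint dependence among
covariates within a group (margins only — so, e.g., wealth–education
correlation is absent and the simulated explained component need not match
published magnitudes), DHS cluster/stratum sampling and its design effects,
GPS displacement, and multi-birth histories. Passing tests therefore
demonstrate that the estimators recover a known truth of the assumed form,
not that any particular published coefficient is correct.

`population_components()` is the oracle: it evaluates the decomposition
directly from the true coefficient vectors over fresh covariate draws
(2 × 10⁵ per group in the validation runs, Monte-Carlo standard errors
attached), with no estimation step, so estimator and oracle share no code
path beyond the link function.

## Numerical and design choices

- **Reference categories** are the first canonical level of each variable;
  changing them changes detailed (not overall) contributions, so they are
  recorded in every fit.
- **Constant columns** (e.g. the survey-year dummy inside a single-year
  window, or a rare level absent from one group) are dropped from *both*
  group fits so the decomposition keeps a shared term namespace; drops are
  logged.
- **Degenerate fits** error loudly: single-class outcomes, non-convergence,
  perfect separation and rank deficiency are explicit errors naming the
  group and columns, never silently absorbed.
- **Missing data** are handled by complete-case deletion per fitted
  equation, with the dropped-row count recorded.
- **Cotton's weight** is computed from the estimation sample after
  missing-data exclusion, with the complementary rural share attached for
  reporting, since reported pooled weights in applied work conventionally
  quote the rural share.
- **Antenatal care** enters the outcome equation as the four-plus-visits
  indicator (`anc4`) by default — the clinically meaningful threshold — with
  the continuous count available through the formula interface.
- **Sampling weights** are accepted but off by default; none of the
  validation studies use them.
- **Determinism**: every stochastic function takes an explicit seed;
  identical (spec, n, seed) gives bit-identical tables, identical
  (table, config, B, seed) gives identical inference, and identical
  pipeline configs give byte-identical JSON reports.

Problem sizes in the validation suite were chosen to make Monte-Carlo error
small relative to the tolerances tested: n = 50,000 for margin and
coefficient recovery (each coefficient within 3.5 reported standard errors
of truth, the multiplicity-aware bound for ~60 simultaneous z-checks),
n = 20,000 for component recovery (within 3 combined bootstrap + oracle
standard errors), 100 replicates of n = 4,000 for the selection-bias study,
and 200 datasets of n = 2,000 with B = 200 for bootstrap coverage.

## Limitations

Survey-design variance (clustering, stratification) is not implemented; the
bootstrap treats rows as exchangeable within residence × year strata.
Detailed contributions for the *unexplained* component are not provided —
they are even more reference-dependent than the explained ones, and the
package follows the practice of decomposing the explained part only.
Distributional (quantile/RIF) decompositions and more than two groups are
out of scope.
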