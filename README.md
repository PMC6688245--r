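# obdecomp

Decomposition of urban–rural gaps in binary health outcomes, built around the
motivating case of institutional delivery among women of reproductive age in
Ghana: urban women deliver in health facilities far more often than rural
women, and the question is how much of that gap reflects *differences in
endowments* (wealth, education, antenatal care, distance to facilities, ...)
versus *differences in the returns to those endowments* (the same
characteristics translating into institutional delivery at different rates —
favoritism toward urban women or discrimination against rural women).

The package is aimed at health-inequality analysts working with DHS-style
survey tables (one row per most-recent birth), and at methodologists who want
a tested, simulation-validated reference implementation of the non-linear
Oaxaca–Blinder machinery.

## The method

Let `j ∈ {U, R}` index the urban and rural groups, each with a fitted
binary-outcome model (logit by default, probit or linear optional) with
coefficients `β^j`, and let `m(β, X) = mean(g⁻¹(Xβ))` be the average
predicted outcome when rows `X` are priced with coefficients `β`. The total
gap is

```
Δ = m(β_U, X_U) − m(β_R, X_R)
```

which for the logit and linear links equals the raw difference in observed
group means exactly (score identity of the intercept).

**Three-fold decompositions.** Under the urban reference (Oaxaca),
`explained = m(β_U, X_U) − m(β_U, X_R)` prices endowment differences at urban
coefficients and `unexplained = m(β_U, X_U) − m(β_R, X_U)` prices coefficient
differences at urban covariates; the interaction is the remainder, so the
three parts sum to `Δ` by construction. The rural reference (Blinder) does
the opposite, and algebraically `explained_U − explained_R` equals the
rural-reference interaction.

**Two-fold decompositions.** A pooled vector `β* = ω β_U + (1 − ω) β_R`
splits the gap into `explained = m(β*, X_U) − m(β*, X_R)`, urban
`advantage = m(β_U, X_U) − m(β*, X_U)` and rural
`disadvantage = m(β*, X_R) − m(β_R, X_R)`. The weight `ω` is 1 (Oaxaca), 0
(Blinder), 0.5 (Reimers) or the urban sample share (Cotton).

**Detailed decomposition.** The explained component is allocated across
covariate groups by linearization weights
`W_k = Δx̄_k β*_k / Σ_j Δx̄_j β*_j`, which is exact under the linear link and
is the standard detailed method for logit/probit decompositions.

**Selection correction.** Because only women with a recent birth enter the
sample, a Heckman two-step is provided: a probit of birth selection on the
full sample of women, then the inverse Mills ratio `λ(z) = φ(z)/Φ(z)` of the
fitted selection index added to the outcome equation as a regressor.

**Inference.** The components carry no closed-form standard errors here;
a stratified pairs bootstrap (resampling within residence × survey-year
strata, refitting both models per replicate) yields standard errors,
percentile intervals and 5%-level significance flags.

A calibrated synthetic-data generator (`default_ghana_spec()`,
`generate_survey()`, `generate_population()`) emulates the pooled Ghana DHS
2003/2008/2014 birth sample — 58.9% rural births, delivery rates near 43%
(rural) and 85% (urban), poor-skewed rural wealth — under a known
data-generating process, and `population_components()` computes the
population-truth components that parameter-recovery and coverage tests
compare against.

## Worked example

```r
library(obdecomp)
spec <- default_ghana_spec()
births <- generate_survey(spec, n = 13802, seed = 1)
fit <- ob_decompose(
  outcome ~ age_band + education + wealth_quintile + parity + complications +
    distance_barrier + reform_period + anc4 + ethnicity + religion + survey_year,
  data = births, boot = 200, seed = 2)
fit
```

```
Decomposition of the residence gap in 'outcome' (logit link)
  urban: n = 5671, mean = 0.8420;  rural: n = 8131, mean = 0.4305
  raw gap (urban - rural): 0.4116

oaxaca decomposition (reference = urban)
  total             0.412*   100.0%
  explained         0.318*    77.3%
  unexplained       0.038*     9.2%
  interaction       0.056*    13.5%
blinder decomposition (reference = rural)
  total             0.412*   100.0%
  explained         0.373*    90.8%
  unexplained       0.094*    22.7%
  interaction      -0.056*   -13.5%
reimers decomposition (weight = 0.50)
  total             0.412*   100.0%
  explained         0.347*    84.3%
  advantage         0.018*     4.3%
  disadvantage      0.047*    11.4%
cotton decomposition (weight = 0.41)
  total             0.412*   100.0%
  explained         0.352*    85.5%
  advantage         0.021*     5.2%
  disadvantage      0.038*     9.3%

* percentile interval excludes 0 (level 95%, B = 200)
```

The total (0.412) is the simulated urban-minus-rural gap in delivery rates;
every scheme reproduces it exactly, and the explained component dominates
under all four weightings. The detailed decomposition
(`fit$detailed`) allocates the explained part across covariate groups:

```
Detailed decomposition of the explained component (0.318), omega = 1.000
   variable_group contribution share_pct
        education        0.052      16.2
  wealth_quintile        0.176      55.3
           parity        0.016       5.1
 distance_barrier        0.012       3.8
             anc4        0.032      10.1
              ...
```

Wealth differences carry over half of the explained component in this
simulated population, followed by education and antenatal care — the pattern
of endowment-driven inequality the package is designed to quantify.

`summary(fit)` adds the bootstrap table; `coef(fit)`, `predict(fit)`,
`residuals(fit)` and `plot(fit)` behave as for other fitted-model objects.
A command line is available via `inst/cli/obdecomp`
(`simulate` / `decompose` / `report`), and `run_analysis()` executes the full
pooled-plus-per-year pipeline with CSV/JSON reports.

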