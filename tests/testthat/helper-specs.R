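# Compact population specifications used across the suite: small enough that
# repeated refits are cheap, rich enough to exercise categorical expansion,
# counts and binaries.

norm_probs <- function(x, var) {
  p <- x / sum(x)
  names(p) <- survey_levels()[[var]]
  p
}

# four-covariate population with distinct group endowments and coefficients
compact_spec <- function(link = "logit", beta_equal = FALSE,
                         covariates_equal = FALSE) {
  cov_r <- list(
    education = norm_probs(c(5, 3, 2, 0.5), "education"),
    wealth_quintile = norm_probs(c(4, 3, 1.5, 1, 0.5), "wealth_quintile"),
    distance_barrier = 0.45,
    parity = 3.5
  )
  cov_u <- list(
    education = norm_probs(c(2, 2, 4, 1), "education"),
    wealth_quintile = norm_probs(c(1, 1, 2, 3, 3), "wealth_quintile"),
    distance_barrier = 0.18,
    parity = 2.8
  )
  if (covariates_equal) cov_u <- cov_r
  ot <- c("education", "wealth_quintile", "parity", "distance_barrier")
  nm <- design_colnames_pub(ot)
  b_r <- c(-1.2, 0.2, 0.5, 0.9, 0.3, 0.6, 0.9, 1.2, -0.08, -0.3)
  b_u <- c(-0.7, 0.25, 0.55, 1.0, 0.35, 0.65, 1.0, 1.3, -0.06, -0.25)
  names(b_r) <- nm
  names(b_u) <- nm
  if (beta_equal) b_u <- b_r
  population_spec(
    group_share_rural = 0.55,
    covariates = list(urban = cov_u, rural = cov_r),
    beta_urban = b_u, beta_rural = b_r,
    link = link, outcome_terms = ot
  )
}

# compact specification with a probit selection stage, for Heckman studies
selection_spec <- function(rho, link = "probit") {
  base <- compact_spec(link = link)
  cov_r <- c(base$covariates$rural,
             list(marital_status = norm_probs(c(8, 1, 1), "marital_status"),
                  contraceptive_use = 0.2))
  cov_u <- c(base$covariates$urban,
             list(marital_status = norm_probs(c(7, 1, 2), "marital_status"),
                  contraceptive_use = 0.3))
  st <- c("education", "wealth_quintile", "marital_status", "residence",
          "contraceptive_use")
  g <- c(0.9, 0.0, -0.1, -0.3, -0.05, -0.1, -0.2, -0.3,
         -0.5, -1.4, -0.15, -0.3)
  names(g) <- design_colnames_pub(st)
  population_spec(
    group_share_rural = base$group_share_rural,
    covariates = list(urban = cov_u, rural = cov_r),
    beta_urban = base$beta_urban, beta_rural = base$beta_rural,
    gamma_selection = g, link = link, rho_selection = rho,
    outcome_terms = base$outcome_terms, selection_terms = st
  )
}

# design column names for a term vector, via the package's own expansion
design_colnames_pub <- function(terms) {
  lv <- survey_levels()
  cols <- "(Intercept)"
  for (v in terms) {
    if (v %in% names(lv)) cols <- c(cols, paste0(v, lv[[v]][-1]))
    else cols <- c(cols, v)
  }
  cols
}

# tiny hand-built table with a linear-link closed form in easy reach
hand_table <- function() {
  data.frame(
    outcome = c(1, 0, 1, 1, 0, 0, 1, 0),
    residence = factor(rep(c("urban", "rural"), each = 4),
                       levels = c("rural", "urban")),
    x = c(1, 0, 1, 0, 1, 0, 0, 1),
    stringsAsFactors = FALSE
  )
}

# build a pair of obd_fit-like objects directly from coefficient vectors, so
# decomposition algebra can be tested without an estimation step
manual_fit <- function(group, coefficients, link = "linear",
                       assign_term = NULL) {
  if (is.null(assign_term)) assign_term <- names(coefficients)
  structure(
    list(group = group, link = link, coefficients = coefficients,
         vcov = NULL, n_obs = NA_integer_, converged = TRUE,
         design_meta = list(assign_term = assign_term)),
    class = "obd_fit"
  )
}
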