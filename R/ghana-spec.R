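# Calibration constants for default_ghana_spec(). The intercepts are solved
# (once) so that the simulated institutional-delivery rates hit the target
# group means; the negative-binomial size parameters are solved so that the
# antenatal-visit distributions match both the group mean visit count and the
# share of women attending four or more visits.
.ghana_intercept_rural <- -1.666360
.ghana_intercept_urban <- -1.877023
.ghana_anc_size_rural <- 2.7877572744
.ghana_anc_size_urban <- 7.1791387536

.ghana_margins <- function() {
  norm <- function(x, var) {
    p <- x / sum(x)
    names(p) <- .obd_levels[[var]]
    p
  }
  list(
    rural = list(
      age_band = norm(c(3.81, 19.11, 26.49, 20.91, 17.36, 9.08, 3.84),
                      "age_band"),
      education = norm(c(48.60, 22.67, 28.05, 0.68), "education"),
      wealth_quintile = norm(c(46.80, 29.84, 16.23, 5.88, 1.25),
                             "wealth_quintile"),
      ethnicity = norm(c(34.87, 4.52, 11.79, 48.81), "ethnicity"),
      religion = norm(c(66.35, 18.16, 8.06, 7.33, 0.10), "religion"),
      marital_status = norm(c(87.35, 5.57, 3.92), "marital_status"),
      reform_period = norm(c(0.27, 0.28, 0.45), "reform_period"),
      survey_year = norm(c(0.336, 0.239, 0.425), "survey_year"),
      complications = 0.6788,
      distance_barrier = 0.4534,
      contraceptive_use = 0.20,
      parity = 4.05,
      anc_visits = c(mu = 7.13, size = .ghana_anc_size_rural)
    ),
    urban = list(
      age_band = norm(c(3.27, 16.28, 26.87, 25.67, 17.98, 7.41, 2.51),
                      "age_band"),
      education = norm(c(21.37, 19.69, 52.68, 6.26), "education"),
      wealth_quintile = norm(c(5.67, 7.58, 20.96, 32.59, 33.21),
                             "wealth_quintile"),
      ethnicity = norm(c(48.98, 6.96, 11.91, 32.15), "ethnicity"),
      religion = norm(c(71.86, 24.66, 0.99, 2.42, 0.07), "religion"),
      marital_status = norm(c(87.06, 6.17, 6.77), "marital_status"),
      reform_period = norm(c(0.19, 0.25, 0.56), "reform_period"),
      survey_year = norm(c(0.238, 0.228, 0.534), "survey_year"),
      complications = 0.7927,
      distance_barrier = 0.1755,
      contraceptive_use = 0.30,
      parity = 3.13,
      anc_visits = c(mu = 8.89, size = .ghana_anc_size_urban)
    )
  )
}

.ghana_betas <- function() {
  nm <- design_colnames(.obd_outcome_terms)
  rural <- c(
    .ghana_intercept_rural,
    0.10, 0.15, 0.15, 0.10, 0.05, 0.00,       # age bands vs 15-19
    0.35, 0.80, 1.60,                          # education vs none
    0.45, 0.95, 1.55, 2.20,                    # wealth vs Q1
    -0.12,                                     # parity
    0.15,                                      # complications
    -0.45,                                     # distance barrier
    0.25, 0.55,                                # reform periods 2, 3
    0.90,                                      # 4+ antenatal visits
    0.10, 0.05, -0.15,                         # ethnicity vs Akan
    -0.10, -0.45, -0.35, -0.10,                # religion vs Christian
    0.20, 0.50                                 # survey year 2008, 2014
  )
  urban <- c(
    .ghana_intercept_urban,
    0.10, 0.20, 0.20, 0.15, 0.05, 0.00,
    0.40, 0.90, 1.80,
    0.50, 1.00, 1.60, 2.30,
    -0.10,
    0.20,
    -0.35,
    0.30, 0.65,
    1.10,
    0.10, 0.05, -0.10,
    -0.10, -0.40, -0.30, -0.10,
    0.25, 0.60
  )
  names(rural) <- nm
  names(urban) <- nm
  list(rural = rural, urban = urban)
}

.ghana_gamma <- function() {
  g <- c(
    0.40,                                      # intercept
    0.55, 0.65, 0.55, 0.30, -0.25, -0.90,      # age bands vs 15-19
    0.00, -0.10, -0.35,                        # education vs none
    -0.05, -0.10, -0.20, -0.30,                # wealth vs Q1
    0.10, 0.05, 0.05, 0.00,                    # religion vs Christian
    0.00, 0.00, 0.05,                          # ethnicity vs Akan
    -0.45, -1.30,                              # marital vs married
    -0.15,                                     # urban residence
    -0.25                                      # contraceptive use
  )
  names(g) <- design_colnames(.obd_selection_terms)
  g
}

#' Preset population calibrated to the Ghana DHS birth sample
#'
#' A documented [population_spec()] whose simulated margins approximate the
#' descriptive profile of the pooled Ghana DHS 2003/2008/2014 most-recent-birth
#' sample: 58.9% of births rural; institutional-delivery rates near 0.431
#' (rural) and 0.847 (urban); wealth heavily skewed poor in the rural stratum,
#' rich in the urban; education, ethnicity, religion, age, antenatal-care,
#' complication, distance-barrier and parity margins matched per group.
#'
#' The calibration targets marginal distributions only: covariates are drawn
#' independently within each residence group, so joint dependence between
#' covariates (beyond the group split) is not reproduced. The coefficient
#' vectors are a documented, plausible choice (strong wealth and education
#' gradients, an antenatal-care effect, a distance penalty, slightly more
#' favourable urban coefficients) with intercepts solved so that group
#' outcome rates hit their targets under the logit link.
#'
#' @param rho_selection correlation between the selection and outcome latent
#'   errors (default 0.35, a mild positive selection).
#' @return a valid `population_spec`.
#' @export
default_ghana_spec <- function(rho_selection = 0.35) {
  betas <- .ghana_betas()
  population_spec(
    group_share_rural = 0.589,
    covariates = .ghana_margins(),
    beta_urban = betas$urban,
    beta_rural = betas$rural,
    gamma_selection = .ghana_gamma(),
    link = "logit",
    rho_selection = rho_selection
  )
}
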