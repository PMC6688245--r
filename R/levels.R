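#' @keywords internal
"_PACKAGE"

# Canonical variable dictionary for a DHS-like most-recent-birth table.
# First-listed level is the reference category throughout (recorded in
# design_meta so detailed decompositions are reproducible).
.obd_levels <- list(
  age_band        = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49"),
  education       = c("none", "primary", "secondary", "tertiary"),
  wealth_quintile = c("Q1", "Q2", "Q3", "Q4", "Q5"),
  ethnicity       = c("Akan", "Ga", "Ewe", "Other"),
  religion        = c("Christian", "Muslim", "Traditional", "NoReligion", "Other"),
  marital_status  = c("married", "formerly_married", "never_married"),
  reform_period   = c("1", "2", "3"),
  survey_year     = c("2003", "2008", "2014"),
  residence       = c("rural", "urban")
)

.obd_binary <- c("complications", "distance_barrier", "contraceptive_use")
.obd_counts <- c("parity", "anc_visits")

# Default outcome-equation terms: age, education, wealth, parity, complications,
# distance barrier, reform period, antenatal care (4+ visits indicator),
# ethnicity, religion, survey year.
.obd_outcome_terms <- c(
  "age_band", "education", "wealth_quintile", "parity", "complications",
  "distance_barrier", "reform_period", "anc4", "ethnicity", "religion",
  "survey_year"
)

# Default selection-equation terms: the mother's age, education, wealth,
# religion, ethnicity, marital status, residence and contraceptive use.
.obd_selection_terms <- c(
  "age_band", "education", "wealth_quintile", "religion", "ethnicity",
  "marital_status", "residence", "contraceptive_use"
)

#' Expected design-matrix column names for a term list
#'
#' Categorical terms expand to `paste0(term, level)` for all non-reference
#' levels under treatment contrasts; numeric/binary terms contribute one
#' column. An intercept column is always first.
#'
#' @param terms character vector of term names.
#' @return character vector of design column names.
#' @keywords internal
design_colnames <- function(terms) {
  cols <- "(Intercept)"
  for (v in terms) {
    if (v %in% names(.obd_levels)) {
      cols <- c(cols, paste0(v, .obd_levels[[v]][-1]))
    } else {
      cols <- c(cols, v)
    }
  }
  cols
}

# link-inverse lookup
obd_linkinv <- function(link) {
  switch(link,
    logit  = stats::plogis,
    probit = stats::pnorm,
    linear = identity,
    stop("unknown link '", link, "'; valid links are logit, probit, linear",
         call. = FALSE)
  )
}

obd_links <- c("logit", "probit", "linear")
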