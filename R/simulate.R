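# Covariate draws for one residence group. Covariates are mutually
# independent within group (joint dependence beyond the group split is not
# part of the specification and is documented as such).
draw_covariates <- function(spec, group, n) {
  cv <- spec$covariates[[group]]
  out <- vector("list", length(cv))
  names(out) <- names(cv)
  for (v in names(cv)) {
    p <- cv[[v]]
    if (v %in% names(.obd_levels)) {
      lv <- .obd_levels[[v]]
      out[[v]] <- factor(sample(lv, n, replace = TRUE, prob = p), levels = lv)
    } else if (v %in% .obd_binary) {
      out[[v]] <- stats::rbinom(n, 1L, p)
    } else if (v == "parity") {
      out[[v]] <- 1L + stats::rpois(n, p - 1)
    } else if (v == "anc_visits") {
      out[[v]] <- stats::rnbinom(n, size = p[["size"]], mu = p[["mu"]])
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if ("anc_visits" %in% names(df)) df$anc4 <- as.integer(df$anc_visits >= 4L)
  df$residence <- factor(group, levels = .obd_levels$residence)
  df
}

# residence vector for n rows, then per-group covariates, reassembled in a
# deterministic shuffled order
draw_table_covariates <- function(spec, n) {
  n_rural <- stats::rbinom(1L, n, spec$group_share_rural)
  parts <- list()
  if (n_rural > 0L) parts$rural <- draw_covariates(spec, "rural", n_rural)
  if (n - n_rural > 0L) parts$urban <- draw_covariates(spec, "urban", n - n_rural)
  df <- do.call(rbind, parts)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

outcome_index <- function(spec, df, group) {
  beta <- if (group == "urban") spec$beta_urban else spec$beta_rural
  X <- build_design(df, spec$outcome_terms)
  drop(X %*% beta)
}

# probability implied by the linear index under the spec's link; the linear
# link requires the index itself to be a valid probability
index_prob <- function(idx, link) {
  p <- obd_linkinv(link)(idx)
  if (link == "linear" && (any(p < 0) || any(p > 1))) {
    warning("linear-link index outside [0, 1]; probabilities clamped",
            call. = FALSE)
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Generate a synthetic survey table of most-recent births
#'
#' Draws `n` birth records from a [population_spec()]: residence is Bernoulli
#' with the spec's rural share, covariates are drawn per group, and the binary
#' institutional-delivery outcome is drawn with probability
#' `linkinv(x' beta_group)`. The same `(spec, n, seed)` triple always yields a
#' bit-identical table.
#'
#' Selection into the birth sample is not simulated here; use
#' [generate_population()] when the Heckman stage needs a full sample with
#' non-mothers.
#'
#' @param spec a valid [population_spec()].
#' @param n number of rows (births) to generate.
#' @param seed integer seed.
#' @return a `data.frame` survey table with columns `outcome`, `residence`,
#'   the spec's covariates, and `anc4` when antenatal visits are modelled.
#' @export
generate_survey <- function(spec, n, seed) {
  validate_population_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  set.seed(seed)
  df <- draw_table_covariates(spec, as.integer(n))
  p <- numeric(nrow(df))
  for (g in c("rural", "urban")) {
    rows <- df$residence == g
    if (any(rows)) {
      p[rows] <- index_prob(outcome_index(spec, df[rows, , drop = FALSE], g),
                            spec$link)
    }
  }
  df$outcome <- stats::rbinom(nrow(df), 1L, p)
  df[c("outcome", setdiff(names(df), "outcome"))]
}

#' Generate a full synthetic sample with a birth-selection stage
#'
#' Simulates `n` women of reproductive age. A latent probit selection equation
#' `gamma' w + u > 0` (u standard normal) determines who has a recent birth
#' (`gave_birth`). The delivery outcome of selected women is drawn from a
#' latent uniform `V = pnorm(sqrt(1 - rho^2) v - rho u)` compared against
#' `linkinv(x' beta_group)`; for the probit link this is exactly the bivariate
#' normal selection model with error correlation `rho_selection`, and for any
#' link `rho_selection = 0` reduces to the no-selection model of
#' [generate_survey()]. Positive `rho_selection` means women likelier to be
#' selected are also likelier to deliver in an institution.
#'
#' @inheritParams generate_survey
#' @return a `data.frame` with one row per woman: covariates, `gave_birth`
#'   (0/1) and `outcome` (0/1 for mothers, `NA` otherwise).
#' @export
generate_population <- function(spec, n, seed) {
  validate_population_spec(spec)
  if (is.null(spec$gamma_selection)) {
    stop("spec has no gamma_selection; a selection equation is required",
         call. = FALSE)
  }
  set.seed(seed)
  df <- draw_table_covariates(spec, as.integer(n))
  W <- build_design(df, spec$selection_terms)
  sel_idx <- drop(W %*% spec$gamma_selection)
  u <- stats::rnorm(nrow(df))
  df$gave_birth <- as.integer(sel_idx + u > 0)

  rho <- spec$rho_selection
  v <- stats::rnorm(nrow(df))
  V <- stats::pnorm(sqrt(1 - rho^2) * v - rho * u)
  p <- numeric(nrow(df))
  for (g in c("rural", "urban")) {
    rows <- df$residence == g
    if (any(rows)) {
      p[rows] <- index_prob(outcome_index(spec, df[rows, , drop = FALSE], g),
                            spec$link)
    }
  }
  df$outcome <- ifelse(df$gave_birth == 1L, as.integer(V < p), NA_integer_)
  df[c("outcome", "gave_birth", setdiff(names(df), c("outcome", "gave_birth")))]
}
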