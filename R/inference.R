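# refit both groups on a design/outcome resample and recompute all requested
# components; used by bootstrap_components so the per-replicate cost is two
# glm.fit calls on a prebuilt matrix
components_from_matrix <- function(X, y, g, link, schemes, omega = NULL,
                                   detailed = FALSE, assign_term = NULL) {
  rows_u <- g == "urban"
  # a resample can lose all variation in a rare dummy within one group;
  # shed such columns from both fits so the namespace stays shared
  const <- group_constant_cols(X, rows_u)
  if (length(const)) {
    keep_cols <- !colnames(X) %in% const
    assign_term <- assign_term[keep_cols]
    X <- X[, keep_cols, drop = FALSE]
  }
  fit2 <- function(rows, group) {
    yy <- y[rows]
    if (length(unique(yy)) < 2L && link != "linear") {
      stop("single-class outcome in resample", call. = FALSE)
    }
    f <- fit_glm_matrix(X[rows, , drop = FALSE], yy, link)
    if (!f$converged || f$rank < ncol(X)) {
      stop("non-converged resample fit", call. = FALSE)
    }
    structure(list(group = group, link = link, coefficients = f$coefficients,
                   vcov = NULL, n_obs = sum(rows), converged = TRUE,
                   design_meta = list(assign_term = assign_term)),
              class = "obd_fit")
  }
  fit_u <- fit2(rows_u, "urban")
  fit_r <- fit2(!rows_u, "rural")
  X_u <- X[rows_u, , drop = FALSE]
  X_r <- X[!rows_u, , drop = FALSE]

  out <- numeric(0)
  for (sc in schemes) {
    res <- decompose_scheme(fit_u, fit_r, X_u, X_r, sc, omega = omega)
    v <- res$components
    names(v) <- paste(sc, names(v), sep = ".")
    out <- c(out, v)
  }
  if (detailed) {
    w <- scheme_omega(schemes[1L], nrow(X_u), nrow(X_r))
    det <- detailed_explained(fit_u, fit_r, X_u, X_r, w)
    dv <- det$table$contribution
    names(dv) <- paste("contribution", det$table$variable_group, sep = ".")
    out <- c(out, dv)
  }
  out
}

#' Bootstrap inference for decomposition components
#'
#' Nonparametric pairs bootstrap: rows are resampled with replacement within
#' strata defined by residence (and survey year, when several years are
#' present), both group models are refit, and every component of every
#' requested scheme — optionally including the detailed contributions of the
#' first scheme — is recomputed per replicate. Standard errors are replicate
#' standard deviations; 95% intervals are percentile intervals; the 5%-level
#' significance flag is "the interval excludes zero". Replicates whose fits
#' fail (separation, single-class resample) are dropped and counted, with an
#' error if more than 5% fail.
#'
#' @param table survey `data.frame` with `outcome` and `residence`.
#' @param link,terms model configuration as in [fit_group_model()].
#' @param schemes character vector of scheme labels.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; fixed seed gives identical inference.
#' @param omega optional two-fold weight override.
#' @param detailed also bootstrap the detailed contributions under the first
#'   scheme's weight.
#' @param conf confidence level for the percentile interval.
#' @return an `obd_inference`: data.frame with one row per component
#'   (`estimate`, `se`, `ci_low`, `ci_high`, `sig`), plus `B`, `B_failed`,
#'   `seed`.
#' @export
bootstrap_components <- function(table, link = "logit", terms = NULL,
                                 schemes = c("oaxaca", "blinder", "reimers",
                                             "cotton"),
                                 B = 1000L, seed = 1L, omega = NULL,
                                 detailed = FALSE, conf = 0.95) {
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  for (sc in schemes) scheme_weight(sc, 1, 1)
  if (is.null(terms)) terms <- default_outcome_terms(table)
  g <- as.character(table$residence)
  if (length(unique(g)) < 2L) {
    stop("both residence groups must be present to bootstrap", call. = FALSE)
  }

  keep <- stats::complete.cases(table[c("outcome", terms, "residence")])
  table <- table[keep, , drop = FALSE]
  g <- g[keep]
  X <- build_design(table, terms)
  # drop columns constant in the full estimation sample
  const <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  const["(Intercept)"] <- FALSE
  at <- attr(X, "assign_term")[!const]
  X <- X[, !const, drop = FALSE]
  y <- table$outcome

  strata <- g
  if ("survey_year" %in% names(table) &&
      length(unique(table$survey_year)) > 1L) {
    strata <- paste(g, table$survey_year)
  }
  idx_by_stratum <- split(seq_along(y), strata)

  point <- components_from_matrix(X, y, g, link, schemes, omega,
                                  detailed, at)

  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_stratum, function(i) {
      i[sample.int(length(i), replace = TRUE)]
    }), use.names = FALSE)
    val <- tryCatch(
      components_from_matrix(X[idx, , drop = FALSE], y[idx], g[idx], link,
                             schemes, omega, detailed, at),
      error = function(e) NULL
    )
    if (is.null(val)) {
      failed <- failed + 1L
    } else {
      # a variable group absent from a resample contributes exactly zero
      row <- structure(numeric(length(point)), names = names(point))
      common <- intersect(names(val), names(point))
      row[common] <- val[common]
      reps[b, ] <- row
    }
  }
  if (failed > 0.05 * B) {
    stop("more than 5% of bootstrap replicates failed to fit (", failed,
         " of ", B, ")", call. = FALSE)
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  alpha <- (1 - conf) / 2
  se <- apply(reps, 2L, stats::sd)
  ci <- apply(reps, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  tab <- data.frame(
    component = names(point),
    estimate = unname(point),
    se = unname(se),
    ci_low = ci[1L, ],
    ci_high = ci[2L, ],
    sig = ci[1L, ] > 0 | ci[2L, ] < 0,
    row.names = NULL
  )
  structure(
    list(table = tab, B = B, B_failed = failed, seed = seed, conf = conf,
         replicates = reps),
    class = "obd_inference"
  )
}

#' @export
print.obd_inference <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap inference: B = %d (%d failed), seed = %d\n",
              x$B, x$B_failed, x$seed))
  tab <- x$table
  for (cc in c("estimate", "se", "ci_low", "ci_high")) {
    tab[[cc]] <- round(tab[[cc]], digits)
  }
  tab$sig <- ifelse(tab$sig, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}
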