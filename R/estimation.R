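#' Build the outcome (or selection) design matrix
#'
#' Expands a term list into a model matrix with an intercept, using treatment
#' contrasts with the first level of each factor as the reference category.
#' Columns of known survey variables are coerced to the canonical level sets so
#' that designs built from different subsets of one table are column-compatible.
#'
#' @param table a survey `data.frame`.
#' @param terms character vector of term (column) names.
#' @return numeric matrix with an `"assign_term"` attribute mapping each column
#'   to the term that produced it.
#' @export
build_design <- function(table, terms) {
  missing <- setdiff(terms, names(table))
  if (length(missing)) {
    stop("design terms not found in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- table[terms]
  for (v in terms) {
    if (v %in% names(.obd_levels)) {
      if (!is.factor(df[[v]]) ||
          !identical(levels(df[[v]]), .obd_levels[[v]])) {
        bad <- setdiff(unique(as.character(df[[v]])), .obd_levels[[v]])
        if (length(bad)) {
          stop("column '", v, "' has unknown categories: ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        df[[v]] <- factor(as.character(df[[v]]), levels = .obd_levels[[v]])
      }
    }
  }
  mf <- stats::model.frame(stats::reformulate(terms), data = df,
                           na.action = stats::na.pass)
  X <- stats::model.matrix(stats::reformulate(terms), data = mf)
  tl <- attr(stats::terms(stats::reformulate(terms)), "term.labels")
  attr(X, "assign_term") <- c("(Intercept)", tl)[attr(X, "assign") + 1L]
  X
}

fit_glm_matrix <- function(X, y, link, weights = NULL) {
  fam <- if (link == "linear") stats::gaussian()
         else stats::binomial(link = link)
  w <- if (is.null(weights)) rep.int(1, length(y)) else weights
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = fam,
                   control = stats::glm.control(maxit = 100))
  )
  fit
}

glm_matrix_vcov <- function(fit, link) {
  p <- fit$rank
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  cov <- chol2inv(Rmat)
  dispersion <- if (link == "linear") {
    sum(fit$residuals^2 * fit$weights) / fit$df.residual
  } else 1
  cov <- cov * dispersion
  piv <- fit$qr$pivot[seq_len(p)]
  out <- matrix(NA_real_, length(fit$coefficients), length(fit$coefficients),
                dimnames = list(names(fit$coefficients),
                                names(fit$coefficients)))
  out[piv, piv] <- cov
  out
}

#' Fit the institutional-delivery model for one residence group
#'
#' Maximum-likelihood logit/probit (or ordinary least squares for the linear
#' link) restricted to the rows of one group. The design is built on the full
#' table so urban and rural fits share a column namespace; columns constant
#' over the full table are dropped (and recorded) when `drop_constant = TRUE`,
#' which is how per-year analyses shed the survey-year effect.
#'
#' @param table survey `data.frame` with an `outcome` column and a `residence`
#'   (or other `group_var`) column.
#' @param group the group level to fit, e.g. `"urban"`.
#' @param link `"logit"` (default), `"probit"` or `"linear"`.
#' @param terms outcome-equation terms; defaults to the canonical equation
#'   filtered to the columns present, plus `mills_ratio` when the table
#'   carries one.
#' @param group_var name of the grouping column.
#' @param drop_constant drop design columns with no variation in the full
#'   table.
#' @param drop_cols additional design columns to exclude (used by the
#'   pipeline so both group fits shed the same namespace).
#' @param weights optional non-negative case weights (e.g. sampling weights).
#' @return an object of class `obd_fit`: coefficients, covariance, group,
#'   link, `n_obs`, `converged`, and `design_meta` (term map, reference
#'   levels, dropped columns, complete-case drops).
#' @export
fit_group_model <- function(table, group, link = c("logit", "probit", "linear"),
                            terms = NULL, group_var = "residence",
                            drop_constant = TRUE, drop_cols = character(0),
                            weights = NULL) {
  link <- match.arg(link)
  if (!group_var %in% names(table)) {
    stop("grouping column '", group_var, "' not found", call. = FALSE)
  }
  if (is.null(terms)) terms <- default_outcome_terms(table)
  if (!"outcome" %in% names(table)) {
    stop("table has no 'outcome' column", call. = FALSE)
  }
  absent <- setdiff(terms, names(table))
  if (length(absent)) {
    stop("design terms not found in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  keep <- stats::complete.cases(table[c("outcome", terms, group_var)])
  n_dropped <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  X_all <- build_design(table, terms)
  dropped <- character(0)
  if (drop_constant) {
    const <- apply(X_all, 2L, function(col) length(unique(col)) == 1L)
    const["(Intercept)"] <- FALSE
    dropped <- colnames(X_all)[const]
  }
  dropped <- union(dropped, intersect(drop_cols, colnames(X_all)))
  if (length(dropped)) {
    keep_cols <- !colnames(X_all) %in% dropped
    at <- attr(X_all, "assign_term")[keep_cols]
    X_all <- X_all[, keep_cols, drop = FALSE]
    attr(X_all, "assign_term") <- at
  }

  rows <- table[[group_var]] == group
  if (!any(rows)) stop("no rows with ", group_var, " == '", group, "'",
                       call. = FALSE)
  X <- X_all[rows, , drop = FALSE]
  y <- table$outcome[rows]
  w <- if (is.null(weights)) NULL else weights[keep][rows]
  if (length(unique(y)) < 2L && link != "linear") {
    stop("outcome is single-class (all ", y[1],
         ") in group '", group, "'; model is degenerate", call. = FALSE)
  }

  fit <- fit_glm_matrix(X, y, link, w)
  if (!fit$converged) {
    stop("group '", group, "' model did not converge (possible separation)",
         call. = FALSE)
  }
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):ncol(X)]]
    stop("design is rank-deficient in group '", group, "'; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (link != "linear" &&
      all(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    stop("perfect separation in group '", group,
         "': all fitted probabilities are numerically 0 or 1", call. = FALSE)
  }

  ref <- lapply(.obd_levels[intersect(terms, names(.obd_levels))], `[`, 1L)
  structure(
    list(
      group = group,
      link = link,
      coefficients = fit$coefficients,
      vcov = glm_matrix_vcov(fit, link),
      n_obs = length(y),
      converged = TRUE,
      design_meta = list(
        terms = terms,
        assign_term = attr(X_all, "assign_term"),
        reference_levels = ref,
        dropped_constant = dropped,
        n_dropped_incomplete = n_dropped
      )
    ),
    class = "obd_fit"
  )
}

# design columns without variation inside either group: both fits must shed
# them so the decomposition keeps a shared namespace
group_constant_cols <- function(X, is_high) {
  const_in <- function(rows) {
    apply(X[rows, , drop = FALSE], 2L,
          function(col) length(unique(col)) == 1L)
  }
  const <- const_in(is_high) | const_in(!is_high)
  const["(Intercept)"] <- FALSE
  colnames(X)[const]
}

default_outcome_terms <- function(table) {
  tt <- .obd_outcome_terms[.obd_outcome_terms %in% names(table)]
  if ("mills_ratio" %in% names(table)) tt <- c(tt, "mills_ratio")
  tt
}

#' @export
print.obd_fit <- function(x, ...) {
  cat(sprintf("Group '%s' %s fit: n = %d, %d coefficients%s\n", x$group,
              x$link, x$n_obs, length(x$coefficients),
              if (length(x$design_meta$dropped_constant))
                paste0(" (dropped constant: ",
                       paste(x$design_meta$dropped_constant, collapse = ", "),
                       ")") else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.obd_fit <- function(object, ...) object$coefficients

#' @export
vcov.obd_fit <- function(object, ...) object$vcov

#' Export a fitted group model to JSON
#'
#' @param fit an `obd_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    group = fit$group, link = fit$link, n_obs = fit$n_obs,
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(sqrt(diag(fit$vcov))),
    reference_levels = fit$design_meta$reference_levels,
    dropped_constant = fit$design_meta$dropped_constant
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Inverse Mills ratio
#'
#' `lambda(z) = phi(z) / Phi(z)`, the hazard of the standard normal evaluated
#' from below: the expected truncation correction of the Heckman two-step
#' estimator. Computed on the log scale so it is accurate far into the left
#' tail (where the naive ratio underflows to 0/0).
#'
#' @param z numeric vector of selection-index values; must be finite.
#' @return strictly positive numeric vector of the same length.
#' @export
inverse_mills <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("`z` must be finite numeric", call. = FALSE)
  }
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

#' Heckman first stage: augment the birth sample with an inverse Mills ratio
#'
#' Fits the selection probit (dependent variable: a previous delivery) on the
#' full sample of women, computes the inverse Mills ratio at each selected
#' woman's fitted selection index, and returns the selected rows with a
#' `mills_ratio` column appended. Downstream outcome fits then include
#' `mills_ratio` as a regressor — the literal two-step procedure with the
#' Mills ratio added to the response equation (not a full-information
#' maximum-likelihood selection model).
#'
#' @param full_table `data.frame` of all women, with a 0/1 selection indicator
#'   column and the selection covariates.
#' @param selection_terms terms of the selection equation; defaults to age,
#'   education, wealth, religion, ethnicity, marital status, residence and
#'   contraceptive use.
#' @param selection_var name of the selection indicator column.
#' @return the selected rows with `mills_ratio` appended; the first-stage
#'   `obd_selection_fit` (gamma, `n_total`, `n_selected`) is attached as
#'   attribute `"selection_fit"`.
#' @export
heckman_augment <- function(full_table, selection_terms = .obd_selection_terms,
                            selection_var = "gave_birth") {
  if (!selection_var %in% names(full_table)) {
    stop("selection indicator column '", selection_var, "' not found",
         call. = FALSE)
  }
  missing <- setdiff(selection_terms, names(full_table))
  if (length(missing)) {
    stop("selection covariates not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(full_table[c(selection_var, selection_terms)])
  full_table <- full_table[keep, , drop = FALSE]
  s <- full_table[[selection_var]]
  if (!all(s %in% c(0, 1))) {
    stop("selection indicator must be 0/1", call. = FALSE)
  }
  W <- build_design(full_table, selection_terms)
  const <- apply(W, 2L, function(col) length(unique(col)) == 1L)
  const["(Intercept)"] <- FALSE
  W <- W[, !const, drop = FALSE]
  fit <- fit_glm_matrix(W, s, "probit")
  if (!fit$converged) stop("selection probit did not converge", call. = FALSE)
  if (anyNA(fit$coefficients)) {
    stop("selection probit is rank-deficient; aliased: ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)],
               collapse = ", "), call. = FALSE)
  }

  sel <- s == 1
  idx <- drop(W[sel, , drop = FALSE] %*% fit$coefficients)
  out <- full_table[sel, , drop = FALSE]
  out$mills_ratio <- inverse_mills(idx)
  rownames(out) <- NULL
  attr(out, "selection_fit") <- structure(
    list(gamma = fit$coefficients, n_total = length(s),
         n_selected = sum(sel), converged = TRUE),
    class = "obd_selection_fit"
  )
  out
}
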