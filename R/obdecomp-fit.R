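#' Decompose a binary-outcome gap between two groups
#'
#' The main fitting function. Fits the outcome model separately in the high
#' (urban) and low (rural) group, then decomposes the gap in mean predicted
#' outcome under the requested weighting schemes: three-fold
#' explained/unexplained/interaction for Oaxaca (urban reference) and Blinder
#' (rural reference), two-fold explained/advantage/disadvantage for Reimers
#' (equal weights) and Cotton (sample-share weights). The explained component
#' is further allocated across covariate groups by the detailed decomposition,
#' and bootstrap inference is attached when `boot > 0`.
#'
#' With the logit (default) and linear links the decomposition total equals
#' the raw difference in observed group outcome means exactly, by the score
#' identity of the intercept; for probit it matches approximately.
#'
#' @param formula outcome model, e.g.
#'   `outcome ~ education + wealth_quintile + parity`; the response must be
#'   0/1.
#' @param data a survey `data.frame` (see [generate_survey()] /
#'   [read_survey_csv()]).
#' @param group name of the binary grouping column (default `"residence"`).
#' @param high the group level treated as the high group; defaults to
#'   `"urban"` when present, otherwise the level with the higher outcome mean.
#' @param link `"logit"`, `"probit"` or `"linear"`.
#' @param schemes character vector of weighting schemes to report.
#' @param omega optional override of the two-fold weight.
#' @param heckman when `TRUE`, `data` must be a full sample with a
#'   `gave_birth` indicator; the Heckman first stage is run and the Mills
#'   ratio enters the outcome equation.
#' @param boot bootstrap replicates for inference (0 = none).
#' @param seed integer seed for the bootstrap.
#' @return an object of class `ob_decomp` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot` methods.
#' @examples
#' spec <- default_ghana_spec()
#' births <- generate_survey(spec, n = 2000, seed = 42)
#' fit <- ob_decompose(outcome ~ education + wealth_quintile + anc4 + parity,
#'                     data = births)
#' fit
#' @export
ob_decompose <- function(formula, data, group = "residence", high = NULL,
                         link = c("logit", "probit", "linear"),
                         schemes = c("oaxaca", "blinder", "reimers", "cotton"),
                         omega = NULL, heckman = FALSE, boot = 0L, seed = 1L) {
  link <- match.arg(link)
  cl <- match.call()
  tf <- stats::terms(formula)
  response <- as.character(attr(tf, "variables"))[attr(tf, "response") + 1L]
  terms <- attr(tf, "term.labels")
  if (!group %in% names(data)) {
    stop("grouping column '", group, "' not found", call. = FALSE)
  }

  selection_fit <- NULL
  if (isTRUE(heckman)) {
    data <- heckman_augment(data)
    selection_fit <- attr(data, "selection_fit")
    terms <- union(terms, "mills_ratio")
  }

  glev <- unique(as.character(data[[group]]))
  glev <- glev[!is.na(glev)]
  if (length(glev) != 2L) {
    stop("grouping column must have exactly 2 observed levels, found ",
         length(glev), call. = FALSE)
  }
  if (response != "outcome") data$outcome <- data[[response]]
  if (is.null(high)) {
    high <- if ("urban" %in% glev) "urban" else {
      means <- tapply(data$outcome, as.character(data[[group]]), mean,
                      na.rm = TRUE)
      names(means)[which.max(means)]
    }
  }
  low <- setdiff(glev, high)

  keep <- stats::complete.cases(data[c("outcome", terms, group)])
  dc <- data[keep, , drop = FALSE]
  X <- build_design(dc, terms)
  pre_drop <- group_constant_cols(X, as.character(dc[[group]]) == high)
  fit_u <- fit_group_model(data, high, link, terms, group_var = group,
                           drop_cols = pre_drop)
  fit_r <- fit_group_model(data, low, link, terms, group_var = group,
                           drop_cols = pre_drop)

  dropc <- fit_u$design_meta$dropped_constant
  if (length(dropc)) {
    at <- attr(X, "assign_term")[!colnames(X) %in% dropc]
    X <- X[, !colnames(X) %in% dropc, drop = FALSE]
    attr(X, "assign_term") <- at
  }
  gu <- as.character(dc[[group]]) == high
  X_u <- X[gu, , drop = FALSE]
  X_r <- X[!gu, , drop = FALSE]

  results <- lapply(schemes, function(sc) {
    decompose_scheme(fit_u, fit_r, X_u, X_r, sc, omega = omega)
  })
  names(results) <- schemes
  detailed <- detailed_explained(
    fit_u, fit_r, X_u, X_r,
    if (!is.null(omega)) omega else
      scheme_omega(schemes[1L], nrow(X_u), nrow(X_r)))

  inference <- NULL
  if (boot > 0L) {
    bd <- dc
    bd$residence <- factor(ifelse(gu, "urban", "rural"),
                           levels = .obd_levels$residence)
    inference <- bootstrap_components(bd, link = link, terms = terms,
                                      schemes = schemes, B = boot, seed = seed,
                                      omega = omega, detailed = TRUE)
  }

  linkinv <- obd_linkinv(link)
  fitted <- numeric(nrow(X))
  fitted[gu] <- linkinv(drop(X_u %*% fit_u$coefficients))
  fitted[!gu] <- linkinv(drop(X_r %*% fit_r$coefficients))

  structure(
    list(call = cl, link = link, group = group, high = high, low = low,
         terms = terms, fits = list(high = fit_u, low = fit_r),
         results = results, detailed = detailed, inference = inference,
         selection_fit = selection_fit,
         observed = c(high = mean(dc$outcome[gu]),
                      low = mean(dc$outcome[!gu])),
         n = c(high = sum(gu), low = sum(!gu)),
         fitted = fitted, y = dc$outcome,
         group_of_row = ifelse(gu, high, low)),
    class = "ob_decomp"
  )
}

#' @export
print.ob_decomp <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Decomposition of the %s gap in '%s' (%s link)\n", x$group, "outcome",
    x$link))
  cat(sprintf("  %s: n = %d, mean = %.4f;  %s: n = %d, mean = %.4f\n",
              x$high, x$n[["high"]], x$observed[["high"]],
              x$low, x$n[["low"]], x$observed[["low"]]))
  cat(sprintf("  raw gap (%s - %s): %.4f\n\n", x$high, x$low,
              x$observed[["high"]] - x$observed[["low"]]))
  sig_of <- function(sc, comp) {
    if (is.null(x$inference)) return("")
    key <- paste(sc, comp, sep = ".")
    m <- x$inference$table
    if (key %in% m$component && m$sig[m$component == key]) "*" else " "
  }
  for (sc in names(x$results)) {
    dec <- x$results[[sc]]
    w <- if (is.finite(dec$omega)) sprintf("weight = %.2f", dec$omega)
         else sprintf("reference = %s", dec$reference)
    cat(sprintf("%s decomposition (%s)\n", sc, w))
    for (comp in names(dec$components)) {
      cat(sprintf("  %-14s %8.*f%s %7.1f%%\n", comp, digits,
                  dec$components[[comp]], sig_of(sc, comp),
                  dec$percent[[comp]]))
    }
  }
  if (!is.null(x$inference)) {
    cat(sprintf("\n* percentile interval excludes 0 (level %.0f%%, B = %d)\n",
                100 * x$inference$conf, x$inference$B))
  }
  invisible(x)
}

#' @export
summary.ob_decomp <- function(object, ...) {
  structure(list(fit = object), class = "summary.ob_decomp")
}

#' @export
print.summary.ob_decomp <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$detailed)
  if (!is.null(x$fit$inference)) {
    cat("\n")
    print(x$fit$inference)
  }
  invisible(x)
}

#' @export
coef.ob_decomp <- function(object, which = c("components", "models"), ...) {
  which <- match.arg(which)
  if (which == "models") {
    cbind(high = object$fits$high$coefficients,
          low = object$fits$low$coefficients)
  } else {
    unlist(lapply(names(object$results), function(sc) {
      v <- object$results[[sc]]$components
      names(v) <- paste(sc, names(v), sep = ".")
      v
    }))
  }
}

#' @export
predict.ob_decomp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- build_design(newdata, object$terms)
  X <- X[, names(object$fits$high$coefficients), drop = FALSE]
  linkinv <- obd_linkinv(object$link)
  g <- as.character(newdata[[object$group]])
  p <- numeric(nrow(X))
  hi <- g == object$high
  p[hi] <- linkinv(drop(X[hi, , drop = FALSE] %*%
                          object$fits$high$coefficients))
  p[!hi] <- linkinv(drop(X[!hi, , drop = FALSE] %*%
                           object$fits$low$coefficients))
  p
}

#' @export
residuals.ob_decomp <- function(object, ...) {
  object$y - object$fitted
}

#' Plot decomposition components by scheme
#'
#' Grouped bar chart of the component estimates of every scheme in the fit,
#' with the common total drawn as a reference line.
#'
#' @param x an `ob_decomp`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ob_decomp <- function(x, ...) {
  comps <- c("explained", "unexplained", "interaction", "advantage",
             "disadvantage")
  mat <- sapply(x$results, function(dec) {
    v <- dec$components[comps]
    names(v) <- comps
    v
  })
  mat[is.na(mat)] <- 0
  total <- x$results[[1L]]$components[["total"]]
  graphics::barplot(mat, beside = TRUE, legend.text = rownames(mat),
                    ylab = "component (probability scale)",
                    main = "Gap decomposition by weighting scheme",
                    args.legend = list(x = "topright", bty = "n"), ...)
  graphics::abline(h = total, lty = 2)
  invisible(x)
}
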