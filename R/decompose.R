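#' Mean counterfactual outcome probability
#'
#' Evaluates `mean(linkinv(X beta))` over the rows of a design matrix: the
#' average predicted outcome if the rows were priced with the given
#' coefficient vector. All decomposition components are differences of such
#' means.
#'
#' @param coefficients named coefficient vector.
#' @param X design matrix whose column names match `names(coefficients)`
#'   (order-free; columns are matched by name).
#' @param link `"logit"`, `"probit"` or `"linear"`.
#' @return a single number; in \[0, 1\] for logit/probit.
#' @export
counterfactual_mean <- function(coefficients, X, link) {
  if (is.null(colnames(X)) || !setequal(colnames(X), names(coefficients))) {
    stop("coefficient names do not match design columns; missing from design: ",
         paste(setdiff(names(coefficients), colnames(X)), collapse = ", "),
         call. = FALSE)
  }
  X <- X[, names(coefficients), drop = FALSE]
  mean(obd_linkinv(link)(drop(X %*% coefficients)))
}

check_fit_pair <- function(fit_u, fit_r) {
  if (fit_u$link != fit_r$link) {
    stop("group fits use different links: ", fit_u$link, " vs ", fit_r$link,
         call. = FALSE)
  }
  if (!identical(names(fit_u$coefficients), names(fit_r$coefficients))) {
    stop("group fits do not share a term namespace", call. = FALSE)
  }
}

new_decomposition <- function(scheme, kind, components, omega = NA_real_,
                              reference = NA_character_, se = NULL) {
  total <- components[["total"]]
  percent <- if (is.finite(total) && total != 0) {
    100 * components / total
  } else {
    components * NA_real_
  }
  structure(
    list(scheme = scheme, kind = kind, omega = omega, reference = reference,
         components = components, percent = percent, se = se),
    class = "obd_decomposition"
  )
}

#' Three-fold decomposition of the group gap
#'
#' Splits the urban-minus-rural gap in mean predicted outcome into explained
#' (endowments), unexplained (coefficients) and interaction components under a
#' reference group. With the urban (high-group) reference, endowment
#' differences are priced at urban coefficients and coefficient differences at
#' urban covariates; with the rural reference, both are priced at rural
#' quantities. The three components sum to the total gap by construction, for
#' any link.
#'
#' @param fit_u,fit_r `obd_fit` objects for the urban (high) and rural (low)
#'   groups, sharing link and term namespace.
#' @param X_u,X_r design matrices of the two groups.
#' @param reference `"urban"` or `"rural"`.
#' @return an `obd_decomposition` with components `total`, `explained`,
#'   `unexplained`, `interaction` and their percentages of total.
#' @export
threefold <- function(fit_u, fit_r, X_u, X_r, reference = c("urban", "rural")) {
  reference <- match.arg(reference)
  check_fit_pair(fit_u, fit_r)
  link <- fit_u$link
  b_u <- fit_u$coefficients
  b_r <- fit_r$coefficients
  m_uu <- counterfactual_mean(b_u, X_u, link)
  m_ur <- counterfactual_mean(b_u, X_r, link)
  m_ru <- counterfactual_mean(b_r, X_u, link)
  m_rr <- counterfactual_mean(b_r, X_r, link)
  total <- m_uu - m_rr
  if (reference == "urban") {
    explained <- m_uu - m_ur
    unexplained <- m_uu - m_ru
  } else {
    explained <- m_ru - m_rr
    unexplained <- m_ur - m_rr
  }
  interaction <- total - explained - unexplained
  new_decomposition(
    scheme = if (reference == "urban") "oaxaca" else "blinder",
    kind = "threefold",
    components = c(total = total, explained = explained,
                   unexplained = unexplained, interaction = interaction),
    reference = reference
  )
}

#' Two-fold decomposition with a pooled coefficient vector
#'
#' Prices endowment differences with the blended coefficient vector
#' `beta* = omega * beta_urban + (1 - omega) * beta_rural` and splits the
#' remaining (unexplained) part into urban advantage — the deviation of the
#' urban group's own coefficients above the pooled norm — and rural
#' disadvantage — the deviation of the rural group's below it.
#'
#' @inheritParams threefold
#' @param omega weight on the urban coefficient vector, in \[0, 1\]; see
#'   [scheme_weight()].
#' @param scheme label stored on the result (`"reimers"`, `"cotton"`, or a
#'   custom tag).
#' @return an `obd_decomposition` with components `total`, `explained`,
#'   `advantage`, `disadvantage`.
#' @export
twofold <- function(fit_u, fit_r, X_u, X_r, omega, scheme = "pooled") {
  check_fit_pair(fit_u, fit_r)
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) ||
      omega < 0 || omega > 1) {
    stop("omega must be a single number in [0, 1]", call. = FALSE)
  }
  link <- fit_u$link
  b_u <- fit_u$coefficients
  b_r <- fit_r$coefficients
  b_s <- omega * b_u + (1 - omega) * b_r
  m_uu <- counterfactual_mean(b_u, X_u, link)
  m_rr <- counterfactual_mean(b_r, X_r, link)
  m_su <- counterfactual_mean(b_s, X_u, link)
  m_sr <- counterfactual_mean(b_s, X_r, link)
  new_decomposition(
    scheme = scheme, kind = "twofold", omega = omega,
    components = c(total = m_uu - m_rr,
                   explained = m_su - m_sr,
                   advantage = m_uu - m_su,
                   disadvantage = m_sr - m_rr)
  )
}

#' Coefficient weight implied by a decomposition scheme
#'
#' Oaxaca prices endowments entirely at the high (urban) group's coefficients
#' (`omega = 1`), Blinder entirely at the low (rural) group's (`omega = 0`),
#' Reimers at the equally weighted mean (`omega = 0.5`), and Cotton at the
#' groups' sample shares (`omega = n_u / (n_u + n_r)` on the urban vector).
#' For Cotton the complementary rural share — the weight conventionally
#' printed in reports — is attached as attribute `"rural_share"`.
#'
#' @param scheme one of `"oaxaca"`, `"blinder"`, `"reimers"`, `"cotton"`.
#' @param n_u,n_r group sample sizes (used only by Cotton).
#' @return the weight on the urban coefficient vector.
#' @export
scheme_weight <- function(scheme, n_u = NULL, n_r = NULL) {
  valid <- c("oaxaca", "blinder", "reimers", "cotton")
  if (!is.character(scheme) || length(scheme) != 1L || !scheme %in% valid) {
    stop("unknown scheme '", paste(scheme, collapse = ","),
         "'; valid schemes: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  switch(scheme,
    oaxaca = 1,
    blinder = 0,
    reimers = 0.5,
    cotton = {
      if (is.null(n_u) || is.null(n_r) || n_u < 1 || n_r < 1) {
        stop("cotton weight needs group sizes n_u, n_r >= 1", call. = FALSE)
      }
      w <- n_u / (n_u + n_r)
      attr(w, "rural_share") <- n_r / (n_u + n_r)
      w
    }
  )
}

#' Decompose under a named scheme
#'
#' Dispatches to [threefold()] for Oaxaca/Blinder and to [twofold()] with the
#' scheme's weight for Reimers/Cotton.
#'
#' @inheritParams threefold
#' @param scheme scheme label; see [scheme_weight()].
#' @param omega optional override of the scheme's weight (two-fold only).
#' @return an `obd_decomposition`.
#' @export
decompose_scheme <- function(fit_u, fit_r, X_u, X_r, scheme,
                             omega = NULL) {
  if (scheme == "oaxaca") return(threefold(fit_u, fit_r, X_u, X_r, "urban"))
  if (scheme == "blinder") return(threefold(fit_u, fit_r, X_u, X_r, "rural"))
  w <- if (!is.null(omega)) omega
       else scheme_weight(scheme, nrow(X_u), nrow(X_r))
  res <- twofold(fit_u, fit_r, X_u, X_r, as.numeric(w), scheme = scheme)
  if (!is.null(attr(w, "rural_share"))) {
    res$rural_share <- attr(w, "rural_share")
  }
  res
}

scheme_omega <- function(scheme, n_u, n_r) {
  as.numeric(scheme_weight(scheme, n_u, n_r))
}

#' Audit the adding-up identity of reported components
#'
#' Checks that decomposition components sum to the stated total within a
#' tolerance — the identity every printed decomposition row must satisfy.
#' Supply either the three-fold components (`unexplained`, `interaction`) or
#' the two-fold ones (`advantage`, `disadvantage`).
#'
#' @param total the reported total gap.
#' @param explained explained (endowment) component.
#' @param unexplained,interaction three-fold components.
#' @param advantage,disadvantage two-fold components.
#' @param tol tolerance; use e.g. `1.5e-3` for values printed to 3 decimals.
#' @return list with `ok` (logical), `sum` of components, and `discrepancy`.
#' @export
audit_components <- function(total, explained, unexplained = NULL,
                             interaction = NULL, advantage = NULL,
                             disadvantage = NULL, tol = 1e-10) {
  parts <- c(explained, unexplained, interaction, advantage, disadvantage)
  s <- sum(parts)
  list(ok = abs(s - total) <= tol, sum = s, discrepancy = s - total)
}

#' Detailed decomposition of the explained component
#'
#' Allocates the explained component across covariates (or covariate groups)
#' by linearization weights: each design column's endowment-gap value
#' `W_k = dxbar_k * beta*_k / sum_j dxbar_j * beta*_j` scales the non-linear
#' explained component, so the allocation is exact for the linear link and is
#' the standard detailed method for logit/probit decompositions. Contributions
#' are aggregated within variable groups (all dummies of one categorical
#' variable together); the Mills ratio, when present, is its own group.
#'
#' Note that contributions of categorical variables depend on the reference
#' category; references are fixed and recorded in each fit's `design_meta`.
#'
#' @inheritParams twofold
#' @param variable_groups optional named list mapping group labels to design
#'   column names; must partition the non-intercept columns. Defaults to one
#'   group per model term.
#' @return an `obd_detailed`: data.frame of per-group `contribution` and
#'   `share` of explained, plus the `explained` total and the numerical
#'   `residual` (zero by construction of the weights).
#' @export
detailed_explained <- function(fit_u, fit_r, X_u, X_r, omega,
                               variable_groups = NULL) {
  check_fit_pair(fit_u, fit_r)
  link <- fit_u$link
  b_s <- omega * fit_u$coefficients + (1 - omega) * fit_r$coefficients
  nm <- names(b_s)
  X_u <- X_u[, nm, drop = FALSE]
  X_r <- X_r[, nm, drop = FALSE]
  explained <- counterfactual_mean(b_s, X_u, link) -
    counterfactual_mean(b_s, X_r, link)

  keep <- setdiff(nm, "(Intercept)")
  dx <- colMeans(X_u)[keep] - colMeans(X_r)[keep]
  d_k <- dx * b_s[keep]

  if (is.null(variable_groups)) {
    at <- fit_u$design_meta$assign_term
    names(at) <- nm
    variable_groups <- split(keep, factor(at[keep], levels = unique(at[keep])))
  } else {
    flat <- unlist(variable_groups, use.names = FALSE)
    if (!setequal(flat, keep) || anyDuplicated(flat)) {
      stop("variable_groups must partition the non-intercept design columns",
           call. = FALSE)
    }
  }

  denom <- sum(d_k)
  if (denom == 0) {
    warning("no endowment differences priced by beta*; all contributions zero",
            call. = FALSE)
    contrib <- vapply(variable_groups, function(cols) 0, numeric(1))
  } else {
    contrib <- vapply(variable_groups,
                      function(cols) sum(d_k[cols]) / denom * explained,
                      numeric(1))
  }
  residual <- explained - sum(contrib)
  shares <- explained_shares(contrib, explained)
  structure(
    list(
      table = data.frame(variable_group = names(variable_groups),
                         contribution = unname(contrib),
                         share = unname(shares),
                         row.names = NULL),
      explained = explained,
      residual = residual,
      omega = omega
    ),
    class = "obd_detailed"
  )
}

#' Share of the explained component attributable to a contribution
#'
#' @param contributions numeric vector of per-variable contributions.
#' @param explained the explained component they decompose.
#' @return `contributions / explained` (fractions of the explained component),
#'   `NA` when `explained` is zero.
#' @export
explained_shares <- function(contributions, explained) {
  if (!is.finite(explained) || explained == 0) {
    return(rep(NA_real_, length(contributions)))
  }
  contributions / explained
}

#' @export
print.obd_decomposition <- function(x, digits = 3, ...) {
  hdr <- sprintf("%s decomposition (%s%s)", x$scheme,
                 x$kind,
                 if (is.finite(x$omega)) sprintf(", weight on urban = %.3f",
                                                 x$omega) else
                   sprintf(", reference = %s", x$reference))
  cat(hdr, "\n")
  tab <- data.frame(
    coefficient = round(x$components, digits),
    percent = round(x$percent, 1)
  )
  print(tab)
  invisible(x)
}

#' @export
print.obd_detailed <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Detailed decomposition of the explained component (%.3f), omega = %.3f\n",
    x$explained, x$omega))
  tab <- x$table
  tab$contribution <- round(tab$contribution, digits)
  tab$share_pct <- round(100 * tab$share, 1)
  tab$share <- NULL
  print(tab, row.names = FALSE)
  if (abs(x$residual) > 1e-10) {
    cat(sprintf("  residual: %.3g\n", x$residual))
  }
  invisible(x)
}
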