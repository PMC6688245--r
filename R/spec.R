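#' Specify a synthetic survey population
#'
#' A `population_spec` fully parameterizes the data-generating process for a
#' DHS-like table of most-recent births: the rural share of births, per-group
#' covariate distributions, link-scale coefficient vectors for the
#' institutional-delivery index of each residence group, and (optionally) a
#' probit selection equation whose latent error is correlated with the outcome
#' error, so that Heckman-type corrections have a recoverable signal.
#'
#' Covariate distributions are supplied per group (`urban`, `rural`) as a named
#' list. Categorical variables take a probability vector named by the canonical
#' levels (see [survey_levels()]); binary variables a single probability;
#' `parity` a mean (parity is drawn as `1 + Poisson(mean - 1)`, so every woman
#' in the birth sample has at least one child); `anc_visits` a vector
#' `c(mu = , size = )` for a negative-binomial visit count (the `anc4`
#' four-plus-visits indicator is derived from it).
#'
#' @param group_share_rural probability that a birth occurs in a rural area.
#' @param covariates list with elements `urban` and `rural`, each a named list
#'   of covariate distributions as described above.
#' @param beta_urban,beta_rural named link-scale coefficient vectors over the
#'   outcome design columns implied by `outcome_terms` (see
#'   [design_colnames()]); must include `"(Intercept)"`.
#' @param gamma_selection optional named coefficient vector for the selection
#'   probit over the columns implied by `selection_terms`.
#' @param link one of `"logit"`, `"probit"`, `"linear"`.
#' @param rho_selection correlation in (-1, 1) between the selection and
#'   outcome latent errors; 0 means selection is ignorable.
#' @param outcome_terms,selection_terms character vectors of term names; the
#'   defaults are the full institutional-delivery and previous-birth selection
#'   equations.
#' @return an object of class `population_spec`.
#' @seealso [generate_survey()], [generate_population()],
#'   [population_components()], [default_ghana_spec()]
#' @export
population_spec <- function(group_share_rural, covariates, beta_urban,
                            beta_rural, gamma_selection = NULL,
                            link = c("logit", "probit", "linear"),
                            rho_selection = 0,
                            outcome_terms = .obd_outcome_terms,
                            selection_terms = .obd_selection_terms) {
  link <- match.arg(link)
  spec <- structure(
    list(
      group_share_rural = group_share_rural,
      covariates = covariates,
      beta_urban = beta_urban,
      beta_rural = beta_rural,
      gamma_selection = gamma_selection,
      link = link,
      rho_selection = rho_selection,
      outcome_terms = outcome_terms,
      selection_terms = selection_terms
    ),
    class = "population_spec"
  )
  validate_population_spec(spec)
}

#' Validate a population specification
#'
#' Checks every invariant of the type: categorical probability vectors sum to
#' one (within 1e-12) over the canonical levels, binary probabilities lie in
#' \[0, 1\], the rural share lies strictly inside (0, 1), and the coefficient
#' vectors share one name space with the design produced from the covariates.
#' Errors name the offending field.
#'
#' @param spec a `population_spec`.
#' @return `spec`, invisibly unchanged, if valid.
#' @export
validate_population_spec <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  fail <- function(field, msg) {
    stop("invalid population_spec: field '", field, "' ", msg, call. = FALSE)
  }

  gsr <- spec$group_share_rural
  if (!is.numeric(gsr) || length(gsr) != 1L || !is.finite(gsr) ||
      gsr <= 0 || gsr >= 1) {
    fail("group_share_rural", "must be a probability strictly inside (0, 1)")
  }
  if (!spec$link %in% obd_links) fail("link", "must be logit, probit or linear")
  rho <- spec$rho_selection
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho <= -1 || rho >= 1) {
    fail("rho_selection", "must lie strictly inside (-1, 1)")
  }

  if (!is.list(spec$covariates) ||
      !all(c("urban", "rural") %in% names(spec$covariates))) {
    fail("covariates", "must be a list with elements 'urban' and 'rural'")
  }
  for (grp in c("urban", "rural")) {
    cv <- spec$covariates[[grp]]
    for (v in names(cv)) {
      field <- paste0("covariates$", grp, "$", v)
      p <- cv[[v]]
      if (v %in% names(.obd_levels)) {
        lv <- .obd_levels[[v]]
        if (length(p) != length(lv) || !identical(names(p), lv)) {
          fail(field, paste0("must be a probability vector named by levels: ",
                             paste(lv, collapse = ", ")))
        }
        if (any(p < 0)) fail(field, "has negative probabilities")
        if (abs(sum(p) - 1) > 1e-12) {
          fail(field, sprintf("probabilities sum to %.15f, not 1", sum(p)))
        }
      } else if (v %in% .obd_binary) {
        if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
          fail(field, "must be a single probability in [0, 1]")
        }
      } else if (v == "parity") {
        if (!is.numeric(p) || length(p) != 1L || p < 1) {
          fail(field, "must be a mean parity >= 1")
        }
      } else if (v == "anc_visits") {
        if (!is.numeric(p) || !all(c("mu", "size") %in% names(p)) ||
            p[["mu"]] <= 0 || p[["size"]] <= 0) {
          fail(field, "must be c(mu = , size = ) with positive entries")
        }
      } else {
        fail(field, "is not a recognized covariate")
      }
    }
    # every outcome/selection term must be drawable for this group
    need <- setdiff(spec$outcome_terms, c("anc4", "residence"))
    need <- sub("^anc4$", "anc_visits", need)
    if ("anc4" %in% spec$outcome_terms) need <- union(need, "anc_visits")
    missing <- setdiff(need, names(cv))
    if (length(missing)) {
      fail(paste0("covariates$", grp),
           paste0("lacks distributions for outcome terms: ",
                  paste(missing, collapse = ", ")))
    }
  }

  want <- design_colnames(spec$outcome_terms)
  for (b in c("beta_urban", "beta_rural")) {
    bv <- spec[[b]]
    if (!is.numeric(bv) || !identical(names(bv), want)) {
      fail(b, paste0("must be a named numeric vector with columns, in order: ",
                     paste(want, collapse = ", ")))
    }
    if (!all(is.finite(bv))) fail(b, "contains non-finite values")
  }

  if (!is.null(spec$gamma_selection)) {
    wantg <- design_colnames(spec$selection_terms)
    gv <- spec$gamma_selection
    if (!is.numeric(gv) || !identical(names(gv), wantg)) {
      fail("gamma_selection",
           paste0("must be a named numeric vector with columns, in order: ",
                  paste(wantg, collapse = ", ")))
    }
  }
  invisible(spec)
}

#' Canonical variable levels of the survey table
#'
#' @return named list of factor levels used by the generator, CSV reader and
#'   design builder; the first level of each variable is its reference
#'   category.
#' @export
survey_levels <- function() .obd_levels

#' @export
print.population_spec <- function(x, ...) {
  cat("Synthetic survey population specification\n")
  cat(sprintf("  link: %s   rural share of births: %.3f   rho_selection: %.2f\n",
              x$link, x$group_share_rural, x$rho_selection))
  cat(sprintf("  outcome terms (%d): %s\n", length(x$outcome_terms),
              paste(x$outcome_terms, collapse = ", ")))
  if (!is.null(x$gamma_selection)) {
    cat(sprintf("  selection terms (%d): %s\n", length(x$selection_terms),
                paste(x$selection_terms, collapse = ", ")))
  } else {
    cat("  no selection equation\n")
  }
  invisible(x)
}

#' Write / read a population specification as a YAML config file
#'
#' The on-disk form is a plain human-readable key-value file; numeric vectors
#' keep their names so the file can be edited by hand and read back.
#'
#' @param spec a `population_spec`.
#' @param path file path.
#' @return `write_spec_config` returns `path` invisibly; `read_spec_config`
#'   returns a validated `population_spec`.
#' @export
write_spec_config <- function(spec, path) {
  validate_population_spec(spec)
  as_kv <- function(v) as.list(v)  # yaml keeps names for named lists
  obj <- list(
    group_share_rural = spec$group_share_rural,
    link = spec$link,
    rho_selection = spec$rho_selection,
    outcome_terms = spec$outcome_terms,
    selection_terms = spec$selection_terms,
    covariates = lapply(spec$covariates, function(cv) lapply(cv, as_kv)),
    beta_urban = as_kv(spec$beta_urban),
    beta_rural = as_kv(spec$beta_rural),
    gamma_selection = if (is.null(spec$gamma_selection)) NULL
                      else as_kv(spec$gamma_selection)
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  as_vec <- function(l) {
    if (is.null(l)) return(NULL)
    v <- unlist(l)
    storage.mode(v) <- "double"
    v
  }
  restore_cv <- function(cv) {
    lapply(cv, function(x) {
      v <- unlist(x)
      storage.mode(v) <- "double"
      if (length(v) == 1L && is.null(names(x))) v <- unname(v)
      v
    })
  }
  population_spec(
    group_share_rural = obj$group_share_rural,
    covariates = lapply(obj$covariates, restore_cv),
    beta_urban = as_vec(obj$beta_urban),
    beta_rural = as_vec(obj$beta_rural),
    gamma_selection = as_vec(obj$gamma_selection),
    link = obj$link,
    rho_selection = obj$rho_selection,
    outcome_terms = unlist(obj$outcome_terms),
    selection_terms = unlist(obj$selection_terms)
  )
}
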