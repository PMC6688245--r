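#' Write / read a survey table as CSV
#'
#' The on-disk header is the canonical column dictionary: `outcome`,
#' `residence`, the covariates of the delivery equation plus marital status
#' and contraceptive use, and optional `mills_ratio` / `sampling_weight` /
#' `gave_birth` columns. `read_survey_csv` validates every row: the outcome
#' and binary flags must be 0/1, categorical values must be known levels,
#' counts non-negative, Mills ratios strictly positive — violations are
#' reported with their row numbers.
#'
#' @param table a survey `data.frame`.
#' @param path CSV file path.
#' @param dictionary optional named character vector mapping canonical roles
#'   to the file's column names, e.g. `c(outcome = "inst_delivery")`; columns
#'   are renamed on read.
#' @return `write_survey_csv` returns `path` invisibly; `read_survey_csv`
#'   returns a validated `data.frame` with canonical factor levels and an
#'   `anc4` indicator derived from `anc_visits` if absent.
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, dictionary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty survey file: ", path, call. = FALSE)
  if (!is.null(dictionary)) {
    for (role in names(dictionary)) {
      src <- dictionary[[role]]
      if (!src %in% names(df)) {
        stop("dictionary column '", src, "' (role '", role,
             "') not found in file", call. = FALSE)
      }
      names(df)[names(df) == src] <- role
    }
  }
  for (col in c("outcome", "residence")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing from survey file: ", col, call. = FALSE)
    }
  }

  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      stop("invalid ", what, " on row(s) ",
           paste(utils::head(which(!ok), 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_rows(df$outcome %in% c(0, 1), "outcome (must be 0/1)")
  for (v in intersect(names(.obd_levels), names(df))) {
    bad_rows(as.character(df[[v]]) %in% .obd_levels[[v]],
             paste0(v, " category"))
    df[[v]] <- factor(as.character(df[[v]]), levels = .obd_levels[[v]])
  }
  for (v in intersect(c(.obd_binary, "anc4", "gave_birth"), names(df))) {
    bad_rows(df[[v]] %in% c(0, 1), paste0(v, " (must be 0/1)"))
  }
  for (v in intersect(.obd_counts, names(df))) {
    bad_rows(is.finite(df[[v]]) & df[[v]] >= 0, paste0(v, " (negative count)"))
  }
  if ("parity" %in% names(df)) bad_rows(df$parity >= 1, "parity (must be >= 1)")
  if ("mills_ratio" %in% names(df)) {
    bad_rows(is.finite(df$mills_ratio) & df$mills_ratio > 0,
             "mills_ratio (must be > 0)")
  }
  if ("sampling_weight" %in% names(df)) {
    bad_rows(is.finite(df$sampling_weight) & df$sampling_weight > 0,
             "sampling_weight (must be > 0)")
  }
  if (!"anc4" %in% names(df) && "anc_visits" %in% names(df)) {
    df$anc4 <- as.integer(df$anc_visits >= 4L)
  }
  df
}

#' Descriptive statistics by residence
#'
#' Percentages for each categorical level, means for parity and antenatal
#' visits, and the institutional-delivery rate, tabulated for rural and urban
#' women with an urban-minus-rural gap column in percentage points (for
#' percentages and the outcome rate) or raw units (for means).
#'
#' @param table survey `data.frame`.
#' @param by_year also compute the per-survey-year breakdown.
#' @return an `obd_descriptives`: data.frame with columns `variable`, `level`,
#'   `statistic`, `rural`, `urban`, `gap` (and a `window` column when
#'   `by_year`); groups absent from the table yield `NA` with the gap flagged
#'   `NA`.
#' @export
descriptives <- function(table, by_year = FALSE) {
  stopifnot(nrow(table) >= 1L)
  one_window <- function(tab, window) {
    rows <- list()
    grp <- function(g) tab[as.character(tab$residence) == g, , drop = FALSE]
    rural <- grp("rural"); urban <- grp("urban")
    pct <- function(x, lev) {
      if (length(x) == 0L) return(NA_real_)
      100 * mean(as.character(x) == lev)
    }
    add <- function(variable, level, statistic, r, u) {
      rows[[length(rows) + 1L]] <<- data.frame(
        window = window, variable = variable, level = level,
        statistic = statistic, rural = r, urban = u, gap = u - r)
    }
    add("outcome", "institutional delivery", "percent",
        if (nrow(rural)) 100 * mean(rural$outcome) else NA_real_,
        if (nrow(urban)) 100 * mean(urban$outcome) else NA_real_)
    for (v in intersect(names(.obd_levels), names(tab))) {
      if (v == "residence") next
      for (lev in .obd_levels[[v]]) {
        add(v, lev, "percent", pct(rural[[v]], lev), pct(urban[[v]], lev))
      }
    }
    for (v in intersect(c(.obd_counts, .obd_binary, "anc4"), names(tab))) {
      stat <- if (v %in% .obd_counts) "mean" else "percent"
      scale <- if (stat == "percent") 100 else 1
      add(v, v, stat,
          if (nrow(rural)) scale * mean(rural[[v]]) else NA_real_,
          if (nrow(urban)) scale * mean(urban[[v]]) else NA_real_)
    }
    do.call(rbind, rows)
  }
  out <- one_window(table, "pooled")
  if (by_year && "survey_year" %in% names(table)) {
    for (yr in sort(unique(as.character(table$survey_year)))) {
      out <- rbind(out,
                   one_window(table[as.character(table$survey_year) == yr, ,
                                    drop = FALSE], yr))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("obd_descriptives", "data.frame"))
}

#' @export
print.obd_descriptives <- function(x, digits = 1, ...) {
  tab <- as.data.frame(x)
  for (cc in c("rural", "urban", "gap")) tab[[cc]] <- round(tab[[cc]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

# deterministic rolling hash of a string (mod 2^31 - 1), for provenance blocks
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full decomposition analysis
#'
#' Ties the stages together: load (or simulate) the survey table, then for the
#' pooled sample and each survey year present, fit the two group models,
#' compute the overall decomposition under every requested scheme, the
#' detailed decomposition of the explained component, and (when `B > 0`)
#' bootstrap inference; write Table-2-style and Table-3-style CSVs, a JSON
#' report with a provenance block, and a log. Identical config and seed
#' reproduce identical outputs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{input}{either `list(csv = path, dictionary = NULL)` or
#'       `list(spec = population_spec, n = rows)`.}
#'     \item{link}{`"logit"` (default), `"probit"` or `"linear"`.}
#'     \item{schemes}{character vector, default all four.}
#'     \item{terms}{optional outcome-equation terms.}
#'     \item{heckman}{logical; when `TRUE` the input must carry a
#'       `gave_birth` indicator and the selection covariates, and the table
#'       is Mills-augmented before estimation.}
#'     \item{B}{bootstrap replicates, 0 to skip inference.}
#'     \item{seed}{integer seed.}
#'     \item{outdir}{output directory (created if needed).}
#'   }
#' @return an `obd_report`: descriptives, per-window results, detailed
#'   contributions, inference, and provenance; written files are listed in
#'   `$files`.
#' @export
run_analysis <- function(config) {
  cfg <- utils::modifyList(
    list(link = "logit", schemes = c("oaxaca", "blinder", "reimers", "cotton"),
         terms = NULL, heckman = FALSE, B = 0L, seed = 1L, outdir = NULL),
    config)
  stage <- "configuration"
  log_lines <- character(0)
  logit <- function(...) {
    log_lines[length(log_lines) + 1L] <<- sprintf(...)
  }
  written <- character(0)
  on_error <- function(e) {
    for (f in written) unlink(f)
    stop("analysis failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    stage <- "input"
    if (!is.null(cfg$input$csv)) {
      table <- read_survey_csv(cfg$input$csv, cfg$input$dictionary)
      logit("read %d rows from %s", nrow(table), cfg$input$csv)
    } else if (!is.null(cfg$input$spec)) {
      gen <- if (isTRUE(cfg$heckman)) generate_population else generate_survey
      table <- gen(cfg$input$spec, cfg$input$n, cfg$seed)
      logit("simulated %d rows (seed %d)", nrow(table), cfg$seed)
    } else {
      stop("config$input must supply either a csv path or a spec")
    }

    selection_fit <- NULL
    if (isTRUE(cfg$heckman)) {
      stage <- "selection"
      table <- heckman_augment(table)
      selection_fit <- attr(table, "selection_fit")
      logit("Heckman stage 1: %d of %d women selected",
            selection_fit$n_selected, selection_fit$n_total)
    }

    stage <- "descriptives"
    desc <- descriptives(table, by_year = TRUE)

    windows <- "pooled"
    if ("survey_year" %in% names(table) &&
        length(unique(table$survey_year)) > 1L) {
      windows <- c(windows, sort(unique(as.character(table$survey_year))))
    }

    results <- list()
    for (wi in seq_along(windows)) {
      win <- windows[wi]
      stage <- paste0("estimation (", win, ")")
      tab <- if (win == "pooled") table else
        table[as.character(table$survey_year) == win, , drop = FALSE]
      terms <- if (is.null(cfg$terms)) default_outcome_terms(tab) else cfg$terms

      keep <- stats::complete.cases(tab[c("outcome", terms, "residence")])
      tabc <- tab[keep, , drop = FALSE]
      X <- build_design(tabc, terms)
      dropc <- group_constant_cols(X, tabc$residence == "urban")
      fit_u <- fit_group_model(tab, "urban", cfg$link, terms,
                               drop_cols = dropc)
      fit_r <- fit_group_model(tab, "rural", cfg$link, terms,
                               drop_cols = dropc)
      dropc <- fit_u$design_meta$dropped_constant
      if (length(dropc)) {
        logit("[%s] dropped constant columns: %s", win,
              paste(dropc, collapse = ", "))
      }
      logit("[%s] n_urban = %d, n_rural = %d (%d incomplete rows dropped)",
            win, fit_u$n_obs, fit_r$n_obs,
            fit_u$design_meta$n_dropped_incomplete)

      if (length(dropc)) {
        at <- attr(X, "assign_term")[!colnames(X) %in% dropc]
        X <- X[, !colnames(X) %in% dropc, drop = FALSE]
        attr(X, "assign_term") <- at
      }
      X_u <- X[tabc$residence == "urban", , drop = FALSE]
      X_r <- X[tabc$residence == "rural", , drop = FALSE]

      stage <- paste0("decomposition (", win, ")")
      overall <- lapply(cfg$schemes, function(sc) {
        decompose_scheme(fit_u, fit_r, X_u, X_r, sc)
      })
      names(overall) <- cfg$schemes
      det <- detailed_explained(
        fit_u, fit_r, X_u, X_r,
        scheme_omega(cfg$schemes[1L], nrow(X_u), nrow(X_r)))

      inference <- NULL
      if (cfg$B > 0L) {
        stage <- paste0("inference (", win, ")")
        inference <- bootstrap_components(
          tabc, link = cfg$link, terms = terms, schemes = cfg$schemes,
          B = cfg$B, seed = cfg$seed + wi, detailed = TRUE)
        inference$replicates <- NULL  # keep the report light
      }

      results[[win]] <- list(window = win, fit_urban = fit_u, fit_rural = fit_r,
                             overall = overall, detailed = det,
                             inference = inference)
    }

    stage <- "report"
    cfg_echo <- cfg[setdiff(names(cfg), c("input", "outdir"))]
    cfg_str <- paste(utils::capture.output(utils::str(cfg_echo)),
                     collapse = "\n")
    provenance <- list(
      seed = cfg$seed,
      config_hash = config_hash(cfg_str),
      n_rows = nrow(table),
      n_urban = sum(table$residence == "urban"),
      n_rural = sum(table$residence == "rural"),
      windows = windows
    )
    report <- structure(
      list(descriptives = desc, results = results,
           selection_fit = selection_fit, provenance = provenance,
           config = cfg_echo, log = log_lines,
           files = character(0)),
      class = "obd_report")

    if (!is.null(cfg$outdir)) {
      stage <- "write"
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(cfg$outdir,
                         c("overall.csv", "detailed.csv", "descriptives.csv",
                           "report.json", "analysis.log"))
      written <- paths
      utils::write.csv(report_overall_table(report), paths[1L],
                       row.names = FALSE)
      utils::write.csv(report_detailed_table(report), paths[2L],
                       row.names = FALSE)
      utils::write.csv(as.data.frame(desc), paths[3L], row.names = FALSE)
      jsonlite::write_json(report_json(report), paths[4L], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      writeLines(log_lines, paths[5L])
      report$files <- paths
    }
    report
  }, error = on_error)
}

# long Table-2-style data.frame: window x scheme x component
report_overall_table <- function(report) {
  rows <- list()
  for (res in report$results) {
    inf <- if (!is.null(res$inference)) res$inference$table else NULL
    for (sc in names(res$overall)) {
      dec <- res$overall[[sc]]
      for (comp in names(dec$components)) {
        row <- data.frame(
          window = res$window, scheme = sc,
          omega = if (is.finite(dec$omega)) dec$omega
                  else if (sc == "oaxaca") 1 else 0,
          component = comp,
          coefficient = unname(dec$components[[comp]]),
          percent = unname(dec$percent[[comp]]))
        if (!is.null(inf)) {
          key <- paste(sc, comp, sep = ".")
          m <- inf[inf$component == key, , drop = FALSE]
          row$se <- m$se; row$ci_low <- m$ci_low; row$ci_high <- m$ci_high
          row$sig <- m$sig
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

# long Table-3-style data.frame: window x variable group
report_detailed_table <- function(report) {
  rows <- list()
  for (res in report$results) {
    det <- res$detailed
    inf <- if (!is.null(res$inference)) res$inference$table else NULL
    tab <- det$table
    tab <- cbind(window = res$window, tab,
                 explained = det$explained, omega = det$omega)
    if (!is.null(inf)) {
      key <- paste("contribution", tab$variable_group, sep = ".")
      m <- inf[match(key, inf$component), , drop = FALSE]
      tab$se <- m$se; tab$ci_low <- m$ci_low; tab$ci_high <- m$ci_high
      tab$sig <- m$sig
    }
    rows[[length(rows) + 1L]] <- tab
  }
  do.call(rbind, rows)
}

report_json <- function(report) {
  list(
    provenance = report$provenance,
    config = report$config,
    selection = if (!is.null(report$selection_fit)) {
      list(gamma = as.list(report$selection_fit$gamma),
           n_total = report$selection_fit$n_total,
           n_selected = report$selection_fit$n_selected)
    },
    overall = report_overall_table(report),
    detailed = report_detailed_table(report),
    descriptives = as.data.frame(report$descriptives),
    log = report$log
  )
}

#' @export
print.obd_report <- function(x, ...) {
  cat("Decomposition analysis report\n")
  cat(sprintf("  rows: %d (urban %d, rural %d); windows: %s\n",
              x$provenance$n_rows, x$provenance$n_urban, x$provenance$n_rural,
              paste(x$provenance$windows, collapse = ", ")))
  for (res in x$results) {
    cat(sprintf("\n== window: %s ==\n", res$window))
    for (sc in names(res$overall)) print(res$overall[[sc]])
    print(res$detailed)
  }
  invisible(x)
}
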