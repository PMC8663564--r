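#' Run the full practice-effect analysis
#'
#' Per test: applies the inclusion filters, computes the characteristics
#' table, the first/fifth/last improvement summary, the confounder-adjusted
#' fifth-to-last regression, the age/adherence correlation panel, and the
#' quantile-regression short-term learning panel with the slope-equality
#' test. Tests flagged for long-term practice — the 95% CI of the
#' fifth-to-last mean percent improvement excludes 0 AND the log-repetitions
#' coefficient of the adjusted regression has p < alpha — additionally get
#' the four-model learning-curve analysis and the derived practice metrics.
#' A stage failure is recorded for its test without aborting the others.
#'
#' @param cohort A cohort (all tests it contains are analyzed unless
#'   \code{tests} narrows them).
#' @param tests Optional character vector of test names.
#' @param min_reps,min_weeks Inclusion filters (main analysis: 5 and 5).
#' @param time_axis \code{"repetition"} or \code{"weeks"}.
#' @param n_boot Bootstrap replicates for the quantile panel.
#' @param seed Integer seed (bootstrap resampling).
#' @param alpha Significance level of the long-term practice gate.
#' @param out_dir Optional directory; per-test JSON reports and TSV tables
#'   are written there with config and seed stamps.
#' @return Object of class \code{"practice_analysis"}: \code{per_test} (one
#'   list per test), \code{selection}, \code{config}.
#' @export
run_analysis <- function(cohort, tests = NULL, min_reps = 5, min_weeks = 5,
                         time_axis = c("repetition", "weeks"),
                         n_boot = 1000, seed = 1L, alpha = 0.05,
                         out_dir = NULL) {
  time_axis <- match.arg(time_axis)
  sel <- select_units(cohort, min_reps = min_reps, min_weeks = min_weeks)
  selected <- sel$cohort
  if (is.null(tests)) tests <- sort(unique(selected$records$test))

  per_test <- lapply(tests, function(tt) {
    res <- list(test = tt)
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        res$errors[[what]] <<- conditionMessage(e)
        NULL
      })
    }
    res$errors <- list()
    spec <- test_spec(tt)
    res$characteristics <- step("characteristics", {
      sub <- selected
      sub$records <- sub$records[sub$records$test == tt, , drop = FALSE]
      cohort_characteristics(sub)
    })
    triples <- step("score_triples", score_triples(selected, tt))
    res$triples <- triples
    res$improvement <- step("improvement_summary",
                            improvement_summary(triples, spec$direction))
    res$regression <- step("fifth_to_last_regression",
                           suppressWarnings(
                             fifth_to_last_regression(triples)))
    res$correlations <- step("correlations", {
      rbind(
        cbind(pair = "age_vs_reps",
              correlation_panel(triples$age_years, triples$n_reps)),
        cbind(pair = "first_vs_reps",
              correlation_panel(triples$first, triples$n_reps)))
    })
    res$quantile <- step("quantile_panel",
                         quantile_panel(selected, tt, n_boot = n_boot,
                                        seed = seed))

    # long-term practice gate: significant 5th-to-last mean improvement and
    # a significant adjusted log-repetitions association
    gate <- FALSE
    if (!is.null(res$improvement) && !is.null(res$regression)) {
      ci <- res$improvement$table["pct_5_to_last", ]
      ci_excl_0 <- ci$lower > 0 || ci$upper < 0
      p_logreps <- res$regression$coefficients["log_reps", 4]
      gate <- isTRUE(ci_excl_0 && p_logreps < alpha)
    }
    res$long_term_practice <- gate

    if (gate) {
      res$fits <- list(
        bounded = step("fit_bounded_growth",
                       fit_bounded_growth(selected, tt, time_axis)),
        spline = step("fit_spline", fit_spline(selected, tt, time_axis)),
        quadratic = step("fit_quadratic_mixed",
                         fit_quadratic_mixed(selected, tt, time_axis)),
        linear = step("fit_linear_mixed",
                      fit_linear_mixed(selected, tt, time_axis)))
      if (!any(vapply(res$fits, is.null, logical(1)))) {
        res$comparison <- step("compare_models",
                               do.call(compare_models, res$fits))
      }
      if (!is.null(res$fits$bounded)) {
        res$metrics <- step("practice_metrics",
                            practice_metrics(res$fits$bounded))
      }
    }
    res
  })
  names(per_test) <- tests

  out <- structure(list(
    per_test = per_test, selection = sel$report,
    config = list(tests = tests, min_reps = min_reps, min_weeks = min_weeks,
                  time_axis = time_axis, n_boot = n_boot, seed = seed,
                  alpha = alpha,
                  package_version = as.character(
                    utils::packageVersion("practicecurve")))
  ), class = "practice_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.practice_analysis <- function(x, ...) {
  cat("Practice-effect analysis (", x$config$time_axis, " axis; filters: >=",
      x$config$min_reps, "reps, >=", x$config$min_weeks, "weeks)\n")
  for (tt in names(x$per_test)) {
    r <- x$per_test[[tt]]
    cat("\n==", tt, "==\n")
    if (!is.null(r$improvement)) print(r$improvement)
    cat("long-term practice flagged:", r$long_term_practice, "\n")
    if (!is.null(r$comparison)) print(r$comparison)
    if (!is.null(r$metrics)) print(r$metrics)
    if (length(r$errors) > 0) {
      cat("stage errors:", paste(names(r$errors), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

analysis_to_list <- function(x) {
  per_test <- lapply(x$per_test, function(r) {
    out <- list(test = r$test,
                long_term_practice = r$long_term_practice,
                errors = r$errors)
    if (!is.null(r$improvement)) {
      out$improvement <- cbind(measure = rownames(r$improvement$table),
                               r$improvement$table)
      out$improvement_pooled_pct <- as.list(r$improvement$pooled_pct)
    }
    if (!is.null(r$regression)) {
      out$regression <- cbind(term = rownames(r$regression$coefficients),
                              r$regression$coefficients)
      out$regression_n <- r$regression$n
    }
    if (!is.null(r$correlations)) out$correlations <- r$correlations
    if (!is.null(r$quantile)) {
      out$quantile <- r$quantile$table
      out$slope_equality <- as.list(r$quantile$slope_equality)
    }
    if (!is.null(r$comparison)) out$model_comparison <- r$comparison$table
    if (!is.null(r$fits$bounded)) {
      f <- r$fits$bounded
      out$bounded_growth <- list(
        mu_y0 = f$mu_y0, mu_boundary = f$mu_boundary, c = f$c,
        var_y0 = f$var_y0, var_boundary = f$var_boundary,
        sigma2 = f$sigma2, rmse = f$rmse, df = f$df,
        ci = cbind(parameter = rownames(f$ci), as.data.frame(f$ci)))
    }
    if (!is.null(r$metrics)) {
      out$practice_points <- r$metrics$practice_points
      out$pct_improvement <- as.list(r$metrics$pct_improvement)
      out$pct_improvement_fixed <- as.list(r$metrics$pct_improvement_fixed)
    }
    if (!is.null(r$characteristics)) out$characteristics <- r$characteristics
    out
  })
  list(config = x$config, selection = x$selection$table,
       per_test = per_test)
}

# TSV with provenance header comments
write_tsv_stamped <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# practicecurve %s | seed=%s | filters: reps>=%s weeks>=%s | axis=%s",
                     config$package_version, config$seed, config$min_reps,
                     config$min_weeks, config$time_axis), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write an analysis report bundle
#'
#' Serializes a \code{\link{run_analysis}} result as one machine-readable
#' JSON report plus per-test TSV tables, each stamped with configuration,
#' seed and package version.
#'
#' @param analysis A \code{"practice_analysis"}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(analysis_to_list(analysis),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  cfg <- analysis$config
  write_tsv_stamped(analysis$selection$table,
                    file.path(out_dir, "selection.tsv"), cfg)
  for (tt in names(analysis$per_test)) {
    r <- analysis$per_test[[tt]]
    safe <- gsub("[^A-Za-z0-9]", "_", tt)
    if (!is.null(r$characteristics)) {
      write_tsv_stamped(r$characteristics,
                        file.path(out_dir,
                                  paste0(safe, "_characteristics.tsv")), cfg)
    }
    if (!is.null(r$quantile)) {
      write_tsv_stamped(r$quantile$table,
                        file.path(out_dir, paste0(safe, "_quantile.tsv")),
                        cfg)
    }
    if (!is.null(r$comparison)) {
      write_tsv_stamped(r$comparison$table,
                        file.path(out_dir, paste0(safe, "_models.tsv")), cfg)
    }
  }
  invisible(out_dir)
}

#' Run the main analysis and the three sensitivity analyses
#'
#' Executes the four analysis cells — main (filters 5/5, repetition axis),
#' sensitivity 1 (5/5, weeks axis), sensitivity 2 (10/10, repetition axis)
#' and sensitivity 3 (10/10, weeks axis) — and tabulates the fifth-to-last
#' percent improvements and boundary improvements side by side per test.
#'
#' @inheritParams run_analysis
#' @return Object of class \code{"sensitivity_analysis"}: \code{cells}
#'   (named list of four \code{"practice_analysis"} objects, \code{main},
#'   \code{s1}, \code{s2}, \code{s3}) and \code{comparison} (data frame).
#' @export
run_sensitivity <- function(cohort, tests = NULL, n_boot = 1000, seed = 1L,
                            alpha = 0.05, out_dir = NULL) {
  grid <- list(
    main = list(min_reps = 5, min_weeks = 5, time_axis = "repetition"),
    s1   = list(min_reps = 5, min_weeks = 5, time_axis = "weeks"),
    s2   = list(min_reps = 10, min_weeks = 10, time_axis = "repetition"),
    s3   = list(min_reps = 10, min_weeks = 10, time_axis = "weeks")
  )
  cells <- lapply(grid, function(g) {
    run_analysis(cohort, tests = tests, min_reps = g$min_reps,
                 min_weeks = g$min_weeks, time_axis = g$time_axis,
                 n_boot = n_boot, seed = seed, alpha = alpha)
  })
  rows <- list()
  for (cell in names(cells)) {
    for (tt in names(cells[[cell]]$per_test)) {
      r <- cells[[cell]]$per_test[[tt]]
      imp5l <- if (!is.null(r$improvement)) {
        r$improvement$table["pct_5_to_last", "mean"]
      } else NA_real_
      bimp <- if (!is.null(r$metrics)) {
        unname(r$metrics$pct_improvement["mean"])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cell = cell, test = tt,
        n_units = sum(cells[[cell]]$selection$table$n_units_selected[
          cells[[cell]]$selection$table$test == tt]),
        pct_5_to_last = imp5l, boundary_improvement_pct = bimp,
        long_term_practice = r$long_term_practice,
        stringsAsFactors = FALSE)
    }
  }
  comparison <- do.call(rbind, rows)
  out <- structure(list(cells = cells, comparison = comparison),
                   class = "sensitivity_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_stamped(comparison, file.path(out_dir, "sensitivity.tsv"),
                      cells$main$config)
    for (cell in names(cells)) {
      write_analysis(cells[[cell]], file.path(out_dir, cell))
    }
  }
  out
}

#' @export
print.sensitivity_analysis <- function(x, ...) {
  cat("Sensitivity grid (main / s1 / s2 / s3):\n")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}
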