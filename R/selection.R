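#' Apply the study inclusion filters to a cohort
#'
#' Keeps, per test, the analysis units with at least \code{min_reps}
#' repetitions and at least \code{min_weeks} weeks (counted as
#' \code{7 * min_weeks} days of elapsed time) between their first and last
#' repetitions. The main-analysis criteria are 5 repetitions and 5 weeks; the
#' stricter sensitivity criteria are 10 and 10.
#'
#' @param cohort A cohort.
#' @param min_reps Minimum repetitions per unit; must be at least 2, and a
#'   warning is raised below 5 because the summary analyses need a fifth
#'   score.
#' @param min_weeks Minimum first-to-last span in weeks.
#' @return A list with \code{cohort} (the filtered cohort) and \code{report}
#'   (class \code{"selection_report"}): per-test totals and selected counts
#'   of units and tests, plus per-unit spans and repetition counts.
#' @export
select_units <- function(cohort, min_reps = 5, min_weeks = 5) {
  if (min_reps < 2) {
    stop("configuration error: min_reps must be >= 2", call. = FALSE)
  }
  if (min_reps < 5) {
    warning("min_reps < 5: fifth-score summaries will be undefined",
            call. = FALSE)
  }
  r <- cohort$records
  key <- paste(r$test, r$unit_id, sep = "\r")
  n_reps <- tapply(r$value, key, length)
  span_weeks <- tapply(r$t_weeks, key, function(w) max(w) - min(w))
  keep_key <- names(n_reps)[n_reps >= min_reps &
                              span_weeks * 7 >= 7 * min_weeks]
  kept <- key %in% keep_key

  per_test <- function(k) {
    tt <- sub("\r.*$", "", k)
    tt
  }
  unit_test <- per_test(names(n_reps))
  sel <- names(n_reps) %in% keep_key
  tests <- sort(unique(unit_test))
  report <- data.frame(
    test = tests,
    n_units_total = as.integer(table(factor(unit_test, levels = tests))),
    n_units_selected = as.integer(tapply(sel, factor(unit_test,
                                                     levels = tests), sum)),
    n_tests_total = as.integer(tapply(as.integer(n_reps),
                                      factor(unit_test, levels = tests),
                                      sum)),
    n_tests_selected = as.integer(tapply(as.integer(n_reps) * sel,
                                         factor(unit_test, levels = tests),
                                         sum)),
    stringsAsFactors = FALSE
  )
  report$pct_units_selected <- 100 * report$n_units_selected /
    report$n_units_total
  report$pct_tests_selected <- 100 * report$n_tests_selected /
    report$n_tests_total

  out <- cohort
  out$records <- r[kept, , drop = FALSE]
  rownames(out$records) <- NULL
  out$provenance <- c(cohort$provenance,
                      sprintf("selected min_reps=%d min_weeks=%g (>= %g days)",
                              min_reps, min_weeks, 7 * min_weeks))
  rep_obj <- structure(list(
    table = report, min_reps = min_reps, min_weeks = min_weeks,
    unit_stats = data.frame(key = names(n_reps), test = unit_test,
                            unit_id = sub("^.*\r", "", names(n_reps)),
                            n_reps = as.integer(n_reps),
                            span_weeks = as.numeric(span_weeks),
                            selected = sel, stringsAsFactors = FALSE)
  ), class = "selection_report")
  list(cohort = out, report = rep_obj)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection: >= %d repetitions and >= %g weeks first-to-last\n",
              x$min_reps, x$min_weeks))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# linear-interpolation quantiles (R type 7) reported as median (IQR; range)
med_iqr_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
             min = NA_real_, max = NA_real_))
  }
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3], min = min(x), max = max(x))
}

#' Cohort characteristics table
#'
#' For each test, computes per-unit statistics — repetition count, median and
#' IQR of consecutive intertest intervals in days, and weeks from first to
#' last test — and summarizes each across units as median (IQR; range), the
#' layout of a study characteristics table. Interval statistics of units with
#' fewer than 2 records are undefined and omitted. Quantiles use the
#' linear-interpolation convention (R type 7). An age summary is included
#' when ages are present.
#'
#' @param cohort A (typically selected) cohort.
#' @return A data frame with one row per (test, statistic) and columns
#'   \code{median}, \code{q25}, \code{q75}, \code{min}, \code{max}.
#' @export
cohort_characteristics <- function(cohort) {
  r <- cohort$records
  out <- list()
  for (tt in sort(unique(r$test))) {
    rt <- r[r$test == tt, , drop = FALSE]
    units <- split(rt, rt$unit_id)
    n_reps <- vapply(units, nrow, integer(1))
    intervals <- lapply(units, function(u) {
      if (nrow(u) < 2) return(NULL)
      diff(as.numeric(u$timestamp[order(u$repetition_index)])) / 86400
    })
    has_int <- !vapply(intervals, is.null, logical(1))
    med_int <- vapply(intervals[has_int], median, numeric(1))
    iqr_int <- vapply(intervals[has_int], function(d) {
      q <- quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
      q[2] - q[1]
    }, numeric(1))
    span_weeks <- vapply(units, function(u) max(u$t_weeks) - min(u$t_weeks),
                         numeric(1))
    stats <- rbind(
      n_repetitions = med_iqr_range(n_reps),
      median_intertest_interval_days = med_iqr_range(med_int),
      iqr_intertest_interval_days = med_iqr_range(iqr_int),
      weeks_first_to_last = med_iqr_range(span_weeks)
    )
    pid <- unique(rt$participant_id)
    ages <- cohort$participants$age_years[
      match(pid, cohort$participants$participant_id)]
    if (any(is.finite(ages))) {
      stats <- rbind(stats, age_years = med_iqr_range(ages))
    }
    df <- data.frame(test = tt, statistic = rownames(stats), stats,
                     row.names = NULL, stringsAsFactors = FALSE)
    out[[tt]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
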