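# mean with two-sided t-based 95% CI (n-1 df)
mean_t_ci <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need >= 2 values for a t interval", call. = FALSE)
  m <- mean(x)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

#' First, fifth and last scores per analysis unit
#'
#' Extracts the positional score triple used in the summary analysis: the
#' first trial (dominated by unfamiliarity), the fifth (the short-term
#' learning baseline), and the last. Units whose first or fifth score is zero
#' cannot enter percent-change computations and are flagged
#' (\code{pct_usable = FALSE}).
#'
#' @param cohort A selected cohort.
#' @param test Test name.
#' @return Data frame with one row per unit with at least 5 repetitions:
#'   \code{unit_id}, \code{first}, \code{fifth}, \code{last}, \code{n_reps},
#'   \code{age_years}, \code{pct_usable}.
#' @export
score_triples <- function(cohort, test) {
  r <- test_records(cohort, test)
  units <- split(r, r$unit_id)
  units <- units[vapply(units, nrow, integer(1)) >= 5]
  if (length(units) == 0) {
    return(data.frame(unit_id = character(), first = numeric(),
                      fifth = numeric(), last = numeric(),
                      n_reps = integer(), age_years = numeric(),
                      pct_usable = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(units, function(u) {
    u <- u[order(u$repetition_index), , drop = FALSE]
    data.frame(unit_id = u$unit_id[1],
               participant_id = u$participant_id[1],
               first = u$value[1], fifth = u$value[5],
               last = u$value[nrow(u)], n_reps = nrow(u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$age_years <- cohort$participants$age_years[
    match(out$participant_id, cohort$participants$participant_id)]
  out$participant_id <- NULL
  out$pct_usable <- out$first != 0 & out$fifth != 0
  out
}

#' Observed improvement summary with confidence intervals
#'
#' Per-unit percent changes 100 (b - a) / a for the pairs first-to-fifth,
#' fifth-to-last and first-to-last, averaged across units with t-based 95%
#' CIs (the per-patient "mean of per-unit ratios" framing; the pooled
#' ratio-of-means is also reported for transparency), plus the mean absolute
#' first-to-last difference in metric units. Signs are preserved: for a
#' lower-is-better test a negative percent change is an improvement.
#'
#' @param triples Output of \code{\link{score_triples}}.
#' @param direction \code{"higher_better"} or \code{"lower_better"}
#'   (annotation only; signs are never flipped).
#' @return Object of class \code{"improvement_summary"}: a list with a
#'   \code{table} (rows \code{pct_1_to_5}, \code{pct_5_to_last},
#'   \code{pct_1_to_last}, \code{abs_1_to_last}; columns mean/lower/upper/n),
#'   \code{pooled_pct} (ratio-of-means variants), \code{n_excluded_zero}.
#' @export
improvement_summary <- function(triples, direction = "higher_better") {
  use <- triples[triples$pct_usable, , drop = FALSE]
  if (nrow(use) < 2) {
    stop("empty-result error: fewer than 2 units usable for percent changes",
         call. = FALSE)
  }
  pct <- function(a, b) 100 * (b - a) / a
  p15 <- pct(use$first, use$fifth)
  p5l <- pct(use$fifth, use$last)
  p1l <- pct(use$first, use$last)
  abs1l <- triples$last - triples$first
  tab <- rbind(
    pct_1_to_5 = mean_t_ci(p15),
    pct_5_to_last = mean_t_ci(p5l),
    pct_1_to_last = mean_t_ci(p1l),
    abs_1_to_last = mean_t_ci(abs1l)
  )
  pooled <- c(
    pct_1_to_5 = pct(mean(use$first), mean(use$fifth)),
    pct_5_to_last = pct(mean(use$fifth), mean(use$last)),
    pct_1_to_last = pct(mean(use$first), mean(use$last))
  )
  structure(list(table = as.data.frame(tab), pooled_pct = pooled,
                 direction = direction,
                 n_excluded_zero = sum(!triples$pct_usable)),
            class = "improvement_summary")
}

#' @export
print.improvement_summary <- function(x, ...) {
  cat("Observed improvements (mean of per-unit changes, 95% CI):\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    unit <- if (grepl("^pct", rownames(tab)[i])) "%" else ""
    cat(sprintf("  %-14s %6.1f%s (%.1f to %.1f), n=%d\n", rownames(tab)[i],
                tab$mean[i], unit, tab$lower[i], tab$upper[i], tab$n[i]))
  }
  if (x$n_excluded_zero > 0) {
    cat("  (", x$n_excluded_zero, "unit(s) with zero first/fifth score",
        "excluded from percent rows )\n")
  }
  invisible(x)
}

#' Confounder-adjusted regression of the fifth-to-last difference
#'
#' Ordinary least squares of (last - fifth) on age, first score, fifth score
#' and the natural log of the repetition count (log-transformed because
#' adherence is strongly right-skewed). A positive, significant
#' log-repetitions coefficient — more repetitions, more improvement after the
#' fifth trial — is the adjusted indicator of a long-term practice effect.
#'
#' @param triples Output of \code{\link{score_triples}}; units without age
#'   are dropped with a warning.
#' @return Object of class \code{"fifth_to_last_fit"}: coefficient table
#'   (estimate, SE, t, two-tailed p), \code{n}, \code{r_squared} and the
#'   underlying \code{lm} fit.
#' @export
fifth_to_last_regression <- function(triples) {
  d <- data.frame(
    diff_5_last = triples$last - triples$fifth,
    age = triples$age_years,
    first = triples$first,
    fifth = triples$fifth,
    log_reps = log(triples$n_reps)
  )
  use_age <- any(is.finite(d$age))
  if (!use_age) {
    warning("no ages available: regression fitted without the age term",
            call. = FALSE)
    d$age <- NULL
  }
  n_drop <- sum(!complete.cases(d))
  if (n_drop > 0) {
    warning(n_drop, " unit(s) without age dropped from the regression",
            call. = FALSE)
    d <- d[complete.cases(d), , drop = FALSE]
  }
  if (nrow(d) < 6) stop("too few units for the 4-covariate regression",
                        call. = FALSE)
  fit <- if (use_age) {
    lm(diff_5_last ~ age + first + fifth + log_reps, data = d)
  } else {
    lm(diff_5_last ~ first + fifth + log_reps, data = d)
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: collinear column(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # degenerate zero-variance response
  structure(list(coefficients = as.data.frame(sm$coefficients),
                 n = nrow(d), r_squared = r2, fit = fit),
            class = "fifth_to_last_fit")
}

#' @export
print.fifth_to_last_fit <- function(x, ...) {
  cat("OLS of (last - fifth) on age, first, fifth, log(repetitions); n =",
      x$n, "\n")
  printCoefmat(as.matrix(x$coefficients))
  invisible(x)
}

#' Pearson and Spearman correlation for pairs of per-unit scalars
#'
#' @param x,y Numeric vectors (pairs with missing values dropped).
#' @return Data frame with \code{pearson_r}, \code{pearson_p} (two-tailed t
#'   test), \code{spearman_rho}, \code{spearman_p}, \code{n}.
#' @export
correlation_panel <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  pe <- cor.test(x, y, method = "pearson")
  # Spearman as rank transform then Pearson (with the t-test on the ranks)
  sp <- cor.test(rank(x), rank(y), method = "pearson")
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = length(x))
}
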