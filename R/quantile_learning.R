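#' Check (pinball) loss of a quantile-regression line
#'
#' @param t Trial numbers (1-based repetition index).
#' @param y Scores.
#' @param intercept,slope Line parameters, with the intercept anchored at
#'   trial 1 (the line is \code{intercept + slope * (t - 1)}).
#' @param tau Quantile level in (0, 1).
#' @return The summed asymmetric absolute loss.
#' @export
pinball_loss <- function(t, y, intercept, slope, tau) {
  stopifnot(length(t) == length(y), tau > 0, tau < 1)
  pinball_loss_cpp(as.numeric(t) - 1, as.numeric(y), intercept, slope, tau)
}

#' Fit one linear quantile-regression line to the first trials
#'
#' Minimizes the check loss \eqn{\sum \rho_\tau(y - \beta_0 - \beta_1 (t-1))}
#' so the intercept is the baseline (trial 1) performance at percentile
#' \code{tau} and the slope is the learning rate in metric units per
#' repetition. For small samples the optimum is found by exact enumeration of
#' all lines through pairs of points with distinct trial numbers (a vertex of
#' the LP), with lexicographically smallest (intercept, slope) among ties;
#' larger samples use a convex search on the slope profile with an
#' interpolation snap.
#'
#' @param t Trial numbers (typically 1..5); at least two distinct values.
#' @param y Scores, same length as \code{t}; at least 3 points.
#' @param tau Quantile level in (0, 1).
#' @param n_exact Sample-size threshold for the exact enumeration path.
#' @return Named vector \code{c(intercept, slope, loss)}.
#' @examples
#' fit_quantile_line(rep(1:5, 2), 2 + 3 * (rep(1:5, 2) - 1), tau = 0.5)
#' @export
fit_quantile_line <- function(t, y, tau, n_exact = 250) {
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3) stop("need >= 3 points", call. = FALSE)
  if (length(unique(t)) < 2) {
    stop("slope unidentifiable: all trial numbers identical", call. = FALSE)
  }
  stopifnot(tau > 0, tau < 1)
  out <- qr_fit_line_cpp(as.numeric(t) - 1, as.numeric(y), tau,
                         as.integer(n_exact))
  setNames(out, c("intercept", "slope", "loss"))
}

#' Short-term learning panel: quantile regression over trials 1-5
#'
#' Fits linear quantile-regression lines at the configured percentiles to all
#' scores from the first \code{max_trial} trials of every selected unit,
#' pooled. Standard errors, 95% CIs and the joint covariance of the slopes
#' are estimated by a cluster bootstrap that resamples analysis units (not
#' rows), respecting the repeated-measures structure. Slope p-values are
#' Bonferroni-adjusted over the family of the \code{length(taus)} slopes per
#' test; intercept CIs are unadjusted.
#'
#' @param cohort A selected cohort.
#' @param test Test name.
#' @param taus Quantile levels; default the 5th/25th/50th/75th/95th
#'   percentiles.
#' @param n_boot Bootstrap replicates (a warning is raised below 100).
#' @param seed Integer seed for the bootstrap.
#' @param max_trial Last trial included (default 5).
#' @return Object of class \code{"quantile_fit_set"}: \code{table} (per-tau
#'   intercept and slope with SEs, CIs, raw and adjusted p),
#'   \code{slope_vcov}, \code{slope_equality} (see
#'   \code{\link{slope_equality_test}}), \code{n_points}, \code{n_units},
#'   \code{n_redrawn}.
#' @export
quantile_panel <- function(cohort, test, taus = c(.05, .25, .50, .75, .95),
                           n_boot = 1000, seed = 1L, max_trial = 5) {
  if (n_boot < 100) warning("n_boot < 100: bootstrap inference will be noisy",
                            call. = FALSE)
  r <- test_records(cohort, test)
  r <- r[r$repetition_index <= max_trial, , drop = FALSE]
  if (nrow(r) < 3) stop("too few points for quantile regression",
                        call. = FALSE)
  t <- r$repetition_index
  y <- r$value
  fits <- vapply(taus, function(tt) fit_quantile_line(t, y, tt)[1:2],
                 numeric(2))
  unit_rows <- split(seq_len(nrow(r)), r$unit_id)
  n_units <- length(unit_rows)

  set.seed(seed)
  k <- length(taus)
  boot_int <- matrix(NA_real_, n_boot, k)
  boot_slp <- matrix(NA_real_, n_boot, k)
  n_redrawn <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- unlist(unit_rows[sample.int(n_units, n_units, replace = TRUE)],
                  use.names = FALSE)
    tb <- t[idx]; yb <- y[idx]
    if (length(unique(tb)) < 2) {  # unidentifiable replicate: redraw
      n_redrawn <- n_redrawn + 1L
      next
    }
    for (j in seq_len(k)) {
      f <- qr_fit_line_cpp(tb - 1, yb, taus[j], 250L)
      boot_int[b, j] <- f[1]
      boot_slp[b, j] <- f[2]
    }
    b <- b + 1L
  }
  se_int <- apply(boot_int, 2, sd)
  se_slp <- apply(boot_slp, 2, sd)
  z975 <- qnorm(0.975)
  p_slp <- 2 * pnorm(-abs(fits[2, ] / se_slp))
  tab <- data.frame(
    tau = taus,
    intercept = fits[1, ], intercept_se = se_int,
    intercept_lower = fits[1, ] - z975 * se_int,
    intercept_upper = fits[1, ] + z975 * se_int,
    slope = fits[2, ], slope_se = se_slp,
    slope_lower = fits[2, ] - z975 * se_slp,
    slope_upper = fits[2, ] + z975 * se_slp,
    slope_p = p_slp,
    slope_p_bonferroni = pmin(1, p_slp * k)
  )
  out <- structure(list(
    test = test, table = tab, slope_vcov = stats::cov(boot_slp),
    n_points = length(y), n_units = n_units, n_boot = n_boot,
    n_redrawn = n_redrawn, taus = taus
  ), class = "quantile_fit_set")
  out$slope_equality <- slope_equality_test(out)
  out
}

#' @export
print.quantile_fit_set <- function(x, ...) {
  cat(sprintf("Quantile learning panel: %s, trials pooled over %d unit(s), %d points\n",
              x$test, x$n_units, x$n_points))
  print(x$table, row.names = FALSE, digits = 4)
  eq <- x$slope_equality
  cat(sprintf("Slope equality (ANOVA-type Wald): chi^2 = %.3f, df = %d, p = %.4g\n",
              eq["statistic"], as.integer(eq["df"]), eq["p"]))
  invisible(x)
}

#' ANOVA-type test of equal learning slopes across percentiles
#'
#' Joint Wald test that the quantile-specific learning slopes are all equal,
#' built on the successive-difference contrasts of the slope vector and the
#' bootstrap covariance of the slopes: W = (Db)' (D V D')^{-1} (Db), referred
#' to a chi-squared distribution with (number of slopes - 1) df. W is
#' invariant to a consistent reordering of the percentiles.
#'
#' @param fitset A \code{\link{quantile_panel}} result (or any list with
#'   elements \code{table$slope} and \code{slope_vcov}).
#' @return Named vector \code{c(statistic, df, p)}.
#' @export
slope_equality_test <- function(fitset) {
  b <- fitset$table$slope
  V <- fitset$slope_vcov
  k <- length(b)
  stopifnot(k >= 2, all(dim(V) == k))
  D <- diff(diag(k))  # successive differences
  d0 <- D %*% b
  if (max(abs(d0)) < 1e-12 * (1 + max(abs(b)))) {
    # estimated slopes are all equal: W = 0 regardless of the covariance
    return(c(statistic = 0, df = k - 1, p = 1))
  }
  M <- D %*% V %*% t(D)
  Mi <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Mi) || !all(is.finite(Mi))) {
    stop("singular contrast covariance; increase n_boot", call. = FALSE)
  }
  d <- D %*% b
  W <- drop(t(d) %*% Mi %*% d)
  c(statistic = W, df = k - 1, p = pchisq(W, df = k - 1, lower.tail = FALSE))
}
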