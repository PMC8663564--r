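#' Expected bounded-growth learning curve
#'
#' The mean trajectory \eqn{y(t) = boundary + (y_0 - boundary) e^{-ct}}:
#' performance starts at \code{y0}, approaches the individual plateau
#' \code{boundary} monotonically, and closes a fraction \eqn{1 - e^{-ct}} of
#' the gap by time \code{t} (repetitions or weeks, depending on the axis the
#' growth constant \code{c} is expressed in).
#'
#' @param y0 Baseline performance (value at \code{t = 0}).
#' @param boundary Plateau performance as \code{t} grows.
#' @param c_rate Growth constant per time unit; nonnegative.
#' @param t Time(s) since the first test; nonnegative, vectorized.
#' @return Numeric vector of expected scores.
#' @examples
#' mean_curve(10, 20, log(2), 0:3)  # 10, 15, 17.5, 18.75
#' @export
mean_curve <- function(y0, boundary, c_rate, t) {
  if (any(c_rate < 0)) stop("c_rate must be nonnegative", call. = FALSE)
  boundary + (y0 - boundary) * exp(-c_rate * t)
}

# lognormal (meanlog, sdlog) hitting a target median and IQR:
# median = e^mu; IQR = 2 * median * sinh(sdlog * qnorm(.75))
lognormal_from_median_iqr <- function(median, iqr) {
  if (median < 1) stop("configuration error: reps median must be >= 1",
                       call. = FALSE)
  if (iqr < 0) stop("configuration error: reps iqr must be >= 0",
                    call. = FALSE)
  z75 <- qnorm(0.75)
  list(meanlog = log(median), sdlog = asinh(iqr / (2 * median)) / z75)
}

#' Simulation configuration for a synthetic testing cohort
#'
#' Defines the data-generating process: per-unit bounded-growth trajectories
#' with Gaussian random baseline and boundary, additive Gaussian residual
#' noise, a right-skewed (rounded-up lognormal) repetition-count law targeted
#' at a given median/IQR with a hard cap, lognormal intertest intervals
#' floored at the test's app-enforced minimum, and an age covariate tied to
#' the repetition count through a Gaussian copula at a configured
#' correlation.
#'
#' Defaults emulate the cognition (symbol-digit) arm of a high-frequency
#' smartphone study: 262 units, baseline mean 41 and boundary mean 57.7
#' correct responses, growth constant \code{log(2)/11} per repetition (half
#' the practice effect after 11 repetitions), residual noise 3.3, repetition
#' counts with median 11 / IQR 11 capped at 119, weekly-floored intervals,
#' and age weakly correlated with adherence (r = 0.2).
#'
#' @param test Test name (sets grouping and the interval floor).
#' @param n_units Number of analysis units (hand-grouped tests emit 2 units
#'   per participant; with an odd count the last participant contributes one
#'   hand).
#' @param mu_y0,sd_y0 Mean and SD of the per-unit baseline.
#' @param mu_boundary,sd_boundary Mean and SD of the per-unit boundary.
#' @param c_rate Growth constant per repetition; nonnegative (0 = flat).
#' @param sigma_resid Residual SD.
#' @param reps_median,reps_iqr,reps_max Targets for the repetition-count law.
#' @param interval_meanlog,interval_sdlog Lognormal intertest-interval law
#'   (days), floored at the test's minimum interval.
#' @param age_mean,age_sd Age law (years).
#' @param age_reps_corr Gaussian-copula correlation between age and
#'   repetition count, in (-1, 1).
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(test = "e-SDMT", n_units = 262,
                       mu_y0 = 41.0, sd_y0 = 10,
                       mu_boundary = 57.7, sd_boundary = 10,
                       c_rate = log(2) / 11, sigma_resid = 3.3,
                       reps_median = 11, reps_iqr = 11, reps_max = 119,
                       interval_meanlog = log(7), interval_sdlog = 0.75,
                       age_mean = 50, age_sd = 11, age_reps_corr = 0.2) {
  spec <- test_spec(test)
  stopifnot(n_units >= 1, sd_y0 >= 0, sd_boundary >= 0, sigma_resid >= 0)
  if (c_rate < 0) stop("configuration error: c_rate must be >= 0",
                       call. = FALSE)
  if (abs(age_reps_corr) >= 1) {
    stop("configuration error: age_reps_corr must be in (-1, 1)",
         call. = FALSE)
  }
  if (spec$direction == "higher_better" && c_rate > 0 &&
      mu_boundary < mu_y0) {
    stop("configuration error: mu_boundary must be >= mu_y0 for a ",
         "higher-is-better test", call. = FALSE)
  }
  lnorm <- lognormal_from_median_iqr(reps_median, reps_iqr)
  structure(list(
    test = test, grouping = spec$grouping,
    min_interval_days = spec$min_interval_days,
    n_units = as.integer(n_units),
    mu_y0 = mu_y0, sd_y0 = sd_y0,
    mu_boundary = mu_boundary, sd_boundary = sd_boundary,
    c_rate = c_rate, sigma_resid = sigma_resid,
    reps_median = reps_median, reps_iqr = reps_iqr, reps_max = reps_max,
    reps_meanlog = lnorm$meanlog, reps_sdlog = lnorm$sdlog,
    interval_meanlog = interval_meanlog, interval_sdlog = interval_sdlog,
    age_mean = age_mean, age_sd = age_sd, age_reps_corr = age_reps_corr
  ), class = "sim_config")
}

# deterministic per-participant child seed: unit-count changes never
# reshuffle the streams of existing participants
child_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647)
  as.integer((s * 48271 + as.double(k) * 9973 + 12345) %% 2147483647)
}

# repetition count from a standard-normal copula draw
reps_from_z <- function(z, config) {
  u <- pnorm(z)
  n <- ceiling(qlnorm(u, config$reps_meanlog, config$reps_sdlog))
  pmin(pmax(n, 1), config$reps_max)
}

#' Simulate a cohort with known ground truth
#'
#' Draws per-unit baseline and boundary from independent normal laws,
#' repetition counts from the rounded-up lognormal law (correlated with age
#' through a Gaussian copula), intertest intervals from a floored lognormal,
#' and observations from the bounded-growth mean curve on the repetition
#' axis plus Gaussian residual noise. Hand-grouped tests emit two interleaved
#' units (left and right hand, the right hand starting one day later) per
#' participant, sharing the participant's age.
#'
#' Each participant has its own child random stream derived from \code{seed},
#' so enlarging \code{n_units} extends the cohort without reshuffling
#' existing units, and the same \code{(config, seed)} reproduces the cohort
#' exactly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer root seed.
#' @param start_date First-test origin; units start uniformly within 90 days
#'   after it.
#' @return A list with elements \code{cohort} (a \code{\link{as_cohort}})
#'   and \code{truth} (data frame: \code{unit_id}, \code{y0_i},
#'   \code{boundary_i}, \code{n_reps_i}, \code{age_i}).
#' @export
simulate_cohort <- function(config, seed = 1L,
                            start_date = as.POSIXct("2020-01-01 12:00:00",
                                                    tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  per_part <- if (config$grouping == "hand") 2L else 1L
  n_parts <- ceiling(config$n_units / per_part)
  hands <- if (per_part == 2L) c("left", "right") else "none"

  rec_list <- vector("list", n_parts * per_part)
  truth_list <- vector("list", n_parts * per_part)
  ages <- numeric(n_parts)
  pids <- sprintf("P%05d", seq_len(n_parts))

  for (p in seq_len(n_parts)) {
    set.seed(child_seed(seed, p))
    z_age <- rnorm(1)
    ages[p] <- config$age_mean + config$age_sd * z_age
    start_p <- start_date + runif(1, 0, 90) * 86400
    for (h in seq_len(per_part)) {
      rho <- config$age_reps_corr
      z_reps <- rho * z_age + sqrt(1 - rho^2) * rnorm(1)
      n_reps <- reps_from_z(z_reps, config)
      y0_i <- rnorm(1, config$mu_y0, config$sd_y0)
      b_i <- rnorm(1, config$mu_boundary, config$sd_boundary)
      gaps <- if (n_reps > 1) {
        pmax(exp(rnorm(n_reps - 1, config$interval_meanlog,
                       config$interval_sdlog)),
             config$min_interval_days)
      } else numeric(0)
      t_days <- cumsum(c(0, gaps)) + (h - 1)  # right hand offset by 1 day
      mu <- mean_curve(y0_i, b_i, config$c_rate, seq_len(n_reps) - 1)
      y <- mu + rnorm(n_reps, 0, config$sigma_resid)
      hand <- hands[h]
      uid <- if (hand == "none") pids[p] else paste(pids[p], hand, sep = ":")
      k <- (p - 1) * per_part + h
      rec_list[[k]] <- data.frame(
        participant_id = pids[p], test = config$test, hand = hand,
        timestamp = start_p + t_days * 86400, value = y,
        stringsAsFactors = FALSE)
      truth_list[[k]] <- data.frame(
        unit_id = uid, y0_i = y0_i, boundary_i = b_i,
        n_reps_i = n_reps, age_i = ages[p], stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_list)
  truth <- do.call(rbind, truth_list)
  # trim surplus unit when an odd unit count was requested for a hand test
  keep_units <- truth$unit_id[seq_len(config$n_units)]
  records <- records[
    ifelse(records$hand == "none", records$participant_id,
           paste(records$participant_id, records$hand, sep = ":")) %in%
      keep_units, , drop = FALSE]
  truth <- truth[truth$unit_id %in% keep_units, , drop = FALSE]
  rownames(truth) <- NULL
  participants <- data.frame(participant_id = pids, age_years = ages,
                             stringsAsFactors = FALSE)
  cohort <- as_cohort(records, participants,
                      provenance = sprintf("simulated test=%s seed=%d",
                                           config$test, seed))
  list(cohort = cohort, truth = truth)
}
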