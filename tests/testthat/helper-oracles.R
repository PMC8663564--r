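# Independent oracles and cohort builders used across the suite.
# Everything here is deliberately brute-force and separate from the package's
# fitting code paths.

# plain-R pinball loss (independent of the compiled implementation)
oracle_pinball <- function(t, y, intercept, slope, tau) {
  r <- y - intercept - slope * (t - 1)
  sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
}

# brute-force quantile line: minimum over all lines through point pairs with
# distinct trial numbers
oracle_qr_pairs <- function(t, y, tau) {
  n <- length(t)
  best <- list(loss = Inf)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[i] == t[j]) next
      slope <- (y[j] - y[i]) / (t[j] - t[i])
      intercept <- y[i] - slope * (t[i] - 1)
      loss <- oracle_pinball(t, y, intercept, slope, tau)
      if (loss < best$loss) {
        best <- list(intercept = intercept, slope = slope, loss = loss)
      }
    }
  }
  best
}

# pooled nonlinear least squares by nested grid search over the growth
# constant with the closed-form linear sub-fit in (y0, boundary)
oracle_nls_grid <- function(t, y, c_lo = 1e-4, c_hi = 5, rounds = 9,
                            n_grid = 80) {
  subfit <- function(cc) {
    e <- exp(-cc * t)
    X <- cbind(e, 1 - e)
    f <- stats::lm.fit(X, y)
    list(rss = sum(f$residuals^2), y0 = unname(f$coefficients[1]),
         boundary = unname(f$coefficients[2]))
  }
  lo <- log(c_lo); hi <- log(c_hi)
  best <- NULL
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = n_grid)
    rss <- vapply(grid, function(g) subfit(exp(g))$rss, numeric(1))
    k <- which.min(rss)
    step <- grid[2] - grid[1]
    lo <- grid[k] - 2 * step
    hi <- grid[k] + 2 * step
    best <- c(subfit(exp(grid[k])), c = exp(grid[k]))
  }
  best
}

# profiled-likelihood grid search for the random-intercept Gaussian mixed
# model (ML): profile over lambda = var_unit / sigma2 with closed-form GLS
oracle_lmm_profile <- function(d, quadratic = FALSE, rounds = 5,
                               n_grid = 80) {
  X <- if (quadratic) cbind(1, d$t, d$t^2) else cbind(1, d$t)
  groups <- split(seq_len(nrow(d)), d$unit)
  N <- nrow(d)
  eval_lambda <- function(lam) {
    A <- matrix(0, ncol(X), ncol(X)); bvec <- numeric(ncol(X))
    for (g in groups) {
      Xi <- X[g, , drop = FALSE]; yi <- d$y[g]; ni <- length(g)
      w <- lam / (1 + lam * ni)
      WX <- Xi - w * matrix(colSums(Xi), ni, ncol(X), byrow = TRUE)
      Wy <- yi - w * sum(yi)
      A <- A + crossprod(Xi, WX); bvec <- bvec + crossprod(Xi, Wy)
    }
    beta <- solve(A, bvec)
    rssw <- 0; logdet <- 0
    for (g in groups) {
      ri <- d$y[g] - X[g, , drop = FALSE] %*% beta
      ni <- length(g)
      w <- lam / (1 + lam * ni)
      rssw <- rssw + sum(ri^2) - w * sum(ri)^2
      logdet <- logdet + log(1 + lam * ni)
    }
    sigma2 <- rssw / N
    ll <- -N / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2
    list(ll = ll, beta = drop(beta), sigma2 = sigma2,
         var_unit = lam * sigma2)
  }
  lo <- log(1e-6); hi <- log(1e3)
  best <- NULL
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = n_grid)
    lls <- vapply(grid, function(g) eval_lambda(exp(g))$ll, numeric(1))
    k <- which.min(-lls)
    step <- grid[2] - grid[1]
    lo <- grid[k] - 2 * step; hi <- grid[k] + 2 * step
    best <- eval_lambda(exp(grid[k]))
  }
  best
}

# cohort whose units all follow one deterministic line y = intercept +
# slope * (repetition - 1) (+ optional iid noise), weekly schedule
make_line_cohort <- function(n_units = 10, intercept = 40, slope = 1,
                             n_reps = 8, interval_days = 7,
                             test = "e-SDMT", noise_sd = 0, seed = 1) {
  set.seed(seed)
  rec <- do.call(rbind, lapply(seq_len(n_units), function(i) {
    tt <- seq(0, by = interval_days, length.out = n_reps)
    data.frame(
      participant_id = sprintf("L%03d", i), test = test, hand = "none",
      timestamp = as.POSIXct("2020-01-01 12:00:00", tz = "UTC") +
        tt * 86400,
      value = intercept + slope * (seq_len(n_reps) - 1) +
        rnorm(n_reps, 0, noise_sd),
      stringsAsFactors = FALSE)
  }))
  as_cohort(rec)
}

# cohort with unit-specific bounded-growth curves built directly (no
# package generator): used where the generator itself is under test elsewhere
make_curve_cohort <- function(n_units = 20, y0 = 40, boundary = 58,
                              c_rate = 0.1, n_reps = 12, noise_sd = 0,
                              sd_y0 = 0, sd_boundary = 0, seed = 1,
                              test = "e-SDMT") {
  set.seed(seed)
  rec <- do.call(rbind, lapply(seq_len(n_units), function(i) {
    a <- y0 + rnorm(1, 0, sd_y0)
    b <- boundary + rnorm(1, 0, sd_boundary)
    t <- 0:(n_reps - 1)
    data.frame(
      participant_id = sprintf("C%03d", i), test = test, hand = "none",
      timestamp = as.POSIXct("2020-01-01 12:00:00", tz = "UTC") +
        t * 7 * 86400,
      value = b + (a - b) * exp(-c_rate * t) + rnorm(n_reps, 0, noise_sd),
      stringsAsFactors = FALSE)
  }))
  as_cohort(rec)
}

# location-shift cohort for quantile-panel calibration: every quantile of
# y given trial has the same slope (unit intercepts + iid noise)
make_slope_cohort <- function(n_units = 200, slope = 2, sd_unit = 5,
                              sd_noise = 3, n_trials = 5, seed = 1,
                              test = "e-SDMT", intercept = 40) {
  set.seed(seed)
  t <- rep(0:(n_trials - 1), n_units)
  a <- rep(rnorm(n_units, intercept, sd_unit), each = n_trials)
  rec <- data.frame(
    participant_id = rep(sprintf("S%04d", seq_len(n_units)),
                         each = n_trials),
    test = test, hand = "none",
    timestamp = as.POSIXct("2020-01-01 12:00:00", tz = "UTC") +
      (rep(seq_len(n_units), each = n_trials) * 977 + t * 7) * 86400,
    value = a + slope * t + rnorm(n_units * n_trials, 0, sd_noise),
    stringsAsFactors = FALSE)
  as_cohort(rec)
}

# small long-format CSV on disk for loader tests
write_toy_csv <- function(path, days = c(0, 7, 14), values = c(30, 34, 36),
                          test = "e-SDMT", hand = "none", id = "P1",
                          baseline = NULL) {
  df <- data.frame(
    participant_id = id, test_name = test, hand = hand,
    test_date = format(as.Date("2021-01-01") + days, "%Y-%m-%d"),
    metric_name = unname(default_metric_map()[test]),
    metric_value = values,
    age_years = 50, stringsAsFactors = FALSE)
  if (!is.null(baseline)) df$sdmt_baseline <- baseline
  write.csv(df, path, row.names = FALSE)
  path
}
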