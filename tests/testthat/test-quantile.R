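test_that("a zero-loss line is recovered exactly at every quantile", {
  t <- rep(1:5, 3)
  y <- 2 + 3 * (t - 1)
  for (tau in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    f <- fit_quantile_line(t, y, tau)
    expect_equal(unname(f["intercept"]), 2)
    expect_equal(unname(f["slope"]), 3)
    expect_equal(unname(f["loss"]), 0)
  }
})

test_that("small-sample fits equal the pairwise-enumeration oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    t <- sample(1:5, n, replace = TRUE)
    if (length(unique(t)) < 2) next
    y <- round(rnorm(n, 40, 8), 2)
    for (tau in c(0.25, 0.5, 0.9)) {
      f <- fit_quantile_line(t, y, tau)
      orc <- oracle_qr_pairs(t, y, tau)
      expect_lte(unname(f["loss"]), orc$loss + 1e-9)
      expect_equal(unname(f["loss"]),
                   oracle_pinball(t, y, f["intercept"], f["slope"], tau),
                   tolerance = 1e-9)
    }
  }
})

test_that("the large-sample path agrees with exact enumeration", {
  set.seed(7)
  t <- sample(1:5, 400, replace = TRUE)
  y <- 30 + 1.5 * (t - 1) + rnorm(400, 0, 5)
  for (tau in c(0.25, 0.5, 0.75)) {
    exact <- fit_quantile_line(t, y, tau, n_exact = 500)
    approx <- fit_quantile_line(t, y, tau, n_exact = 10)
    expect_equal(unname(approx["loss"]), unname(exact["loss"]),
                 tolerance = 1e-7)
  }
})

test_that("optimal fits balance residual signs within quantile bounds", {
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    t <- sample(1:5, n, replace = TRUE)
    y <- 20 + 2 * (t - 1) + rt(n, df = 3) * 4
    for (tau in c(0.25, 0.5, 0.9)) {
      f <- fit_quantile_line(t, y, tau)
      r <- y - f["intercept"] - f["slope"] * (t - 1)
      expect_lte(sum(r < -1e-9), tau * n + 1e-9)
      expect_lte(sum(r > 1e-9), (1 - tau) * n + 1e-9)
    }
  }
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fit_quantile_line(rep(2, 5), rnorm(5), 0.5),
               "unidentifiable")
  expect_error(fit_quantile_line(1:2, rnorm(2), 0.5), ">= 3 points")
})

test_that("panel slope SEs vanish as the noise vanishes", {
  ses <- vapply(c(2, 0.5, 0.05), function(s) {
    co <- make_slope_cohort(n_units = 40, slope = 2, sd_unit = 0,
                            sd_noise = s, seed = 5)
    qp <- quantile_panel(co, "e-SDMT", n_boot = 120, seed = 1)
    mean(qp$table$slope_se)
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3], 0.05)
})

test_that("panel recovers a common slope with calibrated coverage", {
  hits <- 0L
  for (s in 1:10) {
    co <- make_slope_cohort(n_units = 100, slope = 2, seed = s)
    qp <- quantile_panel(co, "e-SDMT", n_boot = 150, seed = s + 100)
    covered <- qp$table$slope_lower <= 2 & 2 <= qp$table$slope_upper
    if (all(covered)) hits <- hits + 1L
  }
  expect_gte(hits, 7L)  # joint coverage of all five 95% intervals
})

test_that("Bonferroni adjustment multiplies by the slope family size", {
  co <- make_slope_cohort(n_units = 60, slope = 2, seed = 2)
  qp <- quantile_panel(co, "e-SDMT", n_boot = 150, seed = 3)
  expect_equal(qp$table$slope_p_bonferroni,
               pmin(1, qp$table$slope_p * length(qp$taus)))
  # intercepts nondecreasing in tau (quantile monotonicity at baseline)
  expect_true(all(diff(qp$table$intercept) > -1e-6))
})

test_that("the equality test is exact under equality and permutation-stable", {
  fake <- list(table = data.frame(slope = rep(1.7, 5)),
               slope_vcov = diag(5) * 0.04)
  eq <- slope_equality_test(fake)
  expect_equal(unname(eq["statistic"]), 0)
  expect_equal(unname(eq["p"]), 1)

  set.seed(9)
  b <- c(1.2, 1.8, 2.0, 2.4, 3.1)
  A <- matrix(rnorm(25), 5)
  V <- crossprod(A) / 10
  w1 <- slope_equality_test(list(table = data.frame(slope = b),
                                 slope_vcov = V))
  perm <- 5:1
  w2 <- slope_equality_test(list(table = data.frame(slope = b[perm]),
                                 slope_vcov = V[perm, perm]))
  expect_equal(w1["statistic"], w2["statistic"], tolerance = 1e-10)

  expect_error(slope_equality_test(list(table = data.frame(slope = b),
                                        slope_vcov = matrix(0, 5, 5))),
               "n_boot")
})

test_that("a divergent top-quantile slope is detected with high power", {
  rejections <- 0L
  for (s in 1:5) {
    set.seed(s)
    n_units <- 300
    n_trials <- 5
    t <- rep(0:(n_trials - 1), n_units)
    # inverse-CDF construction: rows above the u = 0.925 threshold gain an
    # extra 1.0 per trial, so the conditional 95th-percentile slope is
    # exactly 3 while all quantiles below 0.925 keep slope 2
    N <- n_units * n_trials
    u <- runif(N)
    y <- 40 + 2 * t + qnorm(u) + t * 1.0 * (u >= 0.925)
    rec <- data.frame(
      participant_id = rep(sprintf("D%04d", 1:n_units), each = n_trials),
      test = "e-SDMT", hand = "none",
      timestamp = as.POSIXct("2020-01-01 12:00:00", tz = "UTC") +
        (rep(1:n_units, each = n_trials) * 991 + t * 7) * 86400,
      value = y, stringsAsFactors = FALSE)
    qp <- quantile_panel(as_cohort(rec), "e-SDMT", n_boot = 150,
                         seed = s + 50)
    if (qp$slope_equality["p"] < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 4L)
})
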