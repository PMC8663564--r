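test_that("noiseless shared-line data collapse the linear mixed model", {
  co <- make_line_cohort(n_units = 8, intercept = 40, slope = 1.25,
                         n_reps = 8)
  fit <- fit_linear_mixed(co, "e-SDMT")
  expect_equal(unname(fit$fixed), c(40, 1.25), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-5)
  expect_lt(fit$var_unit, 1e-6)
  expect_equal(fit$df, 4)
})

test_that("an exact parabola is recovered by the quadratic mixed model", {
  base <- as.POSIXct("2020-01-01 12:00:00", tz = "UTC")
  rec <- do.call(rbind, lapply(1:6, function(i) {
    t <- 0:9
    data.frame(participant_id = sprintf("Q%02d", i), test = "e-SDMT",
               hand = "none", timestamp = base + t * 7 * 86400,
               value = 30 + 2 * t - 0.1 * t^2, stringsAsFactors = FALSE)
  }))
  fit <- fit_quadratic_mixed(as_cohort(rec), "e-SDMT")
  expect_equal(unname(fit$fixed), c(30, 2, -0.1), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-5)
  expect_equal(fit$df, 5)
})

test_that("linear mixed estimates match the profiled-likelihood oracle", {
  set.seed(55)
  base <- as.POSIXct("2020-01-01 12:00:00", tz = "UTC")
  rec <- do.call(rbind, lapply(1:100, function(i) {
    t <- 0:7
    u <- rnorm(1, 0, 3)
    data.frame(participant_id = sprintf("M%03d", i), test = "e-SDMT",
               hand = "none", timestamp = base + t * 7 * 86400,
               value = 35 + 0.8 * t + u + rnorm(8, 0, 2),
               stringsAsFactors = FALSE)
  }))
  co <- as_cohort(rec)
  fit <- fit_linear_mixed(co, "e-SDMT")
  d <- data.frame(unit = co$records$unit_id, t = co$records$t_rep,
                  y = co$records$value)
  orc <- oracle_lmm_profile(d)
  expect_equal(unname(fit$fixed), unname(orc$beta), tolerance = 1e-4)
  expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-4)
  expect_equal(fit$var_unit, orc$var_unit, tolerance = 1e-3)
})

test_that("quadratic never loses likelihood to linear (nesting)", {
  for (s in 1:3) {
    sim <- simulate_cohort(sim_config(n_units = 40), seed = s)
    co <- select_units(sim$cohort)$cohort
    lin <- fit_linear_mixed(co, "e-SDMT")
    quad <- fit_quadratic_mixed(co, "e-SDMT")
    expect_gte(quad$loglik, lin$loglik - 1e-6)
    expect_lte(quad$rmse, lin$rmse * (1 + 1e-8))
  }
})

test_that("the spline uses ~2 effective df on straight-line data", {
  co <- make_line_cohort(n_units = 6, intercept = 20, slope = 0.7,
                         n_reps = 12)
  fit <- fit_spline(co, "e-SDMT", unit_intercept = FALSE)
  expect_equal(fit$edf, 2, tolerance = 0.1)
  expect_lt(fit$rmse, 1e-4)
  # fewer than 4 distinct time points is an error
  co3 <- make_line_cohort(n_units = 6, n_reps = 3)
  expect_error(fit_spline(co3, "e-SDMT"), "distinct time values")
})

test_that("the spline tracks curvature that defeats the linear model", {
  co <- make_curve_cohort(n_units = 10, y0 = 40, boundary = 58,
                          c_rate = 0.25, n_reps = 15, noise_sd = 0)
  sp <- fit_spline(co, "e-SDMT", unit_intercept = FALSE)
  ln <- fit_linear_mixed(co, "e-SDMT")
  expect_lt(sp$rmse, ln$rmse)
})

test_that("a single noiseless unit is recovered exactly (NLS limit)", {
  co <- make_curve_cohort(n_units = 1, y0 = 10, boundary = 20,
                          c_rate = log(2), n_reps = 6, noise_sd = 0)
  fit <- fit_bounded_growth(co, "e-SDMT", random = FALSE)
  expect_equal(fit$mu_y0, 10, tolerance = 1e-6)
  expect_equal(fit$mu_boundary, 20, tolerance = 1e-6)
  expect_equal(fit$c, log(2), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)
})

test_that("zero-variance fits equal the grid-search pooled NLS oracle", {
  for (s in 1:3) {
    co <- make_curve_cohort(n_units = 20, y0 = 40, boundary = 58,
                            c_rate = 0.08, n_reps = 14, noise_sd = 3,
                            seed = s)
    fit <- fit_bounded_growth(co, "e-SDMT", random = FALSE)
    r <- co$records
    orc <- oracle_nls_grid(r$t_rep, r$value)
    expect_equal(fit$mu_y0, orc$y0, tolerance = 1e-6)
    expect_equal(fit$mu_boundary, orc$boundary, tolerance = 1e-6)
    expect_equal(fit$c, orc$c, tolerance = 1e-6)
  }
})

test_that("the mixed bounded-growth fit recovers simulated parameters", {
  cfg <- sim_config(n_units = 150, mu_y0 = 40, mu_boundary = 58,
                    c_rate = 0.06, sd_y0 = 5, sd_boundary = 5,
                    sigma_resid = 3)
  sim <- simulate_cohort(cfg, seed = 77)
  co <- select_units(sim$cohort)$cohort
  fit <- fit_bounded_growth(co, "e-SDMT")
  expect_equal(fit$df, 6)
  expect_lt(abs(fit$mu_y0 - 40) / 40, 0.05)
  expect_lt(abs(fit$mu_boundary - 58) / 58, 0.05)
  expect_lt(abs(fit$c - 0.06) / 0.06, 0.10)
  expect_gt(fit$var_y0, 1)
  expect_gt(fit$var_boundary, 1)
  expect_equal(nrow(fit$blups), fit$n_units)
})

test_that("practice metrics satisfy the analytic identities", {
  co <- make_curve_cohort(n_units = 12, y0 = 40, boundary = 58,
                          c_rate = 0.06, n_reps = 15, noise_sd = 1,
                          sd_y0 = 2, sd_boundary = 2, seed = 3)
  fit <- fit_bounded_growth(co, "e-SDMT")
  pm <- practice_metrics(fit, levels = c(0.25, 0.5, 0.9, 0.99))
  tp <- pm$practice_points
  expect_equal(tp$t, -log(1 - tp$level) / fit$c, tolerance = 1e-15)
  t50 <- tp$t[tp$level == 0.5]
  t90 <- tp$t[tp$level == 0.9]
  expect_equal(t90 / t50, log(10) / log(2), tolerance = 1e-12)

  # c = ln 2 gives a half-practice point of exactly one repetition
  fake <- fit
  fake$c <- log(2)
  expect_equal(practice_metrics(fake)$practice_points$t[1], 1)

  # mean curve monotone, tangent slope positive and decreasing
  tt <- seq(0, 40, by = 0.5)
  curve <- mean_curve(fit$mu_y0, fit$mu_boundary, fit$c, tt)
  expect_true(all(diff(curve) > 0))
  m <- fit$c * (fit$mu_boundary - fit$mu_y0) * exp(-fit$c * tt)
  pm2 <- practice_metrics(fit, tangent_at = tt)
  expect_equal(pm2$tangent$slope, m, tolerance = 1e-12)
  expect_true(all(pm2$tangent$slope > 0))
  expect_true(all(diff(pm2$tangent$slope) < 0))

  bad <- fit
  bad$c <- -1
  expect_error(practice_metrics(bad), "positive")
})

test_that("model comparison reproduces the expected RMSE ordering", {
  cfg <- sim_config(n_units = 120, mu_y0 = 40, mu_boundary = 58,
                    c_rate = 0.06, sd_y0 = 5, sd_boundary = 5,
                    sigma_resid = 3)
  sim <- simulate_cohort(cfg, seed = 5)
  co <- select_units(sim$cohort)$cohort
  bg <- fit_bounded_growth(co, "e-SDMT")
  sp <- fit_spline(co, "e-SDMT")
  qd <- fit_quadratic_mixed(co, "e-SDMT")
  ln <- fit_linear_mixed(co, "e-SDMT")
  cmp <- compare_models(bg, sp, qd, ln)
  expect_equal(cmp$best, "bounded")
  expect_lt(qd$rmse, ln$rmse)

  # mismatched inputs are refused
  co2 <- select_units(simulate_cohort(cfg, seed = 6)$cohort)$cohort
  ln2 <- fit_linear_mixed(co2, "e-SDMT")
  expect_error(compare_models(bg, sp, qd, ln2), "mismatched")
})
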