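triple_cohort <- function(values_list, test = "e-SDMT", ages = NULL) {
  base <- as.POSIXct("2021-01-01 12:00:00", tz = "UTC")
  rec <- do.call(rbind, lapply(seq_along(values_list), function(i) {
    v <- values_list[[i]]
    data.frame(participant_id = sprintf("T%02d", i), test = test,
               hand = "none", timestamp = base + seq_along(v) * 7 * 86400,
               value = v, stringsAsFactors = FALSE)
  }))
  parts <- NULL
  if (!is.null(ages)) {
    parts <- data.frame(participant_id = sprintf("T%02d",
                                                 seq_along(values_list)),
                        age_years = ages, stringsAsFactors = FALSE)
  }
  as_cohort(rec, parts)
}

test_that("score triples extract first, fifth and last positions", {
  co <- triple_cohort(list(c(10, 12, 14, 16, 18, 20),
                           rep(30, 7),
                           c(0, 1, 2, 3, 4, 5)))
  tr <- score_triples(co, "e-SDMT")
  tr <- tr[order(tr$unit_id), ]
  expect_equal(tr$first, c(10, 30, 0))
  expect_equal(tr$fifth, c(18, 30, 4))
  expect_equal(tr$last, c(20, 30, 5))
  expect_equal(tr$n_reps, c(6L, 7L, 6L))
  expect_equal(tr$pct_usable, c(TRUE, TRUE, FALSE))
  # units with fewer than 5 repetitions yield no triple
  co4 <- triple_cohort(list(c(1, 2, 3, 4)))
  expect_equal(nrow(score_triples(co4, "e-SDMT")), 0)
})

test_that("percent changes chain multiplicatively and constants give zero", {
  co <- triple_cohort(list(rep(30, 6)))
  tr <- score_triples(co, "e-SDMT")
  pct <- function(a, b) 100 * (b - a) / a
  expect_equal(pct(tr$first, tr$fifth), 0)
  expect_equal(pct(tr$fifth, tr$last), 0)

  sim <- simulate_cohort(sim_config(n_units = 40), seed = 17)
  tr2 <- score_triples(select_units(sim$cohort)$cohort, "e-SDMT")
  p15 <- pct(tr2$first, tr2$fifth)
  p5l <- pct(tr2$fifth, tr2$last)
  p1l <- pct(tr2$first, tr2$last)
  expect_equal((1 + p15 / 100) * (1 + p5l / 100), 1 + p1l / 100,
               tolerance = 1e-12)
})

test_that("two-unit improvement summary matches the hand t formula", {
  # pct changes are +10% and +20%: mean 15, half-width qt(.975,1)*sd/sqrt(2)
  co <- triple_cohort(list(c(100, 100, 100, 105, 100, 110),
                           c(100, 100, 100, 100, 100, 120)))
  s <- improvement_summary(score_triples(co, "e-SDMT"))
  half <- qt(0.975, 1) * sd(c(10, 20)) / sqrt(2)
  expect_equal(s$table["pct_1_to_last", "mean"], 15)
  expect_equal(s$table["pct_1_to_last", "lower"], 15 - half)
  expect_equal(s$table["pct_1_to_last", "upper"], 15 + half)
  expect_equal(unname(s$pooled_pct["pct_1_to_last"]), 15)
})

test_that("percent improvements are invariant to metric rescaling", {
  sim <- simulate_cohort(sim_config(n_units = 30), seed = 18)
  co <- select_units(sim$cohort)$cohort
  s1 <- improvement_summary(score_triples(co, "e-SDMT"))
  co$records$value <- co$records$value * 3.7
  s2 <- improvement_summary(score_triples(co, "e-SDMT"))
  pct_rows <- c("pct_1_to_5", "pct_5_to_last", "pct_1_to_last")
  expect_equal(s1$table[pct_rows, ], s2$table[pct_rows, ],
               tolerance = 1e-12)
  expect_equal(s2$table["abs_1_to_last", "mean"],
               3.7 * s1$table["abs_1_to_last", "mean"], tolerance = 1e-12)
})

test_that("lower-better tests keep signed percent changes", {
  co <- triple_cohort(list(c(30, 28, 26, 24, 22, 20),
                           c(40, 36, 32, 28, 26, 24)),
                      test = "StaticBalance")
  s <- improvement_summary(score_triples(co, "StaticBalance"),
                           direction = "lower_better")
  expect_lt(s$table["pct_1_to_last", "mean"], 0)
})

test_that("fifth-to-last regression matches the normal-equation oracle", {
  set.seed(101)
  n <- 500
  age <- rnorm(n, 50, 10)
  first <- rnorm(n, 40, 8)
  fifth <- first + rnorm(n, 5, 2)
  n_reps <- pmax(5, round(exp(rnorm(n, 2.5, 0.8))))
  truth <- c(2, 0.05, -0.3, 0.2, 3)  # intercept, age, first, fifth, log_reps
  y <- truth[1] + truth[2] * age + truth[3] * first + truth[4] * fifth +
    truth[5] * log(n_reps) + rnorm(n, 0, 2)
  triples <- data.frame(unit_id = as.character(seq_len(n)),
                        first = first, fifth = fifth, last = fifth + y,
                        n_reps = n_reps, age_years = age,
                        pct_usable = TRUE)
  fit <- fifth_to_last_regression(triples)
  X <- cbind(1, age, first, fifth, log(n_reps))
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coefficients[, 1]), unname(drop(beta_oracle)),
               tolerance = 1e-10)
  se <- fit$coefficients[, 2]
  expect_true(all(abs(fit$coefficients[, 1] - truth) <= 2 * se))
  # residual orthogonality to every design column at machine precision
  r <- resid(fit$fit)
  expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-8)
})

test_that("a zero response gives zero coefficients and R^2 = 0", {
  triples <- data.frame(unit_id = as.character(1:20),
                        first = rnorm(20, 40), fifth = rnorm(20, 45),
                        n_reps = 5:24, age_years = rnorm(20, 50),
                        pct_usable = TRUE)
  triples$last <- triples$fifth
  fit <- fifth_to_last_regression(triples)
  expect_equal(unname(fit$coefficients[, 1]), rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
})

test_that("rank-deficient designs are reported with the collinear column", {
  triples <- data.frame(unit_id = as.character(1:20),
                        first = 1:20, fifth = 1:20, last = (1:20) + 2,
                        n_reps = rep(6, 20), age_years = rnorm(20, 50),
                        pct_usable = TRUE)
  expect_error(fifth_to_last_regression(triples), "collinear")
})

test_that("correlation panel handles perfect and degenerate cases", {
  x <- rnorm(30)
  self <- correlation_panel(x, x)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$spearman_rho, 1)
  anti <- correlation_panel(x, -x)
  expect_equal(anti$pearson_r, -1)
  expect_error(correlation_panel(x[1:2], x[1:2]), ">= 3")
})
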