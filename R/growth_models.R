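# assemble the modeling frame for one test on the chosen time axis
model_frame <- function(cohort, test, time_axis = c("repetition", "weeks")) {
  time_axis <- match.arg(time_axis)
  r <- test_records(cohort, test)
  if (nrow(r) == 0) stop("no records for test '", test, "'", call. = FALSE)
  data.frame(unit = factor(r$unit_id),
             t = if (time_axis == "repetition") r$t_rep else r$t_weeks,
             rep_index = r$repetition_index,
             y = r$value)
}

rmse_of <- function(res) sqrt(mean(res^2))

#' Linear mixed learning-curve model
#'
#' Maximum-likelihood fit of \code{y = b0 + b1 t + u_i + e} with a random
#' intercept per analysis unit (df = 4: two fixed effects, one random-effect
#' variance, the residual variance). RMSE is conditional, i.e. computed from
#' BLUP-inclusive residuals, so all four learning-curve models are compared
#' on fit-to-observations.
#'
#' @param cohort A selected cohort.
#' @param test Test name.
#' @param time_axis \code{"repetition"} (t = repetition index - 1) or
#'   \code{"weeks"} (weeks since the unit's first test).
#' @return Object of class \code{"practice_lmm"} with elements
#'   \code{fixed}, \code{var_unit}, \code{sigma2}, \code{loglik},
#'   \code{rmse}, \code{df}, \code{fit}.
#' @export
fit_linear_mixed <- function(cohort, test,
                             time_axis = c("repetition", "weeks")) {
  d <- model_frame(cohort, test, time_axis)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ t + (1 | unit), data = d, REML = FALSE))),
    error = function(e) stop("linear mixed model failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    name = "linear", test = test, time_axis = match.arg(time_axis),
    fixed = lme4::fixef(fit),
    var_unit = vc$vcov[vc$grp == "unit"],
    sigma2 = vc$vcov[vc$grp == "Residual"],
    loglik = as.numeric(stats::logLik(fit)),
    rmse = rmse_of(resid(fit)), df = 4, n = nrow(d), fit = fit
  ), class = "practice_lmm")
}

#' Quadratic mixed learning-curve model
#'
#' As \code{\link{fit_linear_mixed}} with an added fixed quadratic time term
#' (df = 5).
#'
#' @inheritParams fit_linear_mixed
#' @return Object of class \code{"practice_lmm"} (\code{df = 5}).
#' @export
fit_quadratic_mixed <- function(cohort, test,
                                time_axis = c("repetition", "weeks")) {
  d <- model_frame(cohort, test, time_axis)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ t + I(t^2) + (1 | unit), data = d, REML = FALSE))),
    error = function(e) stop("quadratic mixed model failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    name = "quadratic", test = test, time_axis = match.arg(time_axis),
    fixed = lme4::fixef(fit),
    var_unit = vc$vcov[vc$grp == "unit"],
    sigma2 = vc$vcov[vc$grp == "Residual"],
    loglik = as.numeric(stats::logLik(fit)),
    rmse = rmse_of(resid(fit)), df = 5, n = nrow(d), fit = fit
  ), class = "practice_lmm")
}

#' @export
print.practice_lmm <- function(x, ...) {
  cat(sprintf("%s mixed model (%s axis): df = %d, RMSE = %.4g\n",
              x$name, x$time_axis, x$df, x$rmse))
  cat("  fixed:", paste(sprintf("%s = %.4g", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  cat(sprintf("  var(unit) = %.4g, sigma^2 = %.4g, logLik = %.2f\n",
              x$var_unit, x$sigma2, x$loglik))
  invisible(x)
}

#' Penalized-spline learning-curve smoother
#'
#' Penalized cubic regression spline of performance on time fitted as a
#' generalized additive model, smoothing parameter chosen by generalized
#' cross-validation; it exposes the unconstrained shape of the learning
#' curve. By default a unit-level random-intercept smooth carries the
#' grouping structure, putting the smoother on the same conditional footing
#' as the mixed models; set \code{unit_intercept = FALSE} for a pure
#' population smoother. Effective df is the trace of the influence matrix.
#'
#' @inheritParams fit_linear_mixed
#' @param k Basis dimension of the time smooth (default 10, reduced when
#'   fewer distinct time values are present).
#' @param unit_intercept Include \code{s(unit, bs = "re")}.
#' @return Object of class \code{"practice_gam"} with \code{edf} (total),
#'   \code{edf_time} (time smooth only), \code{rmse}, \code{fit}.
#' @export
fit_spline <- function(cohort, test, time_axis = c("repetition", "weeks"),
                       k = 10, unit_intercept = TRUE) {
  d <- model_frame(cohort, test, time_axis)
  n_t <- length(unique(d$t))
  if (n_t < 4) stop("need >= 4 distinct time values for the spline",
                    call. = FALSE)
  k <- min(k, n_t)
  use_re <- unit_intercept && nlevels(d$unit) > 1
  form <- if (use_re) y ~ s(t, bs = "cr", k = k) + s(unit, bs = "re")
          else y ~ s(t, bs = "cr", k = k)
  fit <- mgcv::gam(form, data = d, method = "GCV.Cp")
  structure(list(
    name = "spline", test = test, time_axis = match.arg(time_axis),
    edf = sum(fit$hat),
    edf_time = sum(fit$edf[fit$smooth[[1]]$first.para:
                             fit$smooth[[1]]$last.para]),
    unit_intercept = use_re,
    rmse = rmse_of(residuals(fit)), n = nrow(d), fit = fit
  ), class = "practice_gam")
}

#' @export
print.practice_gam <- function(x, ...) {
  cat(sprintf("penalized spline (%s axis): edf = %.2f (time smooth %.2f), RMSE = %.4g\n",
              x$time_axis, x$edf, x$edf_time, x$rmse))
  invisible(x)
}

# pooled profile of the growth constant: for fixed c the bounded-growth mean
# is linear in (y0, boundary); 50-point log-grid with closed-form sub-fit
profile_c_grid <- function(t, y, n_grid = 50, c_range = NULL) {
  tmax <- max(t)
  if (is.null(c_range)) c_range <- c(0.01 / max(tmax, 1), 25 / max(tmax, 1))
  grid <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_grid))
  best <- NULL
  for (cc in grid) {
    e <- exp(-cc * t)
    X <- cbind(e, 1 - e)
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(c = cc, y0 = unname(f$coefficients[1]),
                   boundary = unname(f$coefficients[2]), rss = rss)
    }
  }
  best
}

bounded_growth_start <- function(d) {
  firsts <- tapply(d$y, d$unit, function(v) v[1])
  last_q <- tapply(seq_len(nrow(d)), d$unit, function(i) {
    v <- d$y[i][order(d$t[i])]
    mean(v[max(1, ceiling(0.75 * length(v))):length(v)])
  })
  prof <- profile_c_grid(d$t, d$y)
  list(y0 = mean(firsts), boundary = mean(last_q), c = prof$c, profile = prof)
}

#' Bounded-growth nonlinear mixed learning-curve model
#'
#' Fits \eqn{y_{ij} = b_i + (a_i - b_i) e^{-c t_{ij}} + e_{ij}} with
#' independent Gaussian random effects on the baseline \eqn{a_i} and the
#' boundary \eqn{b_i} and a fixed growth constant \eqn{c > 0} (df = 6: three
#' fixed effects, two random-effect variances, the residual variance).
#'
#' For fixed \eqn{c} the model is linear in both random effects
#' (\eqn{y = a_i w + b_i (1 - w) + e} with \eqn{w = e^{-ct}}), so the exact
#' marginal likelihood is profiled over \eqn{\log c}: each candidate
#' \eqn{c} is evaluated by an exact maximum-likelihood linear-mixed sub-fit
#' in the basis \eqn{(w, 1-w)}, and the outer one-dimensional profile is
#' minimized by golden-section search after a bracketing grid around a
#' pooled 50-point log-grid start. This avoids the linearization error of
#' iterated-approximation schemes on short, unbalanced series. The Wald CI
#' for \eqn{c} comes from the curvature of the profile deviance; CIs for the
#' baseline and boundary means come from the sub-fit at the optimum.
#'
#' With \code{random = FALSE} the random-effect variances are constrained to
#' zero and the model reduces to pooled nonlinear least squares
#' (Levenberg-Marquardt).
#'
#' @inheritParams fit_linear_mixed
#' @param random Fit unit-level random effects (default) or pooled NLS.
#' @return Object of class \code{"bounded_growth_fit"}: fixed effects
#'   \code{mu_y0}, \code{mu_boundary}, \code{c} with Wald 95% \code{ci};
#'   variances \code{var_y0}, \code{var_boundary}, \code{sigma2};
#'   \code{blups} (per-unit \code{y0_i}, \code{boundary_i}); \code{loglik};
#'   conditional \code{rmse}; \code{df = 6}; \code{time_axis}; \code{fit}.
#' @export
fit_bounded_growth <- function(cohort, test,
                               time_axis = c("repetition", "weeks"),
                               random = TRUE) {
  time_axis <- match.arg(time_axis)
  d <- model_frame(cohort, test, time_axis)
  st <- bounded_growth_start(d)
  start <- c(a = st$y0, b = st$boundary, lc = log(st$c))

  if (!random) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + (a - b) * exp(-exp(lc) * t), data = d,
                        start = as.list(start),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) stop("pooled NLS failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    # polish: profile the RSS over log c with the closed-form linear
    # sub-fit in (y0, boundary); removes the flat-direction convergence
    # slack of the Levenberg-Marquardt stop
    rss_of <- function(lc) {
      e <- exp(-exp(lc) * d$t)
      sum(stats::lm.fit(cbind(e, 1 - e), d$y)$residuals^2)
    }
    opt <- stats::optimize(rss_of, cf[["lc"]] + c(-0.2, 0.2),
                           tol = 1e-12)
    cf[["lc"]] <- opt$minimum
    e <- exp(-exp(cf[["lc"]]) * d$t)
    ab <- stats::lm.fit(cbind(e, 1 - e), d$y)$coefficients
    cf[["a"]] <- unname(ab[1]); cf[["b"]] <- unname(ab[2])
    c_hat <- exp(cf[["lc"]])
    check_c_identifiable(c_hat, d$t)
    res <- d$y - (cf[["b"]] + (cf[["a"]] - cf[["b"]]) * e)
    ci <- rbind(
      mu_y0 = cf[["a"]] + c(-1, 1) * qnorm(.975) * se[["a"]],
      mu_boundary = cf[["b"]] + c(-1, 1) * qnorm(.975) * se[["b"]],
      c = exp(cf[["lc"]] + c(-1, 1) * qnorm(.975) * se[["lc"]]))
    colnames(ci) <- c("lower", "upper")
    rownames(ci) <- c("mu_y0", "mu_boundary", "c")
    return(structure(list(
      name = "bounded", test = test, time_axis = time_axis,
      mu_y0 = cf[["a"]], mu_boundary = cf[["b"]],
      c = c_hat, ci = ci,
      var_y0 = 0, var_boundary = 0,
      sigma2 = sum(res^2) / (length(res) - 3),
      blups = data.frame(unit_id = levels(d$unit),
                         y0_i = cf[["a"]],
                         boundary_i = cf[["b"]],
                         stringsAsFactors = FALSE),
      loglik = as.numeric(stats::logLik(fit)),
      rmse = rmse_of(res), df = 4, random = FALSE,
      n = nrow(d), n_units = nlevels(d$unit), fit = fit
    ), class = "bounded_growth_fit"))
  }

  # exact linear-mixed sub-fit in the basis (w, 1-w) for fixed c
  sub_fit <- function(lc) {
    dd <- d
    dd$w <- exp(-exp(lc) * dd$t)
    dd$v <- 1 - dd$w
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 0 + w + v + (0 + w | unit) + (0 + v | unit),
                 data = dd, REML = FALSE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore"))))
  }
  dev_of <- function(lc) {
    tryCatch(-2 * as.numeric(stats::logLik(sub_fit(lc))),
             error = function(e) NA_real_)
  }

  # bracketing grid around the pooled profile start, then golden section
  lc_grid <- start[["lc"]] + seq(-2.5, 2.5, length.out = 11)
  devs <- vapply(lc_grid, dev_of, numeric(1))
  if (all(is.na(devs))) {
    stop("bounded-growth model failed to converge: no candidate growth ",
         "constant yielded a valid mixed sub-fit", call. = FALSE)
  }
  k <- which.min(devs)
  lo <- lc_grid[max(1, k - 1)]
  hi <- lc_grid[min(length(lc_grid), k + 1)]
  invphi <- (sqrt(5) - 1) / 2
  m1 <- hi - invphi * (hi - lo); m2 <- lo + invphi * (hi - lo)
  g1 <- dev_of(m1); g2 <- dev_of(m2)
  it <- 0
  while (hi - lo > 1e-7 && it < 80) {
    if (is.na(g1) || is.na(g2)) break
    if (g1 <= g2) {
      hi <- m2; m2 <- m1; g2 <- g1
      m1 <- hi - invphi * (hi - lo); g1 <- dev_of(m1)
    } else {
      lo <- m1; m1 <- m2; g1 <- g2
      m2 <- lo + invphi * (hi - lo); g2 <- dev_of(m2)
    }
    it <- it + 1
  }
  lc_hat <- (lo + hi) / 2
  fit <- sub_fit(lc_hat)
  dev_hat <- -2 * as.numeric(stats::logLik(fit))
  c_hat <- exp(lc_hat)
  check_c_identifiable(c_hat, d$t)

  cf <- lme4::fixef(fit)  # w -> baseline mean, v -> boundary mean
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_y0 <- vc$vcov[vc$var1 == "w" & !is.na(vc$var1)][1]
  var_boundary <- vc$vcov[vc$var1 == "v" & !is.na(vc$var1)][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"]

  # curvature of the profile deviance gives the Wald SE of log(c)
  h <- 0.05
  d2 <- dev_of(lc_hat + h) + dev_of(lc_hat - h) - 2 * dev_hat
  se_lc <- if (is.finite(d2) && d2 > 0) h * sqrt(2 / d2) else NA_real_

  re <- stats::coef(fit)$unit  # per-unit (a_i, b_i)
  blups <- data.frame(unit_id = rownames(re), y0_i = re$w,
                      boundary_i = re$v, stringsAsFactors = FALSE)
  res <- resid(fit)
  ci <- rbind(
    mu_y0 = cf[["w"]] + c(-1, 1) * qnorm(.975) * se[["w"]],
    mu_boundary = cf[["v"]] + c(-1, 1) * qnorm(.975) * se[["v"]],
    c = exp(lc_hat + c(-1, 1) * qnorm(.975) * se_lc))
  colnames(ci) <- c("lower", "upper")
  structure(list(
    name = "bounded", test = test, time_axis = time_axis,
    mu_y0 = cf[["w"]], mu_boundary = cf[["v"]],
    c = c_hat, ci = ci,
    var_y0 = var_y0, var_boundary = var_boundary,
    sigma2 = sigma2, blups = blups,
    loglik = -dev_hat / 2,
    rmse = rmse_of(res), df = 6, random = TRUE,
    n = nrow(d), n_units = nlevels(d$unit), fit = fit
  ), class = "bounded_growth_fit")
}

check_c_identifiable <- function(c_hat, t) {
  tmax <- max(t)
  if (c_hat * tmax < 1e-4) {
    stop("growth constant collapsed toward 0 (flat curve): the boundary is ",
         "not identifiable; consider the linear mixed model", call. = FALSE)
  }
  if (c_hat * min(diff(sort(unique(t)))) > 50) {
    stop("growth constant diverged (instantaneous learning): the baseline ",
         "is not identifiable; consider the linear mixed model",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.bounded_growth_fit <- function(x, ...) {
  cat(sprintf("bounded growth mixed model (%s axis): df = %d, RMSE = %.4g\n",
              x$time_axis, x$df, x$rmse))
  cat(sprintf("  y0 = %.4g (%.4g to %.4g), boundary = %.4g (%.4g to %.4g)\n",
              x$mu_y0, x$ci["mu_y0", 1], x$ci["mu_y0", 2],
              x$mu_boundary, x$ci["mu_boundary", 1], x$ci["mu_boundary", 2]))
  cat(sprintf("  c = %.4g per %s (%.4g to %.4g)\n", x$c,
              sub("repetition", "repetition", x$time_axis),
              x$ci["c", 1], x$ci["c", 2]))
  cat(sprintf("  var(y0) = %.4g, var(boundary) = %.4g, sigma^2 = %.4g\n",
              x$var_y0, x$var_boundary, x$sigma2))
  invisible(x)
}

#' Compare the four learning-curve models
#'
#' Tabulates conditional RMSE and (effective) df for the bounded-growth,
#' spline, quadratic and linear fits of the same cohort/test/time-axis; the
#' best model has the lowest RMSE (ties broken by fewest df).
#'
#' @param bounded,spline,quadratic,linear The four fit objects.
#' @return Object of class \code{"model_comparison"}: \code{table} (name,
#'   rmse, df) sorted by RMSE and \code{best}.
#' @export
compare_models <- function(bounded, spline, quadratic, linear) {
  fits <- list(bounded = bounded, spline = spline,
               quadratic = quadratic, linear = linear)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  tests <- vapply(fits, function(f) f$test, character(1))
  axes <- vapply(fits, function(f) f$time_axis, character(1))
  if (length(unique(ns)) != 1 || length(unique(tests)) != 1 ||
      length(unique(axes)) != 1) {
    stop("fits come from mismatched cohorts, tests or time axes",
         call. = FALSE)
  }
  tab <- data.frame(
    model = c("bounded", "spline", "quadratic", "linear"),
    rmse = c(bounded$rmse, spline$rmse, quadratic$rmse, linear$rmse),
    df = c(bounded$df, spline$edf, quadratic$df, linear$df)
  )
  ord <- order(tab$rmse, tab$df)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$model[1], test = tests[1],
                 time_axis = axes[1], n = ns[1]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Learning-curve model comparison (%s, %s axis, %d records):\n",
              x$test, x$time_axis, x$n))
  print(x$table, row.names = FALSE, digits = 4)
  cat("best (lowest RMSE):", x$best, "\n")
  invisible(x)
}

#' Practice metrics from a bounded-growth fit
#'
#' Derived quantities of the fitted learning curve: the practice points
#' \eqn{t_p = -\ln(1-p)/c} (time at which a fraction p of the baseline-to-
#' boundary gap is closed; for any c, t90/t50 = ln(10)/ln(2)), the
#' boundary improvement over baseline in percent — the mean of per-unit BLUP
#' ratios 100 (boundary_i - y0_i) / y0_i with a t-based 95% CI, alongside the
#' fixed-effect ratio with a delta-method CI — and the tangent slope
#' \eqn{m(t) = c (boundary - y_0) e^{-ct}} of the fixed-effect curve at
#' requested times.
#'
#' @param fit A converged \code{\link{fit_bounded_growth}}.
#' @param levels Gap fractions for practice points (default 0.5 and 0.9).
#' @param tangent_at Times at which to evaluate the tangent slope (default:
#'   0 and the practice points).
#' @return Object of class \code{"practice_metrics"}: \code{practice_points}
#'   (raw and rounded-to-integer), \code{pct_improvement} (BLUP mean, CI, n),
#'   \code{pct_improvement_fixed} (estimate, delta-method CI),
#'   \code{tangent} (t, slope), \code{time_axis}.
#' @export
practice_metrics <- function(fit, levels = c(0.5, 0.9), tangent_at = NULL) {
  stopifnot(inherits(fit, "bounded_growth_fit"))
  if (!is.finite(fit$c) || fit$c <= 0) {
    stop("undefined metrics: growth constant must be positive",
         call. = FALSE)
  }
  tp <- -log(1 - levels) / fit$c
  names(tp) <- sprintf("t%02d", round(100 * levels))
  if (is.null(tangent_at)) tangent_at <- c(0, unname(tp))
  slope <- fit$c * (fit$mu_boundary - fit$mu_y0) * exp(-fit$c * tangent_at)

  b <- fit$blups
  ok <- b$y0_i != 0
  ratios <- 100 * (b$boundary_i[ok] - b$y0_i[ok]) / b$y0_i[ok]
  imp <- if (length(ratios) >= 2) mean_t_ci(ratios) else
    c(mean = mean(ratios), lower = NA, upper = NA, n = length(ratios))

  # delta method on g = 100 (b - a) / a over the fixed effects (a, b)
  a <- fit$mu_y0; bo <- fit$mu_boundary
  grad <- c(-100 * bo / a^2, 100 / a)
  V <- if (fit$random) {
    as.matrix(vcov(fit$fit))[c("w", "v"), c("w", "v")]
  } else {
    vcov(fit$fit)[c("a", "b"), c("a", "b")]
  }
  se_fixed <- sqrt(drop(t(grad) %*% V %*% grad))
  est_fixed <- 100 * (bo - a) / a
  structure(list(
    practice_points = data.frame(level = levels, t = unname(tp),
                                 t_rounded = round(unname(tp))),
    pct_improvement = imp,
    pct_improvement_fixed = c(estimate = est_fixed,
                              lower = est_fixed - qnorm(.975) * se_fixed,
                              upper = est_fixed + qnorm(.975) * se_fixed),
    tangent = data.frame(t = tangent_at, slope = slope),
    c = fit$c, time_axis = fit$time_axis
  ), class = "practice_metrics")
}

#' @export
print.practice_metrics <- function(x, ...) {
  u <- if (x$time_axis == "repetition") "repetitions" else "weeks"
  for (i in seq_len(nrow(x$practice_points))) {
    cat(sprintf("  %d%% practice point: %.2f %s (~%d)\n",
                round(100 * x$practice_points$level[i]),
                x$practice_points$t[i], u, x$practice_points$t_rounded[i]))
  }
  cat(sprintf("  boundary improvement over baseline: %.1f%% (%.1f to %.1f) [unit-level]\n",
              x$pct_improvement["mean"], x$pct_improvement["lower"],
              x$pct_improvement["upper"]))
  cat(sprintf("                                      %.1f%% (%.1f to %.1f) [fixed-effect]\n",
              x$pct_improvement_fixed["estimate"],
              x$pct_improvement_fixed["lower"],
              x$pct_improvement_fixed["upper"]))
  invisible(x)
}
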