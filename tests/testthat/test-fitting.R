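test_that("BetaGeneral evaluators: analytic mean, uniform special case, inversion", {
  s <- betageneral_stats(3.5954, 23.116, 6.3774, 126.35)
  expect_equal(s$mean, 6.3774 + (126.35 - 6.3774) * 3.5954 / (3.5954 + 23.116),
               tolerance = 1e-12)
  # Beta(1,1) on [a,b] is Uniform(a,b)
  u <- betageneral_stats(1, 1, 2, 10)
  xs <- seq(2, 10, by = 0.5)
  expect_equal(u$cdf(xs), punif(xs, 2, 10), tolerance = 1e-12)
  # cdf/quantile inversion on a grid
  grid <- seq(0.001, 0.999, length.out = 101)
  expect_equal(s$cdf(s$quantile(grid)), grid, tolerance = 1e-9)
  expect_error(betageneral_stats(-1, 2, 0, 1), "positive")
  expect_error(betageneral_stats(1, 2, 5, 5), "min < max")
})

test_that("cdf(quantile(u)) = u for every family", {
  fams <- distribution_families()
  pars <- list(betageneral = c(2, 5, 1, 9), normal = c(3, 2),
               lognormal = c(0.5, 0.4), gamma = c(2, 0.5),
               weibull = c(1.5, 4), triangular = c(0, 2, 10),
               uniform = c(-1, 4))
  grid <- seq(0.01, 0.99, length.out = 50)
  for (f in names(fams)) {
    q <- fams[[f]]$quantile(grid, pars[[f]])
    expect_equal(fams[[f]]$cdf(q, pars[[f]]), grid, tolerance = 1e-9,
                 label = paste("family", f))
    expect_true(all(diff(q) >= 0))
  }
})

test_that("closed-form MLEs: normal and uniform", {
  set.seed(41)
  x <- rnorm(500, 12, 3)
  fn <- fit_mle(x, "normal")
  expect_equal(unname(fn$params), c(mean(x), sqrt(mean((x - mean(x))^2))),
               tolerance = 1e-12)
  fu <- fit_mle(x, "uniform")
  expect_equal(unname(fu$params), range(x), tolerance = 1e-12)
  expect_error(fit_mle(rep(5, 50), "normal"), "degenerate")
  expect_error(fit_mle(c(1, 2, 3), "betageneral"), "too small")
})

test_that("BetaGeneral recovery at n = 5000 within pilot-calibrated bounds", {
  # (shape2, max) are ridge-coupled (the rescaled beta degenerates towards a
  # gamma as max grows) and only weakly identified at this n: pilot runs over
  # seeds 1..10 gave median errors ~8% (shape1), ~20% (shape2), ~0.4 (min),
  # ~18 (max). This guards those levels over a 3-seed panel median; the
  # stricter aspirational tolerances live in the acceptance suite.
  truth <- c(3.6, 23.1, 6.4, 126.4)
  errs <- sapply(1:3, function(seed) {
    set.seed(seed)
    x <- rbetagen(5000, truth[1], truth[2], truth[3], truth[4])
    p <- unname(fit_mle(x, "betageneral")$params)
    expect_true(p[3] < min(x) && p[4] > max(x))
    c(abs(p[1] - truth[1]) / truth[1], abs(p[2] - truth[2]) / truth[2],
      abs(p[3] - truth[3]), abs(p[4] - truth[4]))
  })
  med <- apply(errs, 1, median)
  expect_lt(med[1], 0.15)
  expect_lt(med[2], 0.40)
  expect_lt(med[3], 5)
  expect_lt(med[4], 35)
})

test_that("MLE log-likelihood at the optimum beats the generating parameters", {
  set.seed(43)
  wins <- 0L
  for (rep in 1:20) {
    x <- rgamma(400, shape = 2.5, rate = 0.7)
    fit <- fit_mle(x, "gamma")
    ll_true <- sum(dgamma(x, 2.5, 0.7, log = TRUE))
    if (fit$loglik >= ll_true - 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, 19L)  # >= 95% of replicates
})

test_that("chi_square_gof reproduces the closed-form machinery and edge cases", {
  expect_equal(qchisq(0.95, 28), 41.3371, tolerance = 5e-5)
  expect_equal(pchisq(20.3360, 28, lower.tail = FALSE), 0.8519, tolerance = 5e-5)

  # a sample laid out exactly at equal-probability quantiles -> stat ~ 0, p ~ 1
  set.seed(44)
  fit <- fit_mle(rnorm(600, 5, 2), "normal")
  ideal <- fit$quantile((seq_len(660) - 0.5) / 660)
  g <- chi_square_gof(ideal, fit, n_bins = 33)
  expect_equal(g$chi2_stat, 0, tolerance = 1e-9)
  expect_equal(g$p_value, 1, tolerance = 1e-9)
  expect_equal(g$df, 33 - 1 - 2)
  expect_equal(sum(g$observed), 660)

  expect_error(chi_square_gof(rnorm(50), fit, n_bins = 33), "floor")
  expect_error(chi_square_gof(rnorm(600), fit, n_bins = 3), "df")
})

test_that("default binning yields df = 28 for the four-parameter family", {
  set.seed(45)
  x <- rbetagen(400, 3.6, 23.1, 6.4, 126.4)
  fit <- fit_mle(x, "betageneral")
  g <- chi_square_gof(x, fit, n_bins = 33)
  expect_equal(g$df, 28)
  expect_equal(g$critical_value, qchisq(0.95, 28))
})

test_that("gof p-values are approximately uniform under the null", {
  # scaled-down replicate study: normal family with known-shape samples
  set.seed(46)
  pv <- replicate(300, {
    x <- rnorm(400)
    chi_square_gof(x, fit_mle(x, "normal"), n_bins = 20)$p_value
  })
  ks <- max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
  expect_lt(ks, 0.11)
})

test_that("rank_fits prefers the generating family", {
  set.seed(47)
  xu <- runif(800, 2, 8)
  ru <- rank_fits(xu, c("uniform", "normal"))
  expect_equal(ru$fits$family[1], "uniform")
  expect_equal(ru$best$family, "uniform")

  xn <- rnorm(800, 50, 5)
  rn <- rank_fits(xn, c("normal", "lognormal"))
  expect_equal(rn$fits$family[1], "normal")

  one <- rank_fits(xn, "normal")
  expect_equal(one$best$family, "normal")
  expect_error(rank_fits(rnorm(100) - 100, "lognormal"), "all candidate fits failed")
})

test_that("diagnostics lie on the identity line for exact quantile samples", {
  set.seed(48)
  fit <- fit_mle(rnorm(300, 10, 2), "normal")
  n <- 200
  exact <- fit$quantile((seq_len(n) - 0.5) / n)
  d <- diagnostics(exact, fit)
  expect_equal(d$pp$theoretical, d$pp$empirical, tolerance = 1e-12)
  expect_equal(d$qq$theoretical, d$qq$empirical, tolerance = 1e-12)
  # order invariance
  d2 <- diagnostics(rev(exact), fit)
  expect_equal(d2, d)
  # both sequences non-decreasing in the model coordinate
  expect_true(all(diff(d$pp$theoretical) >= 0))
  expect_true(all(diff(d$qq$theoretical) >= 0))
})

test_that("P-P deviations of a true-model sample stay inside the 99% DKW band", {
  set.seed(49)
  n <- 2000
  x <- rnorm(n, 3, 1.5)
  fit <- fit_mle(x, "normal")
  d <- diagnostics(x, fit)
  band <- sqrt(log(2 / 0.01) / (2 * n))
  expect_lt(max(abs(d$pp$theoretical - d$pp$empirical)), band)
})
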