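test_that("IV-free exposure recovers an exact linear instrument effect", {
  g <- rep(c(0, 1, 2), times = 4)
  x <- 3 + 2 * g
  co <- cohort_table(x, rnorm(12), g)
  ivf <- iv_free_exposure(co)
  expect_equal(ivf$beta_xg, 2)
  expect_equal(ivf$x0, rep(3, 12))
})

test_that("instrument-exposure coefficient matches the closed-form OLS slope", {
  x <- c(2.3, 4.1, 3.0, 5.2, 2.8, 3.9)
  g <- c(0, 2, 1, 2, 0, 1)
  co <- cohort_table(x, rnorm(6), g)
  ivf <- iv_free_exposure(co)
  slope <- sum((g - mean(g)) * (x - mean(x))) / sum((g - mean(g))^2)
  expect_equal(ivf$beta_xg, slope, tolerance = 1e-12)
  # and agrees with lm() exactly
  fit <- lm(x ~ g)
  expect_equal(ivf$beta_xg, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(ivf$se_xg, unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-12)
  # with the adjust flag off, x0 + beta_xg * g reconstructs x exactly
  expect_equal(ivf$x0 + ivf$beta_xg * g, x, tolerance = 1e-12)
})

test_that("instrument effect is recovered under the simulation model", {
  sc <- scenario_config("linear", list(beta = 0.5), reps = 1, seed = 5)
  co <- generate_cohort(sc, 905)
  ivf <- iv_free_exposure(co)
  expect_lt(abs(ivf$beta_xg - 0.25), 3 * ivf$se_xg)
})

test_that("covariate adjustment changes the residual and flags bad designs", {
  set.seed(8)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 50, 5)
  x <- 2 + 0.25 * g + 0.05 * age + rnorm(n)
  co <- cohort_table(x, rnorm(n), g, covariates = data.frame(age = age))
  ivf <- iv_free_exposure(co, adjust_covariates = TRUE)
  fit <- lm(x ~ g + age)
  expect_equal(ivf$x0, unname(residuals(fit)), tolerance = 1e-10)
  expect_equal(ivf$beta_xg, unname(coef(fit)["g"]), tolerance = 1e-12)
  co2 <- cohort_table(x, rnorm(n), g,
                      covariates = data.frame(flat = rep(1.5, n)))
  expect_error(iv_free_exposure(co2, adjust_covariates = TRUE),
               regexp = "flat", class = "lacecurve_estimation_error")
})

test_that("quantile strata have near-equal sizes and a stable tie rule", {
  expect_equal(assign_strata(1:20, 10), rep(1:10, each = 2L))
  expect_equal(assign_strata(rev(1:20), 10), rev(rep(1:10, each = 2L)))
  expect_equal(assign_strata(c(5, 5, 5, 5), 2), c(1L, 1L, 2L, 2L))
  labs <- assign_strata(rnorm(10000), 100)
  expect_equal(unname(table(labs)), rep(100L, 100), ignore_attr = TRUE)
  # sizes differ by at most one when K does not divide n
  labs2 <- assign_strata(rnorm(103), 5)
  expect_lte(diff(range(table(labs2))), 1)
  # invariant to adding a constant
  z <- rnorm(50)
  expect_equal(assign_strata(z, 7), assign_strata(z + 13.7, 7))
  expect_error(assign_strata(1:10, 6), class = "lacecurve_config_error")
})

test_that("LACE is exact on balanced noise-free data and per-stratum means rise", {
  bc <- balanced_cohort(K = 4, slope = 0.5)
  ivf <- iv_free_exposure(bc$cohort)
  expect_equal(ivf$beta_xg, bc$beta_xg, tolerance = 1e-12)
  lace <- estimate_lace(bc$cohort, bc$labels, ivf$beta_xg)
  expect_equal(lace$lace, rep(0.5, 4), tolerance = 1e-12)
  expect_true(all(diff(lace$mean_x) > 0))
  expect_equal(sum(lace$n), nrow(bc$cohort))
})

test_that("a single stratum collapses to the standard ratio IV estimator", {
  set.seed(31)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  u <- runif(n)
  x <- 2 + 0.25 * g + u + rexp(n)
  y <- 0.5 * x + 0.8 * u + rnorm(n)
  co <- cohort_table(x, y, g)
  ivf <- iv_free_exposure(co)
  lace <- estimate_lace(co, rep(1L, n), ivf$beta_xg)
  ratio <- unname(coef(lm(y ~ g))[2] / coef(lm(x ~ g))[2])
  expect_equal(lace$lace, ratio, tolerance = 1e-12)
})

test_that("the ratio estimator is invariant to instrument recoding", {
  set.seed(77)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  u <- runif(n)
  x <- 2 + 0.25 * g + u + rexp(n)
  y <- 0.5 * x + 0.8 * u + rnorm(n)
  co <- cohort_table(x, y, g)
  co_rev <- cohort_table(x, y, 2 - g)
  ivf <- iv_free_exposure(co)
  ivf_rev <- iv_free_exposure(co_rev)
  expect_equal(ivf_rev$beta_xg, -ivf$beta_xg, tolerance = 1e-10)
  labs <- assign_strata(ivf$x0, 5)
  labs_rev <- assign_strata(ivf_rev$x0, 5)
  expect_equal(labs_rev, labs)  # x0 shifts by a constant under recoding
  lace <- estimate_lace(co, labs, ivf$beta_xg)
  lace_rev <- estimate_lace(co_rev, labs_rev, ivf_rev$beta_xg)
  # both ratio terms flip sign, so the LACE and its SE are unchanged
  expect_equal(lace_rev$beta_yg, -lace$beta_yg, tolerance = 1e-10)
  expect_equal(lace_rev$lace, lace$lace, tolerance = 1e-10)
  expect_equal(lace_rev$se_lace, lace$se_lace, tolerance = 1e-10)
  # holding the instrument-exposure coefficient at its original-coding value
  # flips the sign of every LACE while preserving its magnitude
  lace_frozen <- estimate_lace(co_rev, labs_rev, ivf$beta_xg)
  expect_equal(lace_frozen$lace, -lace$lace, tolerance = 1e-10)
})

test_that("grouped closed-form regression matches lm within strata", {
  set.seed(99)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- 1 + 0.3 * g + rnorm(n)
  labels <- assign_strata(rnorm(n), 3)
  go <- lacecurve:::.grouped_ols(y, g, labels, 3L)
  for (k in 1:3) {
    fit <- lm(y[labels == k] ~ g[labels == k])
    expect_equal(go$beta[k], unname(coef(fit)[2]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(go$se[k], unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a stratum with a constant instrument is reported by number", {
  set.seed(4)
  g <- c(rep(1, 10), rbinom(10, 2, 0.5))
  co <- cohort_table(rnorm(20) + 3, rnorm(20), g)
  labels <- rep(1:2, each = 10L)
  expect_error(estimate_lace(co, labels, 0.25), regexp = "stratum 1",
               class = "lacecurve_estimation_error")
})
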