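test_that("derivative designs match hand values and symbolic differentiation", {
  x <- c(1, 2, 4)
  expect_equal(drop(fp_derivative_design(x, fp_spec(1, 1))), rep(1, 3))
  expect_equal(drop(fp_derivative_design(x, fp_spec(1, 0))), c(1, 0.5, 0.25))
  # repeated power 2 at x = 3: d/dx of (b1 x^2 + b2 x^2 ln x)
  d <- fp_derivative_design(3, fp_spec(2, c(2, 2)))
  expect_equal(drop(d), c(6, 6 * log(3) + 3))
  # every candidate design is the numerical derivative of its basis
  xs <- c(0.7, 1.3, 2.9, 5.1)
  h <- 1e-6
  for (spec in lacecurve:::.all_fp_specs()) {
    num <- (lacecurve:::.fp_basis(xs + h, spec) -
              lacecurve:::.fp_basis(xs - h, spec)) / (2 * h)
    expect_equal(fp_derivative_design(xs, spec), num, tolerance = 1e-6)
  }
  expect_error(fp_derivative_design(c(1, -1), fp_spec(1, 0.5)),
               class = "lacecurve_data_error")
})

test_that("linear-power metaregression equals the inverse-variance-weighted mean", {
  lace <- toy_lace(lace = c(0.4, 0.9, 0.3, 0.7), se = c(0.2, 0.5, 0.1, 0.3))
  fit <- fit_metareg(lace, fp_spec(1, 1))
  w <- 1 / lace$se_lace^2
  ivw <- sum(w * lace$lace) / sum(w)
  expect_equal(unname(fit$coefficients), ivw, tolerance = 1e-12)
  expect_equal(unname(drop(fit$vcov)), 1 / sum(w), tolerance = 1e-12)
  # constant LACE with equal SEs: coefficient c, zero residual
  lc <- toy_lace(lace = rep(0.8, 5))
  fitc <- fit_metareg(lc, fp_spec(1, 1))
  expect_equal(unname(fitc$coefficients), 0.8, tolerance = 1e-12)
  expect_equal(fitc$fitted, rep(0.8, 5), tolerance = 1e-12)
})

test_that("metaregression likelihood and coefficients match metafor", {
  lace <- toy_lace(lace = c(0.2, 0.5, 0.9, 1.4, 1.1),
                   se = c(0.15, 0.12, 0.2, 0.25, 0.18))
  for (spec in list(fp_spec(1, 0), fp_spec(1, 2), fp_spec(2, c(0, 2)),
                    fp_spec(2, c(1, 1)))) {
    fit <- fit_metareg(lace, spec)
    expect_equal(fit$loglik, metafor_loglik(lace, spec), tolerance = 1e-8)
  }
  # random effects: DerSimonian-Laird moment estimator vs metafor method="DL"
  X <- fp_derivative_design(lace$mean_x, fp_spec(1, 1))
  ref <- suppressWarnings(
    metafor::rma(yi = lace$lace, vi = lace$se_lace^2, mods = ~ 0 + X,
                 method = "DL"))
  fit_re <- fit_metareg(lace, fp_spec(1, 1), effects = "random")
  expect_equal(fit_re$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(unname(fit_re$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # fixed effects always report tau2 = 0
  expect_identical(fit_metareg(lace, fp_spec(1, 1))$tau2, 0)
})

test_that("model selection matches a brute-force enumeration oracle", {
  lace <- toy_lace(lace = c(2.1, 0.9, 0.55, 0.4), se = c(0.2, 0.1, 0.08, 0.1),
                   mean_x = c(1.5, 3, 4.5, 6))
  sel <- select_model(lace)
  # oracle: metafor log-likelihood for each of the 44 candidate models
  ll1 <- vapply(lacecurve:::.all_fp_specs(degree = 1L),
                function(s) metafor_loglik(lace, s), numeric(1))
  ll2 <- vapply(lacecurve:::.all_fp_specs(degree = 2L),
                function(s) metafor_loglik(lace, s), numeric(1))
  best1_oracle <- lacecurve:::.all_fp_specs(degree = 1L)[[which.max(ll1)]]
  best2_oracle <- lacecurve:::.all_fp_specs(degree = 2L)[[which.max(ll2)]]
  expect_equal(sel$best1$spec$powers, best1_oracle$powers)
  expect_equal(sel$best2$spec$powers, best2_oracle$powers)
  expect_equal(sel$chosen_degree,
               if (2 * (max(ll2) - max(ll1)) > qchisq(0.95, 2)) 2L else 1L)
  # nesting of maximized likelihoods: deg2 >= deg1 >= linear
  lin <- fit_metareg(lace, fp_spec(1, 1))$loglik
  expect_gte(sel$best2$loglik, sel$best1$loglik - 1e-12)
  expect_gte(sel$best1$loglik, lin - 1e-12)
})

test_that("LACE proportional to 1/x selects the log curve", {
  mean_x <- c(2, 3, 4.5, 6)
  lace <- toy_lace(lace = 2 / mean_x, se = rep(0.001, 4), mean_x = mean_x)
  sel <- select_model(lace)
  expect_equal(sel$best1$spec$powers, 0)
})

test_that("anchored curves pass through zero and integrate the derivative", {
  lace <- toy_lace(lace = c(0.45, 0.5, 0.55, 0.52), se = rep(0.05, 4))
  fit <- fit_metareg(lace, fp_spec(1, 1))
  fit$coefficients <- 0.5  # pin the slope for the hand-checked value
  cv <- fp_curve(fit, c(2, 6), x_ref = 2)
  expect_equal(cv$estimate[cv$x == 6], 0.5 * (6 - 2), tolerance = 1e-12)
  fit0 <- fit_metareg(lace, fp_spec(1, 0))
  fit0$coefficients <- 2
  cv0 <- fp_curve(fit0, c(1, exp(1)), x_ref = 1)
  expect_equal(cv0$estimate[cv0$x == exp(1)], 2, tolerance = 1e-12)
  # f(x_ref) = 0 exactly, bands bracket the estimate
  for (spec in list(fp_spec(1, -2), fp_spec(2, c(0, 0)), fp_spec(2, c(0.5, 3)))) {
    f <- fit_metareg(lace, spec)
    cvs <- fp_curve(f, seq(1.5, 7, length.out = 51), x_ref = 3.3)
    expect_equal(cvs$estimate[cvs$x == 3.3], 0)
    expect_true(all(cvs$ci_low <= cvs$estimate + 1e-12))
    expect_true(all(cvs$ci_high >= cvs$estimate - 1e-12))
    # finite differences of the curve reproduce the fitted derivative
    grid <- seq(2, 6, length.out = 2001)
    cfine <- fp_curve(f, grid, x_ref = 4)
    mid <- 2:2000
    num <- (cfine$estimate[mid + 1] - cfine$estimate[mid - 1]) /
      (cfine$x[mid + 1] - cfine$x[mid - 1])
    an <- drop(fp_derivative_design(cfine$x[mid], spec) %*% f$coefficients)
    expect_equal(num, an, tolerance = 1e-5)
    # moving the anchor shifts the curve by a constant only
    c2 <- fp_curve(f, grid, x_ref = 5)
    shift <- cfine$estimate - c2$estimate[match(cfine$x, c2$x)]
    shift <- shift[!is.na(shift)]
    expect_lt(max(abs(shift - shift[1])), 1e-10)
  }
})

test_that("bootstrap LACE tables freeze strata and reproduce analytic spread", {
  set.seed(12)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  u <- runif(n)
  x <- 2 + 0.25 * g + u + rexp(n)
  y <- 0.5 * x + 0.8 * u + rnorm(n)
  co <- cohort_table(x, y, g)
  ivf <- iv_free_exposure(co)
  labels <- assign_strata(ivf$x0, 5)
  lace <- estimate_lace(co, labels, ivf$beta_xg)
  boots <- bootstrap_lace(co, labels, ivf$beta_xg, B = 300, seed = 9)
  expect_length(boots, 300)
  for (b in boots[1:3]) {
    expect_equal(b$mean_x, lace$mean_x, tolerance = 1e-12)
    expect_equal(attr(b, "beta_xg"), ivf$beta_xg, tolerance = 1e-12)
  }
  bm <- vapply(boots, function(b) b$lace, numeric(5))
  sd_ratio <- apply(bm, 1, sd) / lace$se_lace
  expect_true(all(sd_ratio > 0.8 & sd_ratio < 1.2))
  # deterministic given the seed
  boots2 <- bootstrap_lace(co, labels, ivf$beta_xg, B = 3, seed = 9)
  expect_identical(boots2[[1]]$lace, boots[[1]]$lace)
  # the vectorized ratio-only path has the same sampling distribution
  bmat <- lacecurve:::.bootstrap_lace_matrix(co, labels, ivf$beta_xg,
                                             B = 300, seed = 10)
  sd_ratio2 <- apply(bmat, 1, sd) / lace$se_lace
  expect_true(all(sd_ratio2 > 0.8 & sd_ratio2 < 1.2))
})

test_that("bootstrap curves give percentile bands around the analytic curve", {
  lace <- toy_lace(lace = c(0.4, 0.5, 0.6, 0.7), se = rep(0.05, 4))
  fit <- fit_metareg(lace, fp_spec(1, 1))
  set.seed(3)
  boots <- lapply(1:200, function(b) {
    lb <- lace
    lb$lace <- lace$lace + rnorm(4, 0, lace$se_lace)
    lb$beta_yg <- lb$lace * attr(lace, "beta_xg")
    lb
  })
  cv <- fp_curve(fit, c(2, 4, 6), x_ref = 2, ci = "bootstrap", boot_laces = boots)
  expect_true(all(cv$ci_low <= cv$estimate & cv$estimate <= cv$ci_high))
  expect_error(fp_curve(fit, c(2, 4), x_ref = 2, ci = "bootstrap"),
               class = "lacecurve_config_error")
})
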