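# Tests of nonlinearity on a LACE table: Cochran Q heterogeneity, the
# quadratic trend test, and the fractional-polynomial likelihood-ratio test.

.test_result <- function(name, statistic, df, p_value) {
  structure(list(name = name, statistic = statistic, df = as.integer(df),
                 p_value = p_value),
            class = "nonlin_test")
}

#' @export
print.nonlin_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %d, p = %.4g\n",
              x$name, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.nonlin_test <- function(x, ...) {
  data.frame(name = x$name, statistic = x$statistic, df = x$df,
             p_value = x$p_value)
}

#' Cochran Q heterogeneity test
#'
#' Tests whether the stratum LACE estimates differ more than expected by
#' chance: \eqn{Q = \sum_k (\widehat{LACE}_k - \bar L)^2 / se_k^2} with
#' \eqn{\bar L} the inverse-variance-weighted mean, referred to a
#' chi-squared distribution with K-1 df.
#'
#' @param lace a \code{lace_table} with at least 2 strata.
#' @return A \code{nonlin_test}.
#' @export
cochran_q <- function(lace) {
  K <- nrow(lace)
  if (K < 2L) .config_error("Cochran Q needs at least 2 strata")
  w <- 1 / lace$se_lace^2
  lbar <- sum(w * lace$lace) / sum(w)
  Q <- sum(w * (lace$lace - lbar)^2)
  .test_result("Q", Q, K - 1L, pchisq(Q, df = K - 1L, lower.tail = FALSE))
}

#' Quadratic trend test
#'
#' Metaregresses the LACE estimates on the stratum mean exposures (with
#' intercept, weights \eqn{1/se_k^2}) and tests the slope with a Wald z
#' statistic; a linear trend in the localized effects is equivalent to a
#' quadratic exposure-outcome relationship. The statistic reported is
#' \eqn{z^2} on 1 df with a two-sided normal p-value.
#'
#' @param lace a \code{lace_table} with at least 3 strata.
#' @return A \code{nonlin_test}.
#' @export
quadratic_test <- function(lace) {
  K <- nrow(lace)
  if (K < 3L) .config_error("quadratic trend test needs at least 3 strata")
  X <- cbind(1, lace$mean_x)
  w <- 1 / lace$se_lace^2
  V <- solve(t(X * w) %*% X)
  beta <- drop(V %*% (t(X * w) %*% lace$lace))
  z <- beta[2L] / sqrt(V[2L, 2L])
  .test_result("quadratic", z^2, 1L, 2 * pnorm(-abs(z)))
}

#' Fractional-polynomial test of nonlinearity
#'
#' Compares twice the log-likelihood gap between the best-fitting degree-1
#' fractional polynomial and the linear model (power 1) against a
#' chi-squared distribution with 1 df. The statistic is zero, and the
#' p-value one, exactly when the best-fitting power is 1.
#'
#' @param lace a \code{lace_table} with at least 3 strata.
#' @param powers candidate power set.
#' @param effects metaregression effects model.
#' @return A \code{nonlin_test}.
#' @export
fp_test <- function(lace, powers = fp_power_set(),
                    effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  if (nrow(lace) < 3L) .config_error("FP test needs at least 3 strata")
  fits <- lapply(.all_fp_specs(powers, 1L), function(s) fit_metareg(lace, s, effects))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  linear <- which(vapply(fits, function(f) f$spec$powers == 1, logical(1)))
  if (!length(linear)) .config_error("power set must contain 1 for the FP test")
  stat <- max(0, 2 * (max(ll) - ll[linear]))
  .test_result("fp", stat, 1L, pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Set of near-best fractional polynomials
#'
#' Among candidate fits of a common degree, returns those whose twice
#' log-likelihood deficit relative to the best-fitting model is below the
#' \code{level} percentile of a chi-squared distribution with m df (m = the
#' common degree). The best-fitting model is always a member.
#'
#' @param fits list of \code{fp_fit} objects of the same degree.
#' @param level percentile defining the set (default 0.90).
#' @return logical vector marking the members of the set.
#' @export
set_membership <- function(fits, level = 0.90) {
  degs <- vapply(fits, function(f) f$spec$degree, integer(1))
  if (length(unique(degs)) != 1L)
    .config_error("set membership requires candidates of a single degree")
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  2 * (max(ll) - ll) < qchisq(level, df = degs[1L])
}

#' Run all three nonlinearity tests
#'
#' @param lace a \code{lace_table}.
#' @param powers candidate power set for the FP test.
#' @return data.frame with one row per test (name, statistic, df, p_value).
#' @export
nonlinearity_tests <- function(lace, powers = fp_power_set()) {
  do.call(rbind, lapply(list(cochran_q(lace), quadratic_test(lace),
                             fp_test(lace, powers)), as.data.frame))
}
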