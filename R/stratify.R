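# IV-free exposure, quantile strata, and per-stratum LACE estimation.

#' Compute the IV-free exposure
#'
#' Regresses the exposure on the instrument (plus covariates when
#' \code{adjust_covariates = TRUE}) and returns the exposure with the
#' genetically predicted component removed -- the control function on which
#' the population is stratified. With the flag off, the IV-free exposure is
#' \eqn{x - \hat\beta_{X|G} g} (the expected exposure at an instrument value
#' of zero); with the flag on it is the residual from the full regression,
#' matching the covariate-adjusted workflow.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param adjust_covariates logical; regress out the covariate columns too.
#' @return list with \code{x0} (IV-free exposure vector), \code{beta_xg}
#'   (whole-population instrument-exposure coefficient) and \code{se_xg}.
#' @export
iv_free_exposure <- function(cohort, adjust_covariates = FALSE) {
  covs <- attr(cohort, "covariates")
  if (sd(cohort$g) == 0) .data_error("instrument has zero variance")
  if (adjust_covariates && length(covs)) {
    const <- covs[vapply(covs, function(nm) sd(cohort[[nm]]) == 0, logical(1))]
    if (length(const))
      .estimation_error(sprintf("constant covariate column(s): %s",
                                paste(const, collapse = ", ")))
    fit <- lm(reformulate(c("g", covs), response = "x"), data = cohort)
    cf <- coef(fit)
    if (anyNA(cf))
      .estimation_error(sprintf("singular design; aliased column(s): %s",
                                paste(names(cf)[is.na(cf)], collapse = ", ")))
    list(x0 = as.numeric(residuals(fit)),
         beta_xg = unname(cf["g"]),
         se_xg = sqrt(vcov(fit)["g", "g"]))
  } else {
    f <- .simple_ols(cohort$x, cohort$g)
    list(x0 = cohort$x - f$beta * cohort$g, beta_xg = f$beta, se_xg = f$se)
  }
}

#' Assign quantile strata
#'
#' Rank-based assignment of individuals to \code{K} equal-size strata of a
#' vector (normally the IV-free exposure). Stratum sizes differ by at most
#' one; ties are broken by original row order so results are reproducible.
#'
#' @param x0 numeric vector to stratify on.
#' @param K number of strata (at least 2, at most \code{length(x0)/2}).
#' @return integer vector of stratum labels in 1..K.
#' @export
assign_strata <- function(x0, K) {
  n <- length(x0)
  K <- as.integer(K)
  if (K < 2L) .config_error("K must be at least 2")
  if (K > n / 2) .config_error(sprintf("K = %d too large for n = %d (need n >= 2K)", K, n))
  r <- rank(x0, ties.method = "first")
  as.integer(ceiling(r * K / n))
}

#' Estimate localized average causal effects
#'
#' Within each stratum, regresses the outcome on the instrument (plus
#' covariates when \code{adjust_covariates = TRUE}) and forms the LACE as
#' the ratio of the stratum-specific instrument-outcome coefficient to the
#' whole-population instrument-exposure coefficient
#' \eqn{\widehat{LACE}_k = \hat\beta_{Y|G,k} / \hat\beta_{X|G}}, with
#' standard error \eqn{se(\hat\beta_{Y|G,k}) / |\hat\beta_{X|G}|} (the
#' leading delta-method term). \code{mean_x} is the mean of the observed
#' exposure (not the IV-free exposure) in the stratum; it is the
#' metaregression covariate.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param labels integer stratum labels from \code{\link{assign_strata}}.
#' @param beta_xg whole-population instrument-exposure coefficient (from
#'   \code{\link{iv_free_exposure}}), reused in every stratum.
#' @param adjust_covariates logical; adjust the within-stratum regressions.
#' @return A \code{lace_table}: data.frame with columns \code{stratum},
#'   \code{n}, \code{beta_yg}, \code{se_yg}, \code{lace}, \code{se_lace},
#'   \code{mean_x}; attribute \code{beta_xg}.
#' @export
estimate_lace <- function(cohort, labels, beta_xg, adjust_covariates = FALSE) {
  K <- max(labels)
  n_k <- tabulate(labels, nbins = K)
  if (any(n_k < 3L))
    .estimation_error(sprintf("stratum %d has fewer than 3 individuals",
                              which(n_k < 3L)[1L]))
  covs <- attr(cohort, "covariates")
  if (adjust_covariates && length(covs)) {
    beta_yg <- se_yg <- numeric(K)
    for (k in seq_len(K)) {
      sub <- cohort[labels == k, , drop = FALSE]
      if (sd(sub$g) == 0)
        .estimation_error(sprintf(
          "instrument is constant in stratum %d; reduce the number of strata", k))
      fit <- lm(reformulate(c("g", covs), response = "y"), data = sub)
      beta_yg[k] <- unname(coef(fit)["g"])
      se_yg[k] <- sqrt(vcov(fit)["g", "g"])
    }
  } else {
    go <- .grouped_ols(cohort$y, cohort$g, labels, K)
    if (anyNA(go$beta))
      .estimation_error(sprintf(
        "instrument is constant in stratum %d; reduce the number of strata",
        which(is.na(go$beta))[1L]))
    beta_yg <- go$beta
    se_yg <- go$se
  }
  mean_x <- rowsum(cohort$x, labels)[, 1L] / n_k
  lace_table(stratum = seq_len(K), n = n_k, beta_yg = beta_yg, se_yg = se_yg,
             beta_xg = beta_xg, mean_x = mean_x)
}

#' Assemble a LACE table
#'
#' Lower-level constructor used by \code{\link{estimate_lace}} and the
#' bootstrap: forms the ratio estimates and standard errors from
#' per-stratum instrument-outcome coefficients and the shared
#' instrument-exposure coefficient.
#'
#' @param stratum integer stratum ids 1..K.
#' @param n per-stratum sizes.
#' @param beta_yg,se_yg per-stratum instrument-outcome coefficient and SE.
#' @param beta_xg shared instrument-exposure coefficient.
#' @param mean_x per-stratum mean observed exposure.
#' @return A \code{lace_table} data.frame.
#' @export
lace_table <- function(stratum, n, beta_yg, se_yg, beta_xg, mean_x) {
  if (beta_xg == 0) .estimation_error("instrument-exposure coefficient is zero")
  df <- data.frame(stratum = as.integer(stratum), n = as.integer(n),
                   beta_yg = beta_yg, se_yg = se_yg,
                   lace = beta_yg / beta_xg, se_lace = se_yg / abs(beta_xg),
                   mean_x = mean_x)
  structure(df, beta_xg = beta_xg, class = c("lace_table", "data.frame"))
}
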