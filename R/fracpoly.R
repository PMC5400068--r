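# Fractional-polynomial metaregression of LACE estimates on the derivative
# scale, model selection, anchored exposure-outcome curves, and the
# within-stratum bootstrap of the LACE table.

#' Standard fractional-polynomial power set
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Specify a fractional polynomial
#'
#' Degree 1 is \eqn{f(x) = \beta_0 + \beta_1 x^p}; degree 2 is
#' \eqn{\beta_0 + \beta_1 x^{p_1} + \beta_2 x^{p_2}} for distinct powers and
#' \eqn{\beta_0 + \beta_1 x^p + \beta_2 x^p \log x} for a repeated power,
#' with \eqn{x^0} read as \eqn{\log x} throughout. Powers are stored in
#' canonical (sorted) order.
#'
#' @param degree 1 or 2.
#' @param powers one power (degree 1) or two (degree 2), from the power set.
#' @param power_set allowed powers (default \code{\link{fp_power_set}}).
#' @return An object of class \code{fp_spec}.
#' @export
fp_spec <- function(degree, powers, power_set = fp_power_set()) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) .config_error("degree must be 1 or 2")
  if (length(powers) != degree)
    .config_error("number of powers must equal the degree")
  if (!all(powers %in% power_set))
    .config_error(sprintf("powers must be drawn from {%s}",
                          paste(power_set, collapse = ", ")))
  structure(list(degree = degree, powers = sort(as.numeric(powers))),
            class = "fp_spec")
}

#' @export
format.fp_spec <- function(x, ...) {
  sprintf("fp(degree %d; powers %s)", x$degree, paste(x$powers, collapse = ", "))
}

#' @export
print.fp_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Derivative-scale design columns of a fractional polynomial
#'
#' Because a causal effect estimates the derivative of the exposure-outcome
#' relationship, the metaregression design is the derivative of the
#' fractional polynomial: for degree 1, \eqn{p x^{p-1}} (or \eqn{1/x} for
#' \eqn{p = 0}); for degree 2 with distinct powers, one such column per
#' power; for a repeated power \eqn{p \ne 0}, the columns
#' \eqn{(p x^{p-1},\; p x^{p-1}\log x + x^{p-1})}; for
#' \eqn{p_1 = p_2 = 0}, \eqn{(1/x,\; 2\log x / x)}.
#'
#' @param x positive numeric vector (stratum mean exposures).
#' @param spec an \code{\link{fp_spec}}.
#' @return numeric matrix with one column per coefficient.
#' @export
fp_derivative_design <- function(x, spec) {
  if (any(x <= 0)) .data_error("fractional-power design requires x > 0")
  d1 <- function(p) if (p == 0) 1 / x else p * x^(p - 1)
  p <- spec$powers
  if (spec$degree == 1L) {
    m <- cbind(d1(p))
  } else if (p[1] != p[2]) {
    m <- cbind(d1(p[1]), d1(p[2]))
  } else if (p[1] == 0) {
    m <- cbind(1 / x, 2 * log(x) / x)
  } else {
    q <- p[1]
    m <- cbind(q * x^(q - 1), q * x^(q - 1) * log(x) + x^(q - 1))
  }
  if (!all(is.finite(m)))
    .estimation_error("non-finite design value (extreme power/exposure combination)")
  m
}

# Antiderivative basis: the fractional-polynomial terms themselves, whose
# derivative gives the columns of fp_derivative_design. Used to rebuild the
# exposure-outcome curve from the fitted derivative-scale coefficients.
.fp_basis <- function(x, spec) {
  b1 <- function(p) if (p == 0) log(x) else x^p
  p <- spec$powers
  if (spec$degree == 1L) cbind(b1(p))
  else if (p[1] != p[2]) cbind(b1(p[1]), b1(p[2]))
  else if (p[1] == 0) cbind(log(x), log(x)^2)
  else cbind(x^p[1], x^p[1] * log(x))
}

#' Fit a fractional-polynomial metaregression to a LACE table
#'
#' Weighted least squares (no intercept: the curve's constant differentiates
#' away) of the LACE estimates on the derivative-scale design evaluated at
#' the stratum mean exposures, with weights \eqn{1/se_k^2}. Under random
#' effects, an additive between-stratum variance \eqn{\tau^2} is estimated
#' by the DerSimonian-Laird method of moments (truncated at zero) and the
#' fit is redone with weights \eqn{1/(se_k^2 + \tau^2)}. The log-likelihood
#' is the normal likelihood with known per-stratum variances
#' \eqn{v_k = se_k^2 (+ \tau^2)}.
#'
#' @param lace a \code{lace_table}.
#' @param spec an \code{\link{fp_spec}}.
#' @param effects \code{"fixed"} or \code{"random"}.
#' @return An object of class \code{fp_fit}: spec, \code{coefficients},
#'   \code{vcov}, \code{loglik}, \code{effects}, \code{tau2}, \code{fitted}.
#' @export
fit_metareg <- function(lace, spec, effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  K <- nrow(lace)
  X <- fp_derivative_design(lace$mean_x, spec)
  p <- ncol(X)
  if (K < p + 1L)
    .estimation_error(sprintf("need at least %d strata to fit %d coefficient(s)",
                              p + 1L, p))
  l <- lace$lace
  v <- lace$se_lace^2
  if (any(v <= 0)) .estimation_error("nonpositive LACE variance")
  wls <- function(vv) {
    w <- 1 / vv
    XtW <- t(X * w)
    V <- solve(XtW %*% X)
    beta <- drop(V %*% (XtW %*% l))
    fitted <- drop(X %*% beta)
    ll <- sum(dnorm(l, fitted, sqrt(vv), log = TRUE))
    list(beta = beta, V = V, fitted = fitted, loglik = ll)
  }
  tau2 <- 0
  fit <- wls(v)
  if (effects == "random") {
    w <- 1 / v
    Q <- sum(w * (l - fit$fitted)^2)
    XtWX_inv <- fit$V
    trc <- sum(w) - sum(diag(XtWX_inv %*% (t(X * w^2) %*% X)))
    tau2 <- max(0, (Q - (K - p)) / trc)
    fit <- wls(v + tau2)
  }
  structure(list(spec = spec, coefficients = fit$beta, vcov = fit$V,
                 loglik = fit$loglik, effects = effects, tau2 = tau2,
                 fitted = fit$fitted, mean_x = lace$mean_x),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(format(x$spec), sprintf("[%s effects]", x$effects), "\n")
  cat("coefficients:", paste(formatC(x$coefficients, digits = 6), collapse = ", "), "\n")
  cat("log-likelihood:", formatC(x$loglik, digits = 6), "\n")
  if (x$effects == "random") cat("tau2:", formatC(x$tau2, digits = 6), "\n")
  invisible(x)
}

#' @export
summary_list.fp_fit <- function(object, ...) {
  list(degree = object$spec$degree, powers = object$spec$powers,
       coefficients = object$coefficients,
       vcov = object$vcov, loglik = object$loglik,
       effects = object$effects, tau2 = object$tau2)
}

# All candidate specs: 8 of degree 1; 36 of degree 2 (28 distinct pairs
# plus 8 repeated-power log-augmented models).
.all_fp_specs <- function(powers = fp_power_set(), degree = c(1L, 2L)) {
  specs <- list()
  if (1L %in% degree)
    for (p in powers) specs[[length(specs) + 1L]] <- fp_spec(1, p, powers)
  if (2L %in% degree)
    for (i in seq_along(powers)) for (j in i:length(powers))
      specs[[length(specs) + 1L]] <- fp_spec(2, c(powers[i], powers[j]), powers)
  specs
}

# Pick the maximum-likelihood fit; ties broken toward powers closest to 1.
.best_fit <- function(fits) {
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- which(ll >= max(ll) - 1e-12)
  if (length(best) > 1L) {
    dist1 <- vapply(fits[best], function(f) sum(abs(f$spec$powers - 1)), numeric(1))
    best <- best[order(dist1)]
  }
  fits[[best[1L]]]
}

#' Select the best-fitting fractional polynomial
#'
#' Fits every degree-1 and degree-2 model over the power set, picks the
#' maximum-likelihood fit within each degree, and prefers degree 2 only if
#' twice the log-likelihood gain over the best degree-1 model exceeds the
#' 95th percentile of a chi-squared distribution with 2 df. Log-likelihood
#' ties are broken toward the lower degree and then toward powers closest
#' to 1.
#'
#' @param lace a \code{lace_table} (at least 4 strata).
#' @param powers candidate power set.
#' @param effects passed to \code{\link{fit_metareg}}.
#' @return list with \code{best1}, \code{best2} (fp_fit), \code{chosen}
#'   (the selected fit), \code{chosen_degree}, \code{p_deg2_vs_deg1}, and
#'   \code{fits1}, \code{fits2} (all candidate fits by degree).
#' @export
select_model <- function(lace, powers = fp_power_set(),
                         effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  if (nrow(lace) < 4L) .estimation_error("model selection needs at least 4 strata")
  fits1 <- lapply(.all_fp_specs(powers, 1L), function(s) fit_metareg(lace, s, effects))
  fits2 <- lapply(.all_fp_specs(powers, 2L), function(s) fit_metareg(lace, s, effects))
  best1 <- .best_fit(fits1)
  best2 <- .best_fit(fits2)
  stat <- 2 * (best2$loglik - best1$loglik)
  p21 <- pchisq(max(stat, 0), df = 2, lower.tail = FALSE)
  use2 <- stat > qchisq(0.95, df = 2)
  list(best1 = best1, best2 = best2,
       chosen = if (use2) best2 else best1,
       chosen_degree = if (use2) 2L else 1L,
       p_deg2_vs_deg1 = p21, fits1 = fits1, fits2 = fits2)
}

#' Anchored exposure-outcome curve from a fractional-polynomial fit
#'
#' Integrates the fitted derivative-scale model back to the curve
#' \eqn{f(x) = \sum_j \hat\beta_j (B_j(x) - B_j(x_{ref}))}, where the
#' \eqn{B_j} are the fractional-polynomial basis terms, so that
#' \eqn{f(x_{ref}) = 0} exactly (the curve's intercept is not identified
#' and is anchored at a reference exposure). Analytic confidence bands use
#' \eqn{f(x) \pm 1.96 \sqrt{d^\top V d}} with \eqn{d} the anchored basis
#' vector; bootstrap bands take pointwise 2.5/97.5 percentiles of curves
#' refitted on bootstrap LACE tables.
#'
#' @param fit an \code{fp_fit}.
#' @param grid positive, strictly increasing grid of exposure values.
#' @param x_ref positive reference exposure (inserted into the grid).
#' @param ci \code{"analytic"} or \code{"bootstrap"}.
#' @param boot_laces list of bootstrap \code{lace_table}s (required for
#'   bootstrap bands).
#' @return A \code{curve_estimate}: data.frame with columns \code{x},
#'   \code{estimate}, \code{ci_low}, \code{ci_high}; attributes
#'   \code{x_ref} and \code{ci_method}.
#' @export
fp_curve <- function(fit, grid, x_ref, ci = c("analytic", "bootstrap"),
                     boot_laces = NULL) {
  ci <- match.arg(ci)
  if (x_ref <= 0 || any(grid <= 0)) .data_error("grid and x_ref must be positive")
  grid <- sort(unique(c(grid, x_ref)))
  spec <- fit$spec
  D <- .fp_basis(grid, spec) - matrix(.fp_basis(x_ref, spec), nrow = length(grid),
                                      ncol = spec$degree, byrow = TRUE)
  est <- drop(D %*% fit$coefficients)
  if (ci == "analytic") {
    se <- sqrt(rowSums((D %*% fit$vcov) * D))
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
  } else {
    if (is.null(boot_laces)) .config_error("bootstrap bands require boot_laces")
    curves <- vapply(boot_laces, function(bl) {
      drop(D %*% fit_metareg(bl, spec, fit$effects)$coefficients)
    }, numeric(length(grid)))
    qs <- apply(curves, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
    lo <- pmin(qs[1L, ], est)
    hi <- pmax(qs[2L, ], est)
  }
  structure(data.frame(x = grid, estimate = est, ci_low = lo, ci_high = hi),
            x_ref = x_ref, ci_method = ci,
            class = c("curve_estimate", "data.frame"))
}

#' Default curve grid
#'
#' 101 equally spaced points between the 1st and 99th percentiles of the
#' observed exposure.
#'
#' @param x observed exposure vector.
#' @param length_out number of grid points.
#' @return numeric vector.
#' @export
curve_grid <- function(x, length_out = 101L) {
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  seq(q[1L], q[2L], length.out = length_out)
}

#' Bootstrap the LACE table
#'
#' Resamples individuals with replacement independently within each
#' stratum and re-estimates only the per-stratum instrument-outcome
#' coefficients; the strata, stratum mean exposures, and the
#' instrument-exposure coefficient are frozen at their original values. A
#' resampled stratum with a constant instrument is redrawn (up to
#' \code{max_retries} per replicate, logged via a message) before erroring.
#' Deterministic given \code{seed}.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param labels stratum labels.
#' @param beta_xg frozen instrument-exposure coefficient.
#' @param B number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param adjust_covariates logical; covariate-adjusted within-stratum fits.
#' @param max_retries redraw cap per replicate.
#' @return list of \code{B} \code{lace_table}s.
#' @export
bootstrap_lace <- function(cohort, labels, beta_xg, B, seed,
                           adjust_covariates = FALSE, max_retries = 10L) {
  if (B < 1L) .config_error("B must be at least 1")
  set.seed(seed)
  K <- max(labels)
  idx_k <- split(seq_along(labels), labels)
  n_k <- lengths(idx_k)
  mean_x <- rowsum(cohort$x, labels)[, 1L] / n_k
  covs <- attr(cohort, "covariates")
  one_rep <- function() {
    for (attempt in seq_len(max_retries)) {
      beta_yg <- se_yg <- numeric(K)
      ok <- TRUE
      for (k in seq_len(K)) {
        take <- idx_k[[k]][sample.int(n_k[k], n_k[k], replace = TRUE)]
        g <- cohort$g[take]
        if (sd(g) == 0) { ok <- FALSE; break }
        if (adjust_covariates && length(covs)) {
          sub <- cohort[take, , drop = FALSE]
          fit <- lm(reformulate(c("g", covs), response = "y"), data = sub)
          beta_yg[k] <- unname(coef(fit)["g"])
          se_yg[k] <- sqrt(vcov(fit)["g", "g"])
        } else {
          f <- .simple_ols(cohort$y[take], g)
          beta_yg[k] <- f$beta
          se_yg[k] <- f$se
        }
      }
      if (ok)
        return(lace_table(seq_len(K), n_k, beta_yg, se_yg, beta_xg, mean_x))
      message(sprintf("bootstrap_lace: redrawing replicate (constant instrument in stratum %d)", k))
    }
    .estimation_error("bootstrap replicate retries exhausted (instrument too rare)")
  }
  lapply(seq_len(B), function(b) one_rep())
}

# Fast bootstrap of the LACE ratios only (no covariates): returns a K x B
# matrix of bootstrap LACE estimates. Same resampling scheme as
# bootstrap_lace, vectorized over replicates within each stratum.
.bootstrap_lace_matrix <- function(cohort, labels, beta_xg, B, seed) {
  set.seed(seed)
  K <- max(labels)
  idx_k <- split(seq_along(labels), labels)
  out <- matrix(NA_real_, K, B)
  for (k in seq_len(K)) {
    idx <- idx_k[[k]]
    nk <- length(idx)
    take <- matrix(idx[sample.int(nk, nk * B, replace = TRUE)], nk, B)
    gm <- matrix(cohort$g[take], nk, B)
    ym <- matrix(cohort$y[take], nk, B)
    sg <- colSums(gm); sy <- colSums(ym)
    sgg <- colSums(gm * gm); sgy <- colSums(gm * ym)
    Sgg <- sgg - sg^2 / nk
    Sgy <- sgy - sg * sy / nk
    bad <- Sgg <= 0
    if (any(bad)) {
      for (b in which(bad)) {
        for (attempt in 1:10) {
          t2 <- idx[sample.int(nk, nk, replace = TRUE)]
          if (sd(cohort$g[t2]) > 0) {
            g2 <- cohort$g[t2]; y2 <- cohort$y[t2]
            Sgg[b] <- sum((g2 - mean(g2))^2)
            Sgy[b] <- sum((g2 - mean(g2)) * (y2 - mean(y2)))
            break
          }
        }
        if (Sgg[b] <= 0)
          .estimation_error("bootstrap replicate retries exhausted (instrument too rare)")
      }
    }
    out[k, ] <- (Sgy / Sgg) / beta_xg
  }
  out
}
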