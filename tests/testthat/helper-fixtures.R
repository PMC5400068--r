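# Fixtures built in code: toy LACE tables and balanced cohorts with exact
# algebraic structure, used across the unit tests.

# A LACE table with chosen estimates/SEs and increasing mean exposures.
toy_lace <- function(lace, se = rep(1, length(lace)),
                     mean_x = seq(2, 6, length.out = length(lace)),
                     beta_xg = 0.25) {
  K <- length(lace)
  lace_table(stratum = seq_len(K), n = rep(100L, K),
             beta_yg = lace * beta_xg, se_yg = se * abs(beta_xg),
             beta_xg = beta_xg, mean_x = mean_x)
}

# Balanced factorial cohort: within each of K blocks of the exposure's
# non-genetic component, every genotype 0/1/2 appears with every block
# value, so the instrument is exactly orthogonal to the block structure.
# With y = slope * x and no noise, every stratum's LACE equals slope
# exactly.
balanced_cohort <- function(K = 4L, beta_xg = 0.25, slope = 0.5) {
  x0 <- rep(seq_len(K), each = 6L) + rep(c(0.1, 0.2), times = 3L * K)
  g <- rep(rep(0:2, each = 2L), times = K)
  x <- x0 + beta_xg * g
  y <- slope * x
  list(cohort = cohort_table(x, y, g + 0.0),
       labels = rep(seq_len(K), each = 6L), slope = slope,
       beta_xg = beta_xg)
}

# Independent log-likelihood oracle for a derivative-scale metaregression:
# metafor's fixed-effects meta-regression with known sampling variances.
metafor_loglik <- function(lace, spec) {
  X <- fp_derivative_design(lace$mean_x, spec)
  fit <- suppressWarnings(
    metafor::rma(yi = lace$lace, vi = lace$se_lace^2, mods = ~ 0 + X,
                 method = "FE"))
  as.numeric(stats::logLik(fit))
}
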