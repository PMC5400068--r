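# Data-generating model for the simulation study, evaluation metrics, and
# the replicate-level experiment drivers.

#' Describe a simulation scenario
#'
#' Encodes one complete simulation condition: cohort size, the true
#' exposure-outcome function h, the number of strata, replicate and
#' bootstrap counts, and optional violations of the constant-effect
#' assumptions. The default data-generating model for individual i is
#' \deqn{x_i = 2 + 0.25 g_i + u_i + \epsilon_{Xi}, \quad
#'       y_i = h(x_i) + 0.8 u_i + \epsilon_{Yi}}
#' with \eqn{g_i \sim Bin(2, 0.3)}, \eqn{u_i \sim U(0,1)},
#' \eqn{\epsilon_{Xi} \sim Exp(1)}, \eqn{\epsilon_{Yi} \sim N(0,1)}; the
#' exposure is positive and away from zero so that log and negative-power
#' functions are well defined.
#'
#' @param h_name one of \code{"fp1"}, \code{"fp2"}, \code{"linear"},
#'   \code{"quadratic"}, \code{"sqrt"}, \code{"log"}, \code{"threshold"}.
#' @param h_params list of true-function parameters: \code{beta} (scalar, or
#'   length 2 for \code{fp2}), \code{powers} (for \code{fp1}/\code{fp2}),
#'   \code{knot} (threshold location, default 3.65).
#' @param n cohort size.
#' @param K number of strata.
#' @param reps number of simulation replicates.
#' @param boot_B bootstrap replicates for percentile bands.
#' @param alpha rejection threshold for the nonlinearity tests.
#' @param seed master seed; every replicate derives its own stream from it.
#' @param violations list of deviations from the constant-effect model:
#'   \code{iv_effect} (mean per-allele effect on the exposure, default 0.25),
#'   \code{iv_effect_sd} (individual-level SD of that effect, default 0),
#'   \code{causal_sd} (individual-level SD of the causal coefficient,
#'   default 0), \code{effect_correlation} (correlation between the two
#'   individual-level effects, default 0), \code{maf} (minor allele
#'   frequency, default 0.3), \code{genotype_effects} (\code{"additive"},
#'   \code{"superadditive"} = increments 0.1 then 0.3, or
#'   \code{"subadditive"} = 0.3 then 0.1).
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(h_name, h_params, n = 10000L, K = 10L,
                            reps = 500L, boot_B = 500L, alpha = 0.05,
                            seed = 1L, violations = list()) {
  h_name <- match.arg(h_name, c("fp1", "fp2", "linear", "quadratic",
                                "sqrt", "log", "threshold"))
  v <- utils::modifyList(list(iv_effect = 0.25, iv_effect_sd = 0,
                              causal_sd = 0, effect_correlation = 0,
                              maf = 0.3, genotype_effects = "additive"),
                         violations)
  v$genotype_effects <- match.arg(v$genotype_effects,
                                  c("additive", "superadditive", "subadditive"))
  if (v$maf <= 0 || v$maf > 0.5) .config_error("maf must lie in (0, 0.5]")
  if (abs(v$effect_correlation) > 1) .config_error("effect_correlation must lie in [-1, 1]")
  if (n < 2 * K) .config_error("n must be at least 2K")
  if (reps < 1L) .config_error("reps must be at least 1")
  if (h_name == "threshold" && is.null(h_params$knot)) h_params$knot <- 3.65
  structure(list(h_name = h_name, h_params = h_params, n = as.integer(n),
                 K = as.integer(K), reps = as.integer(reps),
                 boot_B = as.integer(boot_B), alpha = alpha,
                 seed = as.integer(seed), violations = v),
            class = "scenario_config")
}

#' Read a scenario from a YAML or JSON file
#'
#' @param path file with fields matching \code{\link{scenario_config}}.
#' @return A \code{scenario_config}.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) .config_error(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg), names(formals(scenario_config)))]
  do.call(scenario_config, args)
}

# Unit shape s(x) with h(x) = beta * s(x), for the single-coefficient
# exposure-outcome families.
.h_shape <- function(h_name, h_params, x) {
  switch(h_name,
    linear = x,
    quadratic = x^2,
    sqrt = sqrt(x),
    log = log(x),
    threshold = pmax(x - h_params$knot, 0),
    fp1 = if (h_params$powers == 0) log(x) else x^h_params$powers,
    .config_error(sprintf("unknown h function: %s", h_name)))
}

#' Evaluate a true exposure-outcome function
#'
#' The threshold model is the continuous hinge
#' \eqn{h(x) = \beta \max(x - knot, 0)}: zero up to the knot, then linear.
#'
#' @param h_name,h_params as in \code{\link{scenario_config}}.
#' @param x exposure values (positive for fractional powers).
#' @return numeric vector \eqn{h(x)}.
#' @export
h_eval <- function(h_name, h_params, x) {
  if (h_name == "fp2") {
    spec <- fp_spec(2, h_params$powers)
    drop(.fp_basis(x, spec) %*% h_params$beta)
  } else {
    h_params$beta * .h_shape(h_name, h_params, x)
  }
}

# Correct-model fractional-polynomial spec for a scenario, or NULL if the
# true function is not a fractional polynomial (threshold).
.correct_spec <- function(scenario) {
  switch(scenario$h_name,
    fp1 = fp_spec(1, scenario$h_params$powers),
    fp2 = fp_spec(2, scenario$h_params$powers),
    linear = fp_spec(1, 1), quadratic = fp_spec(1, 2),
    sqrt = fp_spec(1, 0.5), log = fp_spec(1, 0),
    threshold = NULL)
}

# Per-replicate (and per-replicate bootstrap) seed streams derived from the
# master seed, so replicates are order-independent.
.rep_seeds <- function(seed, reps) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, 2L * reps), reps, 2L)
}

#' Generate one simulated cohort
#'
#' Draws a cohort from the data-generating model of the scenario,
#' including any violation settings: non-additive genotype effects replace
#' the linear term \eqn{0.25 g} by per-genotype increments; individual-level
#' IV and causal effects are drawn (jointly) normal when their SDs are
#' positive (for a degree-2 true function only the second coefficient
#' varies). Fully reproducible given \code{rep_seed}.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param rep_seed integer seed for this replicate.
#' @return A \code{\link{cohort_table}} with columns x, y, g.
#' @export
generate_cohort <- function(scenario, rep_seed) {
  set.seed(rep_seed)
  n <- scenario$n
  v <- scenario$violations
  g <- rbinom(n, 2L, v$maf)
  vary <- v$iv_effect_sd > 0 || v$causal_sd > 0
  if (vary) {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    rho <- v$effect_correlation
    a_i <- v$iv_effect + v$iv_effect_sd * z1
    b_dev <- v$causal_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  } else {
    a_i <- v$iv_effect
    b_dev <- 0
  }
  u <- runif(n)
  eps_x <- rexp(n)
  eps_y <- rnorm(n)
  geno_effect <- switch(v$genotype_effects,
    additive = a_i * g,
    superadditive = c(0, 0.1, 0.4)[g + 1L],
    subadditive = c(0, 0.3, 0.4)[g + 1L])
  x <- 2 + geno_effect + u + eps_x
  hp <- scenario$h_params
  if (scenario$h_name == "fp2") {
    spec <- fp_spec(2, hp$powers)
    basis <- .fp_basis(x, spec)
    hx <- basis[, 1L] * hp$beta[1L] + basis[, 2L] * (hp$beta[2L] + b_dev)
  } else {
    hx <- (hp$beta + b_dev) * .h_shape(scenario$h_name, hp, x)
  }
  needs_positive <- scenario$h_name %in% c("fp1", "fp2", "sqrt", "log")
  if (needs_positive && any(x <= 0))
    .data_error("generated exposure not positive; fractional-power h undefined")
  y <- hx + 0.8 * u + eps_y
  cohort_table(x, y, g)
}

#' Curve-fit heuristic
#'
#' Sum of absolute differences between predicted and true anchored outcome
#' values at the decile mean exposures,
#' \eqn{\sum_k |\hat{\bar y}_k - \bar y_k|}; both curves are anchored at
#' the minimum observed exposure before comparison.
#'
#' @param pred,truth numeric vectors of equal length (normally 10 deciles).
#' @return nonnegative scalar.
#' @export
heuristic <- function(pred, truth) {
  if (length(pred) != length(truth))
    .config_error("pred and truth must have equal length")
  sum(abs(pred - truth))
}

# Shared per-replicate pipeline: cohort -> IV-free exposure -> strata ->
# LACE table. Returns the pieces the drivers need.
.sim_rep <- function(scenario, rep_seed, K = scenario$K) {
  cohort <- generate_cohort(scenario, rep_seed)
  ivf <- iv_free_exposure(cohort)
  labels <- assign_strata(ivf$x0, K)
  lace <- estimate_lace(cohort, labels, ivf$beta_xg)
  list(cohort = cohort, ivf = ivf, labels = labels, lace = lace)
}

#' Replicate the fractional-polynomial simulation experiment
#'
#' For each replicate: generate a cohort, stratify, estimate the LACE
#' table, fit the correct fractional polynomial, and (in \code{"all"}
#' mode) fit every model of the same degree to record whether the correct
#' model was the best-fitting one and whether it fell in the near-best
#' set. Aggregates mean estimate, empirical SD, mean analytic SE, coverage
#' of the true coefficient(s) by the 95% normal interval, and the
#' correct-model and set proportions.
#'
#' @param scenario a \code{\link{scenario_config}} whose h is a fractional
#'   polynomial (or one of the mapped single-power families).
#' @param fit_mode \code{"correct_only"} or \code{"all"}.
#' @param effects metaregression effects model.
#' @return list with \code{metrics} (one row per coefficient) and
#'   \code{per_rep} (replicate-level estimates).
#' @export
run_fp_experiment <- function(scenario, fit_mode = c("all", "correct_only"),
                              effects = c("fixed", "random")) {
  fit_mode <- match.arg(fit_mode)
  effects <- match.arg(effects)
  spec <- .correct_spec(scenario)
  if (is.null(spec))
    .config_error("the true function is not a fractional polynomial")
  beta_true <- scenario$h_params$beta
  seeds <- .rep_seeds(scenario$seed, scenario$reps)
  p <- spec$degree
  est <- se <- matrix(NA_real_, scenario$reps, p)
  correct <- in_set <- rep(NA, scenario$reps)
  all_specs <- .all_fp_specs(degree = spec$degree)
  correct_idx <- which(vapply(all_specs, function(s)
    isTRUE(all.equal(s$powers, spec$powers)), logical(1)))
  for (r in seq_len(scenario$reps)) {
    sr <- .sim_rep(scenario, seeds[r, 1L])
    fit <- fit_metareg(sr$lace, spec, effects)
    est[r, ] <- fit$coefficients
    se[r, ] <- sqrt(diag(fit$vcov))
    if (fit_mode == "all") {
      fits <- lapply(all_specs, function(s) fit_metareg(sr$lace, s, effects))
      best <- .best_fit(fits)
      correct[r] <- isTRUE(all.equal(best$spec$powers, spec$powers))
      in_set[r] <- set_membership(fits)[correct_idx]
    }
  }
  cover <- abs(sweep(est, 2L, beta_true)) <= 1.96 * se
  metrics <- data.frame(
    coefficient = seq_len(p), beta_true = beta_true,
    mean_estimate = colMeans(est), empirical_sd = apply(est, 2L, sd),
    mean_se = colMeans(se), coverage = colMeans(cover),
    correct_prop = if (fit_mode == "all") mean(correct) else NA_real_,
    set_prop = if (fit_mode == "all") mean(in_set) else NA_real_)
  list(metrics = metrics,
       per_rep = data.frame(rep = seq_len(scenario$reps), est, se,
                            correct = correct, in_set = in_set))
}

# Anchored truth and decile evaluation points for one replicate: decile
# (K = 10) means of the observed exposure within IV-free-exposure strata,
# with both curves anchored at the minimum observed exposure.
.decile_eval <- function(scenario, cohort, x0) {
  labels10 <- assign_strata(x0, 10L)
  mean_x10 <- rowsum(cohort$x, labels10)[, 1L] / tabulate(labels10, 10L)
  x_min <- min(cohort$x)
  truth <- h_eval(scenario$h_name, scenario$h_params, mean_x10) -
    h_eval(scenario$h_name, scenario$h_params, x_min)
  list(labels10 = labels10, mean_x10 = mean_x10, x_min = x_min, truth = truth)
}

#' Replicate the piecewise linear simulation experiment
#'
#' For each replicate: fit the piecewise linear curve anchored at the
#' minimum observed exposure, evaluate it at the stratum mean exposures,
#' and (when \code{boot_B > 0}) record the coverage of the bootstrap
#' percentile bands for the true anchored outcome values at those points.
#' Also computes the curve-fit heuristic, on 10 deciles, for both the
#' piecewise method and the best-fitting fractional polynomial.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param heuristics also fit the fractional-polynomial comparator and
#'   compute both heuristics (default TRUE).
#' @return list with \code{by_stratum} (per-stratum true value, mean
#'   prediction, coverage) and \code{heuristics} (mean and SD per method).
#' @export
run_pl_experiment <- function(scenario, heuristics = TRUE) {
  K <- scenario$K
  seeds <- .rep_seeds(scenario$seed, scenario$reps)
  truth <- pred <- cover <- matrix(NA_real_, scenario$reps, K)
  heur <- matrix(NA_real_, scenario$reps, 2L,
                 dimnames = list(NULL, c("fp", "pl")))
  for (r in seq_len(scenario$reps)) {
    sr <- .sim_rep(scenario, seeds[r, 1L])
    ev <- .decile_eval(scenario, sr$cohort, sr$ivf$x0)
    mean_x <- sr$lace$mean_x
    true_k <- h_eval(scenario$h_name, scenario$h_params, mean_x) -
      h_eval(scenario$h_name, scenario$h_params, ev$x_min)
    truth[r, ] <- true_k
    pc <- piecewise_curve(sr$lace, sr$cohort$x, sr$labels, x_ref = ev$x_min)
    pred[r, ] <- pc$eval_points$estimate
    if (scenario$boot_B > 0L) {
      boots <- .bootstrap_lace_matrix(sr$cohort, sr$labels,
                                      sr$ivf$beta_xg, scenario$boot_B,
                                      seeds[r, 2L])
      pcb <- piecewise_ci(sr$lace, boots, sr$cohort$x, sr$labels, ev$x_min)
      cover[r, ] <- true_k >= pcb$eval_points$ci_low &
        true_k <= pcb$eval_points$ci_high
    }
    if (heuristics) {
      pl10 <- predict(pc, ev$mean_x10) - predict(pc, ev$x_min)
      heur[r, "pl"] <- heuristic(pl10, ev$truth)
      sel <- select_model(sr$lace)
      basis10 <- .fp_basis(ev$mean_x10, sel$chosen$spec) -
        matrix(.fp_basis(ev$x_min, sel$chosen$spec), length(ev$mean_x10),
               sel$chosen$spec$degree, byrow = TRUE)
      heur[r, "fp"] <- heuristic(drop(basis10 %*% sel$chosen$coefficients),
                                 ev$truth)
    }
  }
  list(by_stratum = data.frame(
         stratum = seq_len(K),
         true_value = colMeans(truth),
         mean_prediction = colMeans(pred),
         coverage = if (scenario$boot_B > 0L) colMeans(cover) else NA_real_),
       heuristics = data.frame(
         method = c("fp", "pl"),
         mean = colMeans(heur), sd = apply(heur, 2L, sd)))
}

#' Strata-count and nonlinearity-power experiment
#'
#' For each number of strata, computes the rejection proportion at
#' \code{alpha} of the quadratic trend, Cochran Q, and fractional-
#' polynomial tests across replicates, together with the curve-fit
#' heuristics of both methods evaluated on 10 deciles regardless of the
#' number of strata. Cohorts are shared across strata counts within a
#' replicate.
#'
#' @param scenario a \code{\link{scenario_config}} (its \code{K} is ignored).
#' @param K_values strata counts to assess.
#' @param heuristics compute the heuristic columns too (default TRUE).
#' @return data.frame with one row per strata count: rejection rates and
#'   heuristic means/SDs.
#' @export
run_power_experiment <- function(scenario, K_values = c(5L, 10L, 50L, 100L),
                                 heuristics = TRUE) {
  seeds <- .rep_seeds(scenario$seed, scenario$reps)
  nK <- length(K_values)
  rej <- array(NA_real_, c(scenario$reps, nK, 3L),
               dimnames = list(NULL, NULL, c("quadratic", "Q", "fp")))
  heur <- array(NA_real_, c(scenario$reps, nK, 2L),
                dimnames = list(NULL, NULL, c("fp", "pl")))
  for (r in seq_len(scenario$reps)) {
    cohort <- generate_cohort(scenario, seeds[r, 1L])
    ivf <- iv_free_exposure(cohort)
    ev <- .decile_eval(scenario, cohort, ivf$x0)
    for (j in seq_len(nK)) {
      labels <- assign_strata(ivf$x0, K_values[j])
      lace <- estimate_lace(cohort, labels, ivf$beta_xg)
      rej[r, j, "quadratic"] <- quadratic_test(lace)$p_value < scenario$alpha
      rej[r, j, "Q"] <- cochran_q(lace)$p_value < scenario$alpha
      rej[r, j, "fp"] <- fp_test(lace)$p_value < scenario$alpha
      if (heuristics) {
        pc <- piecewise_curve(lace, cohort$x, labels, x_ref = ev$x_min)
        heur[r, j, "pl"] <- heuristic(predict(pc, ev$mean_x10) -
                                        predict(pc, ev$x_min), ev$truth)
        sel <- select_model(lace)
        basis10 <- .fp_basis(ev$mean_x10, sel$chosen$spec) -
          matrix(.fp_basis(ev$x_min, sel$chosen$spec), 10L,
                 sel$chosen$spec$degree, byrow = TRUE)
        heur[r, j, "fp"] <- heuristic(drop(basis10 %*% sel$chosen$coefficients),
                                      ev$truth)
      }
    }
  }
  slice <- function(a, what) matrix(a[, , what], nrow = scenario$reps)
  data.frame(K = K_values,
             power_quadratic = colMeans(slice(rej, "quadratic")),
             power_q = colMeans(slice(rej, "Q")),
             power_fp = colMeans(slice(rej, "fp")),
             heuristic_fp_mean = colMeans(slice(heur, "fp")),
             heuristic_fp_sd = apply(slice(heur, "fp"), 2L, sd),
             heuristic_pl_mean = colMeans(slice(heur, "pl")),
             heuristic_pl_sd = apply(slice(heur, "pl"), 2L, sd))
}
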