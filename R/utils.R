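# Internal helpers: classed conditions and closed-form simple regression.

.condition <- function(class, message, call = sys.call(-1)) {
  structure(
    list(message = message, call = call),
    class = c(class, "lacecurve_error", "error", "condition")
  )
}

.config_error <- function(message) stop(.condition("lacecurve_config_error", message))
.data_error <- function(message) stop(.condition("lacecurve_data_error", message))
.estimation_error <- function(message) stop(.condition("lacecurve_estimation_error", message))

# Simple linear regression y ~ 1 + x via closed-form least squares.
# Identical algebra to lm(); used on hot paths where lm()'s model-frame
# machinery dominates run time. Cross-checked against lm() in the tests.
.simple_ols <- function(y, x) {
  n <- length(y)
  if (n < 3L) .estimation_error("need at least 3 observations for simple regression")
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx * dx)
  if (sxx <= 0) .estimation_error("regressor has zero variance")
  beta <- sum(dx * (y - my)) / sxx
  res <- (y - my) - beta * dx
  sigma2 <- sum(res * res) / (n - 2L)
  list(beta = beta, se = sqrt(sigma2 / sxx), intercept = my - beta * mx)
}

# Per-group simple regression of y on x for integer group labels 1..K.
# Returns one row per group: n, beta, se. Groups with zero x-variance
# yield beta = NA (callers raise a classed error naming the stratum).
.grouped_ols <- function(y, x, labels, K) {
  n_k <- tabulate(labels, nbins = K)
  sx <- rowsum(x, labels)[, 1L]
  sy <- rowsum(y, labels)[, 1L]
  sxx <- rowsum(x * x, labels)[, 1L]
  sxy <- rowsum(x * y, labels)[, 1L]
  syy <- rowsum(y * y, labels)[, 1L]
  Sxx <- sxx - sx^2 / n_k
  Sxy <- sxy - sx * sy / n_k
  Syy <- syy - sy^2 / n_k
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / (n_k - 2L) / Sxx)
  list(n = n_k, beta = beta, se = se)
}

#' @importFrom stats approx coef dnorm lm model.matrix pchisq pnorm qchisq
#'   quantile rbinom reformulate residuals rexp rnorm runif sd setNames vcov
#'   complete.cases
#' @importFrom utils write.table read.delim
NULL
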