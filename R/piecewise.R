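# Continuous piecewise linear exposure-outcome curve whose per-segment
# gradients are the stratum LACE estimates, with bootstrap percentile bands.

# Segment breakpoints: b_0 = min exposure, b_K = max exposure, and interior
# b_k the midpoint between the largest observed exposure in stratum k and
# the smallest in stratum k+1. Because strata are formed on the IV-free
# exposure, observed-exposure ranges can overlap slightly; a non-monotone
# midpoint (rare, many strata) is collapsed onto the previous breakpoint,
# giving that stratum a zero-width segment while keeping continuity.
.piecewise_breakpoints <- function(exposure, labels, K) {
  max_k <- vapply(split(exposure, labels), max, numeric(1))
  min_k <- vapply(split(exposure, labels), min, numeric(1))
  b <- c(min(exposure), (max_k[-K] + min_k[-1L]) / 2, max(exposure))
  unname(cummax(b))
}

#' Piecewise linear exposure-outcome curve
#'
#' Builds the continuous piecewise linear function in which stratum k
#' contributes a segment of gradient \eqn{\widehat{LACE}_k} over the
#' exposure range attributed to that stratum; each segment begins where the
#' previous one finished, and the whole curve is shifted so that
#' \eqn{f(x_{ref}) = 0} (the overall intercept is not identified).
#'
#' @param lace a \code{lace_table} (strata in increasing mean-exposure order).
#' @param exposure observed exposure vector for the cohort.
#' @param labels stratum labels matching \code{exposure}.
#' @param x_ref reference exposure inside the observed range.
#' @return An object of class \code{piecewise_curve}: list with
#'   \code{breakpoints} (length K+1), \code{slopes} (the LACE estimates),
#'   \code{node_values} (curve values at the breakpoints), \code{x_ref},
#'   \code{eval_points} (stratum mean exposures with estimates; bands are
#'   added by \code{\link{piecewise_ci}}), and a \code{segments} data.frame.
#' @export
piecewise_curve <- function(lace, exposure, labels, x_ref) {
  K <- nrow(lace)
  if (is.unsorted(lace$mean_x))
    .estimation_error("strata must be ordered by mean exposure")
  b <- .piecewise_breakpoints(exposure, labels, K)
  if (x_ref < b[1L] || x_ref > b[K + 1L])
    .config_error(sprintf("x_ref = %g outside the observed exposure range [%g, %g]",
                          x_ref, b[1L], b[K + 1L]))
  fb <- unname(c(0, cumsum(lace$lace * diff(b))))
  fb <- fb - approx(b, fb, xout = x_ref)$y
  eval_points <- data.frame(stratum = lace$stratum, mean_x = lace$mean_x,
                            estimate = approx(b, fb, xout = lace$mean_x)$y)
  structure(list(breakpoints = b, slopes = lace$lace, node_values = fb,
                 x_ref = x_ref, eval_points = eval_points,
                 segments = data.frame(b_lo = b[-(K + 1L)], b_hi = b[-1L],
                                       slope = lace$lace, f_hi = fb[-1L])),
            class = "piecewise_curve")
}

#' Evaluate a piecewise linear curve
#'
#' @param object a \code{\link{piecewise_curve}}.
#' @param x exposure values inside the curve's breakpoint range.
#' @param ... unused.
#' @return numeric vector of curve values.
#' @export
predict.piecewise_curve <- function(object, x, ...) {
  approx(object$breakpoints, object$node_values, xout = x)$y
}

#' @export
print.piecewise_curve <- function(x, ...) {
  cat(sprintf("piecewise linear curve: %d segments on [%g, %g], anchored at %g\n",
              length(x$slopes), x$breakpoints[1L],
              x$breakpoints[length(x$breakpoints)], x$x_ref))
  invisible(x)
}

#' Bootstrap percentile bands for the piecewise linear curve
#'
#' Rebuilds the full piecewise curve (same breakpoints and anchoring) from
#' each bootstrap LACE table and takes pointwise empirical 2.5th/97.5th
#' percentiles (linear-interpolation quantiles) at the stratum mean
#' exposures.
#'
#' @param lace the original \code{lace_table}.
#' @param boot_laces list of bootstrap \code{lace_table}s, or a K x B matrix
#'   of bootstrap LACE estimates.
#' @param exposure,labels,x_ref as in \code{\link{piecewise_curve}}.
#' @return The \code{piecewise_curve} with \code{ci_low}/\code{ci_high}
#'   columns added to \code{eval_points}.
#' @export
piecewise_ci <- function(lace, boot_laces, exposure, labels, x_ref) {
  pc <- piecewise_curve(lace, exposure, labels, x_ref)
  if (is.list(boot_laces))
    boot_laces <- vapply(boot_laces, function(bl) bl$lace,
                         numeric(nrow(lace)))
  B <- ncol(boot_laces)
  if (B < 100L)
    warning("fewer than 100 bootstrap replicates: 95% bands will be unstable")
  b <- pc$breakpoints
  db <- diff(b)
  vals <- .piecewise_eval_boot(boot_laces, b, db, x_ref, lace$mean_x)
  qs <- apply(vals, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
  pc$eval_points$ci_low <- pmin(qs[1L, ], pc$eval_points$estimate)
  pc$eval_points$ci_high <- pmax(qs[2L, ], pc$eval_points$estimate)
  pc
}

# Evaluate the anchored piecewise curve for each column of a K x B matrix of
# slopes, at the points xout; returns length(xout) x B.
.piecewise_eval_boot <- function(slopes, b, db, x_ref, xout) {
  K <- nrow(slopes)
  fb <- rbind(0, apply(slopes * db, 2L, cumsum))   # (K+1) x B node values
  at <- function(x) {                              # scalar x -> length-B vector
    i <- min(max(findInterval(x, b, rightmost.closed = TRUE), 1L), K)
    fb[i, ] + (x - b[i]) * slopes[i, ]
  }
  ref <- at(x_ref)
  out <- matrix(NA_real_, length(xout), ncol(slopes))
  for (j in seq_along(xout)) out[j, ] <- at(xout[j]) - ref
  out
}
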