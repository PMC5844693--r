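# Circular statistics for angular data, including axial (period-180) tilt.
#
# All functions take a `period` argument: 360 for ordinary angles, 180 for
# axial quantities such as unsigned tilt.  Internally angles are mapped to
# the full circle by the scale factor 360/period (angle doubling for axial
# data), statistics are computed there, and results are mapped back.

#' Circular mean, resultant and variance
#'
#' Computes the complex mean resultant vector \eqn{R = \sum_k e^{j\theta_k}/N}
#' of a set of angles, the circular mean \eqn{\bar\theta = \arg R} and the
#' circular variance \eqn{1 - |R|}.  For axial data (`period = 180`) the
#' angles are doubled before the resultant is formed and the mean is halved
#' afterwards, the standard treatment of orientation-like quantities.
#'
#' @param angles numeric vector of angles in degrees.
#' @param period period of the domain in degrees: 360 for signed angles,
#'   180 for axial (unsigned tilt) data.
#' @return an object of class `circ_summary`: a list with elements
#'   `resultant` (complex, unit-scaled), `mean` (degrees in `[0, period)`,
#'   `NA` when undefined), `mean_defined` (logical), `variance` (in
#'   `[0, 1]`), and `n`.
#' @examples
#' circ_mean_var(c(0, 90), period = 360)   # mean 45, variance 1 - sqrt(2)/2
#' circ_mean_var(c(10, 170), period = 180) # axial mean 0
#' @export
circ_mean_var <- function(angles, period = 180) {
  stopifnot(length(angles) >= 1L, all(is.finite(angles)), period %in% c(180, 360))
  scale <- 360 / period
  th <- deg2rad(angles * scale)
  R <- mean(complex(modulus = 1, argument = th))
  defined <- Mod(R) >= 1e-9
  m <- if (defined) (rad2deg(Arg(R)) / scale) %% period else NA_real_
  structure(
    list(resultant = R, mean = m, mean_defined = defined,
         variance = 1 - Mod(R), n = length(angles)),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("circular summary (n = %d): mean = %s deg, variance = %.4f, |R| = %.4f\n",
              x$n, if (x$mean_defined) sprintf("%.2f", x$mean) else "undefined",
              x$variance, Mod(x$resultant)))
  invisible(x)
}

#' Signed circular error
#'
#' Wrapped signed difference `estimate - truth`, the circular distance
#' \eqn{e = \arg e^{j(\hat\theta - \theta)}}, returned in
#' `(-period/2, period/2]`.  The boundary case maps to `+period/2`.
#'
#' @param estimate,truth angles in degrees (vectorized, recycled).
#' @param period domain period in degrees.
#' @return signed error(s) in degrees.
#' @export
circ_error <- function(estimate, truth, period = 180) {
  stopifnot(all(is.finite(estimate)), all(is.finite(truth)), period > 0)
  d <- (estimate - truth) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Fisher--Lee circular correlation coefficient
#'
#' The T-linear association coefficient of Fisher and Lee (1983) for paired
#' angular observations,
#' \deqn{\rho = \frac{\sum_{i<j}\sin(a_i-a_j)\sin(b_i-b_j)}
#'  {\sqrt{\sum_{i<j}\sin^2(a_i-a_j)\sum_{i<j}\sin^2(b_i-b_j)}},}
#' evaluated in O(n) via trigonometric sum identities.  Invariant to
#' rotations of either variable.  Axial data are handled through `period`.
#'
#' @param a,b equal-length numeric vectors of angles in degrees.
#' @param period domain period in degrees.
#' @return scalar coefficient in `[-1, 1]`; `NA` (with a warning) when either
#'   sequence is angularly constant.
#' @export
circ_corr <- function(a, b, period = 180) {
  stopifnot(length(a) == length(b), length(a) >= 3L,
            all(is.finite(a)), all(is.finite(b)))
  scale <- 2 * pi / period
  ta <- a * scale
  tb <- b * scale
  sa <- sin(ta); ca <- cos(ta); sb <- sin(tb); cb <- cos(tb)
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb)
  n <- length(a)
  den_a <- (n^2 - sum(cos(2 * ta))^2 - sum(sin(2 * ta))^2) / 4
  den_b <- (n^2 - sum(cos(2 * tb))^2 - sum(sin(2 * tb))^2) / 4
  if (den_a <= 1e-12 || den_b <= 1e-12) {
    warning("circular correlation undefined: constant input sequence")
    return(NA_real_)
  }
  num / sqrt(den_a * den_b)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (or elements) of `data` with replacement, applies
#' `statistic_fn` to each resample, and returns the percentile interval at
#' the requested level.  Degenerate resamples (statistic `NA`/`NaN`, or an
#' error) are skipped and counted.
#'
#' @param statistic_fn function mapping a resampled `data` to a numeric
#'   scalar.
#' @param data vector, matrix or data frame of observations.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given the seed.
#' @return numeric `c(lo, hi)` with attributes `n_skipped` and `replicates`.
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 1000, level = 0.95, seed = 1) {
  stopifnot(n_boot >= 100, level > 0, level < 1)
  n <- NROW(data)
  take <- function(idx) {
    if (is.data.frame(data) || is.matrix(data)) data[idx, , drop = FALSE] else data[idx]
  }
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      out <- tryCatch(statistic_fn(take(idx)), error = function(e) NA_real_)
      if (!is.numeric(out) || length(out) != 1L) NA_real_ else as.numeric(out)
    }, numeric(1))
  })
  ok <- is.finite(stats)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(sprintf("bootstrap_ci: skipped %d degenerate resamples", n_skipped))
  }
  if (!any(ok)) err("all bootstrap resamples degenerate")
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats[ok], c(alpha, 1 - alpha), names = FALSE))
  attr(ci, "n_skipped") <- n_skipped
  attr(ci, "replicates") <- stats[ok]
  ci
}
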