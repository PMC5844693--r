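# Synthetic observer: wraps a set of tilt estimates in axial response noise
# (von Mises on doubled angles), optional per-tilt bias, and uniform lapses,
# standing in for a human reporting unsigned tilt with a probe.

# von Mises sampler on [0, 2*pi), Best & Fisher (1979) rejection method
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      got <- got + k
    }
  }
  (out + mu) %% (2 * pi)
}

# axial von Mises noise in degrees: sampled on doubled angles, halved.
# kappa = Inf gives exactly zero noise.
rvm_axial_deg <- function(n, kappa) {
  if (is.infinite(kappa)) return(rep(0, n))
  th2 <- rvonmises(n, 0, kappa)           # doubled-angle deviation, [0, 2pi)
  dev <- rad2deg(th2) / 2                  # [0, 180)
  ifelse(dev > 90, dev - 180, dev)         # signed axial deviation (-90, 90]
}

#' Synthetic observer specification
#'
#' @param noise_concentration von Mises concentration of response noise on
#'   doubled angles (kappa >= 0; `Inf` = noiseless).
#' @param lapse_rate probability of a uniform random response in `[0, 180)`.
#' @param bias_fn optional function mapping tilt (degrees) to an additive
#'   bias (degrees); `NULL` for no bias.
#' @return an object of class `synthetic_observer_spec`.
#' @export
synthetic_observer_spec <- function(noise_concentration = 10,
                                    lapse_rate = 0,
                                    bias_fn = NULL) {
  stopifnot(noise_concentration >= 0, lapse_rate >= 0, lapse_rate <= 1)
  if (!is.null(bias_fn)) stopifnot(is.function(bias_fn))
  structure(list(noise_concentration = noise_concentration,
                 lapse_rate = lapse_rate, bias_fn = bias_fn),
            class = "synthetic_observer_spec")
}

#' Generate synthetic observer responses
#'
#' Each response is `estimate + bias_fn(estimate) + axial von Mises noise`,
#' reduced mod 180; with probability `lapse_rate` the response is replaced
#' by a uniform draw on `[0, 180)`.
#'
#' @param estimates numeric vector of tilt estimates, degrees `[0, 180)`.
#' @param obs a [synthetic_observer_spec()].
#' @param seed integer seed; responses are deterministic given the seed.
#' @return numeric vector of responses in `[0, 180)`.
#' @export
synthetic_observer <- function(estimates, obs = synthetic_observer_spec(),
                               seed = 1) {
  stopifnot(inherits(obs, "synthetic_observer_spec"), all(is.finite(estimates)))
  n <- length(estimates)
  with_seed(seed, {
    bias <- if (is.null(obs$bias_fn)) 0 else obs$bias_fn(estimates)
    noise <- rvm_axial_deg(n, obs$noise_concentration)
    resp <- (estimates + bias + noise) %% 180
    if (obs$lapse_rate > 0) {
      lapse <- stats::runif(n) < obs$lapse_rate
      resp[lapse] <- stats::runif(sum(lapse), 0, 180)
    }
    resp
  })
}
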