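# Surface texture synthesis: 1/f noise and phase/orientation-randomized
# plaids at fixed spatial frequencies (cycles per degree).
#
# Textures are defined as continuous zero-mean, unit-variance luminance
# fields over plane coordinates (u, v) measured in "projected degrees":
# one unit corresponds to one degree of visual angle at the patch centre
# distance, so a 3.5 cpd plaid painted on a frontoparallel surface projects
# to 3.5 cycles per degree in the image.  Rendering looks textures up at
# arbitrary (u, v); `make_texture()` samples them on a regular pixel grid.

texture_kinds <- c("onef_noise", "plaid_3.5cpd", "plaid_5.25cpd")

plaid_freq_cpd <- function(kind) {
  switch(kind, "plaid_3.5cpd" = 3.5, "plaid_5.25cpd" = 5.25,
         err(sprintf("texture kind '%s' has no plaid frequency", kind)))
}

# Continuous texture field closure.  For plaids the field is analytic; for
# 1/f noise it is a periodic FFT-synthesized grid sampled at pixels_per_degree
# and looked up with bilinear interpolation (wrap-around, so the field tiles).
texture_field <- function(kind, pixels_per_degree, seed, noise_grid = 512L) {
  if (!kind %in% texture_kinds) {
    err(sprintf("unknown texture kind '%s' (expected one of: %s)",
                kind, paste(texture_kinds, collapse = ", ")),
        class = "tiltnorm_texture_error")
  }
  if (kind %in% c("plaid_3.5cpd", "plaid_5.25cpd")) {
    f <- plaid_freq_cpd(kind)
    pars <- with_seed(seed, list(theta = stats::runif(2, 0, 180),
                                 phase = stats::runif(2, 0, 2 * pi)))
    th <- deg2rad(pars$theta)
    fun <- function(u, v) {
      # two gratings with independent random orientations and phases,
      # each of variance 1/2 so the sum has unit variance
      cos(2 * pi * f * (u * cos(th[1]) + v * sin(th[1])) + pars$phase[1]) +
        cos(2 * pi * f * (u * cos(th[2]) + v * sin(th[2])) + pars$phase[2])
    }
    return(list(kind = kind, fun = fun, freq_cpd = f, pars = pars))
  }
  # 1/f noise: amplitude spectrum proportional to 1/f, random phases
  N <- as.integer(noise_grid)
  extent <- N / pixels_per_degree  # degrees spanned by one tile
  grid <- with_seed(seed, {
    w <- matrix(stats::rnorm(N * N), N, N)
    W <- stats::fft(w)
    k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))  # FFT frequency index
    fr <- sqrt(outer(k^2, k^2, "+")) / extent    # cycles per degree
    amp <- 1 / fr
    amp[1, 1] <- 0  # zero-mean
    x <- Re(stats::fft(W * amp, inverse = TRUE)) / (N * N)
    (x - mean(x)) / stats::sd(x)
  })
  fun <- function(u, v) {
    gu <- (u %% extent) / extent * N  # in [0, N)
    gv <- (v %% extent) / extent * N
    i0 <- floor(gu); j0 <- floor(gv)
    du <- gu - i0; dv <- gv - j0
    i0 <- as.integer(i0 %% N); j0 <- as.integer(j0 %% N)
    i1 <- (i0 + 1L) %% N; j1 <- (j0 + 1L) %% N
    # grid indexed [v, u] to match the package's [row = y, col = x] layout
    g00 <- grid[cbind(j0 + 1L, i0 + 1L)]
    g10 <- grid[cbind(j0 + 1L, i1 + 1L)]
    g01 <- grid[cbind(j1 + 1L, i0 + 1L)]
    g11 <- grid[cbind(j1 + 1L, i1 + 1L)]
    (1 - du) * (1 - dv) * g00 + du * (1 - dv) * g10 +
      (1 - du) * dv * g01 + du * dv * g11
  }
  list(kind = kind, fun = fun, freq_cpd = NA_real_, extent = extent)
}

#' Generate a texture patch
#'
#' Samples one of the supported surface textures on a square pixel grid:
#' `"onef_noise"` (random-phase noise with amplitude spectrum proportional
#' to 1/f) or `"plaid_3.5cpd"` / `"plaid_5.25cpd"` (sums of two gratings at
#' the named spatial frequency with independently randomized orientations
#' and phases).  The result is zero-mean (unit variance in expectation);
#' mean luminance and contrast scaling are applied at render time.
#'
#' @param kind one of `"onef_noise"`, `"plaid_3.5cpd"`, `"plaid_5.25cpd"`.
#' @param size patch side length in pixels.
#' @param pixels_per_degree pixel density used to convert cycles per degree
#'   to cycles per pixel.
#' @param seed integer seed; identical seeds give identical textures.
#' @return a `size` x `size` numeric matrix (rows = y, bottom-up).
#' @export
make_texture <- function(kind, size, pixels_per_degree = 1920 / 36, seed = 1) {
  stopifnot(is_scalar_num(size), size > 0, pixels_per_degree > 0)
  fld <- texture_field(kind, pixels_per_degree, seed)
  coord <- (seq_len(size) - (size + 1) / 2) / pixels_per_degree
  u <- matrix(coord, size, size, byrow = TRUE)
  v <- matrix(coord, size, size)
  matrix(fld$fun(as.vector(u), as.vector(v)), size, size)
}
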