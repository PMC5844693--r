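# Separable Gaussian filtering and Gaussian-derivative gradients.
#
# Image convention used throughout the package: matrices are indexed
# [row, col] with rows running bottom-to-top, so increasing row index means
# increasing elevation (y-up) and increasing column index means rightward
# (x).  With this convention the ground plane has tilt 90 degrees.

# normalized Gaussian kernel, truncated at +/- 3 sigma
gauss_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian first-derivative kernel, scaled so that correlation with a
# unit-slope ramp returns exactly 1 (per-pixel units)
dgauss_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- -r:r
  k <- x * exp(-x^2 / (2 * sigma^2))
  k / sum(x * k)
}

# 1D correlation along one image axis with reflected (symmetric) boundaries:
# out[i] = sum_o k[o] img[i + o]
conv_axis <- function(img, k, axis = c("x", "y")) {
  axis <- match.arg(axis)
  r <- (length(k) - 1L) %/% 2L
  if (axis == "x") {
    n <- ncol(img)
    if (r >= n) err("kernel wider than image")
    pad <- cbind(img[, r:1, drop = FALSE], img, img[, n:(n - r + 1L), drop = FALSE])
    out <- matrix(0, nrow(img), n)
    for (t in seq_along(k)) {
      out <- out + k[t] * pad[, (t - 1L) + seq_len(n), drop = FALSE]
    }
  } else {
    n <- nrow(img)
    if (r >= n) err("kernel taller than image")
    pad <- rbind(img[r:1, , drop = FALSE], img, img[n:(n - r + 1L), , drop = FALSE])
    out <- matrix(0, n, ncol(img))
    for (t in seq_along(k)) {
      out <- out + k[t] * pad[(t - 1L) + seq_len(n), , drop = FALSE]
    }
  }
  out
}

# isotropic Gaussian blur, sigma in pixels
gaussian_blur <- function(img, sigma) {
  k <- gauss_kernel(sigma)
  conv_axis(conv_axis(img, k, "x"), k, "y")
}

# Gaussian-derivative gradient; returns per-pixel partials in x (columns,
# rightward) and y (rows, upward), units of image-value per pixel
gauss_gradient <- function(img, sigma) {
  g <- gauss_kernel(sigma)
  d <- dgauss_kernel(sigma)
  list(
    gx = conv_axis(conv_axis(img, d, "x"), g, "y"),
    gy = conv_axis(conv_axis(img, g, "x"), d, "y")
  )
}
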