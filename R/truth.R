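# Groundtruth surface descriptors computed from range maps: tilt (the
# orientation of the range gradient), slant, and local tilt variance.

#' Groundtruth configuration
#'
#' @param sigma_truth_arcmin space constant of the Gaussian kernel used to
#'   smooth the range map before differentiation, in arcmin (default 3;
#'   doubling it should not change qualitative results).
#' @param pixels_per_degree pixel density of the range map.
#' @param central_region_diameter diameter, in degrees, of the central
#'   region over which local tilt variance is computed (default 1).
#' @param grad_eps gradient-magnitude threshold (meters/pixel) below which
#'   tilt is flagged undefined.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(sigma_truth_arcmin = 3,
                         pixels_per_degree = 1920 / 36,
                         central_region_diameter = 1,
                         grad_eps = 1e-6) {
  stopifnot(sigma_truth_arcmin > 0, pixels_per_degree > 0,
            central_region_diameter > 0)
  structure(list(sigma_truth_arcmin = sigma_truth_arcmin,
                 pixels_per_degree = pixels_per_degree,
                 central_region_diameter = central_region_diameter,
                 grad_eps = grad_eps),
            class = "truth_config")
}

#' Smoothed range gradient
#'
#' Convolves the range map with a 2D Gaussian kernel (space constant
#' `sigma_truth_arcmin`, converted to pixels) and returns the partial
#' derivatives in the x (rightward) and y (upward) image directions, in
#' meters per pixel.
#'
#' @param range_map matrix of cyclopean distances, meters, `[row = y, col = x]`.
#' @param cfg a [truth_config()].
#' @return list with matrices `gx` and `gy`.
#' @export
range_gradient <- function(range_map, cfg = truth_config()) {
  stopifnot(is.matrix(range_map), all(is.finite(range_map)), all(range_map > 0))
  sigma_px <- cfg$sigma_truth_arcmin / 60 * cfg$pixels_per_degree
  if (sigma_px < 0.5) {
    warning(sprintf("range-gradient kernel under-resolved (sigma = %.2f px)", sigma_px))
  }
  gauss_gradient(range_map, sigma_px)
}

#' Groundtruth tilt map
#'
#' Signed tilt is the orientation of the range gradient,
#' `atan2(dr/dy, dr/dx)` in degrees `[0, 360)`; a ground-plane-like surface
#' (range increasing with elevation) has tilt 90.  Pixels whose gradient
#' magnitude falls below `cfg$grad_eps` are masked as undefined.
#'
#' @param grad list with `gx`, `gy` from [range_gradient()].
#' @param cfg a [truth_config()].
#' @return an object of class `tilt_map`: list with matrices `signed_tilt`
#'   (degrees `[0, 360)`), `gradient_magnitude` (m/px), and logical
#'   `defined_mask`.
#' @export
groundtruth_tilt <- function(grad, cfg = truth_config()) {
  stopifnot(is.list(grad), is.matrix(grad$gx), is.matrix(grad$gy))
  mag <- sqrt(grad$gx^2 + grad$gy^2)
  tilt <- rad2deg(atan2(grad$gy, grad$gx)) %% 360
  structure(list(signed_tilt = tilt, gradient_magnitude = mag,
                 defined_mask = mag >= cfg$grad_eps),
            class = "tilt_map")
}

#' Reduce an angle to the unsigned (axial) domain
#'
#' Unsigned tilt is tilt modulo 180 degrees, i.e. surface orientation up to
#' the sign ambiguity of the slant direction.  Idempotent.
#'
#' @param angle numeric angles in degrees.
#' @return angles in `[0, 180)`.
#' @export
to_unsigned <- function(angle) {
  stopifnot(all(is.finite(angle)))
  angle %% 180
}

# logical disc mask of the central region, diameter in degrees
central_mask <- function(dim_px, diameter_deg, pixels_per_degree) {
  radius_px <- diameter_deg / 2 * pixels_per_degree
  c0 <- (dim_px + 1) / 2
  d2 <- outer((seq_len(dim_px) - c0)^2, (seq_len(dim_px) - c0)^2, "+")
  d2 <= radius_px^2
}

#' Local tilt variance
#'
#' Circular variance (axial, period 180) of the unsigned groundtruth tilts
#' within the central circular region of the patch.  Zero for a plane,
#' approaching 1 for locally isotropic surface structure; used as the
#' measure of departure from planarity.
#'
#' @param tilt_map a [groundtruth_tilt()] result.
#' @param cfg a [truth_config()].
#' @return scalar in `[0, 1]`.
#' @export
tilt_variance <- function(tilt_map, cfg = truth_config()) {
  stopifnot(inherits(tilt_map, "tilt_map"))
  npx <- nrow(tilt_map$signed_tilt)
  mask <- central_mask(npx, cfg$central_region_diameter, cfg$pixels_per_degree) &
    tilt_map$defined_mask
  if (sum(mask) < 2) err("tilt variance undefined: fewer than 2 defined pixels")
  circ_mean_var(to_unsigned(tilt_map$signed_tilt[mask]), period = 180)$variance
}

#' Groundtruth slant map
#'
#' Slant (angle between the local surface normal and the line of sight) is
#' recovered from the range map as `atan(|grad_angular r| / r)`, where the
#' gradient is taken per radian of visual angle.  This identity is exact at
#' the patch centre for a plane; it is validated against the construction
#' slant of synthetic scenes.
#'
#' @param range_map matrix of cyclopean distances, meters.
#' @param cfg a [truth_config()].
#' @param geom a [viewing_geometry()] (supplies pixels per degree if it
#'   differs from `cfg`).
#' @return matrix of slants in degrees.
#' @export
groundtruth_slant <- function(range_map, cfg = truth_config(), geom = NULL) {
  ppd <- if (!is.null(geom)) geom$pixels_per_degree else cfg$pixels_per_degree
  grad <- range_gradient(range_map, cfg)
  per_rad <- ppd * 180 / pi  # pixels per radian
  gmag <- sqrt(grad$gx^2 + grad$gy^2) * per_rad
  sigma_px <- cfg$sigma_truth_arcmin / 60 * cfg$pixels_per_degree
  r_s <- gaussian_blur(range_map, sigma_px)
  rad2deg(atan(gmag / r_s))
}

#' Groundtruth summary at the patch centre
#'
#' Convenience wrapper: smoothed range gradient, signed and unsigned tilt at
#' the centre pixel, slant at the centre, and local tilt variance over the
#' central region.
#'
#' @param patch a [render_stereo()] patch.
#' @param cfg a [truth_config()]; its `pixels_per_degree` is overridden by
#'   the patch geometry.
#' @return list with `signed_tilt`, `tilt` (unsigned), `slant`,
#'   `tilt_variance`, `defined` (logical), and the full `tilt_map`.
#' @export
patch_truth <- function(patch, cfg = truth_config()) {
  stopifnot(inherits(patch, "stereo_patch"))
  cfg$pixels_per_degree <- patch$geom$pixels_per_degree
  grad <- range_gradient(patch$range_map, cfg)
  tm <- groundtruth_tilt(grad, cfg)
  ctr <- (dim(patch$range_map) + 1) %/% 2
  slant_map <- groundtruth_slant(patch$range_map, cfg, patch$geom)
  list(signed_tilt = tm$signed_tilt[ctr[1], ctr[2]],
       tilt = to_unsigned(tm$signed_tilt[ctr[1], ctr[2]]),
       slant = slant_map[ctr[1], ctr[2]],
       tilt_variance = tilt_variance(tm, cfg),
       defined = tm$defined_mask[ctr[1], ctr[2]],
       tilt_map = tm)
}
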