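# Synthetic stereo scene rendering.
#
# World coordinates: cyclopean eye at the origin, x rightward, y upward,
# z forward into the scene.  The left/right eyes sit at (-b/2, 0, 0) and
# (+b/2, 0, 0) with parallel optical axes along +z, so a frontoparallel
# plane at distance d produces a uniform horizontal disparity of b/d
# radians between the two images.  Each image pixel is addressed by its
# angular position relative to the rendering eye's optical axis; rendering
# is inverse ray casting with analytic (plane) or iterated (bumpy surface)
# ray intersections and bilinear/analytic texture lookup.

#' Viewing geometry
#'
#' Display/observer geometry for stereo rendering.  The default pixel pitch
#' comes from a 1920-pixel image spanning 36 degrees of visual angle
#' (approximately 53.33 px/deg).
#'
#' @param interocular_distance eye separation in meters (default 0.065, a
#'   standard adult interpupillary distance).
#' @param view_distance_screen observer-to-screen distance in meters
#'   (metadata only; default 3).
#' @param pixels_per_degree pixel density of the rendered images.
#' @param image_size side length of the square rendered patch in pixels.
#' @param mean_luminance mean luminance of rendered images, linear arbitrary
#'   units.
#' @param aperture_diameter nominal viewing-aperture diameter in degrees
#'   (metadata; display-side, does not affect cue computation).
#' @return an object of class `viewing_geometry`.
#' @export
viewing_geometry <- function(interocular_distance = 0.065,
                             view_distance_screen = 3,
                             pixels_per_degree = 1920 / 36,
                             image_size = 128L,
                             mean_luminance = 100,
                             aperture_diameter = 3) {
  stopifnot(interocular_distance > 0, view_distance_screen > 0,
            pixels_per_degree > 0, image_size > 0)
  structure(list(interocular_distance = interocular_distance,
                 view_distance_screen = view_distance_screen,
                 pixels_per_degree = pixels_per_degree,
                 image_size = as.integer(image_size),
                 mean_luminance = mean_luminance,
                 aperture_diameter = aperture_diameter),
            class = "viewing_geometry")
}

#' Scene specification
#'
#' Parameters of one synthetic textured surface.  `tilt` is the direction of
#' slant (orientation of the range gradient, counterclockwise from rightward
#' horizontal; 90 degrees is ground-plane-like), `slant` the rotation out of
#' the frontoparallel plane, `distance` the cyclopean distance to the patch
#' centre.  `bump_amplitude > 0` adds a smooth random height field along the
#' surface normal, producing natural-scene-like local tilt variance.
#'
#' @param tilt degrees in `[0, 360)`.
#' @param slant degrees in `[0, 90)`.
#' @param distance meters, positive.
#' @param texture_kind one of `"onef_noise"`, `"plaid_3.5cpd"`,
#'   `"plaid_5.25cpd"`.
#' @param contrast nominal RMS luminance contrast of the rendered patch.
#' @param bump_amplitude standard deviation of the height perturbation in
#'   meters (0 = perfectly planar).
#' @param bump_corr_length correlation length of the height field in
#'   projected degrees.
#' @param seed integer seed controlling texture and bumps.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(tilt, slant, distance,
                       texture_kind = "plaid_3.5cpd",
                       contrast = 0.25,
                       bump_amplitude = 0,
                       bump_corr_length = 0.5,
                       seed = 1) {
  stopifnot(is_scalar_num(tilt), is_scalar_num(slant), is_scalar_num(distance))
  if (distance <= 0) err("scene distance must be positive")
  if (slant < 0 || slant >= 90) err("slant must lie in [0, 90) degrees")
  if (bump_amplitude < 0) err("bump_amplitude must be non-negative")
  if (!texture_kind %in% texture_kinds) {
    err(sprintf("unknown texture kind '%s'", texture_kind),
        class = "tiltnorm_texture_error")
  }
  structure(list(tilt = tilt %% 360, slant = slant, distance = distance,
                 texture_kind = texture_kind, contrast = contrast,
                 bump_amplitude = bump_amplitude,
                 bump_corr_length = bump_corr_length,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Unit surface normal (pointing toward the viewer) and an in-plane
# orthonormal basis for texture coordinates.
plane_basis <- function(tilt, slant) {
  t <- deg2rad(tilt); s <- deg2rad(slant)
  n <- c(sin(s) * cos(t), sin(s) * sin(t), -cos(s))
  a <- if (abs(n[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- c(a[2] * n[3] - a[3] * n[2],
          a[3] * n[1] - a[1] * n[3],
          a[1] * n[2] - a[2] * n[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Height perturbation of a planar surface
#'
#' Builds the smooth random height field added along the surface normal when
#' `bump_amplitude > 0`: Gaussian-filtered white noise with correlation
#' length `bump_corr_length` (projected degrees), rescaled so its standard
#' deviation equals `bump_amplitude` meters.  With `bump_amplitude = 0` the
#' returned field is identically zero and rendering reproduces the exact
#' plane.
#'
#' @param spec a [scene_spec()].
#' @param extent_deg side length of the (clamped) height-field domain in
#'   projected degrees.
#' @param grid_n grid resolution of the field.
#' @return list with elements `fun(u, v)` (height in meters) and `amplitude`.
#' @export
perturb_surface <- function(spec, extent_deg = 12, grid_n = 256L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$bump_amplitude == 0) {
    return(list(fun = function(u, v) rep(0, length(u)), amplitude = 0))
  }
  N <- as.integer(grid_n)
  # widen the domain for long correlation lengths so the smoothing kernel
  # always fits the grid
  extent_deg <- max(extent_deg, 4 * spec$bump_corr_length)
  sigma_px <- spec$bump_corr_length / extent_deg * N
  grid <- with_seed(sub_seed(spec$seed, "bumps"), {
    g <- gaussian_blur(matrix(stats::rnorm(N * N), N, N), max(sigma_px, 0.51))
    g <- g - mean(g)
    g / stats::sd(g) * spec$bump_amplitude
  })
  half <- extent_deg / 2
  fun <- function(u, v) {
    gu <- (pmin(pmax(u, -half), half) + half) / extent_deg * (N - 1)
    gv <- (pmin(pmax(v, -half), half) + half) / extent_deg * (N - 1)
    i0 <- pmin(as.integer(floor(gu)), N - 2L); j0 <- pmin(as.integer(floor(gv)), N - 2L)
    du <- gu - i0; dv <- gv - j0
    g00 <- grid[cbind(j0 + 1L, i0 + 1L)]
    g10 <- grid[cbind(j0 + 1L, i0 + 2L)]
    g01 <- grid[cbind(j0 + 2L, i0 + 1L)]
    g11 <- grid[cbind(j0 + 2L, i0 + 2L)]
    (1 - du) * (1 - dv) * g00 + du * (1 - dv) * g10 +
      (1 - du) * dv * g01 + du * dv * g11
  }
  list(fun = fun, amplitude = spec$bump_amplitude)
}

# Intersect the eye rays of a pixel grid with the (possibly perturbed)
# surface.  `origin` is the eye position; returns distances along the rays
# and plane-local texture coordinates in projected degrees.
trace_surface <- function(origin, tanx, tany, basis, spec, bump, iters) {
  n <- basis$n; e1 <- basis$e1; e2 <- basis$e2
  p0 <- c(0, 0, spec$distance)
  s_deg <- spec$distance * pi / 180  # meters per projected degree at centre
  norm <- sqrt(tanx^2 + tany^2 + 1)
  wx <- tanx / norm; wy <- tany / norm; wz <- 1 / norm
  ndotw <- n[1] * wx + n[2] * wy + n[3] * wz
  base <- sum(n * (p0 - origin))
  if (any(abs(ndotw) < 1e-12)) err("ray parallel to surface within patch")
  r <- base / ndotw
  uu <- vv <- NULL
  for (k in seq_len(iters)) {
    px <- origin[1] + r * wx; py <- origin[2] + r * wy; pz <- origin[3] + r * wz
    dx <- px - p0[1]; dy <- py - p0[2]; dz <- pz - p0[3]
    uu <- (dx * e1[1] + dy * e1[2] + dz * e1[3]) / s_deg
    vv <- (dx * e2[1] + dy * e2[2] + dz * e2[3]) / s_deg
    if (bump$amplitude == 0) break
    h <- bump$fun(as.vector(uu), as.vector(vv))
    r_new <- (base + h) / ndotw
    if (max(abs(r_new - r)) < 1e-9) { r <- r_new; break }
    r <- r_new
  }
  if (any(r <= 0)) err("surface behind viewer")
  list(r = r, uu = uu, vv = vv)
}

#' Render a stereo patch
#'
#' Renders left- and right-eye luminance images of the textured surface in
#' `spec` by inverse ray casting, together with the cyclopean range map
#' (Euclidean distance from the cyclopean eye to the surface, meters) and a
#' half-occlusion mask (pixels whose scene point is hidden from one eye by a
#' surface fold).  Rendering is deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param geom a [viewing_geometry()].
#' @return an object of class `stereo_patch`: list with matrices `left`,
#'   `right`, `range_map`, logical `occlusion_mask`, and the input `spec`
#'   and `geom`.  Matrices are `[row = y (bottom-up), col = x]`.
#' @export
render_stereo <- function(spec, geom = viewing_geometry()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(geom, "viewing_geometry"))
  npx <- geom$image_size
  ppd <- geom$pixels_per_degree
  b <- geom$interocular_distance
  basis <- plane_basis(spec$tilt, spec$slant)
  tex <- texture_field(spec$texture_kind, ppd, sub_seed(spec$seed, "texture"))
  bump <- perturb_surface(spec)
  iters <- if (bump$amplitude > 0) 15L else 1L

  coord <- (seq_len(npx) - (npx + 1) / 2) / ppd  # degrees
  tanx <- matrix(tan(deg2rad(coord)), npx, npx, byrow = TRUE)
  tany <- matrix(tan(deg2rad(coord)), npx, npx)

  cyc <- trace_surface(c(0, 0, 0), tanx, tany, basis, spec, bump, iters)
  lft <- trace_surface(c(-b / 2, 0, 0), tanx, tany, basis, spec, bump, iters)
  rgt <- trace_surface(c(+b / 2, 0, 0), tanx, tany, basis, spec, bump, iters)

  lum <- function(tr) {
    t_val <- matrix(tex$fun(as.vector(tr$uu), as.vector(tr$vv)), npx, npx)
    geom$mean_luminance * (1 + spec$contrast * t_val)
  }
  left <- lum(lft)
  right <- lum(rgt)

  # half-occlusion: a surface fold makes the map from cyclopean pixel to an
  # eye's horizontal angle non-monotonic along a row
  occl <- matrix(FALSE, npx, npx)
  if (bump$amplitude > 0) {
    norm <- sqrt(tanx^2 + tany^2 + 1)
    px <- cyc$r * tanx / norm; pz <- cyc$r / norm
    xl <- atan2(px + b / 2, pz)
    xr <- atan2(px - b / 2, pz)
    fold <- function(xa) {
      d <- xa[, -1, drop = FALSE] - xa[, -ncol(xa), drop = FALSE]
      bad <- d <= 0
      m <- matrix(FALSE, nrow(xa), ncol(xa))
      m[, -1] <- bad
      m[, -ncol(xa)] <- m[, -ncol(xa)] | bad
      m
    }
    occl <- fold(xl) | fold(xr)
  }

  structure(list(left = left, right = right, range_map = cyc$r,
                 occlusion_mask = occl, spec = spec, geom = geom),
            class = "stereo_patch")
}

#' @export
print.stereo_patch <- function(x, ...) {
  cat(sprintf(
    "stereo_patch: %dx%d px, tilt %.1f deg, slant %.1f deg, %.1f m, %s%s\n",
    nrow(x$left), ncol(x$left), x$spec$tilt, x$spec$slant, x$spec$distance,
    x$spec$texture_kind,
    if (x$spec$bump_amplitude > 0)
      sprintf(", bumps %.3f m", x$spec$bump_amplitude) else ""))
  invisible(x)
}
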