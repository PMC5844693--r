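# Local image cues to surface tilt, computed directly from the stereo
# images: orientations of the luminance gradient, of the disparity gradient
# (disparity from windowed cross-correlation), and of the major axis of the
# local amplitude spectrum; plus windowed RMS luminance contrast.

#' Cue configuration
#'
#' @param sigma_cue_arcmin space constant of the Gaussian derivative (and of
#'   the cross-correlation window), arcmin; default 6, qualitative results
#'   should be stable over 3--12.
#' @param pixels_per_degree pixel density of the images.
#' @param disparity_search_range half-width of the integer disparity search,
#'   pixels (search runs over `offset +/- range`).
#' @param texture_window side length of the spectrum analysis window,
#'   degrees.
#' @param contrast_window_diameter diameter of the raised-cosine contrast
#'   window, degrees.
#' @param ncc_threshold minimum peak normalized cross-correlation for a
#'   disparity sample to count as reliable.
#' @param grad_eps gradient magnitude below which an orientation cue is
#'   flagged unreliable.
#' @param eig_ratio_min minimum spectrum eigenvalue ratio (major/minor) for
#'   a reliable texture cue; below it the spectrum is near-isotropic.
#' @param lowfreq_cutoff_cpd radial frequencies below this (and DC) are
#'   removed from the amplitude spectrum.
#' @param lum_pool_sigma space constant (degrees) of the Gaussian window
#'   pooling luminance gradients into the structure tensor of
#'   [luminance_cue()].
#' @param coherence_min minimum structure-tensor orientation coherence for a
#'   reliable luminance cue.
#' @return an object of class `cue_config`.
#' @export
cue_config <- function(sigma_cue_arcmin = 6,
                       pixels_per_degree = 1920 / 36,
                       disparity_search_range = 16L,
                       texture_window = 1,
                       contrast_window_diameter = 1,
                       ncc_threshold = 0.3,
                       grad_eps = 1e-9,
                       eig_ratio_min = 1.05,
                       lowfreq_cutoff_cpd = 1,
                       lum_pool_sigma = 0.75,
                       coherence_min = 0.05) {
  stopifnot(sigma_cue_arcmin > 0, pixels_per_degree > 0,
            disparity_search_range >= 1, texture_window > 0)
  structure(list(sigma_cue_arcmin = sigma_cue_arcmin,
                 pixels_per_degree = pixels_per_degree,
                 disparity_search_range = as.integer(disparity_search_range),
                 texture_window = texture_window,
                 contrast_window_diameter = contrast_window_diameter,
                 ncc_threshold = ncc_threshold,
                 grad_eps = grad_eps,
                 eig_ratio_min = eig_ratio_min,
                 lowfreq_cutoff_cpd = lowfreq_cutoff_cpd,
                 lum_pool_sigma = lum_pool_sigma,
                 coherence_min = coherence_min),
            class = "cue_config")
}

sigma_cue_px <- function(cfg) cfg$sigma_cue_arcmin / 60 * cfg$pixels_per_degree

#' Weighted RMS (Weber) contrast
#'
#' Evaluates \eqn{C = \sqrt{\sum_x ((I(x)-\bar I)/\bar I)^2 W(x) / \sum_x W(x)}}
#' with \eqn{\bar I = \sum_x I(x) W(x)/\sum_x W(x)}; the square root makes
#' the quantity a root-mean-square as named.
#'
#' @param values luminance values (any shape).
#' @param weights non-negative weights, same length.
#' @return scalar contrast (fraction).
#' @export
rms_contrast <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0), sum(weights) > 0)
  ibar <- sum(values * weights) / sum(weights)
  if (ibar <= 0) err("mean luminance is non-positive; contrast undefined")
  sqrt(sum(((values - ibar) / ibar)^2 * weights) / sum(weights))
}

# raised-cosine window over a central disc, diameter in degrees
cosine_window <- function(dim_px, diameter_deg, pixels_per_degree) {
  radius_px <- diameter_deg / 2 * pixels_per_degree
  c0 <- (dim_px + 1) / 2
  d <- sqrt(outer((seq_len(dim_px) - c0)^2, (seq_len(dim_px) - c0)^2, "+"))
  w <- 0.5 * (1 + cos(pi * pmin(d / radius_px, 1)))
  w[d > radius_px] <- 0
  w
}

#' Local luminance contrast of a patch
#'
#' Cosine-windowed RMS Weber contrast over the central region of the image.
#'
#' @param image luminance matrix (linear units).
#' @param cfg a [cue_config()].
#' @return scalar contrast (fraction).
#' @export
local_contrast <- function(image, cfg = cue_config()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  w <- cosine_window(nrow(image), cfg$contrast_window_diameter, cfg$pixels_per_degree)
  rms_contrast(as.vector(image), as.vector(w))
}

# orientation (mod 180) of a gradient field at the centre pixel
centre_orientation <- function(gx, gy, eps) {
  ctr <- (dim(gx) + 1) %/% 2
  vx <- gx[ctr[1], ctr[2]]; vy <- gy[ctr[1], ctr[2]]
  mag <- sqrt(vx^2 + vy^2)
  list(orientation = rad2deg(atan2(vy, vx)) %% 180,
       magnitude = mag, reliable = mag >= eps)
}

#' Luminance-gradient cue
#'
#' Orientation (mod 180) of the local luminance gradient: Gaussian
#' derivatives at `sigma_cue_arcmin` are pooled into a structure tensor
#' under a Gaussian window of space constant `lum_pool_sigma` degrees
#' centred on the patch, and the dominant gradient orientation (principal
#' eigenvector) is returned.  For a spatially uniform gradient field this
#' reduces to the plain gradient orientation at the centre; pooling makes
#' the orientation estimate phase-insensitive on textured surfaces.
#' Flagged unreliable when gradient energy vanishes or the orientation
#' coherence falls below `coherence_min`.
#'
#' @param image luminance matrix.
#' @param cfg a [cue_config()].
#' @return list with `orientation` (degrees `[0, 180)`), `magnitude`,
#'   `coherence`, `reliable`.
#' @export
luminance_cue <- function(image, cfg = cue_config()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  g <- gauss_gradient(image, sigma_cue_px(cfg))
  npx <- nrow(image)
  pool_px <- cfg$lum_pool_sigma * cfg$pixels_per_degree
  c0 <- (npx + 1) / 2
  d2 <- outer((seq_len(npx) - c0)^2, (seq_len(npx) - c0)^2, "+")
  w <- exp(-d2 / (2 * pool_px^2))
  jxx <- sum(w * g$gx^2); jyy <- sum(w * g$gy^2); jxy <- sum(w * g$gx * g$gy)
  energy <- jxx + jyy
  aniso <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coherence <- if (energy > 0) aniso / energy else 0
  mag_floor <- cfg$grad_eps * max(mean(abs(image)), 1e-12)
  list(orientation = rad2deg(0.5 * atan2(2 * jxy, jxx - jyy)) %% 180,
       magnitude = sqrt(energy / sum(w)),
       coherence = coherence,
       reliable = sqrt(energy / sum(w)) >= mag_floor &&
         coherence >= cfg$coherence_min)
}

# shift matrix columns by s (content moves right by s); vacated columns = 0
shift_cols <- function(m, s) {
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  if (s >= 0) {
    if (s < n) out[, (s + 1):n] <- m[, 1:(n - s)]
  } else {
    if (-s < n) out[, 1:(n + s)] <- m[, (1 - s):n]
  }
  out
}

#' Horizontal disparity map by windowed cross-correlation
#'
#' For each pixel, finds the integer horizontal shift (within
#' `offset +/- disparity_search_range`) maximizing the Gaussian-windowed
#' normalized cross-correlation between left and right images, then refines
#' to sub-pixel precision by parabolic interpolation of the correlation
#' peak.  Disparity is signed as `x_left - x_right` (positive for points
#' nearer than the parallel-axis fixation at infinity).
#'
#' @param left,right equal-size rectified luminance matrices.
#' @param cfg a [cue_config()]; the correlation window has the same space
#'   constant as the derivative operator.
#' @param offset integer disparity around which to search, pixels.  Pass the
#'   expected disparity (interocular distance / distance, in pixels) to
#'   emulate vergence on the patch centre.
#' @return list of matrices: `disparity` (px, sub-pixel), `ncc_peak`, and
#'   logical `reliable` (peak above `ncc_threshold` and away from the search
#'   bounds and image margins).
#' @export
disparity_map <- function(left, right, cfg = cue_config(), offset = 0L) {
  stopifnot(is.matrix(left), is.matrix(right), all(dim(left) == dim(right)))
  offset <- as.integer(round(offset))
  rng <- cfg$disparity_search_range
  cand <- offset + (-rng):rng
  sig <- sigma_cue_px(cfg)
  npx <- nrow(left)

  blur <- function(m) gaussian_blur(m, sig)
  mu_l <- blur(left)
  var_l <- pmax(blur(left^2) - mu_l^2, 0)
  ncc <- array(NA_real_, c(npx, ncol(left), length(cand)))
  for (i in seq_along(cand)) {
    rs <- shift_cols(right, cand[i])
    mu_r <- blur(rs)
    var_r <- pmax(blur(rs^2) - mu_r^2, 0)
    cov_lr <- blur(left * rs) - mu_l * mu_r
    ncc[, , i] <- cov_lr / sqrt(pmax(var_l * var_r, 1e-20))
  }
  best <- apply(ncc, c(1, 2), which.max)
  peak <- matrix(ncc[cbind(rep(seq_len(npx), ncol(left)),
                           rep(seq_len(ncol(left)), each = npx),
                           as.vector(best))], npx, ncol(left))
  disp <- matrix(cand[best], npx, ncol(left))
  # parabolic sub-pixel refinement where the peak is interior
  interior <- best > 1 & best < length(cand)
  if (any(interior)) {
    idx <- which(interior, arr.ind = TRUE)
    b <- best[interior]
    c0 <- ncc[cbind(idx, b)]
    cm <- ncc[cbind(idx, b - 1L)]
    cp <- ncc[cbind(idx, b + 1L)]
    denom <- cm - 2 * c0 + cp
    delta <- ifelse(abs(denom) > 1e-12, 0.5 * (cm - cp) / denom, 0)
    disp[interior] <- disp[interior] + pmax(pmin(delta, 0.5), -0.5)
  }
  # columns corrupted by zero-padding of the shifted image: positive shifts
  # zero the left edge, negative shifts the right edge (plus ~1 sigma of
  # window bleed)
  bleed <- ceiling(sig)
  lmar <- max(max(cand), 0L) + bleed
  rmar <- max(-min(cand), 0L) + bleed
  valid_col <- rep(TRUE, ncol(left))
  valid_col[seq_len(min(lmar, ncol(left)))] <- FALSE
  valid_col[seq.int(to = ncol(left), length.out = min(rmar, ncol(left)))] <- FALSE
  reliable <- peak >= cfg$ncc_threshold & interior &
    matrix(valid_col, npx, ncol(left), byrow = TRUE)
  list(disparity = disp, ncc_peak = peak, reliable = reliable)
}

#' Disparity-gradient cue
#'
#' Orientation (mod 180) of the Gaussian-derivative gradient of the
#' disparity map at the patch centre.  Flagged unreliable when the central
#' neighbourhood of the disparity map is itself unreliable or the gradient
#' vanishes.
#'
#' @param dmap result of [disparity_map()].
#' @param cfg a [cue_config()].
#' @return list with `orientation`, `magnitude`, `reliable`.
#' @export
disparity_cue <- function(dmap, cfg = cue_config()) {
  stopifnot(is.list(dmap), is.matrix(dmap$disparity))
  sig <- sigma_cue_px(cfg)
  npx <- nrow(dmap$disparity)
  ctr <- (npx + 1) %/% 2
  half <- ceiling(3 * sig)
  rows <- max(1, ctr - half):min(npx, ctr + half)
  neigh_ok <- mean(dmap$reliable[rows, rows]) >= 0.75
  g <- gauss_gradient(dmap$disparity, sig)
  out <- centre_orientation(g$gx, g$gy, cfg$grad_eps)
  out$reliable <- out$reliable && neigh_ok
  out
}

#' Texture (amplitude-spectrum) cue
#'
#' Orientation of the major axis of the local amplitude spectrum of the
#' luminance image: the central `texture_window` region is Hann-windowed,
#' Fourier transformed, DC and radial frequencies below the cutoff removed,
#' and the principal eigenvector of the second-moment matrix of amplitude
#' mass over frequency coordinates is returned (mod 180).  Near-isotropic
#' spectra (eigenvalue ratio below `eig_ratio_min`) are flagged unreliable.
#'
#' @param image luminance matrix.
#' @param cfg a [cue_config()].
#' @return list with `orientation`, `eig_ratio`, `reliable`.
#' @export
texture_cue <- function(image, cfg = cue_config()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  npx <- nrow(image)
  w_px <- min(npx, 2L * (as.integer(cfg$texture_window * cfg$pixels_per_degree) %/% 2L))
  if (w_px < 8) err("texture window does not fit in patch")
  ctr <- (npx + 1) %/% 2
  half <- w_px %/% 2
  rows <- (ctr - half + 1):(ctr + half)
  sub <- image[rows, rows]
  sub <- sub - mean(sub)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(w_px) - 1) / (w_px - 1)))
  sub <- sub * outer(hann, hann)
  amp <- Mod(stats::fft(sub))
  k <- c(0:(w_px %/% 2), -((w_px - w_px %/% 2 - 1):1)) / w_px  # cycles/px
  fx <- matrix(k, w_px, w_px, byrow = TRUE) * cfg$pixels_per_degree  # cpd
  fy <- matrix(k, w_px, w_px) * cfg$pixels_per_degree
  fr <- sqrt(fx^2 + fy^2)
  amp[fr < cfg$lowfreq_cutoff_cpd] <- 0
  total <- sum(amp)
  if (total <= 0) err("empty amplitude spectrum")
  mxx <- sum(amp * fx^2) / total
  myy <- sum(amp * fy^2) / total
  mxy <- sum(amp * fx * fy) / total
  tr2 <- (mxx + myy) / 2
  det_root <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  lam1 <- tr2 + det_root
  lam2 <- max(tr2 - det_root, 1e-15)
  orient <- rad2deg(0.5 * atan2(2 * mxy, mxx - myy)) %% 180
  ratio <- lam1 / lam2
  list(orientation = orient, eig_ratio = ratio,
       reliable = ratio >= cfg$eig_ratio_min)
}

#' Compute the cue triplet of a stereo patch
#'
#' Assembles the three orientation cues at the patch centre (luminance and
#' texture cues from the left-eye image; disparity cue from the pair, with
#' the correlation search centred on the disparity expected from the
#' centre-pixel range, emulating vergence on the scene point) plus the local
#' luminance contrast.  Deterministic for fixed inputs.
#'
#' @param patch a [render_stereo()] patch (or any list with `left`, `right`,
#'   `range_map`, `geom`).
#' @param cfg a [cue_config()]; its `pixels_per_degree` is overridden by the
#'   patch geometry.
#' @return an object of class `cue_triplet`: list with `lum`, `disp`, `tex`
#'   (degrees `[0, 180)` or `NA` when unreliable), logical vector
#'   `reliable`, `contrast`, and `disparity_center` (px).
#' @export
compute_cue_triplet <- function(patch, cfg = cue_config()) {
  stopifnot(!is.null(patch$left), !is.null(patch$right), !is.null(patch$range_map))
  cfg$pixels_per_degree <- patch$geom$pixels_per_degree
  ctr <- (dim(patch$left) + 1) %/% 2
  r_c <- patch$range_map[ctr[1], ctr[2]]
  offset <- round(patch$geom$interocular_distance / r_c *
                    180 / pi * cfg$pixels_per_degree)
  lum <- luminance_cue(patch$left, cfg)
  dmap <- disparity_map(patch$left, patch$right, cfg, offset = offset)
  dsp <- disparity_cue(dmap, cfg)
  tex <- texture_cue(patch$left, cfg)
  structure(list(
    lum = if (lum$reliable) lum$orientation else NA_real_,
    disp = if (dsp$reliable) dsp$orientation else NA_real_,
    tex = if (tex$reliable) tex$orientation else NA_real_,
    reliable = c(lum = lum$reliable, disp = dsp$reliable, tex = tex$reliable),
    contrast = local_contrast(patch$left, cfg),
    disparity_center = dmap$disparity[ctr[1], ctr[2]]
  ), class = "cue_triplet")
}
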