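# Stimulus sampling: constrained random sampling of rendered stereo patches
# (the experiment's stimulus set), a cardinal-heavy tilt prior emulating
# natural-scene statistics, and a cheap cue-sample simulator used to train
# estimate cubes at desk scale.

#' Stimulus sampling constraints
#'
#' Defaults follow the experimental constraints: slants larger than 30
#' degrees, distances between 5 and 50 m, contrasts between 5% and 40%,
#' 24 tilt bins, binocular visibility (no half-occlusions).
#'
#' @param min_slant minimum slant, degrees.
#' @param max_slant maximum slant drawn by the sampler, degrees.
#' @param distance_range length-2 numeric, meters.
#' @param contrast_range length-2 numeric, fraction.
#' @param n_tilt_bins number of (signed) tilt bins over `[0, 360)`.
#' @param n_per_bin stimuli per tilt bin.
#' @return an object of class `sampling_constraints`.
#' @export
sampling_constraints <- function(min_slant = 30, max_slant = 75,
                                 distance_range = c(5, 50),
                                 contrast_range = c(0.05, 0.40),
                                 n_tilt_bins = 24L, n_per_bin = 150L) {
  stopifnot(min_slant >= 0, max_slant < 90, max_slant > min_slant,
            length(distance_range) == 2, distance_range[1] > 0,
            diff(distance_range) > 0, length(contrast_range) == 2,
            contrast_range[1] > 0, diff(contrast_range) > 0,
            n_tilt_bins >= 1, n_per_bin >= 1)
  structure(list(min_slant = min_slant, max_slant = max_slant,
                 distance_range = distance_range,
                 contrast_range = contrast_range,
                 n_tilt_bins = as.integer(n_tilt_bins),
                 n_per_bin = as.integer(n_per_bin)),
            class = "sampling_constraints")
}

#' Sample a constrained stimulus set
#'
#' Draws `n_tilt_bins * n_per_bin` rendered stereo patches by rejection
#' sampling: per tilt bin, tilt is uniform within the bin and slant,
#' distance and nominal contrast are uniform within their ranges; a patch
#' is accepted only if its measured central contrast lies in
#' `contrast_range` and no half-occlusions touch the central region.
#' Acceptance rates are recorded per bin.
#'
#' @param constraints a [sampling_constraints()].
#' @param geom a [viewing_geometry()].
#' @param seed integer seed.
#' @param texture_kinds texture kinds to draw from.
#' @param bump_amplitude_range length-2 range of bump amplitudes (meters);
#'   `c(0, 0)` renders perfectly planar (artificial-style) stimuli.
#' @param cue_cfg a [cue_config()] used for the contrast re-check.
#' @param max_attempts_per_accept abort threshold: if a bin's acceptance
#'   rate falls below `1/max_attempts_per_accept` the sampler stops with a
#'   diagnostic.
#' @return list of `stereo_patch` objects with attribute
#'   `acceptance_rate` (per-bin fraction of accepted draws).
#' @export
sample_stimuli <- function(constraints, geom = viewing_geometry(), seed = 1,
                           texture_kinds = c("onef_noise", "plaid_3.5cpd",
                                             "plaid_5.25cpd"),
                           bump_amplitude_range = c(0, 0),
                           cue_cfg = NULL,
                           max_attempts_per_accept = 1000L) {
  stopifnot(inherits(constraints, "sampling_constraints"))
  if (is.null(cue_cfg)) {
    cue_cfg <- cue_config(pixels_per_degree = geom$pixels_per_degree)
  }
  nb <- constraints$n_tilt_bins
  width <- 360 / nb
  patches <- vector("list", nb * constraints$n_per_bin)
  acc <- numeric(nb)
  ppd <- geom$pixels_per_degree
  npx <- geom$image_size
  central <- central_mask(npx, min(1, npx / ppd), ppd)
  with_seed(seed, {
    out_i <- 0L
    for (bin in seq_len(nb)) {
      accepted <- 0L
      attempts <- 0L
      while (accepted < constraints$n_per_bin) {
        attempts <- attempts + 1L
        if (attempts > max_attempts_per_accept * constraints$n_per_bin) {
          err(sprintf(
            "tilt bin %d: acceptance rate below %.2g%% (%d accepted of %d attempts)",
            bin, 100 / max_attempts_per_accept, accepted, attempts))
        }
        spec <- scene_spec(
          tilt = (bin - 1) * width + stats::runif(1, 0, width),
          slant = stats::runif(1, constraints$min_slant, constraints$max_slant),
          distance = stats::runif(1, constraints$distance_range[1],
                                  constraints$distance_range[2]),
          texture_kind = sample(texture_kinds, 1),
          contrast = stats::runif(1, constraints$contrast_range[1] * 1.1,
                                  constraints$contrast_range[2] * 0.9),
          bump_amplitude = stats::runif(1, bump_amplitude_range[1],
                                        bump_amplitude_range[2]),
          seed = sample.int(.Machine$integer.max - 1L, 1))
        patch <- tryCatch(render_stereo(spec, geom), error = function(e) NULL)
        if (is.null(patch)) next
        if (any(patch$occlusion_mask & central)) next
        ctr <- local_contrast(patch$left, cue_cfg)
        if (ctr < constraints$contrast_range[1] ||
            ctr > constraints$contrast_range[2]) next
        accepted <- accepted + 1L
        out_i <- out_i + 1L
        patches[[out_i]] <- patch
      }
      acc[bin] <- accepted / attempts
    }
  })
  attr(patches, "acceptance_rate") <- acc
  patches
}

#' Sample tilts from a cardinal-heavy natural prior
#'
#' Mixture emulating the distribution of unsigned tilt in natural scenes:
#' a ground-plane component concentrated at 90 degrees, a trunk-like
#' component concentrated at 0/180, and a uniform oblique minority.
#' Concentrated components are axial von Mises.
#'
#' @param n number of tilts.
#' @param weights length-3 non-negative weights `(ground, trunk, oblique)`;
#'   default `c(0.5, 0.3, 0.2)`.
#' @param concentration von Mises kappa (doubled angles) of the cardinal
#'   components.
#' @param seed integer seed.
#' @return numeric vector of unsigned tilts in `[0, 180)`.
#' @export
sample_tilt_prior <- function(n, weights = c(0.5, 0.3, 0.2),
                              concentration = 8, seed = 1) {
  stopifnot(n >= 1, length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  with_seed(seed, {
    comp <- sample.int(3, n, replace = TRUE, prob = weights)
    tilt <- numeric(n)
    ng <- sum(comp == 1); nt <- sum(comp == 2); no <- sum(comp == 3)
    if (ng) tilt[comp == 1] <- (90 + rvm_axial_deg(ng, concentration)) %% 180
    if (nt) tilt[comp == 2] <- (0 + rvm_axial_deg(nt, concentration)) %% 180
    if (no) tilt[comp == 3] <- stats::runif(no, 0, 180)
    tilt
  })
}

#' Simulate (cue triplet, groundtruth tilt) training samples
#'
#' Cheap stand-in for measuring cues on millions of rendered patches:
#' tilts are drawn from the cardinal-heavy prior, each stimulus receives a
#' base reliability level (a von Mises kappa drawn from `kappa_set`), and
#' each of the three cues is the tilt corrupted by independent axial von
#' Mises noise at the base kappa times an independent per-cue jitter
#' factor.  Reliability is thus correlated across the cues of a stimulus
#' (as in natural scenes, where a flat or low-contrast region degrades all
#' measurements) but not identical (each cue has its own failure modes), so
#' cue consistency within a triplet carries reliability information, as it
#' does for real image cues.
#'
#' @param n number of samples.
#' @param kappa_set candidate base cue-noise concentrations (doubled-angle
#'   von Mises kappa); default `c(1, 4, 16)` spanning near-uniform to
#'   precise.
#' @param kappa_probs mixture probabilities (default equal).
#' @param kappa_jitter per-cue multiplicative jitter factors applied
#'   independently to the base kappa (default `c(0.5, 1, 2)`).
#' @param prior_weights,prior_concentration passed to [sample_tilt_prior()].
#' @param seed integer seed.
#' @return data frame with columns `tilt`, `lum`, `disp`, `tex`, `kappa`
#'   (the base kappa).
#' @export
sample_cue_database <- function(n, kappa_set = c(1, 4, 16),
                                kappa_probs = NULL,
                                kappa_jitter = c(0.5, 1, 2),
                                prior_weights = c(0.5, 0.3, 0.2),
                                prior_concentration = 8, seed = 1) {
  stopifnot(n >= 1, all(kappa_set >= 0), all(kappa_jitter > 0))
  tilt <- sample_tilt_prior(n, prior_weights, prior_concentration,
                            seed = sub_seed(seed, "prior"))
  with_seed(sub_seed(seed, "cues"), {
    kappa <- if (length(kappa_set) == 1) rep(kappa_set, n) else
      sample(kappa_set, n, replace = TRUE, prob = kappa_probs)
    noisy <- function() {
      k <- kappa * if (length(kappa_jitter) == 1) kappa_jitter else
        sample(kappa_jitter, n, replace = TRUE)
      out <- numeric(n)
      for (kv in unique(k)) {
        m <- k == kv
        out[m] <- (tilt[m] + rvm_axial_deg(sum(m), kv)) %% 180
      }
      out
    }
    data.frame(tilt = tilt, lum = noisy(), disp = noisy(), tex = noisy(),
               kappa = kappa)
  })
}
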