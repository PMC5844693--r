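# stereo rendering: geometry, determinism, disparity consistency, bumps

test_that("frontoparallel plane has constant range equal to its distance", {
  p <- cached_patch(0, 0, 3, "onef_noise", seed = 5)
  expect_lt(max(abs(p$range_map - 3)), 3 * 2e-3)  # radial vs planar distance
  expect_false(any(p$occlusion_mask))
})

test_that("range increases with elevation for a ground-plane-like patch", {
  p <- cached_patch(90, 45, 10, "plaid_3.5cpd", seed = 3)
  npx <- nrow(p$range_map)
  col <- p$range_map[, (npx + 1) %/% 2]
  expect_true(all(diff(col) > 0))
  # analytic gradient direction at the centre is 90 degrees
  tr <- patch_truth(p)
  expect_lt(abs(circ_error(tr$signed_tilt, 90, 360)), 1)
})

test_that("rendering is bit-deterministic in the seed", {
  s <- scene_spec(37, 55, 8, "onef_noise", seed = 21, bump_amplitude = 0.05)
  g <- test_geom(64)
  p1 <- render_stereo(s, g)
  p2 <- render_stereo(s, g)
  expect_identical(p1$left, p2$left)
  expect_identical(p1$right, p2$right)
  expect_identical(p1$range_map, p2$range_map)
})

test_that("invalid scenes are rejected", {
  expect_error(scene_spec(0, 95, 5), class = "tiltnorm_error")
  expect_error(scene_spec(0, 45, -2), class = "tiltnorm_error")
  expect_error(scene_spec(0, 45, 5, bump_amplitude = -1),
               class = "tiltnorm_error")
})

test_that("frontoparallel left/right images differ by the analytic shift", {
  geom <- test_geom(160)
  b <- geom$interocular_distance
  ppd <- geom$pixels_per_degree
  shift_px <- 66L
  # choose the distance whose analytic disparity b/d is exactly 66 px
  d <- b * 180 / pi * ppd / shift_px
  p <- render_stereo(scene_spec(0, 0, d, "onef_noise", seed = 8), geom)
  n <- ncol(p$left)
  # a scene point appears shift_px further right in the left eye's image
  lhs <- p$left[, (shift_px + 1):n]
  rhs <- p$right[, 1:(n - shift_px)]
  # sub-0.5 px agreement: residual off-integer part of the true shift plus
  # bilinear interpolation error must stay well below one pixel's worth of
  # luminance change
  scale_px <- max(abs(diff(t(p$left))))  # typical per-pixel luminance step
  expect_lt(max(abs(lhs - rhs)), 0.5 * scale_px)
})

test_that("zero bump amplitude reproduces the exact plane", {
  g <- test_geom(64)
  flat <- render_stereo(scene_spec(120, 50, 10, "onef_noise", seed = 2,
                                   bump_amplitude = 0), g)
  # perturb_surface with amplitude 0 is the zero field
  ps <- perturb_surface(scene_spec(120, 50, 10, "onef_noise", seed = 2))
  expect_identical(ps$fun(c(-1, 0, 2), c(0, 1, -3)), c(0, 0, 0))
  # perspective makes tilt vary infinitesimally across a planar patch, so
  # the variance is numerically zero rather than exactly zero
  expect_lt(patch_truth(flat)$tilt_variance, 1e-3)
})

test_that("tilt variance rises with bump amplitude and vanishes for long
           correlation lengths", {
  g <- test_geom(64)
  amps <- c(0.02, 0.08, 0.25)
  tv <- matrix(NA_real_, 50, length(amps))
  for (s in 1:50) {
    for (j in seq_along(amps)) {
      p <- render_stereo(scene_spec(45, 50, 10, "onef_noise", seed = 100 + s,
                                    bump_amplitude = amps[j],
                                    bump_corr_length = 0.5), g)
      tv[s, j] <- patch_truth(p)$tilt_variance
    }
  }
  med <- apply(tv, 2, median)
  expect_true(all(diff(med) > 0))
  # correlation length much larger than the patch: locally planar
  p <- render_stereo(scene_spec(45, 50, 10, "onef_noise", seed = 3,
                                bump_amplitude = 0.1, bump_corr_length = 30), g)
  expect_lt(patch_truth(p)$tilt_variance, 0.01)
})

test_that("sample_stimuli returns the requested counts and respects
           constraints on re-check", {
  cons <- sampling_constraints(n_tilt_bins = 2L, n_per_bin = 3L)
  geom <- test_geom(96)
  patches <- sample_stimuli(cons, geom, seed = 12)
  expect_length(patches, 2L * 3L)
  expect_length(attr(patches, "acceptance_rate"), 2L)
  cfg <- cue_config(pixels_per_degree = geom$pixels_per_degree)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    expect_gt(p$spec$slant, 30)
    expect_gte(p$spec$distance, 5)
    expect_lte(p$spec$distance, 50)
    ctr <- local_contrast(p$left, cfg)
    expect_gte(ctr, 0.05)
    expect_lte(ctr, 0.40)
    # groundtruth tilt of the planar patch falls in its assigned bin
    bin <- (i - 1) %/% 3L + 1L
    tt <- patch_truth(p)$signed_tilt
    expect_lt(abs(circ_error(tt, (bin - 0.5) * 180, 360)), 90 + 1)
  }
  # requested-count arithmetic matches the experiment's printed sizes
  expect_identical(sampling_constraints()$n_tilt_bins *
                     sampling_constraints()$n_per_bin, 3600L)
  expect_identical(sampling_constraints(n_per_bin = 60L)$n_tilt_bins * 60L,
                   1440L)
})

test_that("synthetic observer recovers limits and its concentration", {
  est <- runif(200, 0, 180)
  # noiseless limit
  resp <- synthetic_observer(est, synthetic_observer_spec(Inf, 0), seed = 1)
  expect_equal(resp, est %% 180, tolerance = 1e-12)
  # kappa = 0: uniform axial responses, circular variance near 1
  resp <- synthetic_observer(rep(45, 10000), synthetic_observer_spec(0, 0),
                             seed = 2)
  expect_gt(circ_mean_var(resp, 180)$variance, 0.95)
  # kappa recovered within 10% by an ML fit on doubled angles
  resp <- synthetic_observer(rep(45, 10000), synthetic_observer_spec(5, 0),
                             seed = 3)
  k_hat <- ml_kappa(pi / 180 * (2 * resp))
  expect_lt(abs(k_hat - 5) / 5, 0.10)
  # determinism
  expect_identical(synthetic_observer(est, synthetic_observer_spec(3, 0.1), 7),
                   synthetic_observer(est, synthetic_observer_spec(3, 0.1), 7))
})
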