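# Shared fixtures and independent oracles used across test files.

# Brute-force MMSE oracle: the angle minimizing the mean squared circular
# (axial) distance to a set of tilts, over a 0.1-degree grid.
brute_force_circ_mmse <- function(tilts, period = 180, step = 0.1) {
  grid <- seq(0, period - step, by = step)
  cost <- vapply(grid, function(g)
    mean(circ_error(g, tilts, period = period)^2), numeric(1))
  grid[which.min(cost)]
}

# Maximum-likelihood von Mises concentration from angles on the full circle
# (radians), via the standard A1-inverse approximation (Fisher 1993).
ml_kappa <- function(theta) {
  R <- Mod(mean(complex(modulus = 1, argument = theta)))
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

# 90-degree counterclockwise rotation in the package's y-up convention:
# new[r, c] = old[n + 1 - c, r]
rot90_yup <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Small rendering geometry used by most tests (2.4 deg patch at full pixel
# density keeps every cue window valid while staying fast).
test_geom <- function(image_size = 128L) viewing_geometry(image_size = image_size)

# Render-once cache shared within a test file run.
.patch_cache <- new.env(parent = emptyenv())
cached_patch <- function(tilt, slant, distance, texture_kind, seed,
                         contrast = 0.3, image_size = 128L, ...) {
  key <- paste(tilt, slant, distance, texture_kind, seed, contrast,
               image_size, ..., sep = "|")
  if (is.null(.patch_cache[[key]])) {
    .patch_cache[[key]] <- render_stereo(
      scene_spec(tilt = tilt, slant = slant, distance = distance,
                 texture_kind = texture_kind, contrast = contrast,
                 seed = seed, ...),
      test_geom(image_size))
  }
  .patch_cache[[key]]
}

# Simulated-cue estimate cube shared within a test file run.
.cube_cache <- new.env(parent = emptyenv())
cached_cube <- function(n = 4e6, bins = 64L, min_count = 10L, seed = 42,
                        kappa_set = c(1, 4, 16)) {
  key <- paste(n, bins, min_count, seed, paste(kappa_set, collapse = ","),
               sep = "|")
  if (is.null(.cube_cache[[key]])) {
    .cube_cache[[key]] <- build_cube(
      sample_cue_database(n, kappa_set = kappa_set, seed = seed),
      bins, min_count)
  }
  .cube_cache[[key]]
}

# axial von Mises cue noise around given tilts (test-side generator)
noisy_cues_df <- function(tilt, kappa, seed) {
  with_seed_test(seed, {
    data.frame(
      lum = (tilt + tiltnorm:::rvm_axial_deg(length(tilt), kappa)) %% 180,
      disp = (tilt + tiltnorm:::rvm_axial_deg(length(tilt), kappa)) %% 180,
      tex = (tilt + tiltnorm:::rvm_axial_deg(length(tilt), kappa)) %% 180)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
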