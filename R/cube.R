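# The estimate cube: a nonparametric minimum mean squared error tilt
# estimator.  Cue triplets are quantized into a B x B x B table (default
# 64^3); each cell stores the circular mean (on doubled angles, since
# unsigned tilt is axial) of the groundtruth tilts of the training samples
# that fell in the cell.  Estimation is pure table lookup; sparsely
# populated cells fall back to the prior mean, the cue-free MMSE answer.

#' Quantize a cue triplet to cube cell indices
#'
#' Uniform half-open bins `[i * 180/B, (i+1) * 180/B)` per cue.  Returns
#' 1-based indices; a cue exactly on a bin edge goes to the upper bin.
#'
#' @param cues either a numeric vector `c(lum, disp, tex)` in degrees
#'   `[0, 180)`, a `cue_triplet`, or a data frame with columns `lum`,
#'   `disp`, `tex`.
#' @param bins_per_cue number of bins per cue (default 64).
#' @return integer matrix with columns `i`, `j`, `k` (one row per triplet).
#' @export
quantize_cues <- function(cues, bins_per_cue = 64L) {
  B <- as.integer(bins_per_cue)
  stopifnot(B >= 1)
  if (inherits(cues, "cue_triplet")) {
    m <- cbind(cues$lum, cues$disp, cues$tex)
  } else if (is.data.frame(cues)) {
    m <- cbind(cues$lum, cues$disp, cues$tex)
  } else {
    stopifnot(is.numeric(cues), length(cues) %% 3 == 0)
    m <- matrix(cues, ncol = 3, byrow = is.null(dim(cues)))
  }
  if (any(m < 0 | m >= 180, na.rm = TRUE)) err("cues must lie in [0, 180)")
  idx <- floor(m / 180 * B) + 1L
  idx[idx > B] <- B  # guard against floating-point roundoff at 180-epsilon
  colnames(idx) <- c("i", "j", "k")
  storage.mode(idx) <- "integer"
  idx
}

cell_linear_index <- function(idx, B) {
  (idx[, 1] - 1L) + B * (idx[, 2] - 1L) + B * B * (idx[, 3] - 1L) + 1L
}

#' Build an estimate cube from training samples
#'
#' Accumulates, per quantized cue-triplet cell, the doubled-angle complex
#' resultant of the groundtruth tilts, and stores the circular-mean tilt of
#' each cell as its minimum mean squared (circular) error estimate.  Cells
#' with fewer than `min_count` samples (or a vanishing resultant) fall back
#' to the prior mean, the circular mean of all training tilts.
#'
#' @param samples data frame with columns `lum`, `disp`, `tex` (cue
#'   orientations, degrees `[0, 180)`) and `tilt` (unsigned groundtruth,
#'   degrees `[0, 180)`).  Rows with any `NA` cue are excluded.
#' @param bins_per_cue bins per cue dimension (default 64).
#' @param min_count minimum cell occupancy for a data-driven estimate
#'   (default 10).
#' @return an object of class `estimate_cube`.
#' @export
build_cube <- function(samples, bins_per_cue = 64L, min_count = 10L) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 1) err("no training samples")
  need <- c("lum", "disp", "tex", "tilt")
  if (!all(need %in% names(samples))) {
    err(paste("samples must have columns:", paste(need, collapse = ", ")))
  }
  keep <- stats::complete.cases(samples[, need])
  samples <- samples[keep, , drop = FALSE]
  if (nrow(samples) < 1) err("no training samples with all cues reliable")
  B <- as.integer(bins_per_cue)
  idx <- cell_linear_index(quantize_cues(samples, B), B)
  th2 <- deg2rad(2 * samples$tilt)
  n_cells <- B^3
  count <- tabulate(idx, nbins = n_cells)
  cos2 <- sin2 <- numeric(n_cells)
  agg_c <- rowsum(cos(th2), idx)
  agg_s <- rowsum(sin(th2), idx)
  cells <- as.integer(rownames(agg_c))
  cos2[cells] <- agg_c[, 1]
  sin2[cells] <- agg_s[, 1]
  prior <- circ_mean_var(samples$tilt, period = 180)
  prior_mean <- if (prior$mean_defined) prior$mean else 0
  resultant_len <- sqrt(cos2^2 + sin2^2)
  est <- rep(prior_mean, n_cells)
  ok <- count >= min_count & resultant_len > 1e-12
  est[ok] <- (rad2deg(atan2(sin2[ok], cos2[ok])) / 2) %% 180
  structure(list(bins_per_cue = B, min_count = as.integer(min_count),
                 cell_estimate = est, cell_count = count,
                 cell_cos2 = cos2, cell_sin2 = sin2,
                 prior_mean = prior_mean, n_train = nrow(samples)),
            class = "estimate_cube")
}

#' @export
print.estimate_cube <- function(x, ...) {
  pop <- sum(x$cell_count > 0)
  cat(sprintf(
    "estimate cube: %d^3 cells (%d populated, %d above min_count %d), %d training samples, prior mean %.1f deg\n",
    x$bins_per_cue, pop, sum(x$cell_count >= x$min_count), x$min_count,
    x$n_train, x$prior_mean))
  invisible(x)
}

#' MMSE tilt estimates by cube lookup
#'
#' Quantizes each cue triplet and reads the stored cell estimate; no
#' interpolation.  Triplets with any unreliable (`NA`) cue receive the
#' prior-mean fallback and are flagged.
#'
#' @param cube an [build_cube()] estimate cube.
#' @param cues a `cue_triplet`, data frame with columns `lum`/`disp`/`tex`,
#'   or length-3 numeric vector.
#' @return data frame with columns `estimate` (degrees `[0, 180)`),
#'   `fallback` (logical: prior-mean used), and `cell_count`.
#' @export
estimate_tilt <- function(cube, cues) {
  stopifnot(inherits(cube, "estimate_cube"))
  if (inherits(cues, "cue_triplet")) {
    df <- data.frame(lum = cues$lum, disp = cues$disp, tex = cues$tex)
  } else if (is.data.frame(cues)) {
    df <- cues
  } else {
    df <- as.data.frame(matrix(cues, ncol = 3, byrow = is.null(dim(cues))))
    names(df) <- c("lum", "disp", "tex")
  }
  n <- nrow(df)
  est <- rep(cube$prior_mean, n)
  fallback <- rep(TRUE, n)
  count <- integer(n)
  ok <- stats::complete.cases(df[, c("lum", "disp", "tex")])
  if (any(ok)) {
    idx <- cell_linear_index(
      quantize_cues(df[ok, , drop = FALSE], cube$bins_per_cue), cube$bins_per_cue)
    est[ok] <- cube$cell_estimate[idx]
    count[ok] <- cube$cell_count[idx]
    fallback[ok] <- cube$cell_count[idx] < cube$min_count
  }
  data.frame(estimate = est, fallback = fallback, cell_count = count)
}

#' Train on a holdout partition and estimate the held-out samples
#'
#' Builds the cube from all samples except `test_ids` and returns estimates
#' for the held-out rows.  With large training sets, excluding a small test
#' set should change held-out estimates by well under a degree (median).
#'
#' @param samples training data frame (see [build_cube()]).
#' @param test_ids integer row indices of the held-out samples (may be
#'   empty).
#' @param bins_per_cue,min_count passed to [build_cube()].
#' @return list with `cube` (trained without the test rows) and `estimates`
#'   (data frame from [estimate_tilt()] for the test rows).
#' @export
holdout_train_test <- function(samples, test_ids, bins_per_cue = 64L,
                               min_count = 10L) {
  stopifnot(is.data.frame(samples))
  test_ids <- as.integer(test_ids)
  if (length(test_ids) > 0 &&
      (min(test_ids) < 1 || max(test_ids) > nrow(samples))) {
    err("test_ids out of range")
  }
  train <- if (length(test_ids)) samples[-test_ids, , drop = FALSE] else samples
  if (nrow(train) < 1) err("empty training partition")
  cube <- build_cube(train, bins_per_cue, min_count)
  estimates <- if (length(test_ids)) {
    estimate_tilt(cube, samples[test_ids, , drop = FALSE])
  } else {
    data.frame(estimate = numeric(0), fallback = logical(0),
               cell_count = integer(0))
  }
  list(cube = cube, estimates = estimates)
}

#' Mean circular distance between adjacent populated cells
#'
#' Smoothness diagnostic: averages the absolute circular (axial) distance
#' between estimates of face-adjacent cells that both meet `min_count`.
#'
#' @param cube an estimate cube.
#' @return mean adjacent-cell distance in degrees (`NA` if no adjacent
#'   populated pairs).
#' @export
cube_smoothness <- function(cube) {
  stopifnot(inherits(cube, "estimate_cube"))
  B <- cube$bins_per_cue
  pop <- which(cube$cell_count >= cube$min_count)
  if (!length(pop)) return(NA_real_)
  zero <- pop - 1L
  i <- zero %% B
  j <- (zero %/% B) %% B
  k <- zero %/% (B * B)
  dists <- c()
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
    okrng <- i2 < B & j2 < B & k2 < B
    nb <- i2[okrng] + B * j2[okrng] + B * B * k2[okrng] + 1L
    both <- cube$cell_count[nb] >= cube$min_count
    if (any(both)) {
      a <- cube$cell_estimate[pop[okrng][both]]
      b <- cube$cell_estimate[nb[both]]
      dists <- c(dists, abs(circ_error(a, b, period = 180)))
    }
  }
  if (!length(dists)) NA_real_ else mean(dists)
}
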