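# Evaluation pipeline: trial records, per-tilt summary statistics,
# conditional distributions, bias correction, trial-by-trial correlation,
# variance explained, covariate effects and Monte Carlo experiment repeats.
# All tilt analyses run on the unsigned (period-180) domain with 24 bins of
# 7.5 degrees by default.

#' Assemble trial records
#'
#' One row per stimulus presentation, carrying groundtruth, estimate, the
#' wrapped signed error, and optional stimulus covariates.
#'
#' @param truth unsigned groundtruth tilts, degrees `[0, 180)`.
#' @param estimate unsigned tilt estimates, degrees `[0, 180)`.
#' @param stimulus_id stimulus identifiers (default sequential).
#' @param slant,distance,contrast,tilt_var optional per-trial covariates.
#' @param observer observer label.
#' @return data frame of class `trial_records` with columns `stimulus_id`,
#'   `truth`, `estimate`, `error`, plus covariates.
#' @export
make_trials <- function(truth, estimate, stimulus_id = seq_along(truth),
                        slant = NA_real_, distance = NA_real_,
                        contrast = NA_real_, tilt_var = NA_real_,
                        observer = "model") {
  stopifnot(length(truth) == length(estimate))
  df <- data.frame(stimulus_id = stimulus_id,
                   truth = truth %% 180, estimate = estimate %% 180,
                   error = circ_error(estimate, truth, period = 180),
                   slant = slant, distance = distance, contrast = contrast,
                   tilt_var = tilt_var, observer = observer,
                   stringsAsFactors = FALSE)
  class(df) <- c("trial_records", class(df))
  df
}

# half-open bin index over [0, period)
tilt_bin_index <- function(angle, n_bins, period = 180) {
  idx <- floor((angle %% period) / period * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

#' Summary statistics by groundtruth tilt bin
#'
#' Bins trials by groundtruth tilt and reports, per bin: presented and
#' estimated counts, the estimate count ratio, the circular mean and
#' circular variance of the estimates, and the mean bias (circular distance
#' from bin centre to mean estimate).
#'
#' @param trials a [make_trials()] data frame.
#' @param n_bins number of bins over `[0, period)` (default 24).
#' @param period domain period, degrees.
#' @return data frame with one row per bin; empty bins have `NA` statistics
#'   and `empty = TRUE`.
#' @export
summarize_by_tilt <- function(trials, n_bins = 24L, period = 180) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  width <- period / n_bins
  centers <- (seq_len(n_bins) - 0.5) * width
  tb <- tilt_bin_index(trials$truth, n_bins, period)
  eb <- tilt_bin_index(trials$estimate, n_bins, period)
  n_est <- tabulate(eb, nbins = n_bins)
  out <- data.frame(bin = seq_len(n_bins), center = centers,
                    n_presented = tabulate(tb, nbins = n_bins),
                    n_estimated = n_est,
                    count_ratio = NA_real_, est_mean = NA_real_,
                    est_var = NA_real_, bias = NA_real_, empty = FALSE)
  out$count_ratio <- ifelse(out$n_presented > 0,
                            out$n_estimated / out$n_presented, NA_real_)
  for (b in seq_len(n_bins)) {
    e <- trials$estimate[tb == b]
    if (!length(e)) { out$empty[b] <- TRUE; next }
    s <- circ_mean_var(e, period = period)
    out$est_mean[b] <- s$mean
    out$est_var[b] <- s$variance
    if (s$mean_defined) {
      out$bias[b] <- circ_error(s$mean, centers[b], period = period)
    }
  }
  out
}

#' Conditional error distribution for one groundtruth-tilt bin
#'
#' Normalized histogram of the signed errors of trials whose groundtruth
#' tilt falls in the given bin.
#'
#' @param trials trial records.
#' @param truth_bin 1-based index of the groundtruth bin.
#' @param n_bins number of groundtruth bins (default 24).
#' @param n_error_bins number of error histogram bins over
#'   `(-period/2, period/2]`.
#' @param period domain period, degrees.
#' @return data frame with columns `mid` (bin midpoints, degrees) and `p`
#'   (probabilities summing to 1).
#' @export
conditional_error_dist <- function(trials, truth_bin, n_bins = 24L,
                                   n_error_bins = 24L, period = 180) {
  tb <- tilt_bin_index(trials$truth, n_bins, period)
  e <- trials$error[tb == truth_bin]
  if (!length(e)) err(sprintf("groundtruth bin %d is empty", truth_bin))
  brk <- seq(-period / 2, period / 2, length.out = n_error_bins + 1)
  cnt <- tabulate(findInterval(pmin(pmax(e, -period / 2 + 1e-12), period / 2),
                               brk, rightmost.closed = TRUE,
                               left.open = TRUE),
                  nbins = n_error_bins)
  data.frame(mid = (brk[-1] + brk[-length(brk)]) / 2, p = cnt / sum(cnt))
}

#' Conditional groundtruth distribution for one estimate bin
#'
#' Normalized histogram of groundtruth tilts among trials whose estimate
#' falls in the given bin.
#'
#' @param trials trial records.
#' @param estimate_bin 1-based index of the estimate bin.
#' @param n_bins number of bins over the tilt domain.
#' @param period domain period, degrees.
#' @return data frame with columns `mid` and `p`.
#' @export
conditional_truth_dist <- function(trials, estimate_bin, n_bins = 24L,
                                   period = 180) {
  eb <- tilt_bin_index(trials$estimate, n_bins, period)
  t_in <- trials$truth[eb == estimate_bin]
  if (!length(t_in)) err(sprintf("estimate bin %d is empty", estimate_bin))
  tb <- tilt_bin_index(t_in, n_bins, period)
  width <- period / n_bins
  data.frame(mid = (seq_len(n_bins) - 0.5) * width,
             p = tabulate(tb, nbins = n_bins) / length(t_in))
}

#' Bias-corrected errors
#'
#' Subtracts, from each trial's error, the circular mean error of its
#' groundtruth-tilt bin (the observer's bias at that tilt), re-wrapping the
#' result: `e* = e - E[e | truth bin]`.  By construction the per-bin
#' circular mean of `e*` is zero.  Bins with fewer than two trials get zero
#' bias with a warning.
#'
#' @param trials trial records.
#' @param n_bins number of groundtruth bins.
#' @param period domain period, degrees.
#' @return `trials` with added columns `bias` (per-bin mean error) and
#'   `error_bc`.
#' @export
bias_correct <- function(trials, n_bins = 24L, period = 180) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  tb <- tilt_bin_index(trials$truth, n_bins, period)
  bias <- numeric(nrow(trials))
  for (b in unique(tb)) {
    m <- tb == b
    if (sum(m) < 2) {
      warning(sprintf("bin %d has < 2 trials; bias set to 0", b))
      next
    }
    s <- circ_mean_var(trials$error[m], period = period)
    if (s$mean_defined) {
      bias[m] <- circ_error(s$mean, 0, period = period)
    }
  }
  trials$bias <- bias
  trials$error_bc <- circ_error(trials$error, bias, period = period)
  trials
}

#' Trial-by-trial error correlation between two observers
#'
#' Matches the two trial sets by `stimulus_id` and computes the circular
#' (Fisher--Lee) correlation of their raw or bias-corrected errors with a
#' percentile bootstrap confidence interval.
#'
#' @param trials_a,trials_b trial records sharing the same stimulus ids.
#' @param corrected use bias-corrected errors (computed here if absent).
#' @param n_boot,level,seed passed to [bootstrap_ci()].
#' @param n_bins groundtruth bins used for bias correction.
#' @return list with `coefficient`, `ci` (length-2), `n`.
#' @export
trial_corr <- function(trials_a, trials_b, corrected = FALSE,
                       n_boot = 1000, level = 0.95, seed = 1, n_bins = 24L) {
  stopifnot(is.data.frame(trials_a), is.data.frame(trials_b))
  if (!setequal(trials_a$stimulus_id, trials_b$stimulus_id) ||
      nrow(trials_a) != nrow(trials_b)) {
    err("trial sets do not share the same stimulus ids")
  }
  if (corrected) {
    if (is.null(trials_a$error_bc)) trials_a <- bias_correct(trials_a, n_bins)
    if (is.null(trials_b$error_bc)) trials_b <- bias_correct(trials_b, n_bins)
    col <- "error_bc"
  } else {
    col <- "error"
  }
  b_ord <- trials_b[match(trials_a$stimulus_id, trials_b$stimulus_id), ]
  pairs <- data.frame(ea = trials_a[[col]], eb = b_ord[[col]])
  rho <- circ_corr(pairs$ea, pairs$eb, period = 180)
  ci <- bootstrap_ci(function(d) circ_corr(d$ea, d$eb, period = 180),
                     pairs, n_boot = n_boot, level = level, seed = seed)
  list(coefficient = rho, ci = ci, n = nrow(pairs))
}

#' Proportion of variance explained
#'
#' `R^2 = 1 - SS_res / SS_tot` between a reference statistic vector and a
#' model's prediction of it.  For angular statistics the residuals are
#' circular distances and the total sum of squares is taken about the
#' circular mean of the reference; for counts/variances ordinary
#' differences are used.  May be negative.
#'
#' @param reference,model equal-length numeric vectors.
#' @param angular treat the vectors as angles.
#' @param period domain period when `angular`.
#' @return scalar R^2 (`NA` with a warning when the reference has zero
#'   variance).
#' @export
variance_explained <- function(reference, model, angular = FALSE, period = 180) {
  stopifnot(length(reference) == length(model))
  ok <- is.finite(reference) & is.finite(model)
  reference <- reference[ok]; model <- model[ok]
  if (angular) {
    res <- circ_error(model, reference, period = period)
    ctr <- circ_mean_var(reference, period = period)
    if (!ctr$mean_defined) {
      warning("variance_explained undefined: reference circular mean undefined")
      return(NA_real_)
    }
    tot <- circ_error(reference, ctr$mean, period = period)
  } else {
    res <- model - reference
    tot <- reference - mean(reference)
  }
  sst <- sum(tot^2)
  if (sst <= 1e-12) {
    warning("variance_explained undefined: zero total variance")
    return(NA_real_)
  }
  1 - sum(res^2) / sst
}

#' Effect of a stimulus covariate on absolute error
#'
#' Bins trials by a covariate (fixed-width or equal-count quantile bins),
#' reports the mean absolute circular error per bin, and fits an ordinary
#' least-squares line through the bin means.
#'
#' @param trials trial records containing the covariate column.
#' @param covariate one of `"slant"`, `"distance"`, `"tilt_var"`,
#'   `"contrast"`.
#' @param binning `"quantile"` (equal counts, ties broken by stable order)
#'   or `"fixed"` (equal width).
#' @param n_bins number of covariate bins (default 5 quintiles).
#' @return list with `bins` (data frame: `center`, `n`, `mean_abs_error`),
#'   `slope`, `intercept`.
#' @export
covariate_effect <- function(trials, covariate = c("slant", "distance",
                                                   "tilt_var", "contrast"),
                             binning = c("quantile", "fixed"), n_bins = 5L) {
  covariate <- match.arg(covariate)
  binning <- match.arg(binning)
  if (n_bins < 2) err("need at least 2 covariate bins")
  x <- trials[[covariate]]
  if (is.null(x) || all(is.na(x))) err(sprintf("covariate '%s' absent", covariate))
  ok <- is.finite(x)
  x <- x[ok]
  ae <- abs(trials$error[ok])
  if (binning == "quantile") {
    ord <- order(x)  # stable: ties keep original order
    grp <- integer(length(x))
    grp[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
    grp[grp > n_bins] <- n_bins
  } else {
    brk <- seq(min(x), max(x), length.out = n_bins + 1)
    grp <- findInterval(x, brk, rightmost.closed = TRUE)
    grp[grp > n_bins] <- n_bins
  }
  bins <- data.frame(
    bin = seq_len(n_bins),
    center = vapply(seq_len(n_bins), function(b)
      if (any(grp == b)) stats::median(x[grp == b]) else NA_real_, numeric(1)),
    n = tabulate(grp, nbins = n_bins),
    mean_abs_error = vapply(seq_len(n_bins), function(b)
      if (any(grp == b)) mean(ae[grp == b]) else NA_real_, numeric(1)))
  use <- is.finite(bins$center) & is.finite(bins$mean_abs_error)
  fit <- stats::lm(mean_abs_error ~ center, data = bins[use, ])
  list(bins = bins, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Split trials into cardinal and oblique groundtruth tilts
#'
#' Cardinal: groundtruth within 22.5 degrees of 0 or 90 (half-open windows,
#' axial); oblique: within 22.5 degrees of 45 or 135.  The two subsets are
#' disjoint and exhaustive.
#'
#' @param trials trial records.
#' @return list with data frames `cardinal` and `oblique`.
#' @export
cardinal_oblique_split <- function(trials) {
  stopifnot(is.data.frame(trials))
  d0 <- abs(circ_error(trials$truth, 0, period = 180))
  d90 <- abs(circ_error(trials$truth, 90, period = 180))
  is_card <- pmin(d0, d90) < 22.5
  list(cardinal = trials[is_card, , drop = FALSE],
       oblique = trials[!is_card, , drop = FALSE])
}

#' Monte Carlo repeats of the experiment
#'
#' Re-runs a trial generator `n_repeats` times with derived seeds, computes
#' the per-tilt summary statistics of each repeat, and returns percentile
#' confidence bands across repeats for each statistic and bin.  Failed
#' repeats are skipped and counted.
#'
#' @param generate_trials function of a single integer seed returning a
#'   trial-records data frame.
#' @param n_repeats number of simulated repeats (default 1000).
#' @param level band level (default 0.95).
#' @param seed master seed; repeat seeds are derived deterministically.
#' @param n_bins,period passed to [summarize_by_tilt()].
#' @return list with `bands` (data frame: bin, center, and lo/hi for
#'   `count_ratio`, `est_mean`, `est_var`), `n_repeats_used`, `n_failed`.
#' @export
monte_carlo_experiment <- function(generate_trials, n_repeats = 1000,
                                   level = 0.95, seed = 1, n_bins = 24L,
                                   period = 180) {
  stopifnot(is.function(generate_trials), n_repeats >= 2)
  seeds <- vapply(seq_len(n_repeats), function(i) sub_seed(seed, i), integer(1))
  stats_list <- vector("list", n_repeats)
  n_failed <- 0L
  for (i in seq_len(n_repeats)) {
    s <- tryCatch(summarize_by_tilt(generate_trials(seeds[i]), n_bins, period),
                  error = function(e) NULL)
    if (is.null(s)) n_failed <- n_failed + 1L else stats_list[[i]] <- s
  }
  stats_list <- Filter(Negate(is.null), stats_list)
  if (!length(stats_list)) err("all Monte Carlo repeats failed")
  alpha <- (1 - level) / 2
  grab <- function(col) {
    m <- vapply(stats_list, function(s) s[[col]], numeric(n_bins))
    m <- matrix(m, nrow = n_bins)
    t(apply(m, 1, function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) c(NA_real_, NA_real_) else
        stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    }))
  }
  cr <- grab("count_ratio"); em <- grab("est_mean"); ev <- grab("est_var")
  bands <- data.frame(bin = seq_len(n_bins),
                      center = (seq_len(n_bins) - 0.5) * period / n_bins,
                      count_ratio_lo = cr[, 1], count_ratio_hi = cr[, 2],
                      est_mean_lo = em[, 1], est_mean_hi = em[, 2],
                      est_var_lo = ev[, 1], est_var_hi = ev[, 2])
  list(bands = bands, n_repeats_used = length(stats_list), n_failed = n_failed)
}
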