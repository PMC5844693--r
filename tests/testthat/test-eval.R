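# evaluation pipeline: summaries, conditional distributions, bias
# correction, correlations, covariate effects, Monte Carlo bands

identity_trials <- function(n = 960, seed = 2) {
  with_seed_test(seed, {
    tt <- runif(n, 0, 180)
    make_trials(tt, tt)
  })
}

test_that("summarize_by_tilt handles identity and uniform observers", {
  tr <- identity_trials()
  sm <- summarize_by_tilt(tr, 24)
  expect_false(any(sm$empty))
  expect_equal(sum(sm$n_presented), nrow(tr))
  expect_true(all(abs(circ_error(sm$est_mean, sm$center, 180)) < 7.5 / 2 + 1e-9))
  expect_true(all(sm$est_var < 0.02))
  expect_true(all(abs(sm$count_ratio - 1) < 0.35))  # identity keeps bins equal
  # uniform random estimator: per-bin variance near 1
  with_seed_test(5, {
    tru <- make_trials(runif(10000, 0, 180), runif(10000, 0, 180))
  })
  smu <- summarize_by_tilt(tru, 24)
  expect_true(all(smu$est_var > 0.9))
})

test_that("conditional distributions are normalized with correct modes", {
  tr <- identity_trials()
  h <- conditional_error_dist(tr, truth_bin = 5, n_bins = 24, n_error_bins = 25)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(h$mid[which.max(h$p)], 0, tolerance = 7.2 / 2)
  ht <- conditional_truth_dist(tr, estimate_bin = 5, n_bins = 24)
  expect_equal(sum(ht$p), 1, tolerance = 1e-12)
  expect_identical(which.max(ht$p), 5L)
  # cardinal-snapping observer at truth near 60: errors peak at -60 and +30
  with_seed_test(6, {
    tt <- runif(4000, 56.25, 63.75)   # the tau = 60 bin
    snap <- ifelse(runif(4000) < 0.5, 0, 90)
    trs <- make_trials(tt, snap)
  })
  hs <- conditional_error_dist(trs, truth_bin = 9, n_bins = 24,
                               n_error_bins = 24)
  top2 <- order(hs$p, decreasing = TRUE)[1:2]
  expect_setequal(round(hs$mid[top2] / 7.5) * 7.5, c(-60, 30))
  expect_error(conditional_error_dist(identity_trials(10), 24, 24),
               class = "tiltnorm_error")
})

test_that("bias_correct removes per-bin bias exactly", {
  tr <- identity_trials()
  # unbiased observer: e* = e
  bc <- bias_correct(tr, 24)
  expect_lt(max(abs(bc$error_bc - bc$error)), 7.5)
  # constant +10 degree bias: e* collapses to zero
  trb <- make_trials(tr$truth, (tr$truth + 10) %% 180)
  bcb <- bias_correct(trb, 24)
  expect_lt(max(abs(bcb$error_bc)), 1e-9)
  # per-bin circular mean of e* vanishes for arbitrary observers
  with_seed_test(9, {
    noisy <- make_trials(tr$truth,
                         (tr$truth + 20 * sin(tr$truth / 30) + rnorm(nrow(tr), 0, 15)) %% 180)
  })
  bcn <- bias_correct(noisy, 24)
  tb <- floor(bcn$truth / 7.5) + 1
  for (b in unique(tb)) {
    m <- circ_mean_var(bcn$error_bc[tb == b], 180)
    if (m$mean_defined) {
      expect_lt(abs(circ_error(m$mean, 0, 180)), 1e-6)
    }
  }
})

test_that("trial_corr matches stimuli and orders related observers", {
  tr <- identity_trials(600)
  obs_a <- tr
  obs_a$estimate <- synthetic_observer(tr$truth, synthetic_observer_spec(3), 11)
  obs_a <- make_trials(tr$truth, obs_a$estimate, stimulus_id = tr$stimulus_id)
  self <- trial_corr(obs_a, obs_a, n_boot = 200, seed = 1)
  expect_equal(self$coefficient, 1, tolerance = 1e-9)
  bad <- obs_a
  bad$stimulus_id <- bad$stimulus_id + 100000
  expect_error(trial_corr(obs_a, bad), class = "tiltnorm_error")
})

test_that("variance_explained matches definition and a worked table", {
  ref <- c(3, 7, 11, 2)
  expect_equal(variance_explained(ref, ref), 1)
  expect_equal(variance_explained(ref, rep(mean(ref), 4)), 0)
  # angular worked example, computed from the definition by hand:
  # ref {0, 60} (axial): circular mean 30, SStot = 30^2 + 30^2 = 1800;
  # model {10, 50}: residuals 10, -10, SSres = 200; R^2 = 1 - 200/1800
  expect_equal(variance_explained(c(0, 60), c(10, 50), angular = TRUE),
               1 - 200 / 1800, tolerance = 1e-9)
  expect_warning(v <- variance_explained(c(5, 5), c(1, 2)), "zero total")
  expect_true(is.na(v))
})

test_that("covariate_effect bins equally and fits slopes", {
  tr <- identity_trials(100)
  tr$slant <- seq(31, 70, length.out = 100)
  ce <- covariate_effect(tr, "slant", "quantile", 5)
  expect_true(all(ce$bins$n == 20))
  expect_equal(ce$bins$mean_abs_error, rep(0, 5))
  expect_equal(ce$slope, 0)
  expect_error(covariate_effect(tr, "slant", n_bins = 1),
               class = "tiltnorm_error")
  expect_error(covariate_effect(identity_trials(10), "tilt_var"),
               class = "tiltnorm_error")
})

test_that("cardinal/oblique split partitions by the 22.5-degree windows", {
  tr <- make_trials(c(60, 10, 0, 45, 112.49, 112.5, 157.5), rep(0, 7))
  sp <- cardinal_oblique_split(tr)
  expect_equal(nrow(sp$cardinal) + nrow(sp$oblique), 7L)
  expect_true(60 %in% sp$oblique$truth)
  expect_true(10 %in% sp$cardinal$truth)
  expect_true(112.49 %in% sp$cardinal$truth)
  expect_true(112.5 %in% sp$oblique$truth)
  expect_true(157.5 %in% sp$oblique$truth)
})

test_that("monte_carlo_experiment is deterministic with sane defaults", {
  expect_equal(eval(formals(monte_carlo_experiment)$n_repeats), 1000)
  expect_equal(eval(formals(monte_carlo_experiment)$level), 0.95)
  # seed-independent generator -> identical repeats -> zero-width bands
  fixed <- identity_trials(480)
  mc <- monte_carlo_experiment(function(s) fixed, n_repeats = 3, seed = 5)
  expect_equal(mc$n_repeats_used, 3L)
  expect_equal(mc$bands$est_var_lo, mc$bands$est_var_hi, tolerance = 1e-12)
  # stochastic generator: bands cover the generating process most of the time
  gen <- function(s) {
    with_seed_test(s, {
      tt <- runif(400, 0, 180)
      make_trials(tt, synthetic_observer(tt, synthetic_observer_spec(8), s))
    })
  }
  mc2 <- monte_carlo_experiment(gen, n_repeats = 60, seed = 7)
  pop <- summarize_by_tilt(gen(987654), 24)  # an independent realization
  inside <- mean(pop$est_var >= mc2$bands$est_var_lo &
                   pop$est_var <= mc2$bands$est_var_hi, na.rm = TRUE)
  expect_gt(inside, 0.75)
})
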