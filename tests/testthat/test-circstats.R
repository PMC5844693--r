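# circular statistics: means/variances, signed errors, Fisher-Lee
# correlation, bootstrap intervals

test_that("circ_mean_var matches closed forms on both periods", {
  s <- circ_mean_var(c(90, 90, 90), period = 180)
  expect_equal(s$mean, 90)
  expect_equal(s$variance, 0, tolerance = 1e-12)
  expect_equal(s$n, 3L)

  s <- circ_mean_var(c(0, 90), period = 360)
  expect_equal(s$mean, 45)
  expect_equal(s$variance, 1 - sqrt(2) / 2, tolerance = 1e-12)

  # axial wrap: 10 and 170 are 20 degrees apart across the 0/180 seam
  s <- circ_mean_var(c(10, 170), period = 180)
  expect_equal(s$mean, 0, tolerance = 1e-9)

  # antipodal after doubling: mean undefined, variance 1
  s <- circ_mean_var(c(0, 90), period = 180)
  expect_false(s$mean_defined)
  expect_true(is.na(s$mean))
  expect_equal(s$variance, 1, tolerance = 1e-12)
})

test_that("circular mean equals the brute-force MMSE minimizer on
           concentrated samples", {
  # the doubled-angle circular mean and the squared-circular-distance
  # minimizer coincide for clustered angles (they diverge for widely
  # dispersed samples, where sin(2e) and linear influence differ)
  set.seed(11)
  for (i in 1:8) {
    tilts <- (runif(1, 0, 180) + 8 * rnorm(12)) %% 180
    got <- circ_mean_var(tilts, period = 180)$mean
    want <- brute_force_circ_mmse(tilts)
    expect_lt(abs(circ_error(got, want, 180)), 0.5)
  }
})

test_that("rotation shifts the mean and leaves the variance unchanged", {
  set.seed(4)
  a <- runif(40, 0, 180)
  base <- circ_mean_var(a, 180)
  for (shift in c(13, 90, 171)) {
    s <- circ_mean_var((a + shift) %% 180, 180)
    expect_equal(circ_error(s$mean, (base$mean + shift) %% 180, 180), 0,
                 tolerance = 1e-9)
    expect_equal(s$variance, base$variance, tolerance = 1e-12)
  }
})

test_that("axial statistics equal doubled-angle statistics", {
  set.seed(5)
  a <- runif(50, 0, 180)
  ax <- circ_mean_var(a, period = 180)
  db <- circ_mean_var(2 * a, period = 360)
  expect_equal(ax$variance, db$variance, tolerance = 1e-12)
  expect_equal(ax$mean, (db$mean / 2) %% 180, tolerance = 1e-9)
})

test_that("circ_error wraps, composes, and matches the worked tilt example", {
  expect_equal(circ_error(60, 60, 180), 0)
  # estimating 0 or 90 when truth is 60 gives errors -60 and +30
  expect_equal(circ_error(0, 60, 180), -60)
  expect_equal(circ_error(90, 60, 180), 30)
  # boundary fixed at +period/2
  expect_equal(circ_error(90, 0, 180), 90)
  set.seed(6)
  a <- runif(50, 0, 180); b <- runif(50, 0, 180)
  expect_equal(circ_error(a, b, 180), -circ_error(b, a, 180),
               tolerance = 1e-12)  # no boundary hits for continuous draws
  expect_equal((b + circ_error(a, b, 180)) %% 180, a %% 180,
               tolerance = 1e-9)
})

test_that("circ_corr: self-correlation, rotation invariance, null level", {
  set.seed(7)
  a <- runif(200, 0, 180)
  expect_equal(circ_corr(a, a, 180), 1, tolerance = 1e-9)
  expect_equal(circ_corr(a, (a + 57) %% 180, 180), 1, tolerance = 1e-9)
  # brute-force pairwise formula agreement on a small sample
  sml <- a[1:25]
  b <- (sml + 20 * rnorm(25)) %% 180
  num <- 0; da <- 0; db <- 0
  for (i in 1:24) for (j in (i + 1):25) {
    sa <- sin(2 * pi / 180 * (sml[i] - sml[j]))
    sb <- sin(2 * pi / 180 * (b[i] - b[j]))
    num <- num + sa * sb; da <- da + sa^2; db <- db + sb^2
  }
  expect_equal(circ_corr(sml, b, 180), num / sqrt(da * db), tolerance = 1e-9)
  # independent sequences: |rho| small in at least 95% of runs
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    x <- runif(1000, 0, 180); y <- runif(1000, 0, 180)
    if (abs(circ_corr(x, y, 180)) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_warning(r <- circ_corr(rep(45, 10), runif(10, 0, 180), 180),
                 "constant")
  expect_true(is.na(r))
})

test_that("bootstrap_ci is seed-deterministic with sane defaults", {
  expect_equal(eval(formals(bootstrap_ci)$n_boot), 1000)
  expect_equal(eval(formals(bootstrap_ci)$level), 0.95)
  x <- rnorm(50)
  ci1 <- bootstrap_ci(mean, x, n_boot = 200, seed = 3)
  ci2 <- bootstrap_ci(mean, x, n_boot = 200, seed = 3)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  # constant statistic -> zero-width interval
  ci <- bootstrap_ci(function(d) 1.5, x, n_boot = 100, seed = 1)
  expect_equal(as.numeric(ci), c(1.5, 1.5))
})
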