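test_that("Savitzky-Golay detrending annihilates low-order drift", {
  tr <- 2
  t_s <- seq_len(300) * tr
  # quadratic drift: removed exactly (order-2 filter fits it perfectly)
  drift <- 3 + 0.01 * t_s + 2e-4 * t_s^2
  run <- bold_run(cbind(drift, rep(5, 300)), tr = tr)
  out <- detrend_savgol(run)
  expect_lt(max(abs(out$data)), 1e-8)
  # high-frequency sinusoid riding on the drift survives detrending
  sine <- sin(2 * pi * t_s / 30)
  run2 <- bold_run(matrix(drift + sine), tr = tr)
  out2 <- detrend_savgol(run2)
  interior <- 40:260
  expect_gt(cor(out2$data[interior, 1], sine[interior]), 0.99)
  expect_error(detrend_savgol(bold_run(matrix(rnorm(20)), tr = 2)),
               "shorter")
})

test_that("trimming removes the requested volumes from both ends", {
  run <- bold_run(matrix(seq_len(300), ncol = 1), tr = 2)
  expect_equal(nrow(trim_run(run)$data), 280)
  expect_identical(trim_run(run, 0), run)
  short <- bold_run(matrix(seq_len(21), ncol = 1), tr = 2)
  expect_equal(nrow(trim_run(short, 10)$data), 1)
  expect_equal(trim_run(short, 10)$data[1, 1], 11)
  expect_error(trim_run(short, 11), "too short")
})

test_that("z-scoring standardizes voxels and is idempotent", {
  run <- bold_run(matrix(rnorm(200 * 5, mean = 3, sd = 4), 200), tr = 2)
  z <- zscore_voxels(run)
  expect_true(all(abs(colMeans(z$data)) < 1e-9))
  expect_true(all(abs(apply(z$data, 2, var) - 1) < 1e-9))
  expect_equal(zscore_voxels(z)$data, z$data, tolerance = 1e-9)
  # constant voxel: zeroed with a warning, indexing preserved
  runc <- bold_run(cbind(rnorm(100), rep(7, 100)), tr = 2)
  expect_warning(zc <- zscore_voxels(runc), "constant")
  expect_true(all(zc$data[, 2] == 0))
  expect_equal(ncol(zc$data), 2)
})

test_that("explainable variance is 1 for identical repeats and 0 for noise", {
  x <- matrix(rnorm(500 * 4), 500)
  r <- bold_run(x, tr = 2)
  expect_equal(explainable_variance(list(r, r, r)), rep(1, 4))
  # pure noise centers on zero after bias correction (Monte-Carlo)
  evs <- vapply(1:100, function(s) {
    set.seed(s)
    reps <- lapply(1:5, function(i) matrix(rnorm(200 * 3), 200))
    mean(explainable_variance(reps))
  }, numeric(1))
  expect_lt(abs(mean(evs)), 0.01)
  expect_error(explainable_variance(list(r)), "at least 2")
  expect_error(explainable_variance(list(r, bold_run(x[1:10, ], tr = 2))),
               "shape")
})

test_that("explainable variance recovers the generating signal fraction", {
  set.seed(11)
  n <- 2000; v <- 30
  sig <- matrix(rnorm(n * v), n)
  make_reps <- function(noise_sd) {
    lapply(1:5, function(i) sig + noise_sd * matrix(rnorm(n * v), n))
  }
  for (ev_true in c(0.3, 0.7)) {
    reps <- make_reps(sqrt((1 - ev_true) / ev_true))
    expect_equal(mean(explainable_variance(reps)), ev_true, tolerance = 0.03)
  }
})

test_that("explainable variance is affine-invariant and consistent", {
  set.seed(12)
  sig <- matrix(rnorm(800 * 6), 800)
  reps <- lapply(1:4, function(i) sig + matrix(rnorm(800 * 6), 800))
  ev <- explainable_variance(reps)
  scaled <- lapply(reps, function(r) sweep(sweep(r, 2, 1:6, "*"), 2, -3:2, "+"))
  expect_equal(explainable_variance(scaled), ev, tolerance = 1e-10)
  # absolute estimation error shrinks with the number of TRs
  err_at <- function(n_tr) {
    errs <- vapply(1:30, function(s) {
      set.seed(s)
      sig <- matrix(rnorm(n_tr * 4), n_tr)
      reps <- lapply(1:4, function(i) sig + matrix(rnorm(n_tr * 4), n_tr))
      mean(abs(explainable_variance(reps) - 0.5))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(5000), err_at(500))
})

test_that("language mask applies an inclusive threshold", {
  m <- language_mask(c(0.04, 0.05, 0.5))
  expect_equal(m$flags, c(FALSE, TRUE, TRUE))
  expect_true(all(language_mask(c(0, 0.2, 0.9), threshold = 0)$flags))
  expect_false(language_mask(c(NaN, 0.2), threshold = 0.05)$flags[1])
  expect_error(language_mask(c(0.1), threshold = 2), "threshold")
})

test_that("all-noise data yields a masked fraction near the estimator's null rate", {
  set.seed(13)
  reps <- lapply(1:5, function(i) matrix(rnorm(400 * 200), 400))
  frac <- mean(language_mask(explainable_variance(reps))$flags)
  # 5% cut on a null EV distribution: only a small tail passes
  expect_lt(frac, 0.1)
})

test_that("the preprocess chain is idempotent at the z-scoring stage", {
  set.seed(14)
  raw <- bold_run(matrix(rnorm(300 * 4), 300) + outer(1:300, rep(0.01, 4)),
                  tr = 2)
  once <- zscore_voxels(trim_run(detrend_savgol(raw)))
  twice <- zscore_voxels(once)
  expect_equal(twice$data, once$data, tolerance = 1e-9)
})
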