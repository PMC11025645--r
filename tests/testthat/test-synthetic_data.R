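test_that("latent factors are standardized, seeded, and seed-sensitive", {
  lf <- make_latent_factors(1000, 5, seed = 0)
  expect_equal(dim(lf$values), c(1000, 5))
  expect_true(all(abs(colMeans(lf$values)) < 1e-9))
  expect_true(all(abs(apply(lf$values, 2, var) - 1) < 1e-9))
  expect_identical(lf$values, make_latent_factors(1000, 5, seed = 0)$values)
  expect_false(identical(lf$values, make_latent_factors(1000, 5, seed = 1)$values))
  expect_error(make_latent_factors(0, 5, seed = 1), "positive")
  expect_error(make_latent_factors(4, 5, seed = 1), "exceed")
})

test_that("representation family reflects factor usage and noise", {
  lf <- make_latent_factors(400, 5, seed = 2)
  fam <- make_representation_family(lf, list(
    all = list(dims = 8, used_factors = 1:5, noise_sigma = 0),
    none = list(dims = 8, used_factors = integer(0), noise_sigma = 1)),
    seed = 3)
  # noiseless all-factor representation has rank min(dims, k)
  expect_equal(qr(fam$all$values)$rank, 5)
  # zero-factor representation is pure noise: no linear relation to latent
  r2 <- summary(lm(fam$none$values[, 1] ~ lf$values))$r.squared
  expect_lt(r2, 0.05)
  expect_error(make_representation_family(lf, list(), seed = 1), "non-empty")
  expect_error(make_representation_family(
    lf, list(a = list(dims = 3, used_factors = 6, noise_sigma = 0)), seed = 1),
    "out of range")
})

test_that("representations sharing factors are mutually linearly predictable", {
  lf <- make_latent_factors(600, 4, seed = 5)
  fam <- make_representation_family(lf, list(
    a = list(dims = 6, used_factors = 1:4, noise_sigma = 0),
    b = list(dims = 6, used_factors = 1:4, noise_sigma = 0)), seed = 6)
  # regress one noiseless all-factor rep onto the other, both directions
  r2_ab <- 1 - mean((fam$b$values - oracle_ols_predict(
    fam$a$values, fam$b$values, fam$a$values))^2) / mean(scale(fam$b$values, scale = FALSE)^2)
  r2_ba <- 1 - mean((fam$a$values - oracle_ols_predict(
    fam$b$values, fam$a$values, fam$b$values))^2) / mean(scale(fam$a$values, scale = FALSE)^2)
  expect_gt(r2_ab, 0.999)
  expect_gt(r2_ba, 0.999)
})

test_that("broader factor coverage gives at least as much predictability", {
  lf <- make_latent_factors(600, 4, seed = 8)
  fam <- make_representation_family(lf, list(
    all = list(dims = 8, used_factors = 1:4, noise_sigma = 0),
    sub = list(dims = 8, used_factors = 1:2, noise_sigma = 0),
    other = list(dims = 8, used_factors = 2:4, noise_sigma = 0)), seed = 9)
  r2_of <- function(from, to) {
    1 - mean((to - oracle_ols_predict(from, to, from))^2) /
      mean(scale(to, scale = FALSE)^2)
  }
  for (tgt in names(fam)) {
    expect_gte(r2_of(fam$all$values, fam[[tgt]]$values) + 1e-9,
               r2_of(fam$sub$values, fam[[tgt]]$values))
  }
})

test_that("word stream entropy rate matches analytic values", {
  # deterministic cycle: zero entropy
  V <- 5
  P_cycle <- diag(V)[, c(2:V, 1)]
  expect_equal(markov_entropy_rate(P_cycle), 0)
  # uniform chain: log V
  P_unif <- matrix(1 / V, V, V)
  expect_equal(markov_entropy_rate(P_unif), log(V))
  # symmetric 2-state chain: analytic row entropy
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(markov_entropy_rate(P2), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
})

test_that("sampled streams match their recorded entropy rate", {
  st <- make_word_stream(50000, vocab = 30, concentration = 1, seed = 3)
  expect_true(all(diff(st$onsets) > 0))
  expect_true(all(st$offsets >= st$onsets))
  expect_true(all(abs(rowSums(st$transition_matrix) - 1) < 1e-9))
  expect_true(all(st$word_ids >= 1 & st$word_ids <= 30))
  # Monte-Carlo surprisal within 2% of the analytic rate at 50k words
  expect_equal(oracle_mc_surprisal(st), st$entropy_rate,
               tolerance = 0.02)
  expect_error(make_word_stream(1, 10, seed = 1), "n_words")
})

test_that("BOLD generation shares signal across repeats and scales noise", {
  X <- matrix(rnorm(5000 * 6), 5000)
  W <- matrix(rnorm(6 * 8), 6)
  # zero noise: repeats are bit-identical
  runs <- make_bold(X, W, noise_sigma = 0, n_repeats = 2, seed = 1)
  expect_identical(runs[[1]]$data, runs[[2]]$data)
  # zero weights: per-voxel sample variance matches noise_sigma^2
  sig <- c(0.5, 1, 2, rep(1, 5))
  runs <- make_bold(X, W * 0, noise_sigma = sig, n_repeats = 1, seed = 2)
  expect_equal(apply(runs[[1]]$data, 2, sd), sig, tolerance = 0.05)
  expect_error(make_bold(X, matrix(0, 5, 8), 1), "shape mismatch")
})

test_that("explainable variance of generated BOLD matches the design ratio", {
  # Monte-Carlo over seeds: EV estimate close to s^2 / (s^2 + n^2)
  X <- matrix(rnorm(700 * 5), 700)
  W <- matrix(rnorm(5 * 10), 5)
  sig_sd <- apply(X %*% W, 2, sd)
  W <- sweep(W, 2, sig_sd, "/")        # unit signal sd
  ev_target <- 1 / (1 + 1.5^2)
  evs <- vapply(1:50, function(s) {
    runs <- make_bold(X, W, noise_sigma = 1.5, n_repeats = 4, seed = s)
    mean(explainable_variance(runs))
  }, numeric(1))
  expect_equal(mean(evs), ev_target, tolerance = 0.02)
})

test_that("embedding tables are distinct-rowed and optionally orthonormal", {
  emb <- make_embedding_table(30, 16, seed = 1)
  expect_equal(dim(emb$vectors), c(30, 16))
  expect_equal(anyDuplicated(emb$vectors), 0)
  embo <- make_embedding_table(20, 24, seed = 2, orthonormal = TRUE)
  expect_equal(tcrossprod(embo$vectors), diag(20), tolerance = 1e-10)
  expect_error(make_embedding_table(30, 16, seed = 1, orthonormal = TRUE),
               "orthonormal")
})
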