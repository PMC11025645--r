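test_that("readout recovers an identity mapping and degrades to the mean", {
  set.seed(1)
  emb <- make_embedding_table(20, 12, seed = 2)
  st <- make_word_stream(400, 20, concentration = 1, seed = 3)
  n <- 400
  # representation rows literally equal the next word's embedding
  rep_next <- rbind(emb$vectors[st$word_ids[-1], ], rnorm(12))
  ro <- fit_next_word_readout(rep_next, st, emb)
  pred <- rep_next[-n, , drop = FALSE] %*% ro$weights +
    matrix(ro$intercept, n - 1, 12, byrow = TRUE)
  expect_lt(mean((pred - emb$vectors[st$word_ids[-1], ])^2), 1e-18)
  # pure-noise representation: predictions collapse to the grand mean
  noise_rep <- matrix(rnorm(n * 6), n)
  ro2 <- fit_next_word_readout(noise_rep, st, emb)
  pred2 <- noise_rep[-n, ] %*% ro2$weights +
    matrix(ro2$intercept, n - 1, 12, byrow = TRUE)
  grand <- colMeans(emb$vectors[st$word_ids[-1], ])
  expect_lt(mean((pred2 - matrix(grand, n - 1, 12, byrow = TRUE))^2),
            0.05 * mean(scale(emb$vectors[st$word_ids[-1], ], scale = FALSE)^2))
})

test_that("duplicated rows fit the same readout as a weighted fit", {
  set.seed(4)
  emb <- make_embedding_table(10, 8, seed = 5)
  st <- make_word_stream(60, 10, concentration = 1, seed = 6)
  X <- matrix(rnorm(60 * 4), 60)
  ro <- fit_next_word_readout(X, st, emb)
  # duplicating every (row, next-word-embedding) pair leaves the
  # least-squares solution unchanged; oracle fits the doubled pairs
  Xp <- X[-60, , drop = FALSE]
  Yp <- emb$vectors[st$word_ids[-1], , drop = FALSE]
  co <- stats::lm.fit(cbind(1, rbind(Xp, Xp)), rbind(Yp, Yp))$coefficients
  expect_equal(unname(ro$weights), unname(co[-1, , drop = FALSE]),
               tolerance = 1e-9)
  expect_equal(unname(ro$intercept), unname(co[1, ]), tolerance = 1e-9)
})

test_that("embedding-to-distribution is a proper temperature softmax", {
  emb <- make_embedding_table(3, 3, seed = 1, orthonormal = TRUE)
  # hand-computed three-term softmax
  pred <- c(1, 2, 0.5)
  logits <- as.vector(emb$vectors %*% pred) / 0.7
  by_hand <- exp(logits - max(logits))
  by_hand <- by_hand / sum(by_hand)
  expect_equal(embedding_to_distribution(pred, emb, temperature = 0.7),
               by_hand, tolerance = 1e-12)
  expect_equal(sum(embedding_to_distribution(rnorm(3), emb)), 1,
               tolerance = 1e-9)
  # zero prediction: uniform
  expect_equal(embedding_to_distribution(rep(0, 3), emb), rep(1 / 3, 3))
  # saturated prediction on an orthonormal row: probability -> 1
  p <- embedding_to_distribution(50 * emb$vectors[2, ], emb)
  expect_gt(p[2], 0.999)
  expect_error(embedding_to_distribution(c(NaN, 1, 1), emb), "finite")
  expect_error(embedding_to_distribution(c(1, 1, 1), emb, temperature = 0),
               "positive")
})

test_that("uniform predictions give perplexity equal to the vocabulary size", {
  emb <- make_embedding_table(100, 16, seed = 7)
  st <- make_word_stream(500, 100, concentration = 1, seed = 8)
  ro <- structure(list(weights = matrix(0, 5, 16), intercept = rep(0, 16)),
                  class = "next_word_readout")
  res <- perplexity(ro, matrix(rnorm(500 * 5), 500), st, emb)
  expect_equal(res$perplexity, 100, tolerance = 1e-9)
  expect_equal(res$perplexity, exp(res$mean_cross_entropy))
})

test_that("probability one on the truth gives perplexity one", {
  emb <- make_embedding_table(10, 10, seed = 9, orthonormal = TRUE)
  st <- make_word_stream(50, 10, concentration = 1, seed = 10)
  n <- 50
  # saturated predictions pointing exactly at the next word's embedding
  rep_next <- rbind(1e4 * emb$vectors[st$word_ids[-1], ], rnorm(10))
  ro <- structure(list(weights = diag(10), intercept = rep(0, 10)),
                  class = "next_word_readout")
  res <- perplexity(ro, rep_next, st, emb)
  expect_equal(res$perplexity, 1, tolerance = 1e-6)
})

test_that("perplexity is invariant to representation rescaling", {
  emb <- make_embedding_table(15, 10, seed = 11)
  st <- make_word_stream(800, 15, concentration = 1, seed = 12)
  X <- matrix(rnorm(800 * 6), 800)
  p1 <- nwp_perplexity(X, st, emb, temperature = 1)
  p2 <- nwp_perplexity(5 * X, st, emb, temperature = 1)
  expect_equal(p2$perplexity, p1$perplexity, tolerance = 1e-9)
})

test_that("a full-state Markov representation approaches the entropy bound", {
  st <- make_word_stream(70000, vocab = 50, concentration = 5, seed = 11)
  emb <- make_embedding_table(50, 50, seed = 12, orthonormal = TRUE)
  onehot <- diag(50)[st$word_ids, ]
  res <- nwp_perplexity(onehot, st, emb, train_frac = 0.64, val_frac = 0.07)
  bound <- exp(st$entropy_rate)
  expect_gt(res$perplexity, bound * 0.99)      # cannot beat the bound
  expect_lt(res$perplexity, bound * 1.05)      # within 5% with tuned softmax
})

test_that("perplexity improves monotonically with representation coverage", {
  st <- make_word_stream(8000, vocab = 30, concentration = 2, seed = 13)
  emb <- make_embedding_table(30, 36, seed = 14)
  lat <- latent_from_stream(st, 6, seed = 15)
  fam <- make_representation_family(lat, list(
    full = list(dims = 18, used_factors = 1:6, noise_sigma = 0.1),
    half = list(dims = 18, used_factors = 1:3, noise_sigma = 0.1),
    none = list(dims = 18, used_factors = integer(0), noise_sigma = 1)),
    seed = 16)
  ppl <- vapply(fam, function(f) {
    nwp_perplexity(f$values, st, emb)$perplexity
  }, numeric(1))
  expect_lt(ppl["full"], ppl["half"])
  expect_lt(ppl["half"], ppl["none"])
  # every proper predictor sits above the chain's entropy bound
  expect_true(all(ppl > exp(st$entropy_rate) * 0.99))
})
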