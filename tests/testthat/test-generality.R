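# Trainer settings that run SGD to convergence for oracle comparisons.
converged <- list(max_epochs = 8000, patience = 8000, min_delta = 0,
                  val_frac = 0)

test_that("the bottleneck encoder matches reduced-rank regression", {
  fx <- fixture_linear_target(n = 500, du = 40, dt = 30, r = 30, seed = 1)
  enc <- train_bottleneck_encoder(fx$U, fx$Tg, latent_dim = 20, seed = 3,
                                  max_epochs = converged$max_epochs,
                                  patience = converged$patience,
                                  min_delta = converged$min_delta,
                                  val_frac = converged$val_frac)
  mse_sgd <- mean((encoder_predict(enc, fx$U_eval) - fx$T_eval)^2)
  mse_rrr <- mean((oracle_rrr_predict(fx$U, fx$Tg, 20, fx$U_eval) -
                     fx$T_eval)^2)
  expect_lt(mse_sgd, 1.01 * mse_rrr)
})

test_that("a rank-limited exact linear target is reconstructed to ~zero error", {
  set.seed(2)
  U <- matrix(rnorm(500 * 30), 500)
  A <- matrix(rnorm(30 * 15), 30) / sqrt(30)   # rank 15 <= 20
  Tg <- (U %*% A) %*% (matrix(rnorm(15 * 24), 15) / sqrt(15))
  enc <- train_bottleneck_encoder(U, Tg, latent_dim = 20, seed = 3,
                                  max_epochs = 4000, patience = 4000,
                                  min_delta = 0, val_frac = 0)
  rel <- mean((encoder_predict(enc, U) - Tg)^2) / mean(scale(Tg, scale = FALSE)^2)
  expect_lt(rel, 1e-3)
})

test_that("an unrelated target is predicted no better than its mean", {
  set.seed(3)
  U <- matrix(rnorm(400 * 20), 400)
  Tg <- matrix(rnorm(400 * 12), 400)
  enc <- train_bottleneck_encoder(U, Tg, latent_dim = 10, seed = 4,
                                  max_epochs = 300, patience = 20)
  mse <- mean((encoder_predict(enc, U) - Tg)^2)
  mse_mean <- mean(scale(Tg, scale = FALSE)^2)
  expect_gt(mse, 0.9 * mse_mean)
})

test_that("encoder training is deterministic given the seed", {
  fx <- fixture_linear_target(n = 200, du = 12, dt = 8, r = 8, seed = 5)
  e1 <- train_bottleneck_encoder(fx$U, fx$Tg, latent_dim = 4, seed = 9,
                                 max_epochs = 50)
  e2 <- train_bottleneck_encoder(fx$U, fx$Tg, latent_dim = 4, seed = 9,
                                 max_epochs = 50)
  expect_identical(e1$We, e2$We)
  expect_identical(e1$Wh, e2$Wh)
  expect_warning(
    train_bottleneck_encoder(fx$U, fx$Tg, latent_dim = 8, seed = 1,
                             max_epochs = 2),
    "vacuous")
})

test_that("the transfer decoder matches ordinary least squares", {
  set.seed(6)
  n <- 500
  Z <- matrix(rnorm(n * 20), n)
  W0 <- matrix(rnorm(20 * 30), 20) / sqrt(20)
  Td <- Z %*% W0 + 0.5 * matrix(rnorm(n * 30), n)
  dec <- train_transfer_decoder(Z, Td, seed = 4,
                                max_epochs = 4000, patience = 4000,
                                min_delta = 0, val_frac = 0)
  mse_sgd <- mean((decoder_predict(dec, Z) - Td)^2)
  mse_ols <- mean((oracle_ols_predict(Z, Td, Z) - Td)^2)
  expect_lt(mse_sgd, 1.01 * mse_ols)
  # exact linear map (zero-padded latents): error ~ 0
  Tpad <- cbind(Z, matrix(0, n, 4))
  dpad <- train_transfer_decoder(Z, Tpad, seed = 5, max_epochs = 3000,
                                 patience = 3000, min_delta = 0,
                                 val_frac = 0)
  expect_lt(mean((decoder_predict(dpad, Z) - Tpad)^2), 1e-4)
  # orthogonal target: no better than the mean predictor
  Torth <- matrix(rnorm(n * 10), n)
  dorth <- train_transfer_decoder(Z, Torth, seed = 6, max_epochs = 500,
                                  patience = 30)
  expect_gt(mean((decoder_predict(dorth, Z) - Torth)^2),
            0.9 * mean(scale(Torth, scale = FALSE)^2))
})

test_that("batched decoder training equals per-target training", {
  set.seed(7)
  Z <- matrix(rnorm(300 * 10), 300)
  targets <- list(a = Z %*% matrix(rnorm(10 * 6), 10) / 3 +
                    0.3 * matrix(rnorm(300 * 6), 300),
                  b = matrix(rnorm(300 * 4), 300))
  multi <- train_transfer_decoders_multi(Z, targets, seed = 11,
                                         max_epochs = 120, patience = 10)
  for (id in names(targets)) {
    single <- train_transfer_decoder(Z, targets[[id]], seed = 11,
                                     max_epochs = 120, patience = 10,
                                     target_id = id)
    expect_equal(multi[[id]]$W, single$W, tolerance = 1e-10)
    expect_equal(decoder_predict(multi[[id]], Z),
                 decoder_predict(single, Z), tolerance = 1e-8)
  }
})

test_that("encoder and decoder predictions are exactly affine", {
  fx <- fixture_linear_target(n = 300, du = 16, dt = 10, r = 10, seed = 8)
  enc <- train_bottleneck_encoder(fx$U, fx$Tg, latent_dim = 6, seed = 2,
                                  max_epochs = 80)
  # affine maps commute with convex combinations of random probes
  u1 <- fx$U_eval[1:5, ]; u2 <- fx$U_eval[6:10, ]
  for (a in c(-1.5, 0.3, 2)) {
    expect_equal(encoder_predict(enc, a * u1 + (1 - a) * u2),
                 a * encoder_predict(enc, u1) +
                   (1 - a) * encoder_predict(enc, u2),
                 tolerance = 1e-9)
  }
  Z <- encode_latents(enc, fx$U)
  dec <- train_transfer_decoder(Z, fx$Tg, seed = 3, max_epochs = 80)
  z1 <- Z[1:5, ]; z2 <- Z[6:10, ]
  for (a in c(-0.5, 0.7)) {
    expect_equal(decoder_predict(dec, a * z1 + (1 - a) * z2),
                 a * decoder_predict(dec, z1) +
                   (1 - a) * decoder_predict(dec, z2),
                 tolerance = 1e-9)
  }
})

test_that("tournament entries implement the smoothed win ratio", {
  # worked example: 75% vs 25% of samples, no smoothing -> exactly 3
  fx <- fixture_error_pair(100, 75)
  expect_identical(tournament_entry(fx$e_i, fx$e_j, epsilon = 0), 3)
  # identical error sequences: all ties split, ratio 1
  e <- runif(50)
  expect_equal(tournament_entry(e, e, epsilon = 0), 1)
  expect_equal(tournament_entry(e, e, epsilon = 1), 1)
  # clean sweep with smoothing: 100 wins + 1 over 0 + 1
  fx2 <- fixture_error_pair(100, 100)
  expect_equal(tournament_entry(fx2$e_i, fx2$e_j, epsilon = 1), 101)
  expect_error(tournament_entry(numeric(0), numeric(0)), "empty")
  expect_error(tournament_entry(1:3, 1:4), "equal length")
})

test_that("tournament matrices are reciprocal and detect information order", {
  set.seed(10)
  # reciprocity: entry(i,j) * entry(j,i) = 1 with no ties and epsilon 0
  errs <- list(a = runif(200), b = runif(200), c = runif(200))
  W <- tournament_from_errors(errs, epsilon = 0)
  for (i in 1:3) for (j in 1:3) {
    if (i != j) expect_equal(W[i, j] * W[j, i], 1, tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(W))))
  # with epsilon 0 and no ties, log W is antisymmetric
  expect_equal(log(W[upper.tri(W)]),
               -log(t(W)[upper.tri(W)]), tolerance = 1e-12)
  # duplicated source: entry between duplicates ~ 1 (all ties)
  errs2 <- list(x = errs$a, x_copy = errs$a)
  W2 <- tournament_from_errors(errs2, epsilon = 0)
  expect_equal(W2["x", "x_copy"], 1)
  # informative source crushes a noise source
  n <- 500
  lat <- matrix(rnorm(n * 5), n)
  target <- lat %*% matrix(rnorm(5 * 8), 5) + 0.2 * matrix(rnorm(n * 8), n)
  noise <- matrix(rnorm(n * 5), n)
  d_lat <- train_transfer_decoder(lat[1:400, ], target[1:400, ], seed = 1,
                                  max_epochs = 400, patience = 30)
  d_noise <- train_transfer_decoder(noise[1:400, ], target[1:400, ], seed = 1,
                                    max_epochs = 400, patience = 30)
  W3 <- tournament_matrix(
    list(lat = d_lat, noise = d_noise),
    list(lat = lat[401:500, ], noise = noise[401:500, ]),
    target[401:500, ])
  expect_gt(W3["lat", "noise"], 5)
})

test_that("generality scores average tournaments consistently", {
  set.seed(12)
  ids <- c("p", "q", "r")
  mats <- lapply(ids, function(t) {
    e <- lapply(ids, function(i) runif(80))
    names(e) <- ids
    tournament_from_errors(e, epsilon = 1, target_id = t)
  })
  names(mats) <- ids
  g <- generality_scores(mats)
  # averaging transfer scores over targets reproduces the generality score
  for (i in ids) {
    per_target <- vapply(setdiff(ids, i), function(t) {
      s <- transfer_score_to_target(mats[[t]])
      s$score[s$rep_id == i]
    }, numeric(1))
    expect_equal(g$score[g$rep_id == i], mean(per_target), tolerance = 1e-12)
  }
  # identical sources: equal scores
  e0 <- runif(60)
  mats_eq <- lapply(ids, function(t) {
    e <- list(p = e0, q = e0, r = e0)
    tournament_from_errors(e, epsilon = 1, target_id = t)
  })
  names(mats_eq) <- ids
  expect_equal(diff(range(generality_scores(mats_eq)$score)), 0)
  # scores are invariant to representation ordering
  mats_perm <- lapply(mats, function(m) {
    p <- c("r", "p", "q")
    structure(unclass(m)[p, p], target_id = attr(m, "target_id"),
              epsilon = 1, n_test = attr(m, "n_test"),
              class = class(m))
  })
  g2 <- generality_scores(mats_perm[ids])
  expect_equal(g2$score[match(g$rep_id, g2$rep_id)], g$score)
})

test_that("two-representation tournaments reduce to the single entry", {
  e <- fixture_error_pair(100, 60)
  W <- tournament_from_errors(list(u = e$e_i, v = e$e_j), epsilon = 0,
                              target_id = "w")
  s <- transfer_score_to_target(W, target_id = NULL)
  expect_equal(s$score[s$rep_id == "u"] / s$score[s$rep_id == "v"],
               W["u", "v"] / W["v", "u"])
  expect_error(transfer_score_to_target(W, target_id = "absent"),
               "not present")
})

test_that("generality ranks the full-coverage representation first", {
  fx <- fixture_generality_family(seed = 21)
  mats <- run_generality_tournament(fx$U, fx$family, 1:1200, 1201:1600,
                                    seed = 21)
  g <- generality_scores(mats)
  ord <- g$rep_id[order(-g$score)]
  expect_equal(ord[1], "full")
  expect_equal(ord[4], "noise")
  # single-target transfer: a source sharing the target's factors beats a
  # disjoint-coverage source
  s <- transfer_score_to_target(mats[["mid"]])
  expect_gt(s$score[s$rep_id == "full"], s$score[s$rep_id == "noise"])
})
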