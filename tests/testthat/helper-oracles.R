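# Independent closed-form oracles and small fixture builders used across
# the suite. These never call the code paths they check.

# Reduced-rank regression: rank-k least-squares predictor of Tg from U,
# via OLS followed by SVD truncation of the fitted values.
oracle_rrr_predict <- function(U, Tg, k, U_new) {
  um <- colMeans(U); tm <- colMeans(Tg)
  Uc <- sweep(U, 2, um); Tc <- sweep(Tg, 2, tm)
  B <- qr.solve(crossprod(Uc), crossprod(Uc, Tc))
  sv <- svd(Uc %*% B)
  Bk <- B %*% sv$v[, seq_len(k), drop = FALSE] %*%
    t(sv$v[, seq_len(k), drop = FALSE])
  sweep(sweep(U_new, 2, um) %*% Bk, 2, tm, "+")
}

# Ordinary least squares with intercept (minimum-norm solution via the
# pseudo-inverse, so rank-deficient noiseless fixtures are handled).
oracle_ols_predict <- function(X, Y, X_new) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  B <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], sweep(Y, 2, ym)) / sv$d[keep])
  sweep(sweep(X_new, 2, xm) %*% B, 2, ym, "+")
}

# Monte-Carlo surprisal of a sampled Markov stream under its own
# transition matrix (checks the analytic entropy rate).
oracle_mc_surprisal <- function(stream) {
  P <- stream$transition_matrix
  ids <- stream$word_ids
  n <- length(ids)
  -mean(log(P[cbind(ids[-n], ids[-1])]))
}

# Linear fixture with unit-variance target dimensions and a decaying
# coefficient spectrum (the shape typical of representation matrices).
fixture_linear_target <- function(n, du, dt, r, seed, n_eval = 2000) {
  set.seed(seed)
  U <- matrix(rnorm(n * du), n)
  A <- (matrix(rnorm(du * r), du) / sqrt(du)) %*%
    diag(1 / seq_len(r)^0.7, r) %*%
    (matrix(rnorm(r * dt), r) / sqrt(r)) * 3
  A <- sweep(A, 2, apply(U %*% A, 2, sd), "/")
  U_eval <- matrix(rnorm(n_eval * du), n_eval)
  list(U = U, Tg = U %*% A, U_eval = U_eval, T_eval = U_eval %*% A)
}

# Per-sample squared-error pair where the first sequence wins on exactly
# `wins` of `n` samples, with no ties.
fixture_error_pair <- function(n, wins, seed = 1) {
  set.seed(seed)
  base <- runif(n, 1, 2)
  idx <- sample.int(n, wins)
  delta <- runif(n, 0.05, 0.5)
  e_i <- base
  e_j <- base
  e_i[idx] <- base[idx] - delta[idx]
  e_i[-idx] <- base[-idx] + delta[-idx]
  list(e_i = e_i, e_j = e_j)
}

# Small synthetic generality family with known information ordering.
fixture_generality_family <- function(seed, n = 1600, k = 6, du = 32,
                                      dt = 24) {
  lat <- make_latent_factors(n, k, seed = seed)
  set.seed(seed + 1000)
  Mu <- matrix(rnorm(k * du), k)
  U <- lat$values %*% Mu + 0.3 * matrix(rnorm(n * du), n)
  specs <- list(
    full  = list(dims = dt, used_factors = seq_len(k), noise_sigma = 0.2),
    mid   = list(dims = dt, used_factors = seq_len(k %/% 2), noise_sigma = 0.5),
    low   = list(dims = dt, used_factors = 2L, noise_sigma = 0.8),
    noise = list(dims = dt, used_factors = integer(0), noise_sigma = 1))
  fam <- make_representation_family(lat, specs, seed = seed + 2000)
  list(U = U, family = fam, latent = lat)
}

rep_vals <- function(x) {
  if (inherits(x, "representation_matrix")) x$values else as.matrix(x)
}

# Full generality tournament over a family: encoders, decoders, matrices.
run_generality_tournament <- function(U, family, train_idx, test_idx,
                                      seed, latent_dim = 20,
                                      max_epochs = 200, patience = 12,
                                      epsilon = 1) {
  ids <- names(family)
  encs <- lapply(ids, function(id) {
    train_bottleneck_encoder(U[train_idx, , drop = FALSE],
                             rep_vals(family[[id]])[train_idx, , drop = FALSE],
                             latent_dim = latent_dim, seed = seed,
                             max_epochs = max_epochs, patience = patience)
  })
  names(encs) <- ids
  ltr <- lapply(encs, encode_latents, universal = U[train_idx, , drop = FALSE])
  lte <- lapply(encs, encode_latents, universal = U[test_idx, , drop = FALSE])
  targets <- lapply(family, function(f) {
    rep_vals(f)[train_idx, , drop = FALSE]
  })
  decs <- lapply(ids, function(src) {
    train_transfer_decoders_multi(ltr[[src]], targets, seed = seed,
                                  max_epochs = max_epochs,
                                  patience = patience)
  })
  names(decs) <- ids
  mats <- lapply(ids, function(tgt) {
    d <- lapply(ids, function(src) decs[[src]][[tgt]])
    names(d) <- ids
    tournament_matrix(d, lte,
                      rep_vals(family[[tgt]])[test_idx, , drop = FALSE],
                      epsilon = epsilon)
  })
  names(mats) <- ids
  mats
}
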