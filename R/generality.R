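# Representational generality: bottlenecked linear encoders from the
# universal input space, pairwise linear transfer decoders, tournament
# win-ratio matrices, and the generality / single-target transfer scores.
#
# The encoders and decoders are trained by plain stochastic gradient
# descent on the squared error summed over each batch (so the printed
# learning rates scale with batch size, the classic SGD convention), with
# early stopping on a held-out validation split. Both maps are strictly
# linear end to end: internal whitening/scaling is affine preconditioning
# that folds back into the fitted map and leaves the optimum unchanged.

sgd_early_stop_state <- function() {
  list(best_val = Inf, best = NULL, wait = 0L)
}

#' Train a bottlenecked linear encoder from the universal space
#'
#' Learns `target ~ f(E(universal))` where `E` maps the universal input
#' space to a small latent space (20-dim by default) and `f` maps the
#' latent space to the target representation, both strictly linear, fit
#' end-to-end by SGD on squared error (equivalent to reduced-rank
#' regression in the noiseless linear case). The bottleneck forces the
#' encoder to extract only the information in the universal space that the
#' target representation actually uses, normalizing representations by
#' their dimensionality.
#'
#' @param universal n x d_u matrix of universal input features (e.g. word
#'   embeddings of the stimulus), row-aligned with `target`.
#' @param target `representation_matrix` or n x d_t matrix.
#' @param latent_dim Bottleneck width (default 20).
#' @param batch Batch size (default 1024).
#' @param lr Learning rate (default 1e-4).
#' @param seed Integer seed (initialization, shuffling, validation split).
#' @param max_epochs Epoch budget (default 500).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param min_delta Minimum relative validation improvement (default 1e-7).
#' @param val_frac Validation fraction (default 0.1).
#' @param standardize Precondition internally before SGD (default TRUE):
#'   inputs are whitened and targets z-scored on the training split. The
#'   stored transform folds back into the final affine map, so the fitted
#'   model stays strictly linear and the least-squares optimum is
#'   unchanged; without it, gradient steps at the stated learning rates
#'   are unstable on strongly correlated inputs.
#' @return `bottleneck_encoder`: `We` (whitened-input x latent_dim), `Wh`
#'   (latent_dim x d_t), preconditioning transform, target id, and a
#'   training log.
#' @export
train_bottleneck_encoder <- function(universal, target, latent_dim = 20,
                                     batch = 1024, lr = 1e-4, seed = 1,
                                     max_epochs = 500, patience = 20,
                                     min_delta = 1e-7, val_frac = 0.1,
                                     standardize = TRUE) {
  U <- as.matrix(universal)
  Tg <- rep_values(target)
  if (nrow(U) != nrow(Tg)) stop("universal and target must be row-aligned")
  if (latent_dim >= min(ncol(U), ncol(Tg))) {
    warning("latent_dim >= min(input dims): the bottleneck is vacuous")
  }
  n <- nrow(U)
  with_seed(seed, {
    perm <- sample.int(n)
    if (val_frac <= 0) {
      # no held-out split: train on everything, track the training loss
      val_idx <- perm
      trn_idx <- perm
    } else {
      n_val <- max(1L, floor(n * val_frac))
      val_idx <- perm[seq_len(n_val)]
      trn_idx <- perm[-seq_len(n_val)]
    }
    tm <- colMeans(Tg[trn_idx, , drop = FALSE])
    if (standardize) {
      uw <- whiten_fit(U[trn_idx, , drop = FALSE])
      ts_ <- pmax(col_sds(Tg[trn_idx, , drop = FALSE]), 1e-8)
    } else {
      uw <- list(mean = rep(0, ncol(U)), Wm = diag(ncol(U)))
      ts_ <- rep(1, ncol(Tg))
    }
    Uc <- whiten_apply(U, uw)
    Tc <- sweep(sweep(Tg, 2L, tm, "-"), 2L, ts_, "/")
    Utr <- Uc[trn_idx, , drop = FALSE]; Ttr <- Tc[trn_idx, , drop = FALSE]
    Uva <- Uc[val_idx, , drop = FALSE]; Tva <- Tc[val_idx, , drop = FALSE]
    # balanced random init; stable because the whitened input makes the
    # gradient curvature uniform (O(1) per direction)
    We <- matrix(stats::rnorm(ncol(Uc) * latent_dim), ncol(Uc)) / sqrt(ncol(Uc))
    Wh <- matrix(stats::rnorm(latent_dim * ncol(Tg)), latent_dim) / sqrt(latent_dim)
    st <- sgd_early_stop_state()
    log_val <- numeric(0)
    n_tr <- length(trn_idx)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = batch)
      for (s in starts) {
        rows <- ord[s:min(s + batch - 1L, n_tr)]
        Ub <- Utr[rows, , drop = FALSE]
        Z <- Ub %*% We
        E <- Z %*% Wh - Ttr[rows, , drop = FALSE]
        g_Wh <- 2 * crossprod(Z, E)
        g_We <- 2 * crossprod(Ub, E %*% t(Wh))
        Wh <- Wh - lr * g_Wh
        We <- We - lr * g_We
      }
      val <- mean((Uva %*% We %*% Wh - Tva)^2)
      log_val <- c(log_val, val)
      if (!is.finite(val)) stop("encoder training diverged; reduce lr")
      if (val < st$best_val * (1 - min_delta)) {
        st$best_val <- val
        st$best <- list(We = We, Wh = Wh)
        st$wait <- 0L
      } else {
        st$wait <- st$wait + 1L
        if (st$wait >= patience) break
      }
    }
    if (is.null(st$best)) st$best <- list(We = We, Wh = Wh)
    structure(list(We = st$best$We, Wh = st$best$Wh,
                   u_mean = uw$mean, u_whiten = uw$Wm,
                   t_mean = tm, t_scale = ts_,
                   latent_dim = as.integer(latent_dim),
                   target_id = if (inherits(target, "representation_matrix"))
                     target$rep_id else NA_character_,
                   seed = seed, lr = lr, batch = batch,
                   val_loss = log_val),
              class = "bottleneck_encoder")
  })
}

#' Project universal inputs into an encoder's latent space
#' @param encoder A `bottleneck_encoder`.
#' @param universal n x d_u matrix.
#' @return n x latent_dim latent matrix.
#' @export
encode_latents <- function(encoder, universal) {
  whiten_apply(universal, list(mean = encoder$u_mean,
                               Wm = encoder$u_whiten)) %*% encoder$We
}

#' Reconstruct the target representation from an encoder
#' @param encoder A `bottleneck_encoder`.
#' @param universal n x d_u matrix.
#' @return n x d_t prediction of the target representation.
#' @export
encoder_predict <- function(encoder, universal) {
  sweep(sweep(encode_latents(encoder, universal) %*% encoder$Wh,
              2L, encoder$t_scale, "*"),
        2L, encoder$t_mean, "+")
}

#' Train a linear transfer decoder from a frozen source latent space
#'
#' Fits a strictly linear map from the source encoder's 20-dim latents to
#' a target representation by SGD on squared error; the source encoder is
#' never updated. This is a convex problem, so the fit converges to the
#' ordinary-least-squares solution.
#'
#' @param source_latents n x latent_dim matrix from [encode_latents()].
#' @param target `representation_matrix` or n x d_t matrix, row-aligned.
#' @param batch Batch size (default 1024).
#' @param lr Learning rate (default 2e-5).
#' @param seed Integer seed.
#' @param max_epochs,patience,min_delta,val_frac Early stopping as in
#'   [train_bottleneck_encoder()].
#' @param source_id,target_id Labels carried on the result.
#' @param standardize Precondition internally (default TRUE): latents
#'   whitened, targets z-scored; predictions come back in original units
#'   and the least-squares optimum is unchanged.
#' @return `transfer_decoder`: `W` (whitened-latent x d_t), the
#'   preconditioning transform, source/target ids, training log.
#' @export
train_transfer_decoder <- function(source_latents, target, batch = 1024,
                                   lr = 2e-5, seed = 1, max_epochs = 500,
                                   patience = 20, min_delta = 1e-7,
                                   val_frac = 0.1, source_id = NA_character_,
                                   target_id = NA_character_,
                                   standardize = TRUE) {
  Z <- as.matrix(source_latents)
  Tg <- rep_values(target)
  if (nrow(Z) != nrow(Tg)) stop("latents and target must be row-aligned")
  n <- nrow(Z)
  with_seed(seed, {
    perm <- sample.int(n)
    if (val_frac <= 0) {
      # no held-out split: train on everything, track the training loss
      val_idx <- perm
      trn_idx <- perm
    } else {
      n_val <- max(1L, floor(n * val_frac))
      val_idx <- perm[seq_len(n_val)]
      trn_idx <- perm[-seq_len(n_val)]
    }
    tm <- colMeans(Tg[trn_idx, , drop = FALSE])
    if (standardize) {
      zw <- whiten_fit(Z[trn_idx, , drop = FALSE])
      ts_ <- pmax(col_sds(Tg[trn_idx, , drop = FALSE]), 1e-8)
    } else {
      zw <- list(mean = rep(0, ncol(Z)), Wm = diag(ncol(Z)))
      ts_ <- rep(1, ncol(Tg))
    }
    Zc <- whiten_apply(Z, zw)
    Tc <- sweep(sweep(Tg, 2L, tm, "-"), 2L, ts_, "/")
    Ztr <- Zc[trn_idx, , drop = FALSE]; Ttr <- Tc[trn_idx, , drop = FALSE]
    Zva <- Zc[val_idx, , drop = FALSE]; Tva <- Tc[val_idx, , drop = FALSE]
    W <- matrix(0, ncol(Zc), ncol(Tg))
    st <- sgd_early_stop_state()
    log_val <- numeric(0)
    n_tr <- length(trn_idx)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = batch)
      for (s in starts) {
        rows <- ord[s:min(s + batch - 1L, n_tr)]
        Zb <- Ztr[rows, , drop = FALSE]
        g <- 2 * crossprod(Zb, Zb %*% W - Ttr[rows, , drop = FALSE])
        W <- W - lr * g
      }
      val <- mean((Zva %*% W - Tva)^2)
      log_val <- c(log_val, val)
      if (!is.finite(val)) stop("decoder training diverged; reduce lr")
      if (val < st$best_val * (1 - min_delta)) {
        st$best_val <- val
        st$best <- W
        st$wait <- 0L
      } else {
        st$wait <- st$wait + 1L
        if (st$wait >= patience) break
      }
    }
    if (is.null(st$best)) st$best <- W
    structure(list(W = st$best, z_mean = zw$mean, z_whiten = zw$Wm,
                   t_mean = tm, t_scale = ts_,
                   source_id = source_id, target_id = target_id,
                   seed = seed, lr = lr, batch = batch, val_loss = log_val),
              class = "transfer_decoder")
  })
}

#' Predict a target representation from source latents
#' @param decoder A `transfer_decoder`.
#' @param latents n x latent_dim matrix.
#' @return n x d_t prediction.
#' @export
decoder_predict <- function(decoder, latents) {
  Zc <- whiten_apply(latents, list(mean = decoder$z_mean,
                                   Wm = decoder$z_whiten))
  sweep(sweep(Zc %*% decoder$W, 2L, decoder$t_scale, "*"),
        2L, decoder$t_mean, "+")
}

#' Per-sample squared reconstruction errors of a decoder
#' @param decoder A `transfer_decoder`.
#' @param latents Held-out source latents.
#' @param target Held-out target rows.
#' @return Per-sample mean squared error (over target dimensions).
#' @export
decoder_sample_errors <- function(decoder, latents, target) {
  Tg <- rep_values(target)
  rowMeans((decoder_predict(decoder, latents) - Tg)^2)
}

#' Single tournament-matrix entry from two error sequences
#'
#' `(wins_i + epsilon) / (wins_j + epsilon)`, where `wins_i` counts the
#' held-out samples on which decoder i has strictly lower squared error
#' than decoder j; exact ties contribute half a win to each side. The
#' smoothing count `epsilon` keeps entries finite when one decoder wins
#' every sample (the raw ratio is undefined at 100%/0%); with `epsilon = 0`
#' and no ties the entry is the exact win-count ratio.
#'
#' @param errors_i,errors_j Equal-length per-sample squared errors on the
#'   shared held-out set.
#' @param epsilon Smoothing pseudo-count added to both win counts
#'   (default 1).
#' @return Positive scalar win ratio.
#' @export
tournament_entry <- function(errors_i, errors_j, epsilon = 1) {
  if (length(errors_i) == 0L) stop("empty test set")
  if (length(errors_i) != length(errors_j)) stop("error sequences must be equal length")
  ties <- sum(errors_i == errors_j)
  wins_i <- sum(errors_i < errors_j) + 0.5 * ties
  wins_j <- sum(errors_j < errors_i) + 0.5 * ties
  (wins_i + epsilon) / (wins_j + epsilon)
}

#' Tournament matrix over decoders that share a target
#'
#' Fights all pairs of decoders outputting to the same target on a shared
#' held-out set: entry (i, j) is the win ratio of source i's decoder over
#' source j's decoder. The diagonal is undefined (NA).
#'
#' @param decoders Named list (by source rep id) of `transfer_decoder`s to
#'   a common target.
#' @param latents_test Named list (same names) of held-out source latents.
#' @param target_test Held-out target representation rows.
#' @param epsilon Smoothing count (default 1).
#' @return `tournament_matrix`: n x n matrix with source rep ids as
#'   dimnames, attributes `target_id`, `n_test`, `epsilon`.
#' @export
tournament_matrix <- function(decoders, latents_test, target_test,
                              epsilon = 1) {
  if (length(decoders) < 2L) stop("need at least 2 sources")
  ids <- names(decoders)
  if (is.null(ids) || anyDuplicated(ids)) stop("decoders must be uniquely named by source")
  missing <- setdiff(ids, names(latents_test))
  if (length(missing)) stop("missing test latents for source(s): ",
                            paste(missing, collapse = ", "))
  errors <- lapply(ids, function(i) {
    decoder_sample_errors(decoders[[i]], latents_test[[i]], target_test)
  })
  names(errors) <- ids
  tournament_from_errors(errors, epsilon = epsilon,
                         target_id = decoders[[1]]$target_id)
}

#' Tournament matrix from precomputed per-sample error sequences
#'
#' @param errors Named list of equal-length per-sample squared-error
#'   vectors, one per source.
#' @param epsilon Smoothing count (default 1).
#' @param target_id Label stored on the result.
#' @return `tournament_matrix` (see [tournament_matrix()]).
#' @export
tournament_from_errors <- function(errors, epsilon = 1,
                                   target_id = NA_character_) {
  ids <- names(errors)
  n <- length(ids)
  W <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        W[i, j] <- tournament_entry(errors[[i]], errors[[j]], epsilon)
      }
    }
  }
  structure(W, target_id = target_id, n_test = length(errors[[1]]),
            epsilon = epsilon, class = c("tournament_matrix", "matrix", "array"))
}

#' Generality scores from per-target tournament matrices
#'
#' Averages the per-target tournament matrices into `W*` and then averages
#' `W*` along its first axis. For each source i, matrices whose target is i
#' are excluded from i's row average (self-transfer is degenerate), and the
#' diagonal (i vs itself) is never included.
#'
#' @param all_matrices Named list, target rep id -> `tournament_matrix`,
#'   all indexed by the same source ids.
#' @param log_domain If TRUE, scores are mean log win ratios (0 = even
#'   performance; robust when ratios span orders of magnitude). Default
#'   FALSE: arithmetic mean of the raw ratios.
#' @return Data frame `rep_id`, `score`, `derivation = "average"`, with the
#'   averaged matrix attached as attribute `W_star`.
#' @export
generality_scores <- function(all_matrices, log_domain = FALSE) {
  targets <- names(all_matrices)
  ids <- rownames(all_matrices[[1]])
  ok <- vapply(all_matrices, function(m) identical(rownames(m), ids) &&
                 identical(colnames(m), ids), logical(1))
  if (!all(ok)) stop("inconsistent indexing across tournament matrices")
  n <- length(ids)
  agg <- function(x) if (log_domain) mean(log(x)) else mean(x)
  W_star <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    use_t <- setdiff(targets, ids[i])
    for (j in seq_len(n)) {
      if (i != j) {
        W_star[i, j] <- agg(vapply(use_t, function(t) all_matrices[[t]][i, j],
                                   numeric(1)))
      }
    }
  }
  # W_star entries already live on the chosen scale (ratio or log-ratio),
  # so the row summary is a plain mean in both modes
  score <- vapply(seq_len(n), function(i) mean(W_star[i, -i]), numeric(1))
  out <- data.frame(rep_id = ids, score = score, derivation = "average",
                    stringsAsFactors = FALSE)
  attr(out, "W_star") <- W_star
  out
}

#' Transfer scores toward one named target representation
#'
#' Averages a single target's tournament matrix along its first axis,
#' giving one score per non-target representation (the target itself is
#' excluded from the scored sources).
#'
#' @param matrix_for_target A `tournament_matrix` for the named target.
#' @param target_id Target rep id; defaults to the matrix's own attribute.
#' @param log_domain If TRUE, scores are mean log win ratios (0 = even);
#'   appropriate when ratios span orders of magnitude.
#' @return Data frame `rep_id`, `score`, `derivation = target_id`.
#' @export
transfer_score_to_target <- function(matrix_for_target, target_id = NULL,
                                     log_domain = FALSE) {
  explicit <- !is.null(target_id)
  target_id <- target_id %||% attr(matrix_for_target, "target_id", exact = TRUE)
  ids <- rownames(matrix_for_target)
  if (explicit && !is.na(target_id) && !(target_id %in% ids)) {
    stop("target not present in the tournament matrix")
  }
  agg <- function(x) if (log_domain) mean(log(x)) else mean(x)
  keep <- setdiff(ids, target_id)
  score <- vapply(keep, function(i) {
    agg(matrix_for_target[i, setdiff(ids, i)])
  }, numeric(1))
  data.frame(rep_id = keep, score = unname(score),
             derivation = target_id %||% NA_character_,
             stringsAsFactors = FALSE)
}
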