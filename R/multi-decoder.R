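# Batched training of the transfer decoders that share a source latent
# space. The squared-error loss is column-separable, so SGD on the
# concatenated targets takes exactly the same per-target steps as
# training each decoder alone with the same seed; early stopping is
# tracked per target block. This keeps the n^2 decoder stage tractable
# without changing any decoder's fitted weights.

#' Train all transfer decoders from one source latent space at once
#'
#' Equivalent to calling [train_transfer_decoder()] once per target with
#' the same seed (the batch order is shared and the gradient is
#' blockwise-separable across targets); provided because a representation
#' family needs n^2 decoders.
#'
#' @param source_latents n x latent_dim matrix from the frozen source
#'   encoder.
#' @param targets Named list of `representation_matrix` objects or
#'   matrices, all row-aligned with `source_latents`.
#' @inheritParams train_transfer_decoder
#' @return Named list of `transfer_decoder` objects, one per target.
#' @export
train_transfer_decoders_multi <- function(source_latents, targets,
                                          batch = 1024, lr = 2e-5, seed = 1,
                                          max_epochs = 500, patience = 20,
                                          min_delta = 1e-7, val_frac = 0.1,
                                          source_id = NA_character_,
                                          standardize = TRUE) {
  Z <- as.matrix(source_latents)
  mats <- lapply(targets, rep_values)
  ids <- names(targets)
  dts <- vapply(mats, ncol, integer(1))
  ends <- cumsum(dts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
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
    Tall <- do.call(cbind, mats)
    tm <- colMeans(Tall[trn_idx, , drop = FALSE])
    if (standardize) {
      zw <- whiten_fit(Z[trn_idx, , drop = FALSE])
      ts_ <- pmax(col_sds(Tall[trn_idx, , drop = FALSE]), 1e-8)
    } else {
      zw <- list(mean = rep(0, ncol(Z)), Wm = diag(ncol(Z)))
      ts_ <- rep(1, ncol(Tall))
    }
    Zc <- whiten_apply(Z, zw)
    Tc <- sweep(sweep(Tall, 2L, tm, "-"), 2L, ts_, "/")
    Ztr <- Zc[trn_idx, , drop = FALSE]; Ttr <- Tc[trn_idx, , drop = FALSE]
    Zva <- Zc[val_idx, , drop = FALSE]; Tva <- Tc[val_idx, , drop = FALSE]
    W <- matrix(0, ncol(Zc), sum(dts))
    best_val <- rep(Inf, length(ids))
    wait <- integer(length(ids))
    active <- rep(TRUE, length(ids))
    best_W <- lapply(dts, function(d) matrix(0, ncol(Zc), d))
    n_tr <- length(trn_idx)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      bstarts <- seq(1L, n_tr, by = batch)
      for (s in bstarts) {
        rows <- ord[s:min(s + batch - 1L, n_tr)]
        Zb <- Ztr[rows, , drop = FALSE]
        g <- 2 * crossprod(Zb, Zb %*% W - Ttr[rows, , drop = FALSE])
        W <- W - lr * g
      }
      Vpred <- Zva %*% W
      for (b in which(active)) {
        cols <- starts[b]:ends[b]
        val <- mean((Vpred[, cols, drop = FALSE] -
                       Tva[, cols, drop = FALSE])^2)
        if (!is.finite(val)) stop("decoder training diverged; reduce lr")
        if (val < best_val[b] * (1 - min_delta)) {
          best_val[b] <- val
          best_W[[b]] <- W[, cols, drop = FALSE]
          wait[b] <- 0L
        } else {
          wait[b] <- wait[b] + 1L
          if (wait[b] >= patience) active[b] <- FALSE
        }
      }
      if (!any(active)) break
    }
    for (b in which(active)) {
      if (!is.finite(best_val[b])) {
        best_W[[b]] <- W[, starts[b]:ends[b], drop = FALSE]
      }
    }
    out <- lapply(seq_along(ids), function(b) {
      cols <- starts[b]:ends[b]
      structure(list(W = best_W[[b]], z_mean = zw$mean, z_whiten = zw$Wm,
                     t_mean = tm[cols], t_scale = ts_[cols],
                     source_id = source_id, target_id = ids[b],
                     seed = seed, lr = lr, batch = batch,
                     val_loss = numeric(0)),
                class = "transfer_decoder")
    })
    names(out) <- ids
    out
  })
}
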