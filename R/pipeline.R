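# Configuration-driven end-to-end pipeline over synthetic data:
# synth -> preprocess -> temporal design -> encoding -> next-word metric ->
# generality -> variance partitioning -> metric comparison.

#' Latent factor scores tied to word identity
#'
#' Assigns each vocabulary item a fixed k-dimensional factor score and
#' instantiates it over a word stream, so the latent structure behind the
#' representation family is a function of word identity. This links the
#' stream's next-word statistics to the representations: knowing a token's
#' factor scores is (partial) knowledge of the current word, which is what
#' a next-word readout needs.
#'
#' @param stream A `word_stream`.
#' @param k Number of factors.
#' @param seed Integer seed (determines the vocabulary factor table).
#' @param extra_ids Optional additional word-id vector appended after the
#'   stream's tokens (used to instantiate the same factors on a second
#'   stream).
#' @param basis `"random"` (i.i.d. Gaussian factor table) or
#'   `"predictive"`: the factor table spans the top-k principal directions
#'   of the mean-next-word-embedding map of the stream's Markov chain, so
#'   the shared latent structure is the stream's predictive structure and
#'   factor coverage directly controls how much next-word information a
#'   representation carries.
#' @param embeddings `embedding_table`, required for the predictive basis.
#' @return `latent_factors` whose rows follow `c(stream$word_ids,
#'   extra_ids)`, columns standardized; the vocabulary table is attached as
#'   field `factor_table`.
#' @export
latent_from_stream <- function(stream, k, seed, extra_ids = integer(0),
                               basis = c("random", "predictive"),
                               embeddings = NULL) {
  basis <- match.arg(basis)
  if (basis == "random") {
    Fv <- with_seed(seed, matrix(stats::rnorm(stream$vocab * k),
                                 stream$vocab, k))
  } else {
    if (is.null(embeddings)) stop("predictive basis requires embeddings")
    if (is.null(stream$transition_matrix)) {
      stop("predictive basis requires the stream's transition matrix")
    }
    # mean next-word embedding per state, top-k principal directions
    M <- stream$transition_matrix %*% embeddings$vectors
    M <- scale(M, scale = FALSE)
    sv <- svd(M, nu = min(k, stream$vocab), nv = 0)
    Fv <- sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE]
    if (ncol(Fv) < k) {
      extra <- with_seed(seed, matrix(stats::rnorm(stream$vocab *
                                                     (k - ncol(Fv))),
                                      stream$vocab))
      Fv <- cbind(Fv, extra)
    }
  }
  ids <- c(stream$word_ids, extra_ids)
  values <- Fv[ids, , drop = FALSE]
  values <- scale(values)
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  structure(list(values = values, k = as.integer(k), seed = as.integer(seed),
                 factor_table = Fv),
            class = "latent_factors")
}

#' Build family specs with cycling latent-factor coverage
#'
#' Generates `n_reps` representation specs whose factor coverage cycles
#' through 0..k factors (so the family spans pure noise through full
#' coverage) with i.i.d. noise levels in `noise_range`.
#'
#' @param n_reps Number of representations.
#' @param k Latent factor count.
#' @param dims Output dimensionality per representation.
#' @param noise_range Length-2 range for per-representation noise sigma.
#' @param seed Integer seed.
#' @param coverage_levels Coverage values to cycle through (default
#'   `0:k`, i.e. pure noise up to full coverage).
#' @return Named list of specs for [make_representation_family()].
#' @export
make_family_specs <- function(n_reps, k, dims = 24, noise_range = c(0.1, 1.2),
                              seed = 1, coverage_levels = seq(0, k)) {
  with_seed(seed, {
    out <- lapply(seq_len(n_reps), function(i) {
      n_used <- coverage_levels[(i - 1L) %% length(coverage_levels) + 1L]
      list(dims = dims,
           used_factors = if (n_used > 0) sort(sample.int(k, n_used)) else integer(0),
           noise_sigma = stats::runif(1, noise_range[1], noise_range[2]))
    })
    names(out) <- sprintf("rep%02d", seq_len(n_reps))
    out
  })
}

#' Default pipeline configuration
#'
#' The study conditions of the synthetic experiment: a 40-word vocabulary
#' Markov stream at natural-speech word rate (0.4 s/word), 48-dim word
#' embeddings as the universal space, 6 latent factors behind a 72-member
#' representation family, BOLD at TR 2 s with 5 repeated test runs, FIR
#' delays 2/4/6/8 s, and the 20-dim bottleneck generality pipeline.
#'
#' @return Nested configuration list (YAML-serializable).
#' @export
default_config <- function() {
  list(
    seed = 1,
    synth = list(
      vocab = 30, embedding_dim = 36, concentration = 0.6, k = 8,
      n_words_train = 2600, n_words_test = 1300, mean_word_dur = 0.4,
      n_reps = 72, rep_dims = 24, noise_range = c(0.15, 1.0),
      coverage_levels = seq(1, 8), latent_basis = "predictive"
    ),
    bold = list(
      tr = 2, n_voxels = 60, frac_responsive = 0.75, noise_sigma = 1,
      signal_scale = 1, n_test_repeats = 5
    ),
    preprocess = list(
      window_s = 120, order = 2, trim_volumes = 10, ev_threshold = 0.05
    ),
    design = list(delays = c(2, 4, 6, 8), lobes = 3),
    encoding = list(
      enabled = TRUE, alpha_log10_range = c(0, 4), n_alphas = 10,
      n_folds = 5, chunk_len = 40
    ),
    nwp = list(enabled = TRUE, train_frac = 0.75),
    generality = list(
      enabled = TRUE, latent_dim = 20, batch = 1024, lr_encoder = 1e-4,
      lr_decoder = 2e-5, max_epochs = 100, patience = 10, min_delta = 1e-7,
      n_train_tokens = 700, n_test_tokens = 600, epsilon = 1,
      transfer_target = NULL
    ),
    varpart = list(enabled = TRUE, rep_A = NULL, rep_B = NULL),
    compare = list(k = 70, n_iter = 10000)
  )
}

# Recursive config merge: user values override defaults.
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges of the fields the pipeline relies on; errors
#' name the offending field path.
#'
#' @param cfg Configuration list (already merged with defaults).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(path, why) stop(sprintf("config field %s: %s", path, why),
                                   call. = FALSE)
  chk_num <- function(x, path, lo = -Inf, hi = Inf, len = 1L) {
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
      fail(path, "must be finite numeric")
    }
    if (any(x < lo) || any(x > hi)) {
      fail(path, sprintf("must be in [%g, %g]", lo, hi))
    }
  }
  chk_num(cfg$seed, "seed")
  chk_num(cfg$synth$vocab, "synth.vocab", lo = 2)
  chk_num(cfg$synth$embedding_dim, "synth.embedding_dim", lo = 1)
  chk_num(cfg$synth$concentration, "synth.concentration", lo = 1e-9)
  chk_num(cfg$synth$k, "synth.k", lo = 1)
  chk_num(cfg$synth$n_words_train, "synth.n_words_train", lo = 50)
  chk_num(cfg$synth$n_words_test, "synth.n_words_test", lo = 50)
  chk_num(cfg$synth$mean_word_dur, "synth.mean_word_dur", lo = 1e-3)
  chk_num(cfg$synth$n_reps, "synth.n_reps", lo = 2)
  chk_num(cfg$synth$rep_dims, "synth.rep_dims", lo = 1)
  cl <- cfg$synth$coverage_levels
  if (!is.null(cl) && (any(cl < 0) || any(cl > cfg$synth$k))) {
    fail("synth.coverage_levels", "must lie in 0..synth.k")
  }
  chk_num(cfg$synth$noise_range, "synth.noise_range", lo = 0, len = 2L)
  chk_num(cfg$bold$tr, "bold.tr", lo = 1e-3)
  chk_num(cfg$bold$n_voxels, "bold.n_voxels", lo = 2)
  chk_num(cfg$bold$frac_responsive, "bold.frac_responsive", lo = 0, hi = 1)
  chk_num(cfg$bold$n_test_repeats, "bold.n_test_repeats", lo = 2)
  chk_num(cfg$preprocess$trim_volumes, "preprocess.trim_volumes", lo = 0)
  chk_num(cfg$preprocess$ev_threshold, "preprocess.ev_threshold", lo = 0, hi = 1)
  chk_num(cfg$design$delays, "design.delays", lo = 0,
          len = length(cfg$design$delays))
  for (st in c("encoding", "nwp", "generality", "varpart")) {
    if (!is.logical(cfg[[st]]$enabled %||% TRUE)) {
      fail(paste0(st, ".enabled"), "must be logical")
    }
  }
  chk_num(cfg$compare$k, "compare.k", lo = 3)
  chk_num(cfg$compare$n_iter, "compare.n_iter", lo = 1)
  invisible(cfg)
}

trim_rows <- function(x, n_volumes) {
  n <- nrow(x)
  x[(n_volumes + 1L):(n - n_volumes), , drop = FALSE]
}

preprocess_run <- function(run, pp) {
  zscore_voxels(trim_run(detrend_savgol(run, window_s = pp$window_s,
                                        order = pp$order),
                         n_volumes = pp$trim_volumes))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage on synthetic data with known ground truth and
#' writes the result tables (CSV/TSV/JSON/YAML) to `outdir`. Fully
#' reproducible from the configuration and its seed; stages can be
#' disabled independently via `<stage>$enabled`.
#'
#' @param config `NULL` (defaults), a configuration list, or a path to a
#'   YAML file; values are merged over [default_config()].
#' @param outdir Output directory (created if missing).
#' @param seed Optional override of the config seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the metric table, correlations,
#'   subsample reports, per-stage objects, and the ground truth.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("langenc_run"),
                         seed = NULL, quiet = FALSE) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- seed
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage_failed <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  ## --- synth -------------------------------------------------------------
  synth <- tryCatch({
    sc <- cfg$synth
    stream_train <- make_word_stream(sc$n_words_train, sc$vocab,
                                     concentration = sc$concentration,
                                     mean_word_dur = sc$mean_word_dur,
                                     seed = derive_seed(cfg$seed, 11))
    stream_test <- make_word_stream(sc$n_words_test, sc$vocab,
                                    mean_word_dur = sc$mean_word_dur,
                                    seed = derive_seed(cfg$seed, 12),
                                    transition_matrix = stream_train$transition_matrix)
    embeddings <- make_embedding_table(sc$vocab, sc$embedding_dim,
                                       seed = derive_seed(cfg$seed, 13))
    latent <- latent_from_stream(stream_train, sc$k,
                                 seed = derive_seed(cfg$seed, 14),
                                 extra_ids = stream_test$word_ids,
                                 basis = sc$latent_basis %||% "random",
                                 embeddings = embeddings)
    specs <- make_family_specs(sc$n_reps, sc$k, dims = sc$rep_dims,
                               noise_range = sc$noise_range,
                               seed = derive_seed(cfg$seed, 15),
                               coverage_levels = sc$coverage_levels %||%
                                 seq(0, sc$k))
    family <- make_representation_family(latent, specs,
                                         seed = derive_seed(cfg$seed, 16))
    n_tr_tok <- sc$n_words_train
    split_rep <- function(r) {
      list(train = r$values[seq_len(n_tr_tok), , drop = FALSE],
           test = r$values[-seq_len(n_tr_tok), , drop = FALSE],
           spec = list(used_factors = r$used_factors,
                       noise_sigma = r$noise_sigma))
    }
    reps <- lapply(family, split_rep)
    latent_train <- latent$values[seq_len(n_tr_tok), , drop = FALSE]
    latent_test <- latent$values[-seq_len(n_tr_tok), , drop = FALSE]
    list(stream_train = stream_train, stream_test = stream_test,
         embeddings = embeddings, latent_train = latent_train,
         latent_test = latent_test, reps = reps, specs = specs)
  }, error = function(e) stage_failed("synth", e))
  say("synth: %d train + %d test words, %d representations [%.1fs]",
      length(synth$stream_train$word_ids), length(synth$stream_test$word_ids),
      length(synth$reps), proc.time()[["elapsed"]] - t0)
  write_word_stream(synth$stream_train, file.path(outdir, "word_stream_train.tsv"))
  write_word_stream(synth$stream_test, file.path(outdir, "word_stream_test.tsv"))

  ## --- bold + preprocess -------------------------------------------------
  pp <- cfg$preprocess
  bold <- tryCatch({
    bc <- cfg$bold
    tr_grid <- function(stream) {
      seq(0, max(stream$offsets) + 10, by = bc$tr)
    }
    tt_train <- tr_grid(synth$stream_train)
    tt_test <- tr_grid(synth$stream_test)
    X_train <- temporal_design(synth$latent_train, tt_train,
                               delays = cfg$design$delays,
                               lobes = cfg$design$lobes,
                               onsets = synth$stream_train$onsets)
    X_test <- temporal_design(synth$latent_test, tt_test,
                              delays = cfg$design$delays,
                              lobes = cfg$design$lobes,
                              onsets = synth$stream_test$onsets)
    n_resp <- round(bc$frac_responsive * bc$n_voxels)
    W <- with_seed(derive_seed(cfg$seed, 21), {
      w <- matrix(stats::rnorm(ncol(X_train) * bc$n_voxels), ncol(X_train))
      w[, seq_len(bc$n_voxels) > n_resp] <- 0
      w
    })
    sig_sd <- col_sds(X_train %*% W)
    scale_v <- ifelse(sig_sd > 1e-12, bc$signal_scale / sig_sd, 0)
    W <- sweep(W, 2L, scale_v, "*")
    run_train <- make_bold(X_train, W, noise_sigma = bc$noise_sigma,
                           n_repeats = 1, seed = derive_seed(cfg$seed, 22),
                           tr = bc$tr, run_prefix = "train")[[1]]
    runs_test <- make_bold(X_test, W, noise_sigma = bc$noise_sigma,
                           n_repeats = bc$n_test_repeats,
                           seed = derive_seed(cfg$seed, 23), tr = bc$tr,
                           run_prefix = "test")
    run_train_pp <- preprocess_run(run_train, pp)
    runs_test_pp <- lapply(runs_test, preprocess_run, pp = pp)
    ev <- explainable_variance(runs_test_pp)
    mask <- language_mask(ev, threshold = pp$ev_threshold)
    avg_test <- zscore_voxels(bold_run(
      Reduce(`+`, lapply(runs_test_pp, `[[`, "data")) / length(runs_test_pp),
      tr = bc$tr, run_id = "test_avg"))
    list(tt_train = tt_train, tt_test = tt_test, run_train_pp = run_train_pp,
         avg_test = avg_test, ev = ev, mask = mask, n_resp = n_resp,
         true_weights = W)
  }, error = function(e) stage_failed("bold", e))
  say("bold: %d/%d voxels pass the %.0f%% explainable-variance mask [%.1fs]",
      sum(bold$mask$flags), cfg$bold$n_voxels, 100 * pp$ev_threshold,
      proc.time()[["elapsed"]] - t0)
  utils::write.csv(data.frame(voxel_index = seq_along(bold$ev),
                              value = bold$ev),
                   file.path(outdir, "explainable_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(voxel_index = seq_along(bold$mask$flags),
                              value = bold$mask$flags),
                   file.path(outdir, "language_mask.csv"), row.names = FALSE)

  rep_ids <- names(synth$reps)
  metric <- data.frame(rep_id = rep_ids, stringsAsFactors = FALSE)

  ## --- encoding ----------------------------------------------------------
  scores_by_rep <- NULL
  if (isTRUE(cfg$encoding$enabled)) {
    enc <- tryCatch({
      ec <- cfg$encoding
      grid <- 10^seq(ec$alpha_log10_range[1], ec$alpha_log10_range[2],
                     length.out = ec$n_alphas)
      design_of <- function(vals, tt, onsets) {
        trim_rows(temporal_design(vals, tt, delays = cfg$design$delays,
                                  lobes = cfg$design$lobes, onsets = onsets),
                  pp$trim_volumes)
      }
      per_rep <- lapply(rep_ids, function(id) {
        r <- synth$reps[[id]]
        Xtr <- design_of(r$train, bold$tt_train, synth$stream_train$onsets)
        Xte <- design_of(r$test, bold$tt_test, synth$stream_test$onsets)
        m <- fit_ridge(Xtr, bold$run_train_pp, alpha_grid = grid,
                       n_folds = ec$n_folds, seed = derive_seed(cfg$seed, 31),
                       chunk_len = ec$chunk_len)
        score_correlation(m, Xte, bold$avg_test)
      })
      names(per_rep) <- rep_ids
      per_rep
    }, error = function(e) stage_failed("encoding", e))
    scores_by_rep <- enc
    metric$encoding_performance <- vapply(enc, encoding_performance,
                                          numeric(1), mask = bold$mask)
    metric$encoding_all_voxels <- vapply(enc, mean, numeric(1))
    say("encoding: masked mean r in [%.3f, %.3f] [%.1fs]",
        min(metric$encoding_performance), max(metric$encoding_performance),
        proc.time()[["elapsed"]] - t0)
  }

  ## --- next-word perplexity ----------------------------------------------
  if (isTRUE(cfg$nwp$enabled)) {
    nw <- tryCatch({
      tf <- cfg$nwp$train_frac
      n_tr_tok <- length(synth$stream_train$word_ids)
      n_fit <- floor(n_tr_tok * tf)
      idx_fit <- seq_len(n_fit)
      idx_val <- seq(n_fit + 1L, n_tr_tok)
      sub_stream <- function(stream, idx) {
        structure(list(word_ids = stream$word_ids[idx],
                       onsets = stream$onsets[idx],
                       offsets = stream$offsets[idx],
                       transition_matrix = stream$transition_matrix,
                       entropy_rate = stream$entropy_rate,
                       vocab = stream$vocab),
                  class = "word_stream")
      }
      rows <- lapply(rep_ids, function(id) {
        r <- synth$reps[[id]]
        readout <- fit_next_word_readout(r$train[idx_fit, , drop = FALSE],
                                         sub_stream(synth$stream_train, idx_fit),
                                         synth$embeddings)
        temp <- fit_temperature(readout, r$train[idx_val, , drop = FALSE],
                                sub_stream(synth$stream_train, idx_val),
                                synth$embeddings)
        perplexity(readout, r$test, synth$stream_test, synth$embeddings,
                   temperature = temp)
      })
      names(rows) <- rep_ids
      rows
    }, error = function(e) stage_failed("nwp", e))
    metric$neg_perplexity <- -vapply(nw, `[[`, numeric(1), "perplexity")
    utils::write.csv(data.frame(
      rep_id = rep_ids,
      perplexity = vapply(nw, `[[`, numeric(1), "perplexity"),
      mean_cross_entropy = vapply(nw, `[[`, numeric(1), "mean_cross_entropy"),
      n_tokens = vapply(nw, `[[`, numeric(1), "n_tokens"),
      temperature = vapply(nw, `[[`, numeric(1), "temperature")),
      file.path(outdir, "perplexity.csv"), row.names = FALSE)
    say("nwp: perplexity in [%.1f, %.1f] (chain bound %.1f) [%.1fs]",
        min(-metric$neg_perplexity), max(-metric$neg_perplexity),
        exp(synth$stream_train$entropy_rate), proc.time()[["elapsed"]] - t0)
  }

  ## --- generality ---------------------------------------------------------
  if (isTRUE(cfg$generality$enabled)) {
    gen <- tryCatch({
      gc_ <- cfg$generality
      n_gt <- min(gc_$n_train_tokens, length(synth$stream_train$word_ids))
      n_ge <- min(gc_$n_test_tokens, length(synth$stream_test$word_ids))
      U_train <- synth$embeddings$vectors[
        synth$stream_train$word_ids[seq_len(n_gt)], , drop = FALSE]
      U_test <- synth$embeddings$vectors[
        synth$stream_test$word_ids[seq_len(n_ge)], , drop = FALSE]
      enc_seed <- derive_seed(cfg$seed, 41)
      encoders <- lapply(rep_ids, function(id) {
        train_bottleneck_encoder(
          U_train, synth$reps[[id]]$train[seq_len(n_gt), , drop = FALSE],
          latent_dim = gc_$latent_dim, batch = gc_$batch,
          lr = gc_$lr_encoder, seed = enc_seed,
          max_epochs = gc_$max_epochs, patience = gc_$patience,
          min_delta = gc_$min_delta)
      })
      names(encoders) <- rep_ids
      lat_train <- lapply(encoders, encode_latents, universal = U_train)
      lat_test <- lapply(encoders, encode_latents, universal = U_test)
      targets_train <- lapply(synth$reps,
                              function(r) r$train[seq_len(n_gt), , drop = FALSE])
      dec_seed <- derive_seed(cfg$seed, 42)
      decoders_by_source <- lapply(rep_ids, function(src) {
        train_transfer_decoders_multi(
          lat_train[[src]], targets_train, batch = gc_$batch,
          lr = gc_$lr_decoder, seed = dec_seed,
          max_epochs = gc_$max_epochs, patience = gc_$patience,
          min_delta = gc_$min_delta, source_id = src)
      })
      names(decoders_by_source) <- rep_ids
      matrices <- lapply(rep_ids, function(tgt) {
        decs <- lapply(rep_ids, function(src) decoders_by_source[[src]][[tgt]])
        names(decs) <- rep_ids
        tournament_matrix(decs, lat_test,
                          synth$reps[[tgt]]$test[seq_len(n_ge), , drop = FALSE],
                          epsilon = gc_$epsilon)
      })
      names(matrices) <- rep_ids
      # geometric-mean (log-domain) scores are the headline metric: win
      # ratios are multiplicative and can span orders of magnitude on a
      # synthetic family; the arithmetic ratio means are written alongside
      scores <- generality_scores(matrices, log_domain = TRUE)
      scores_ratio <- generality_scores(matrices)
      # default transfer target: a rich (full-coverage) representation of
      # median noise, standing in for a task model's intermediate layer
      coverage <- vapply(synth$reps, function(r) length(r$spec$used_factors),
                         integer(1))
      noise <- vapply(synth$reps, function(r) r$spec$noise_sigma, numeric(1))
      full_ids <- rep_ids[coverage == max(coverage)]
      default_target <- full_ids[order(noise[coverage == max(coverage)])][
        ceiling(length(full_ids) / 2)]
      target_id <- gc_$transfer_target %||% default_target
      transfer <- transfer_score_to_target(matrices[[target_id]],
                                           target_id = target_id,
                                           log_domain = TRUE)
      transfer_ratio <- transfer_score_to_target(matrices[[target_id]],
                                                 target_id = target_id)
      list(matrices = matrices, scores = scores,
           scores_ratio = scores_ratio, transfer = transfer,
           transfer_ratio = transfer_ratio, transfer_target = target_id)
    }, error = function(e) stage_failed("generality", e))
    metric$generality <- gen$scores$score[match(rep_ids, gen$scores$rep_id)]
    metric$target_transfer <- gen$transfer$score[match(rep_ids,
                                                       gen$transfer$rep_id)]
    gs <- gen$scores
    gs$score_ratio_mean <- gen$scores_ratio$score[
      match(gs$rep_id, gen$scores_ratio$rep_id)]
    utils::write.csv(gs, file.path(outdir, "generality_scores.csv"),
                     row.names = FALSE)
    ts <- gen$transfer
    ts$score_ratio_mean <- gen$transfer_ratio$score[
      match(ts$rep_id, gen$transfer_ratio$rep_id)]
    utils::write.csv(ts, file.path(outdir, "transfer_scores.csv"),
                     row.names = FALSE)
    Wst <- attr(gen$scores, "W_star")
    utils::write.csv(data.frame(rep_id = rownames(Wst), Wst,
                                check.names = FALSE),
                     file.path(outdir, "tournament_average.csv"),
                     row.names = FALSE)
    say("generality: scores in [%.2f, %.2f]; transfer target %s [%.1fs]",
        min(metric$generality), max(metric$generality), gen$transfer_target,
        proc.time()[["elapsed"]] - t0)
  } else {
    gen <- NULL
  }

  ## --- variance partitioning ----------------------------------------------
  vp <- NULL
  if (isTRUE(cfg$varpart$enabled) && isTRUE(cfg$encoding$enabled)) {
    vp <- tryCatch({
      coverage <- vapply(synth$reps,
                         function(r) length(r$spec$used_factors), integer(1))
      noise <- vapply(synth$reps,
                      function(r) r$spec$noise_sigma, numeric(1))
      full <- which(coverage == max(coverage))
      id_A <- cfg$varpart$rep_A %||% rep_ids[full[which.min(noise[full])]]
      mid <- which(coverage == ceiling(max(coverage) / 2))
      id_B <- cfg$varpart$rep_B %||%
        rep_ids[if (length(mid)) mid[which.min(noise[mid])] else 1L]
      ec <- cfg$encoding
      grid <- 10^seq(ec$alpha_log10_range[1], ec$alpha_log10_range[2],
                     length.out = ec$n_alphas)
      d_of <- function(id, part, tt, onsets) {
        trim_rows(temporal_design(synth$reps[[id]][[part]], tt,
                                  delays = cfg$design$delays,
                                  lobes = cfg$design$lobes, onsets = onsets),
                  pp$trim_volumes)
      }
      variance_partition(
        d_of(id_A, "train", bold$tt_train, synth$stream_train$onsets),
        d_of(id_B, "train", bold$tt_train, synth$stream_train$onsets),
        bold$run_train_pp, bold$avg_test,
        d_of(id_A, "test", bold$tt_test, synth$stream_test$onsets),
        d_of(id_B, "test", bold$tt_test, synth$stream_test$onsets),
        mask = bold$mask, alpha_grid = grid, n_folds = ec$n_folds,
        seed = derive_seed(cfg$seed, 51), chunk_len = ec$chunk_len,
        id_A = id_A, id_B = id_B)
    }, error = function(e) stage_failed("varpart", e))
    utils::write.csv(vp$per_voxel, file.path(outdir, "varpart_voxels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(component = names(vp$summary),
                                masked_mean = as.numeric(vp$summary)),
                     file.path(outdir, "varpart_summary.csv"),
                     row.names = FALSE)
    say("varpart: %s vs %s, masked unique = %.3f / %.3f, shared = %.3f [%.1fs]",
        vp$id_A, vp$id_B, vp$summary[["unique_A"]], vp$summary[["unique_B"]],
        vp$summary[["shared"]], proc.time()[["elapsed"]] - t0)
  }

  ## --- comparison ----------------------------------------------------------
  utils::write.csv(metric, file.path(outdir, "metric_table.csv"),
                   row.names = FALSE)
  correlations <- NULL
  subsamples <- list()
  if (isTRUE(cfg$encoding$enabled)) {
    others <- intersect(c("neg_perplexity", "generality", "target_transfer"),
                        names(metric))
    rows <- lapply(others, function(mname) {
      ok <- stats::complete.cases(metric[, c("encoding_performance", mname)])
      x <- metric$encoding_performance[ok]
      y <- metric[[mname]][ok]
      r <- metric_correlation(x, y)
      k_use <- min(cfg$compare$k, length(x))
      rep_sub <- subsample_correlation(x, y, k = k_use,
                                       n_iter = cfg$compare$n_iter,
                                       seed = derive_seed(cfg$seed, 61))
      subsamples[[mname]] <<- rep_sub
      data.frame(metric = mname, n = length(x), r = r,
                 subsample_k = k_use,
                 subsample_mean = mean(rep_sub$values),
                 subsample_min = min(rep_sub$values),
                 subsample_max = max(rep_sub$values))
    })
    correlations <- do.call(rbind, rows)
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    for (mname in names(subsamples)) {
      utils::write.csv(data.frame(r = subsamples[[mname]]$values),
                       file.path(outdir, sprintf("subsample_%s.csv", mname)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(subsamples, function(s) as.list(summary(s))),
      file.path(outdir, "subsample_summary.json"),
      auto_unbox = TRUE, digits = NA)
    say("compare: r(encoding, .) = %s [%.1fs]",
        paste(sprintf("%s %.3f", correlations$metric, correlations$r),
              collapse = ", "), proc.time()[["elapsed"]] - t0)
  }

  truth <- list(
    entropy_rate = synth$stream_train$entropy_rate,
    chain_perplexity_bound = exp(synth$stream_train$entropy_rate),
    n_responsive_voxels = bold$n_resp,
    noise_sigma = cfg$bold$noise_sigma,
    rep_coverage = lapply(synth$reps, function(r)
      list(used_factors = r$spec$used_factors,
           noise_sigma = r$spec$noise_sigma))
  )
  write_ground_truth(truth, file.path(outdir, "ground_truth.yaml"))
  yaml::write_yaml(cfg, file.path(outdir, "config_used.yaml"))

  invisible(list(config = cfg, metric_table = metric,
                 correlations = correlations, subsamples = subsamples,
                 scores_by_rep = scores_by_rep, ev = bold$ev,
                 mask = bold$mask, generality = gen, varpart = vp,
                 truth = truth, outdir = outdir))
}
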