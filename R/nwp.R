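# Linearly extractable next-word-prediction perplexity: a linear readout
# from a representation to the embedding of the next word, converted to a
# vocabulary distribution by a temperature softmax over embedding dot
# products, and summarized as exponentiated average cross entropy.

#' Fit a linear readout from a representation to next-word embeddings
#'
#' Ordinary least squares (with intercept) from representation row `t` to
#' the embedding of word `t + 1`; the last token is dropped.
#'
#' @param rep `representation_matrix` or words x d matrix.
#' @param stream `word_stream` aligned with the representation rows.
#' @param embeddings `embedding_table` over the stream's vocabulary.
#' @return `next_word_readout`: `weights` (d x d_emb), `intercept`.
#' @export
fit_next_word_readout <- function(rep, stream, embeddings) {
  X <- rep_values(rep)
  ids <- stream$word_ids
  if (nrow(X) != length(ids)) stop("representation rows must match the stream")
  n <- nrow(X)
  if (n - 1 < ncol(X) + 1) {
    warning("fewer training tokens than readout parameters; fit is rank-deficient")
  }
  Y <- embeddings$vectors[ids[-1], , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X[-n, , drop = FALSE]), Y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(weights = coefs[-1, , drop = FALSE],
                 intercept = coefs[1, ],
                 n_train = n - 1L),
            class = "next_word_readout")
}

predict_readout <- function(readout, rep) {
  X <- rep_values(rep)
  sweep(X %*% readout$weights, 2L, readout$intercept, "+")
}

#' Convert a predicted embedding into a next-word distribution
#'
#' Softmax over dot products between the predicted embedding and every
#' vocabulary embedding, divided by a temperature. The temperature makes
#' the metric invariant to embedding norm conventions; it is typically fit
#' on a validation split (see [fit_temperature()]).
#'
#' @param predicted Predicted embedding vector (d_emb).
#' @param embeddings `embedding_table`.
#' @param temperature Positive scalar (default 1).
#' @return Probability vector over the vocabulary, summing to 1.
#' @export
embedding_to_distribution <- function(predicted, embeddings, temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (!all(is.finite(predicted))) stop("predicted embedding must be finite")
  logits <- as.vector(embeddings$vectors %*% predicted) / temperature
  m <- max(logits)
  p <- exp(logits - m)
  p / sum(p)
}

# Log-probabilities assigned to the true next words; log-sum-exp guarded.
nwp_log_probs <- function(readout, rep, stream, embeddings, temperature) {
  X <- rep_values(rep)
  ids <- stream$word_ids
  n <- nrow(X)
  pred <- predict_readout(readout, X[-n, , drop = FALSE])
  logits <- pred %*% t(embeddings$vectors) / temperature
  lse <- row_logsumexp(logits)
  truth <- ids[-1]
  logits[cbind(seq_len(n - 1L), truth)] - lse
}

#' Perplexity of a representation's linear next-word readout
#'
#' Exponentiated average cross entropy between the softmax distribution
#' over predicted next words and the ground-truth next word, on held-out
#' tokens.
#'
#' @param readout A `next_word_readout` fit on disjoint tokens.
#' @param rep_test Held-out representation rows.
#' @param stream_test Held-out `word_stream`.
#' @param embeddings `embedding_table`.
#' @param temperature Positive scalar (default 1).
#' @return `perplexity_result`: `perplexity`, `mean_cross_entropy` (nats),
#'   `n_tokens`, `temperature`.
#' @export
perplexity <- function(readout, rep_test, stream_test, embeddings,
                       temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  lp <- nwp_log_probs(readout, rep_test, stream_test, embeddings, temperature)
  ce <- -mean(lp)
  structure(list(perplexity = exp(ce), mean_cross_entropy = ce,
                 n_tokens = length(lp), temperature = temperature),
            class = "perplexity_result")
}

#' Tune the softmax temperature on a validation split
#'
#' Minimizes validation cross entropy over log-temperature by
#' golden-section search; when a temperature of 1 is within numerical
#' tolerance of the optimum, 1 is returned (canonical default).
#'
#' @param readout A `next_word_readout`.
#' @param rep_val Validation representation rows.
#' @param stream_val Validation `word_stream`.
#' @param embeddings `embedding_table`.
#' @param interval Search interval for the temperature (default
#'   `c(1e-3, 1e2)`).
#' @return Optimal temperature (positive scalar).
#' @export
fit_temperature <- function(readout, rep_val, stream_val, embeddings,
                            interval = c(1e-3, 1e2)) {
  ce <- function(log_t) {
    -mean(nwp_log_probs(readout, rep_val, stream_val, embeddings, exp(log_t)))
  }
  opt <- stats::optimize(ce, log(interval), tol = 1e-4)
  if (ce(0) <= opt$objective + 1e-10) return(1)
  exp(opt$minimum)
}

#' End-to-end linearly extractable perplexity for one representation
#'
#' Splits the stream contiguously into train/validation/test token ranges,
#' fits the linear readout on train, tunes the softmax temperature on
#' validation, and reports held-out perplexity.
#'
#' @param rep `representation_matrix` or matrix aligned with `stream`.
#' @param stream `word_stream`.
#' @param embeddings `embedding_table`.
#' @param train_frac,val_frac Contiguous split fractions (test gets the
#'   remainder).
#' @param temperature Fixed temperature; if `NULL` (default), tuned on the
#'   validation split.
#' @return `perplexity_result` with an added `rep_id` field.
#' @export
nwp_perplexity <- function(rep, stream, embeddings, train_frac = 0.6,
                           val_frac = 0.2, temperature = NULL) {
  X <- rep_values(rep)
  n <- nrow(X)
  n_tr <- floor(n * train_frac)
  n_va <- floor(n * val_frac)
  if (n_tr < 2 || n - n_tr - n_va < 2) stop("stream too short to split")
  idx_tr <- seq_len(n_tr)
  idx_va <- seq(n_tr + 1L, n_tr + n_va)
  idx_te <- seq(n_tr + n_va + 1L, n)
  sub_stream <- function(idx) {
    structure(list(word_ids = stream$word_ids[idx],
                   onsets = stream$onsets[idx],
                   offsets = stream$offsets[idx],
                   transition_matrix = stream$transition_matrix,
                   entropy_rate = stream$entropy_rate,
                   vocab = stream$vocab),
              class = "word_stream")
  }
  readout <- fit_next_word_readout(X[idx_tr, , drop = FALSE],
                                   sub_stream(idx_tr), embeddings)
  if (is.null(temperature)) {
    temperature <- fit_temperature(readout, X[idx_va, , drop = FALSE],
                                   sub_stream(idx_va), embeddings)
  }
  out <- perplexity(readout, X[idx_te, , drop = FALSE], sub_stream(idx_te),
                    embeddings, temperature)
  out$rep_id <- if (inherits(rep, "representation_matrix")) rep$rep_id else NA_character_
  out
}
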