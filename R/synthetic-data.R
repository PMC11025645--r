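#' Generate standardized latent factor scores
#'
#' Draws a `n_words` x `k` matrix of i.i.d. Gaussian latent scores and
#' standardizes each column to zero mean and unit variance. The latent
#' factors play the role of the shared low-dimensional structure behind a
#' family of stimulus representations: representations are built as noisy
#' linear mixtures of subsets of these factors, so "how much of the latent
#' space a representation sees" is a controlled ground-truth quantity.
#'
#' @param n_words Number of word tokens (rows).
#' @param k Number of latent factors (columns); must satisfy `n_words > k >= 1`.
#' @param seed Integer seed; the function is a pure function of its arguments.
#' @return An object of class `latent_factors`: list with `values`
#'   (`n_words` x `k` matrix), `k`, and `seed`.
#' @export
make_latent_factors <- function(n_words, k, seed) {
  if (!is.numeric(n_words) || n_words <= 0 || !is.numeric(k) || k <= 0) {
    stop("n_words and k must be positive")
  }
  if (n_words <= k) stop("n_words must exceed k")
  values <- with_seed(seed, matrix(stats::rnorm(n_words * k), n_words, k))
  values <- scale(values)
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  structure(list(values = values, k = as.integer(k), seed = as.integer(seed)),
            class = "latent_factors")
}

#' Build a family of representations from shared latent factors
#'
#' Each representation is `latent[, used_factors] %*% L + noise`, with `L`
#' an i.i.d. standard-normal loading matrix. Representations using more
#' factors are strictly more informative about the latent space; a
#' representation using zero factors is pure noise. This emulates a set of
#' NLP-model feature spaces that capture a common linguistic structure to
#' varying degrees.
#'
#' @param latent A `latent_factors` object.
#' @param specs Named list; each element a list with `dims` (output
#'   dimensionality), `used_factors` (integer vector, possibly empty,
#'   subset of `1:k`), and `noise_sigma` (nonnegative).
#' @param seed Integer seed.
#' @return Named list of `representation_matrix` objects. Each carries
#'   attributes-like fields `loading`, `used_factors`, `noise_sigma` as the
#'   generating ground truth.
#' @export
make_representation_family <- function(latent, specs, seed) {
  stopifnot(inherits(latent, "latent_factors"))
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- sprintf("rep%02d", seq_along(specs))
  }
  k <- latent$k
  n <- nrow(latent$values)
  with_seed(seed, {
    out <- lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      dims <- sp$dims
      uf <- as.integer(sp$used_factors %||% integer(0))
      sigma <- sp$noise_sigma %||% 0
      if (dims < 1) stop("dims must be >= 1")
      if (length(uf) > 0 && (any(uf < 1) || any(uf > k))) {
        stop("used_factors out of range 1..k")
      }
      signal <- if (length(uf) > 0) {
        L <- matrix(stats::rnorm(length(uf) * dims), length(uf), dims)
        latent$values[, uf, drop = FALSE] %*% L
      } else {
        L <- matrix(0, 0, dims)
        matrix(0, n, dims)
      }
      values <- signal + sigma * matrix(stats::rnorm(n * dims), n, dims)
      representation_matrix(values, rep_id = names(specs)[i],
                            loading = L, used_factors = uf,
                            noise_sigma = sigma)
    })
    names(out) <- names(specs)
    out
  })
}

#' Representation matrix constructor
#'
#' @param values words x dims numeric matrix (finite).
#' @param rep_id Label.
#' @param stream Optional `word_stream` giving word timing for the rows.
#' @param ... Extra ground-truth fields stored alongside.
#' @return `representation_matrix` object.
#' @export
representation_matrix <- function(values, rep_id, stream = NULL, ...) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("representation values must be finite")
  structure(c(list(values = values, rep_id = rep_id, stream = stream),
              list(...)),
            class = "representation_matrix")
}

# Accept either a representation_matrix or a plain matrix.
rep_values <- function(x) {
  if (inherits(x, "representation_matrix")) x$values else as.matrix(x)
}

#' Stationary distribution of a row-stochastic matrix
#' @param P Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Analytic entropy rate of a Markov chain (nats/word)
#'
#' `H = -sum_i pi_i sum_j P_ij log P_ij`, with `0 log 0 = 0` and `pi` the
#' stationary distribution.
#'
#' @param P Row-stochastic transition matrix.
#' @return Entropy rate in nats per word.
#' @export
markov_entropy_rate <- function(P) {
  P <- as.matrix(P)
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("rows of P must sum to 1")
  p <- stationary_distribution(P)
  row_h <- rowSums(ifelse(P > 0, -P * log(P), 0))
  sum(p * row_h)
}

#' Generate a Markov word stream with known entropy rate
#'
#' Transition rows are drawn from a symmetric Dirichlet with the given
#' concentration (low concentration gives near-deterministic transitions,
#' hence low entropy), or a transition matrix may be supplied directly.
#' Word durations are i.i.d. gamma with the requested mean; words are
#' contiguous, so onsets are strictly increasing and `offset >= onset`.
#'
#' @param n_words Number of word tokens to sample (`>= 2`).
#' @param vocab Vocabulary size (`>= 2`).
#' @param concentration Dirichlet concentration for transition rows (`> 0`).
#' @param mean_word_dur Mean word duration, seconds.
#' @param seed Integer seed.
#' @param transition_matrix Optional row-stochastic matrix overriding the
#'   Dirichlet draw.
#' @param dur_shape Gamma shape for word durations (default 5; higher =
#'   less jitter).
#' @return `word_stream` object: `word_ids`, `onsets`, `offsets`,
#'   `transition_matrix`, `entropy_rate`, `vocab`.
#' @export
make_word_stream <- function(n_words, vocab, concentration = 1,
                             mean_word_dur = 0.4, seed = 1,
                             transition_matrix = NULL, dur_shape = 5) {
  if (n_words < 2) stop("n_words must be >= 2")
  if (vocab < 2) stop("vocab must be >= 2")
  if (concentration <= 0) stop("concentration must be positive")
  with_seed(seed, {
    P <- transition_matrix
    if (is.null(P)) {
      P <- matrix(stats::rgamma(vocab * vocab, shape = concentration),
                  vocab, vocab)
      P <- P / rowSums(P)
    } else {
      P <- as.matrix(P)
      if (nrow(P) != vocab || ncol(P) != vocab) stop("transition_matrix must be vocab x vocab")
      if (any(abs(rowSums(P) - 1) > 1e-9)) stop("transition_matrix rows must sum to 1")
    }
    ids <- integer(n_words)
    ids[1] <- sample.int(vocab, 1L)
    for (t in 2:n_words) {
      ids[t] <- sample.int(vocab, 1L, prob = P[ids[t - 1L], ])
    }
    dur <- stats::rgamma(n_words, shape = dur_shape,
                         rate = dur_shape / mean_word_dur)
    offsets <- cumsum(dur)
    onsets <- offsets - dur
    structure(list(word_ids = ids, onsets = onsets, offsets = offsets,
                   transition_matrix = P,
                   entropy_rate = markov_entropy_rate(P),
                   vocab = as.integer(vocab)),
              class = "word_stream")
  })
}

#' Generate a vocabulary embedding table
#'
#' Serves as the universal input space: a fixed vector per vocabulary item.
#' Rows are i.i.d. Gaussian (scaled by `1/sqrt(d)`), or orthonormal when
#' requested (requires `d >= vocab`), which makes any function of word
#' identity exactly linearly decodable from the embedding.
#'
#' @param vocab Vocabulary size.
#' @param d Embedding dimension.
#' @param seed Integer seed.
#' @param orthonormal If TRUE, rows are orthonormal.
#' @return `embedding_table` object: `vectors` (vocab x d), `vocab`, `d`.
#' @export
make_embedding_table <- function(vocab, d, seed = 1, orthonormal = FALSE) {
  if (vocab < 2 || d < 1) stop("vocab >= 2 and d >= 1 required")
  vectors <- with_seed(seed, {
    if (orthonormal) {
      if (d < vocab) stop("orthonormal rows require d >= vocab")
      Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
      t(Q[, seq_len(vocab), drop = FALSE])
    } else {
      matrix(stats::rnorm(vocab * d), vocab, d) / sqrt(d)
    }
  })
  if (anyDuplicated(round(vectors, 12))) stop("embedding rows must be distinct")
  structure(list(vectors = vectors, vocab = as.integer(vocab),
                 d = as.integer(d)),
            class = "embedding_table")
}

#' Generate BOLD-like runs as delayed linear responses plus noise
#'
#' Each repeat shares the same signal component `design %*% weights` and
#' receives independent Gaussian noise, mimicking repeated presentations of
#' the same stimulus. The design matrix is expected to already carry the
#' FIR delay structure, so encoding-model recovery is exact in the
#' noiseless limit.
#'
#' @param design TRs x p design matrix (e.g. from [make_delayed()]).
#' @param weights p x voxels true weight matrix.
#' @param noise_sigma Scalar or per-voxel noise standard deviation.
#' @param n_repeats Number of repeated runs.
#' @param seed Integer seed.
#' @param tr Repetition time in seconds (default 2).
#' @param run_prefix Label prefix for run ids.
#' @return List of `bold_run` objects sharing the signal exactly.
#' @export
make_bold <- function(design, weights, noise_sigma, n_repeats = 1, seed = 1,
                      tr = 2, run_prefix = "run") {
  X <- as.matrix(design)
  W <- as.matrix(weights)
  if (ncol(X) != nrow(W)) {
    stop(sprintf("shape mismatch: design has %d columns, weights %d rows",
                 ncol(X), nrow(W)))
  }
  v <- ncol(W)
  sigma <- rep_len(noise_sigma, v)
  signal <- X %*% W
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      noise <- matrix(stats::rnorm(nrow(X) * v), nrow(X), v)
      noise <- sweep(noise, 2L, sigma, "*")
      bold_run(signal + noise, tr = tr,
               run_id = sprintf("%s%02d", run_prefix, r))
    })
  })
}
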