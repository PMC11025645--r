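# Voxelwise linearized ridge regression, solved exactly through a single
# SVD of the design reused across the alpha grid and all voxels.

# Assign contiguous TR chunks to folds so temporal autocorrelation cannot
# leak across the train/validation boundary within a chunk.
chunked_folds <- function(n, n_folds, chunk_len, seed) {
  chunk_len <- max(1L, min(chunk_len, floor(n / n_folds)))
  n_chunks <- ceiling(n / chunk_len)
  chunk_of <- rep(seq_len(n_chunks), each = chunk_len)[seq_len(n)]
  fold_of_chunk <- with_seed(seed, sample(rep_len(seq_len(n_folds), n_chunks)))
  fold_of_chunk[chunk_of]
}

# Ridge predictions/coefficients from a precomputed SVD.
ridge_coef_svd <- function(sv, uty, alpha) {
  shrink <- sv$d / (sv$d^2 + alpha)
  sv$v %*% (uty * shrink)
}

#' Fit per-voxel ridge encoding models with cross-validated regularization
#'
#' Solves exact ridge regressions from a delay-stacked design matrix to
#' every voxel simultaneously via one singular-value decomposition per
#' training set, reused across the whole alpha grid. The per-voxel alpha is
#' chosen by mean held-out correlation over chunked cross-validation folds
#' (contiguous TR blocks, so temporally autocorrelated samples stay
#' together); ties are broken toward the larger alpha, and weights are then
#' refit on all training data at the chosen alpha.
#'
#' @param design TRs x p design matrix (e.g. from [temporal_design()]).
#' @param bold A `bold_run` or TRs x voxels matrix, row-aligned with
#'   `design`.
#' @param alpha_grid Positive ridge penalties (default 10 log-spaced values
#'   from 1 to 1e4).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for the chunk-to-fold assignment, the only stochastic
#'   element of fitting.
#' @param chunk_len Chunk length in TRs (default 40).
#' @return `encoding_model`: weights (p x voxels), per-voxel `alpha` and
#'   `intercept`, training means, CV correlation table, and metadata.
#' @export
fit_ridge <- function(design, bold, alpha_grid = 10^seq(0, 4, length.out = 10),
                      n_folds = 5, seed = 1, chunk_len = 40) {
  X <- as.matrix(design)
  Y <- if (inherits(bold, "bold_run")) bold$data else as.matrix(bold)
  if (nrow(X) != nrow(Y)) stop("design and bold must share the TR count")
  if (length(alpha_grid) == 0L || any(alpha_grid <= 0)) {
    stop("alpha_grid must be non-empty and positive")
  }
  if (anyNA(X) || anyNA(Y)) stop("NaN/NA in inputs")
  alpha_grid <- sort(alpha_grid)
  n <- nrow(X); v <- ncol(Y)
  folds <- chunked_folds(n, n_folds, chunk_len, seed)
  r_sum <- matrix(0, length(alpha_grid), v)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(folds != f)
    va_idx <- which(folds == f)
    xm <- colMeans(X[tr_idx, , drop = FALSE])
    ym <- colMeans(Y[tr_idx, , drop = FALSE])
    Xtr <- sweep(X[tr_idx, , drop = FALSE], 2L, xm, "-")
    Ytr <- sweep(Y[tr_idx, , drop = FALSE], 2L, ym, "-")
    Xva <- sweep(X[va_idx, , drop = FALSE], 2L, xm, "-")
    Yva <- Y[va_idx, , drop = FALSE]
    sv <- svd(Xtr)
    keep <- sv$d > max(sv$d) * 1e-12
    if (!any(keep)) stop("rank-0 design")
    sv$d <- sv$d[keep]; sv$u <- sv$u[, keep, drop = FALSE]
    sv$v <- sv$v[, keep, drop = FALSE]
    uty <- crossprod(sv$u, Ytr)
    Pva <- Xva %*% sv$v
    for (a in seq_along(alpha_grid)) {
      shrink <- sv$d / (sv$d^2 + alpha_grid[a])
      pred <- Pva %*% (uty * shrink)
      r <- suppressWarnings(
        sapply(seq_len(v), function(j) stats::cor(pred[, j], Yva[, j]))
      )
      r[!is.finite(r)] <- 0
      r_sum[a, ] <- r_sum[a, ] + r
    }
  }
  r_cv <- r_sum / n_folds
  best <- apply(r_cv, 2L, function(z) max(which(z >= max(z) - 1e-12)))
  alpha_vox <- alpha_grid[best]

  xm <- colMeans(X); ym <- colMeans(Y)
  sv <- svd(sweep(X, 2L, xm, "-"))
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep)) stop("rank-0 design")
  sv$d <- sv$d[keep]; sv$u <- sv$u[, keep, drop = FALSE]
  sv$v <- sv$v[, keep, drop = FALSE]
  uty <- crossprod(sv$u, sweep(Y, 2L, ym, "-"))
  W <- matrix(0, ncol(X), v)
  for (a in unique(best)) {
    vox <- which(best == a)
    W[, vox] <- ridge_coef_svd(sv, uty[, vox, drop = FALSE], alpha_grid[a])
  }
  structure(list(weights = W, alpha = alpha_vox, intercept = ym,
                 x_mean = xm, cv_correlation = r_cv,
                 alpha_grid = alpha_grid, n_folds = n_folds, seed = seed,
                 rep_id = attr(design, "rep_id", exact = TRUE)),
            class = "encoding_model")
}

#' Predict held-out responses from an encoding model
#'
#' @param object An `encoding_model`.
#' @param design Design matrix on the same feature space.
#' @param ... Unused.
#' @return TRs x voxels prediction matrix.
#' @export
predict.encoding_model <- function(object, design, ...) {
  X <- as.matrix(design)
  sweep(sweep(X, 2L, object$x_mean, "-") %*% object$weights,
        2L, object$intercept, "+")
}

#' Score an encoding model by held-out prediction correlation
#'
#' Pearson correlation per voxel between prediction and response. Voxels
#' with zero-variance prediction or response get r = 0 with a warning.
#'
#' @param model An `encoding_model`.
#' @param design_test Held-out design matrix.
#' @param bold_test Held-out `bold_run` or matrix.
#' @return Per-voxel correlation vector in `[-1, 1]`.
#' @export
score_correlation <- function(model, design_test, bold_test) {
  Y <- if (inherits(bold_test, "bold_run")) bold_test$data else as.matrix(bold_test)
  pred <- predict(model, design_test)
  if (nrow(pred) != nrow(Y) || ncol(pred) != ncol(Y)) {
    stop("prediction and response shapes differ")
  }
  r <- suppressWarnings(
    sapply(seq_len(ncol(Y)), function(j) stats::cor(pred[, j], Y[, j]))
  )
  bad <- !is.finite(r)
  if (any(bad)) {
    warning(sprintf("%d voxel(s) with zero-variance prediction or response; r set to 0",
                    sum(bad)))
    r[bad] <- 0
  }
  r
}

#' Aggregate encoding performance over masked voxels and subjects
#'
#' Mean correlation over language-responsive voxels, then mean over
#' subjects when given per-subject lists.
#'
#' @param scores Per-voxel correlation vector, or list of them (one per
#'   subject).
#' @param mask A `voxel_mask`, logical vector, or list matching `scores`.
#' @return Scalar encoding performance.
#' @export
encoding_performance <- function(scores, mask) {
  one <- function(s, m) {
    flags <- if (inherits(m, "voxel_mask")) m$flags else as.logical(m)
    if (length(flags) != length(s)) stop("mask length must match scores")
    if (!any(flags)) stop("empty mask")
    mean(s[flags])
  }
  if (is.list(scores) && !inherits(scores, "voxel_mask")) {
    if (!is.list(mask)) mask <- rep(list(mask), length(scores))
    mean(mapply(one, scores, mask))
  } else {
    one(scores, mask)
  }
}
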