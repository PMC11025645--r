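# Internal numeric helpers shared across modules.

# Row-wise log-sum-exp, numerically stable.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-stage seed from a global one; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

# Column means/sds without dropping to a data frame.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu, "-")^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Whitening transform fit on training rows: returns the centering mean and
# a matrix Wm such that (X - mean) %*% Wm has identity covariance on the
# retained (non-degenerate) directions. Used as optimizer preconditioning;
# it folds back into the final affine map, so the fitted model class and
# the least-squares optimum are unchanged.
whiten_fit <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d, 1e-300) * 1e-8
  if (!any(keep)) {
    # degenerate (constant) input: map everything to a single zero column
    return(list(mean = mu, Wm = matrix(0, ncol(X), 1L)))
  }
  Wm <- sv$v[, keep, drop = FALSE] %*%
    diag(sqrt(nrow(X) - 1) / sv$d[keep], sum(keep))
  list(mean = mu, Wm = Wm)
}

whiten_apply <- function(X, wt) {
  sweep(as.matrix(X), 2L, wt$mean, "-") %*% wt$Wm
}
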