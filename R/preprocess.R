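#' BOLD run constructor
#'
#' @param data TRs x voxels numeric matrix with finite entries.
#' @param tr Repetition time in seconds (`> 0`).
#' @param run_id Label.
#' @return `bold_run` object.
#' @export
bold_run <- function(data, tr, run_id = "run") {
  data <- as.matrix(data)
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, tr = tr, run_id = run_id), class = "bold_run")
}

#' Remove low-frequency drift with a Savitzky-Golay filter
#'
#' Fits a running second-order polynomial over a ~120 s window per voxel
#' and subtracts it, removing scanner drift while leaving task-band signal
#' intact. The window length in TRs is `round(window_s / tr)` forced odd;
#' boundaries use the filter's truncated-window polynomial fit (the
#' trimming step removes most residual edge artifact).
#'
#' @param run A `bold_run`.
#' @param window_s Filter window in seconds (default 120).
#' @param order Polynomial order (default 2).
#' @return A detrended `bold_run`.
#' @export
detrend_savgol <- function(run, window_s = 120, order = 2) {
  stopifnot(inherits(run, "bold_run"))
  win <- round(window_s / run$tr)
  if (win %% 2 == 0) win <- win + 1
  if (win <= order) stop("window length in TRs must exceed the filter order")
  if (nrow(run$data) < win) {
    stop(sprintf("run has %d TRs, shorter than the %d-TR filter window",
                 nrow(run$data), win))
  }
  trend <- apply(run$data, 2L, signal::sgolayfilt, p = order, n = win)
  bold_run(run$data - trend, tr = run$tr, run_id = run$run_id)
}

#' Trim volumes from both ends of a run
#'
#' Removes onset artifact and filter edge effects by dropping the first and
#' last `n_volumes` TRs (10 volumes = 20 s at TR 2 s by default).
#'
#' @param run A `bold_run`.
#' @param n_volumes Volumes to drop from each end.
#' @return Trimmed `bold_run`.
#' @export
trim_run <- function(run, n_volumes = 10) {
  stopifnot(inherits(run, "bold_run"))
  if (n_volumes == 0) return(run)
  n <- nrow(run$data)
  if (n <= 2 * n_volumes) stop("run too short to trim")
  keep <- (n_volumes + 1L):(n - n_volumes)
  bold_run(run$data[keep, , drop = FALSE], tr = run$tr, run_id = run$run_id)
}

#' Z-score each voxel's time series
#'
#' Subtracts the mean and scales to unit variance per voxel. Constant
#' voxels cannot be standardized; they are set to zero (preserving voxel
#' indexing) and a warning is issued.
#'
#' @param run A `bold_run`.
#' @return Standardized `bold_run`.
#' @export
zscore_voxels <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  x <- run$data
  mu <- colMeans(x)
  s <- col_sds(x)
  const <- !is.na(s) & s < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant voxel(s) set to zero", sum(const)))
    s[const] <- 1
  }
  out <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  out[, const] <- 0
  bold_run(out, tr = run$tr, run_id = run$run_id)
}

#' Explainable variance from repeated presentations
#'
#' For each voxel, the fraction of single-repeat variance explained by the
#' mean response across repeats, with a small-sample bias correction
#' `EV_corr = 1 - (1 - EV_raw) * n / (n - 1)` (n = number of repeats) so
#' that pure noise centers on zero. This is the noise-ceiling estimate used
#' to identify stimulus-locked voxels.
#'
#' @param repeats List of `bold_run` objects of equal shape (>= 2).
#' @return Numeric vector of per-voxel explainable variance (<= 1).
#' @export
explainable_variance <- function(repeats) {
  if (length(repeats) < 2L) stop("need at least 2 repeats")
  mats <- lapply(repeats, function(r) {
    if (inherits(r, "bold_run")) r$data else as.matrix(r)
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("repeats must share a common shape")
  }
  n_rep <- length(mats)
  m <- Reduce(`+`, mats) / n_rep
  n_tr <- nrow(m)
  total <- Reduce(`+`, lapply(mats, function(x) {
    colSums(sweep(x, 2L, colMeans(x), "-")^2) / (n_tr - 1)
  })) / n_rep
  resid <- Reduce(`+`, lapply(mats, function(x) {
    d <- x - m
    colSums(sweep(d, 2L, colMeans(d), "-")^2) / (n_tr - 1)
  })) / n_rep
  ev_raw <- ifelse(total > 1e-24, 1 - resid / total, 0)
  1 - (1 - ev_raw) * n_rep / (n_rep - 1)
}

#' Threshold explainable variance into a language-responsive voxel mask
#'
#' Flags voxels whose explainable variance is at least `threshold`
#' (inclusive, default 5%).
#'
#' @param ev Per-voxel explainable-variance vector.
#' @param threshold Cut-off in `[0, 1]`.
#' @return `voxel_mask` object: logical `flags` plus the `threshold`.
#' @export
language_mask <- function(ev, threshold = 0.05) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  flags <- is.finite(ev) & ev >= threshold
  structure(list(flags = flags, threshold = threshold), class = "voxel_mask")
}
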