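#' Lanczos kernel
#'
#' Windowed-sinc kernel with `lobes` side lobes and cutoff frequency
#' `cutoff` (Hz); value 1 at `t = 0`, zero outside `|t| > lobes / cutoff`.
#'
#' @param t Time offsets in seconds.
#' @param cutoff Cutoff frequency in Hz.
#' @param lobes Number of lobes (default 3).
#' @return Kernel values, same length as `t`.
#' @export
lanczos_kernel <- function(t, cutoff, lobes = 3) {
  x <- pi * cutoff * t
  val <- lobes * sin(x) * sin(x / lobes) / (x^2)
  val[abs(t) < 1e-12] <- 1
  val[abs(t) > lobes / cutoff] <- 0
  val
}

#' Resample word-level features onto the TR grid by Lanczos interpolation
#'
#' Each TR value is a Lanczos-kernel-weighted sum of word-level features,
#' with features anchored at word onsets and the kernel cutoff at the
#' Nyquist frequency of the TR grid. This is the word-time to scan-time
#' alignment step that precedes the FIR delay stacking.
#'
#' @param rep A `representation_matrix` or plain words x d matrix.
#' @param tr_times Increasing vector of TR acquisition times (seconds).
#' @param lobes Lanczos lobe count (default 3).
#' @param onsets Word onset times; defaults to the stream attached to `rep`.
#' @param cutoff Kernel cutoff in Hz; defaults to the TR-grid Nyquist.
#' @return TRs x d numeric matrix.
#' @export
lanczos_resample <- function(rep, tr_times, lobes = 3, onsets = NULL,
                             cutoff = NULL) {
  values <- rep_values(rep)
  if (is.null(onsets) && inherits(rep, "representation_matrix") &&
      !is.null(rep$stream)) {
    onsets <- rep$stream$onsets
  }
  if (any(diff(tr_times) <= 0)) stop("tr_times must be strictly increasing")
  if (nrow(values) == 0L) return(matrix(0, length(tr_times), ncol(values)))
  if (is.null(onsets)) stop("word onsets are required")
  if (length(onsets) != nrow(values)) {
    stop("onsets must match the representation's row count")
  }
  tr <- stats::median(diff(tr_times))
  if (is.null(cutoff)) cutoff <- 1 / (2 * tr)
  W <- outer(tr_times, onsets, function(a, b) lanczos_kernel(a - b, cutoff, lobes))
  W %*% values
}

#' Stack FIR hemodynamic delays onto a TR-aligned feature matrix
#'
#' Horizontally concatenates copies of the features shifted forward by each
#' delay (in seconds, validated as integer multiples of the TR), zero-padded
#' at the run start. The regression then absorbs the hemodynamic lag by
#' weighting the delayed copies.
#'
#' @param features TRs x d matrix on the TR grid.
#' @param delays Delays in seconds (default `c(2, 4, 6, 8)`).
#' @param tr Repetition time in seconds.
#' @return TRs x (d * length(delays)) `design_matrix` (a matrix with
#'   `delays` and `tr` attributes).
#' @export
make_delayed <- function(features, delays = c(2, 4, 6, 8), tr = 2) {
  X <- as.matrix(features)
  n <- nrow(X)
  d <- ncol(X)
  blocks <- lapply(delays, function(del) {
    shift <- del / tr
    if (del < 0 || abs(shift - round(shift)) > 1e-8) {
      stop(sprintf("delay %g s is not a nonnegative integer multiple of tr = %g s",
                   del, tr))
    }
    shift <- as.integer(round(shift))
    if (shift == 0L) return(X)
    if (shift >= n) return(matrix(0, n, d))
    rbind(matrix(0, shift, d), X[seq_len(n - shift), , drop = FALSE])
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- paste0(rep(sprintf("d%gs", delays), each = d), "_f",
                          rep(seq_len(d), length(delays)))
  structure(out, delays = delays, tr = tr, class = c("design_matrix", class(out)))
}

#' Full temporal transformation: Lanczos resampling plus FIR delays
#'
#' @inheritParams lanczos_resample
#' @inheritParams make_delayed
#' @return A `design_matrix`.
#' @export
temporal_design <- function(rep, tr_times, delays = c(2, 4, 6, 8), lobes = 3,
                            onsets = NULL) {
  tr <- stats::median(diff(tr_times))
  make_delayed(lanczos_resample(rep, tr_times, lobes = lobes, onsets = onsets),
               delays = delays, tr = tr)
}
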