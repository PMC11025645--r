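# Comparing per-representation metrics: full-sample Pearson correlations
# and the subsampled-correlation distribution used to gauge robustness.

#' Pearson correlation between two per-representation metrics
#'
#' @param x,y Aligned numeric vectors (one value per representation,
#'   `n >= 3`).
#' @return Pearson correlation coefficient.
#' @export
metric_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("metrics must be aligned")
  if (length(x) < 3L) stop("need at least 3 representations")
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15) {
    stop("zero variance in a metric")
  }
  stats::cor(x, y)
}

#' Distribution of correlations over random subsamples
#'
#' Draws `k` of the n representation points at random `n_iter` times
#' (without replacement by default; with replacement gives a bootstrap)
#' and correlates each subsample, yielding a distribution suitable for a
#' boxplot summary of how robust the full-sample correlation is.
#'
#' @param x,y Aligned metric vectors.
#' @param k Subsample size (default 70; must satisfy `3 <= k <= n`).
#' @param n_iter Number of subsamples (default 10000).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default FALSE).
#' @return `subsample_report`: `values` (length `n_iter`), `k`, `n_iter`,
#'   `seed`, `replace`, `full_r`.
#' @export
subsample_correlation <- function(x, y, k = 70, n_iter = 10000, seed = 1,
                                  replace = FALSE) {
  n <- length(x)
  if (k < 3) stop("k must be at least 3")
  if (!replace && k > n) stop("k cannot exceed the number of points")
  vals <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, k, replace = replace)
      suppressWarnings(stats::cor(x[idx], y[idx]))
    }, numeric(1))
  })
  vals[!is.finite(vals)] <- 0
  structure(list(values = vals, k = as.integer(k),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 replace = replace, full_r = stats::cor(x, y)),
            class = "subsample_report")
}

#' Summarize a subsample report
#' @param object A `subsample_report`.
#' @param ... Unused.
#' @return Named vector: mean, median, quartiles, min, max, full-sample r.
#' @export
summary.subsample_report <- function(object, ...) {
  q <- stats::quantile(object$values, c(0, 0.25, 0.5, 0.75, 1))
  c(mean = mean(object$values), min = unname(q[1]), q25 = unname(q[2]),
    median = unname(q[3]), q75 = unname(q[4]), max = unname(q[5]),
    full_r = object$full_r)
}
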