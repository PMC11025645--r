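# Pairwise variance partitioning: three ridge encoding models (A, B, and
# the column-concatenation A.B) per voxel, compared on held-out signed R².

#' Signed R-squared
#'
#' `r * |r|`: squared-correlation magnitude with the sign of the
#' correlation preserved, so partition components can go negative (as when
#' a concatenated model scores slightly below the better single model).
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return `r * |r|`, same shape as `r`.
#' @export
signed_r_squared <- function(r) {
  r * abs(r)
}

#' Partition held-out explained variance between two feature spaces
#'
#' Fits three encoding models — on `design_A`, on `design_B`, and on their
#' column concatenation (with a single per-voxel alpha on the joint space)
#' — and decomposes held-out signed R² into
#' `unique_A = r2_AB - r2_B`, `unique_B = r2_AB - r2_A`, and
#' `shared = r2_A + r2_B - r2_AB`. The three components sum to `r2_AB`
#' exactly, by construction, and any component may be negative.
#'
#' @param design_A,design_B Training design matrices, row-aligned with
#'   `bold_train`.
#' @param bold_train Training `bold_run` or matrix.
#' @param bold_test Held-out `bold_run` or matrix.
#' @param design_A_test,design_B_test Held-out design matrices, row-aligned
#'   with `bold_test`.
#' @param mask Optional `voxel_mask` (or logical vector) restricting the
#'   summary means.
#' @param alpha_grid,n_folds,seed,chunk_len Passed to [fit_ridge()].
#' @param id_A,id_B Labels for the two feature spaces.
#' @return `variance_partition`: `per_voxel` data frame (`voxel`, `r2_A`,
#'   `r2_B`, `r2_AB`, `unique_A`, `unique_B`, `shared`), `summary` of
#'   masked means, and the two ids.
#' @export
variance_partition <- function(design_A, design_B, bold_train, bold_test,
                               design_A_test, design_B_test, mask = NULL,
                               alpha_grid = 10^seq(0, 4, length.out = 10),
                               n_folds = 5, seed = 1, chunk_len = 40,
                               id_A = "A", id_B = "B") {
  if (nrow(as.matrix(design_A)) != nrow(as.matrix(design_B))) {
    stop("design_A and design_B must be row-aligned")
  }
  p_joint <- ncol(as.matrix(design_A)) + ncol(as.matrix(design_B))
  if (p_joint > nrow(as.matrix(design_A))) {
    warning("concatenated design has more columns than rows; joint fit may be ill-conditioned")
  }
  fit_score <- function(Xtr, Xte) {
    m <- fit_ridge(Xtr, bold_train, alpha_grid = alpha_grid,
                   n_folds = n_folds, seed = seed, chunk_len = chunk_len)
    score_correlation(m, Xte, bold_test)
  }
  r_A <- fit_score(design_A, design_A_test)
  r_B <- fit_score(design_B, design_B_test)
  r_AB <- fit_score(cbind(as.matrix(design_A), as.matrix(design_B)),
                    cbind(as.matrix(design_A_test), as.matrix(design_B_test)))
  r2_A <- signed_r_squared(r_A)
  r2_B <- signed_r_squared(r_B)
  r2_AB <- signed_r_squared(r_AB)
  unique_A <- r2_AB - r2_B
  unique_B <- r2_AB - r2_A
  shared <- r2_A + r2_B - r2_AB
  per_voxel <- data.frame(voxel = seq_along(r_A), r2_A = r2_A, r2_B = r2_B,
                          r2_AB = r2_AB, unique_A = unique_A,
                          unique_B = unique_B, shared = shared)
  flags <- if (is.null(mask)) rep(TRUE, length(r_A)) else {
    if (inherits(mask, "voxel_mask")) mask$flags else as.logical(mask)
  }
  summarise <- function(x) mean(x[flags])
  structure(list(per_voxel = per_voxel,
                 summary = c(r2_A = summarise(r2_A), r2_B = summarise(r2_B),
                             r2_AB = summarise(r2_AB),
                             unique_A = summarise(unique_A),
                             unique_B = summarise(unique_B),
                             shared = summarise(shared)),
                 id_A = id_A, id_B = id_B,
                 n_masked = sum(flags)),
            class = "variance_partition")
}
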