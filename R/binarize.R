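#' Poisson upper-tail binarization of binned counts
#'
#' The control-free binarization rule used for chromatin-state input: a bin
#' is called present (1) for a mark iff the upper-tail Poisson probability
#' `P(X >= c; lambda)` of its count `c` under the mark's background rate
#' `lambda` is at most `tail_p_threshold`.
#'
#' @param counts bins x marks matrix of non-negative counts (a numeric
#'   vector is treated as a one-mark matrix).
#' @param tail_p_threshold upper-tail probability cutoff (default `1e-4`).
#' @param lambda per-mark background rates; defaults to the global mean of
#'   each mark's counts.
#' @return an integer bins x marks matrix with entries in \{0, 1\}.
#' @export
binarize <- function(counts, tail_p_threshold = 1e-4, lambda = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  stopifnot(tail_p_threshold > 0, tail_p_threshold < 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lambda)) lambda <- colMeans(counts)
  lambda <- rep_len(lambda, ncol(counts))
  if (any(lambda == 0 & colSums(counts) > 0))
    stop("zero background rate with nonzero counts")
  out <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    # P(X >= c) = ppois(c - 1, lambda, lower.tail = FALSE); c = 0 gives P = 1
    p_tail <- stats::ppois(counts[, j] - 1, lambda[j], lower.tail = FALSE)
    out[, j] <- as.integer(p_tail <= tail_p_threshold)
  }
  out
}

#' Pool and binarize a count tensor per cohort
#'
#' Sums counts across the samples of each cohort per mark and binarizes the
#' pooled track against its own global-mean background rate, mirroring
#' concatenated-mode chromatin-state preprocessing.
#'
#' @param tensor a `mark_tensor`.
#' @param tail_p_threshold passed to [binarize()].
#' @return named list (per cohort) of bins x marks 0/1 matrices.
#' @export
binarize_cohorts <- function(tensor, tail_p_threshold = 1e-4) {
  cohorts <- unique(tensor$samples$cohort)
  out <- lapply(cohorts, function(co) {
    idx <- tensor$samples$cohort == co
    pooled <- vapply(tensor$counts, function(m) rowSums(m[, idx, drop = FALSE]),
                     numeric(nrow(tensor$counts[[1]])))
    binarize(pooled, tail_p_threshold = tail_p_threshold)
  })
  names(out) <- cohorts
  out
}
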