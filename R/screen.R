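#' Consensus-clustering screen configuration
#'
#' Monti-style feature-resampling consensus clustering settings: the
#' top-variance window, number of resamples, feature subsample fraction,
#' the k range, and the sample distance (1 - Pearson, average linkage).
#'
#' @param top_n number of most-variable regions (default 2000).
#' @param offset variance-rank window offset (0 selects ranks 1..top_n,
#'   2000 selects 2001..4000, etc.).
#' @param n_resamples resampling iterations (default 100).
#' @param item_subsample_fraction fraction of regions per resample.
#' @param k_range candidate cluster numbers (default 2:5).
#' @param seed integer seed.
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(top_n = 2000, offset = 0, n_resamples = 100,
                             item_subsample_fraction = 0.8, k_range = 2:5,
                             seed = 1) {
  stopifnot(top_n >= max(k_range), item_subsample_fraction > 0,
            item_subsample_fraction <= 1)
  structure(list(top_n = top_n, offset = offset, n_resamples = n_resamples,
                 item_subsample_fraction = item_subsample_fraction,
                 k_range = k_range, seed = seed),
            class = "consensus_config")
}

#' Region-level normalized signal matrix for one (state, mark)
#'
#' Sums a mark's counts over each segment of a state and normalizes to
#' RPKM-like units: `counts / (segment kb x sample library millions)`.
#'
#' @param tensor a `mark_tensor`.
#' @param seg a `segmentation` on the tensor's layout.
#' @param state state index or label passed to [segments_of_state()] /
#'   functional class for [segments_of_label_class()].
#' @param mark mark name.
#' @param samples optional subset of sample ids (default: all).
#' @return regions x samples numeric matrix with region coordinates as
#'   rownames and the segment table as attribute `"segments"`.
#' @export
region_signal_matrix <- function(tensor, seg, state, mark, samples = NULL) {
  if (!mark %in% names(tensor$counts)) stop("unknown mark: ", mark)
  segs <- if (is.character(state) && state %in% label_class(seg))
    segments_of_label_class(seg, state) else segments_of_state(seg, state)
  if (nrow(segs) == 0L) stop("state has no segments")
  cnt <- tensor$counts[[mark]]
  if (!is.null(samples)) cnt <- cnt[, samples, drop = FALSE]
  lib <- colSums(tensor$counts[[mark]])[colnames(cnt)]
  mat <- region_counts(tensor$layout, cnt, segs)
  kb <- (segs$end - segs$start) / 1000
  out <- mat / (kb %o% (lib / 1e6))
  rownames(out) <- paste0(segs$chrom, ":", segs$start, "-", segs$end)
  attr(out, "segments") <- segs
  out
}

# raw counts summed per region (rows) per sample (columns)
region_counts <- function(layout, counts, regions) {
  out <- matrix(0, nrow(regions), ncol(counts))
  colnames(out) <- colnames(counts)
  for (i in seq_len(nrow(regions))) {
    b <- bins_of_intervals(layout, regions[i, , drop = FALSE])
    out[i, ] <- if (length(b) > 1) colSums(counts[b, , drop = FALSE])
                else counts[b, ]
  }
  out
}

#' Select the top-variance window of a region matrix
#'
#' Rows are ranked by variance of `log2(x + 1)` (descending, deterministic
#' tie-break by original row order, i.e. genomic position) and the window
#' `[offset + 1, offset + top_n]` is returned. A window beyond the available
#' rows is an error; a partially covered window is truncated with a warning.
#'
#' @param mat regions x samples matrix.
#' @param cfg a `consensus_config` (or list with `top_n`, `offset`).
#' @return the reduced matrix.
#' @export
top_variable <- function(mat, cfg = consensus_config()) {
  v <- apply(log2(mat + 1), 1, stats::var)
  o <- order(-v, seq_along(v))
  lo <- cfg$offset + 1
  if (lo > nrow(mat)) stop("variance window starts beyond available rows")
  hi <- min(cfg$offset + cfg$top_n, nrow(mat))
  if (hi < cfg$offset + cfg$top_n)
    warning("variance window truncated to ", hi - lo + 1, " rows")
  mat[o[lo:hi], , drop = FALSE]
}

#' Monti-style consensus clustering of samples
#'
#' For each resample: subsample regions (rows), cluster samples by average
#' linkage on 1 - Pearson of the `log2(x + 1)` signal, cut at each k. The
#' consensus matrix entry (i, j) is the fraction of resamples co-clustering
#' samples i and j; the final partition per k is an average-linkage cut of
#' `1 - consensus`.
#'
#' @param mat regions x samples matrix.
#' @param cfg a `consensus_config`.
#' @return list with `consensus` (per k) and `partition` (per k, named
#'   integer vectors).
#' @export
consensus_cluster <- function(mat, cfg = consensus_config()) {
  ns <- ncol(mat)
  if (ns < max(cfg$k_range)) stop("fewer samples than the largest k")
  lm <- log2(mat + 1)
  if (nrow(lm) < 2) stop("need at least 2 regions to resample")
  if (all(apply(lm, 1, stats::var) == 0)) stop("all regions have zero variance")
  set.seed(cfg$seed)
  n_sub <- min(nrow(lm), max(2, round(cfg$item_subsample_fraction * nrow(lm))))
  ks <- cfg$k_range
  co <- lapply(ks, function(k) matrix(0, ns, ns))
  names(co) <- as.character(ks)
  for (r in seq_len(cfg$n_resamples)) {
    rows <- sample.int(nrow(lm), n_sub)
    d <- stats::as.dist(1 - stats::cor(lm[rows, , drop = FALSE]))
    d[is.na(d)] <- 1
    hc <- stats::hclust(d, method = "average")
    for (k in ks) {
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, `==`)
      co[[as.character(k)]] <- co[[as.character(k)]] + same
    }
  }
  consensus <- lapply(co, function(m) {
    m <- m / cfg$n_resamples
    dimnames(m) <- list(colnames(mat), colnames(mat))
    m
  })
  partition <- lapply(seq_along(ks), function(i) {
    m <- consensus[[i]]
    hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
    stats::setNames(stats::cutree(hc, k = ks[i]), colnames(mat))
  })
  names(partition) <- as.character(ks)
  list(consensus = consensus, partition = partition)
}

#' Does any partition exactly separate the two cohorts?
#'
#' A partition separates iff, restricted to the two contrasted cohorts,
#' every cluster is pure (merging clusters down to two groups by majority
#' label leaves no minority-label sample in either group).
#'
#' @param partitions named list of integer partitions (per k).
#' @param labels named cohort labels per sample.
#' @param contrast the two cohort labels to contrast (default APL vs AML).
#' @return list with `separation_flag` and `flag_k` (ks achieving
#'   separation).
#' @export
separation_flag <- function(partitions, labels,
                            contrast = c("APL", "AML")) {
  flag_k <- character(0)
  for (k in names(partitions)) {
    part <- partitions[[k]]
    if (is.null(names(part))) stop("partitions must be named by sample")
    lab <- labels[names(part)]
    keep <- lab %in% contrast
    pure <- all(vapply(split(lab[keep], part[keep]),
                       function(x) length(unique(x)) == 1, TRUE))
    if (pure) flag_k <- c(flag_k, k)
  }
  list(separation_flag = length(flag_k) > 0, flag_k = flag_k)
}

#' Run the (mark, state) separation screen
#'
#' For each combination: build the region signal matrix over the state's
#' segments, select the top-variance window, consensus-cluster the APL+AML
#' samples and flag exact cohort separation. Per-combination errors are
#' caught and logged, not fatal.
#'
#' @param tensor a `mark_tensor`.
#' @param seg a `segmentation`.
#' @param combos data.frame with columns `mark` and `state` (state label
#'   class or index).
#' @param cfg a `consensus_config`.
#' @param contrast cohorts to contrast.
#' @return data.frame of screen results (one row per combo) with the
#'   partitions in attribute `"partitions"`.
#' @export
run_screen <- function(tensor, seg, combos, cfg = consensus_config(),
                       contrast = c("APL", "AML")) {
  if (!nrow(combos)) stop("empty combination list")
  labels <- stats::setNames(tensor$samples$cohort, tensor$samples$sample_id)
  use <- tensor$samples$sample_id[tensor$samples$cohort %in% contrast]
  rows <- list(); parts <- list()
  for (i in seq_len(nrow(combos))) {
    mark <- combos$mark[i]; state <- combos$state[i]
    res <- tryCatch({
      mat <- region_signal_matrix(tensor, seg, state, mark, samples = use)
      mat <- top_variable(mat, cfg)
      cc <- consensus_cluster(mat, cfg)
      fl <- separation_flag(cc$partition, labels, contrast)
      parts[[paste(mark, state, sep = "|")]] <- cc$partition
      data.frame(mark = mark, state = as.character(state),
                 n_regions = nrow(mat),
                 separation_flag = fl$separation_flag,
                 flag_k = paste(fl$flag_k, collapse = ","),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(mark = mark, state = as.character(state), n_regions = 0L,
                 separation_flag = NA, flag_k = "",
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "partitions") <- parts
  out
}

#' Default screen combinations from a model
#'
#' Each mark crossed with the states whose emission probability for that
#' mark exceeds a threshold (the "relevant" chromatin states per mark).
#'
#' @param model a `chromhmm_model`.
#' @param labels state labels (from [assign_state_labels()]).
#' @param emission_min emission threshold (default 0.3).
#' @return data.frame with `mark` and `state` (state label) columns.
#' @export
default_screen_combos <- function(model, labels, emission_min = 0.3) {
  combos <- list()
  for (m in model$marks) {
    ks <- which(model$emission[, match(m, model$marks)] > emission_min)
    for (k in ks)
      combos[[length(combos) + 1L]] <- data.frame(mark = m, state = labels[k],
                                                  stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, combos))
}

#' Per-state Jaccard between two cohorts' segmentations
#'
#' For each state label, the bp Jaccard index of the two segment sets. A
#' label absent from one cohort gives Jaccard 0.
#'
#' @param seg_a,seg_b `segmentation`s with matched label spaces.
#' @return data.frame with `label` and `jaccard`.
#' @export
cohort_state_jaccard <- function(seg_a, seg_b) {
  labels <- union(seg_a$labels, seg_b$labels)
  jac <- vapply(labels, function(l) {
    a <- if (l %in% seg_a$labels) segments_of_state(seg_a, l) else interval_set()
    b <- if (l %in% seg_b$labels) segments_of_state(seg_b, l) else interval_set()
    if (nrow(a) == 0L || nrow(b) == 0L) return(0)
    jaccard_index(a, b)
  }, 0)
  data.frame(label = labels, jaccard = unname(jac))
}
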