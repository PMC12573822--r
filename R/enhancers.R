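#' Call cohort-specific enhancers from differential results
#'
#' Retains regions passing the enhancer rule (padj < `p_cut` and
#' log2FC >= `lfc_cut`, gains only) whose distance to the closest gene TSS
#' is strictly greater than `min_tss_dist` bp.
#'
#' @param diff a `diff_result` computed over active-enhancer-state segments;
#'   region coordinates are taken from the `segments` attribute or parsed
#'   from `id` of the form `chrom:start-end`.
#' @param genes gene-model data.frame.
#' @param min_tss_dist minimum TSS distance in bp (strict `>`).
#' @param p_cut,lfc_cut enhancer rule thresholds.
#' @return an `interval_set` of enhancer calls with the diff statistics and
#'   `tss_distance` as extra columns.
#' @export
call_specific_enhancers <- function(diff, genes, min_tss_dist = 500,
                                    p_cut = 0.05, lfc_cut = 1) {
  diff <- classify(diff, p_cut = p_cut, lfc_cut = lfc_cut)
  regions <- diff_regions(diff)
  keep <- diff$class == "gain"
  out <- regions[keep, , drop = FALSE]
  out$name <- diff$id[keep]
  out$log2fc <- diff$log2fc[keep]
  out$padj <- diff$padj[keep]
  if (!nrow(out)) return(interval_set(out))
  d <- distance_to_nearest_tss(interval_set(out), genes)
  out$tss_distance <- d
  interval_set(out[d > min_tss_dist, , drop = FALSE])
}

diff_regions <- function(diff) {
  segs <- attr(diff, "segments")
  if (!is.null(segs)) return(as.data.frame(segs)[, c("chrom", "start", "end")])
  m <- regmatches(diff$id, regexec("^([^:]+):([0-9]+)-([0-9]+)$", diff$id))
  if (any(lengths(m) != 4))
    stop("diff ids are not of the form chrom:start-end and no segments attribute")
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.numeric(vapply(m, `[`, "", 3)),
             end = as.numeric(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' ROSE-style stitching of enhancer peaks
#'
#' Peaks fully contained within `tss_exclusion` bp of any TSS are removed,
#' the rest are merged when their gap is at most `stitch_gap` bp (inclusive,
#' the ROSE convention), and each stitched region records its constituent
#' peak names.
#'
#' @param peaks an `interval_set` of enhancer peaks (named).
#' @param genes gene-model data.frame.
#' @param stitch_gap stitching distance in bp (ROSE default 12500).
#' @param tss_exclusion TSS exclusion zone in bp (the `-t 500` option).
#' @return an `interval_set` of stitched regions; `name` holds the
#'   comma-separated constituents and `score` their count.
#' @export
rose_stitch <- function(peaks, genes, stitch_gap = 12500, tss_exclusion = 500) {
  if (nrow(peaks) == 0L) stop("no peaks to stitch")
  if (tss_exclusion > 0 && nrow(genes)) {
    tss_zone <- interval_set(data.frame(
      chrom = genes$chrom,
      start = pmax(0, genes$tss - tss_exclusion),
      end = genes$tss + tss_exclusion + 1))
    gr_p <- as_granges(peaks); gr_z <- as_granges(tss_zone)
    within <- IRanges::overlapsAny(gr_p, gr_z, type = "within",
                                   ignore.strand = TRUE)
    peaks <- peaks[!within, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) stop("all peaks fall in TSS exclusion zones")
  merge_within(interval_set(as.data.frame(peaks)), stitch_gap)
}

#' Rank regions and place the tangent cutoff of the SE curve
#'
#' Scores are sorted ascending and both axes scaled to `[0, 1]`; the cutoff
#' is the score at the point where a line of slope 1 is tangent to the
#' curve from below, i.e. the point minimizing
#' `scaled_score - scaled_rank` (the rank-ordering geometry: sliding the
#' unit-slope diagonal up until it touches the curve). Regions scoring
#' strictly above the cutoff are super-enhancers. Ties break toward fewer
#' super-enhancers (the larger rank wins); a perfectly linear curve has the
#' diagonal touching everywhere and yields none, and a constant curve is
#' degenerate with none.
#'
#' @param regions an `interval_set` of stitched regions.
#' @param scores per-region signal scores.
#' @return list of class `se_curve` with the ranking table (`rank`,
#'   ascending by score; `scaled_rank`; `scaled_score`; `is_super`),
#'   `cutoff_score` and `cutoff_index` (in ascending order).
#' @export
rose_rank_and_cutoff <- function(regions, scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 regions to place a cutoff")
  if (nrow(regions) != n) stop("regions and scores differ in length")
  o <- order(scores)
  s <- scores[o]
  rng <- s[n] - s[1]
  x <- (seq_len(n) - 1) / (n - 1)
  if (rng == 0) {
    y <- rep(0, n); cutoff <- s[n]; ci <- n
  } else {
    y <- (s - s[1]) / rng
    d <- y - x
    ci <- max(which(d == min(d)))  # ties toward fewer super-enhancers
    cutoff <- s[ci]
  }
  is_super_sorted <- s > cutoff
  tab <- data.frame(region = o, rank = seq_len(n), score = s,
                    scaled_rank = x, scaled_score = y,
                    is_super = is_super_sorted)
  is_super <- logical(n); is_super[o] <- is_super_sorted
  structure(list(table = tab, cutoff_score = cutoff, cutoff_index = ci,
                 is_super = is_super, regions = regions),
            class = "se_curve")
}

#' Mean-normalized signal score of stitched regions
#'
#' Cohort-averaged, depth-normalized signal summed over each stitched
#' region's constituent span (the total-signal ranking used by the
#' rank-ordering of super-enhancers).
#'
#' @param tensor a `mark_tensor`.
#' @param regions stitched regions (`interval_set`).
#' @param mark mark name (typically H3K27ac).
#' @param cohort cohort label whose samples are averaged.
#' @return numeric score per region.
#' @export
se_signal_score <- function(tensor, regions, mark, cohort) {
  idx <- tensor$samples$cohort == cohort
  if (!any(idx)) stop("no samples in cohort ", cohort)
  cnt <- tensor$counts[[mark]][, idx, drop = FALSE]
  lib <- colSums(tensor$counts[[mark]])[idx]
  mat <- region_counts(tensor$layout, cnt, regions)
  norm <- sweep(mat, 2, lib / 1e6, `/`)
  rowMeans(norm)
}

#' Super-enhancers unique to one cohort
#'
#' Cohort-A super-enhancers with no 1 bp-or-more overlap with any cohort-B
#' super-enhancer and containing at least one cohort-A-specific enhancer.
#'
#' @param se_a,se_b `interval_set`s of the two cohorts' super-enhancers.
#' @param specific_enhancers_a cohort-A-specific enhancer calls
#'   (`interval_set`).
#' @return an `interval_set` of unique super-enhancers with
#'   `n_specific_enhancers` column.
#' @export
cohort_unique_super_enhancers <- function(se_a, se_b, specific_enhancers_a) {
  if (nrow(se_a) == 0L) return(se_a)
  keep <- !overlaps_any(se_a, se_b)
  out <- se_a[keep, , drop = FALSE]
  n_spec <- count_overlaps(interval_set(as.data.frame(out)), specific_enhancers_a)
  out$n_specific_enhancers <- n_spec
  out <- out[n_spec >= 1, , drop = FALSE]
  interval_set(as.data.frame(out))
}

#' Fusion-protein binding-site overlap of enhancer calls
#'
#' Flags each call overlapping (>= 1 bp) a binding site, and reports the
#' fraction of sites within `tss_window` bp of a TSS plus the per-state fold
#' enrichment of the site set (via [overlap_enrichment()]) when a
#' segmentation is supplied.
#'
#' @param calls enhancer calls (`interval_set`).
#' @param fusion_sites binding sites (`interval_set`).
#' @param genes gene-model data.frame (for TSS proximity).
#' @param seg optional `segmentation` for the state enrichment table.
#' @param tss_window TSS proximity window in bp (default 3000).
#' @return list with `calls` (annotated with `fusion_bound`),
#'   `bound_fraction`, `tss_proximal_fraction` and `state_enrichment`.
#' @export
fusion_overlap <- function(calls, fusion_sites, genes, seg = NULL,
                           tss_window = 3000) {
  bound <- overlaps_any(calls, fusion_sites)
  calls$fusion_bound <- bound
  tss_frac <- if (nrow(fusion_sites)) {
    d <- distance_to_nearest_tss(fusion_sites, genes)
    mean(d <= tss_window)
  } else NA_real_
  enr <- if (!is.null(seg) && nrow(fusion_sites))
    overlap_enrichment(seg, fusion_sites) else NULL
  list(calls = calls,
       bound_fraction = if (nrow(calls)) mean(bound) else NA_real_,
       n_bound = sum(bound),
       tss_proximal_fraction = tss_frac,
       state_enrichment = enr)
}
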