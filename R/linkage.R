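#' Pearson correlation with t-distribution p-value
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `r = +/-1` gives `p = 0` by convention; zero-variance input gives
#' `(NA, NA)`.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r`, `p` and `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Guilt-by-association enhancer-gene linkage
#'
#' Candidate pairs are (enhancer, gene) with the gene TSS within `window` bp
#' of the enhancer edges (inclusive, up- or downstream). For each pair, the
#' Pearson correlation between per-sample enhancer signal and
#' `log2(RPKM + 1)` gene expression is tested; a link passes iff
#' `r >= r_min` and `p <= p_max` (inclusive operators).
#'
#' @param enh_signal enhancers x samples signal matrix; enhancer coordinates
#'   are supplied via `enhancers`.
#' @param enhancers an `interval_set` matching the rows of `enh_signal`.
#' @param expression genes x samples RPKM matrix (rownames = gene ids);
#'   log-transformed internally.
#' @param genes gene-model data.frame.
#' @param window linkage window in bp (default 1 Mb).
#' @param r_min,p_max pass thresholds (defaults 0.7 and 0.01).
#' @param log_transform apply `log2(x + 1)` to both channels (default TRUE;
#'   set FALSE if already transformed).
#' @return a `link_result` data.frame: `enhancer_id`, `gene_id`, `r`, `p`,
#'   `n`, `distance`, `passes`.
#' @export
guilt_by_association <- function(enh_signal, enhancers, expression, genes,
                                 window = 1e6, r_min = 0.7, p_max = 0.01,
                                 log_transform = TRUE) {
  if (nrow(enhancers) != nrow(enh_signal))
    stop("enhancer coordinates and signal rows differ")
  if (!identical(colnames(enh_signal), colnames(expression)))
    stop("sample names of signal and expression do not match")
  expr <- if (log_transform) log2(expression + 1) else expression
  if (log_transform) enh_signal <- log2(enh_signal + 1)
  rows <- list()
  for (i in seq_len(nrow(enhancers))) {
    ch <- enhancers$chrom[i]
    s <- enhancers$start[i]; e <- enhancers$end[i]
    cand <- genes[genes$chrom == ch &
                    genes$tss >= s - window & genes$tss <= e + window, ]
    if (!nrow(cand)) next
    eid <- enhancers$name[i]
    if (is.na(eid)) eid <- rownames(enh_signal)[i]
    if (is.null(eid) || is.na(eid)) eid <- paste0("enh_", i)
    for (j in seq_len(nrow(cand))) {
      gi <- match(cand$gene_id[j], rownames(expr))
      if (is.na(gi)) next
      pt <- pearson_test(enh_signal[i, ], expr[gi, ])
      d <- if (cand$tss[j] >= s && cand$tss[j] < e) 0
           else min(abs(cand$tss[j] - s), abs(cand$tss[j] - e))
      rows[[length(rows) + 1L]] <- data.frame(
        enhancer_id = eid, gene_id = cand$gene_id[j],
        r = pt$r, p = pt$p, n = pt$n, distance = d,
        passes = !is.na(pt$r) && pt$r >= r_min && pt$p <= p_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enhancer_id = character(), gene_id = character(),
               r = numeric(), p = numeric(), n = integer(),
               distance = numeric(), passes = logical())
  class(out) <- c("link_result", "data.frame")
  out
}

#' Super-enhancer to gene association
#'
#' The guilt-by-association machinery applied to SE-level signal; each link
#' is annotated with the super-enhancer's fusion-binding flag.
#'
#' @param se_signal SEs x samples signal matrix.
#' @param ses `interval_set` of super-enhancers.
#' @param fusion_sites binding sites (`interval_set`) for the
#'   `fusion_bound` annotation.
#' @inheritParams guilt_by_association
#' @return a `link_result` data.frame with a `fusion_bound` column.
#' @export
se_gene_association <- function(se_signal, ses, expression, genes,
                                fusion_sites = interval_set(),
                                window = 1e6, r_min = 0.7, p_max = 0.01) {
  if (nrow(ses) == 0L) {
    out <- guilt_by_association(matrix(numeric(0), 0, ncol(expression),
                                       dimnames = list(NULL, colnames(expression))),
                                ses, expression, genes, window, r_min, p_max)
    out$fusion_bound <- logical(0)
    return(out)
  }
  links <- guilt_by_association(se_signal, ses, expression, genes,
                                window, r_min, p_max)
  bound <- overlaps_any(ses, fusion_sites)
  ids <- ses$name
  ids[is.na(ids)] <- paste0("enh_", which(is.na(ids)))
  links$fusion_bound <- bound[match(links$enhancer_id, ids)]
  links
}

#' Cross-breakpoint enhancer-gene correlation grid
#'
#' For a configured translocation breakpoint, correlates every enhancer
#' within `flank` bp of the breakpoint on one chromosome with every gene TSS
#' within `flank` bp on the partner chromosome (both directions are computed
#' separately). Cells with p < 0.05 are starred; no multiple-testing
#' correction is applied to the stars (a BH column is additionally emitted).
#'
#' @param enhancers `interval_set` of enhancer calls with per-sample signal
#'   in `enh_signal` (rows aligned).
#' @param enh_signal enhancers x samples matrix.
#' @param expression genes x samples RPKM matrix.
#' @param genes gene-model data.frame.
#' @param breakpoint list with `chrom_a`, `pos_a`, `chrom_b`, `pos_b` and
#'   optionally `flank` (default 2 Mb).
#' @param star_p star threshold (raw p, default 0.05).
#' @return list with two long-format data.frames `a_enh_b_genes` and
#'   `b_enh_a_genes` (`enhancer_id`, `gene_id`, `r`, `p`, `padj`, `star`).
#' @export
hijack_matrix <- function(enhancers, enh_signal, expression, genes,
                          breakpoint, star_p = 0.05) {
  flank <- if (is.null(breakpoint$flank)) 2e6 else breakpoint$flank
  expr <- log2(expression + 1)
  enh_signal <- log2(enh_signal + 1)
  side <- function(enh_chrom, enh_pos, gene_chrom, gene_pos) {
    ei <- which(enhancers$chrom == enh_chrom &
                  enhancers$start >= enh_pos - flank &
                  enhancers$end <= enh_pos + flank)
    g <- genes[genes$chrom == gene_chrom &
                 abs(genes$tss - gene_pos) <= flank, ]
    if (!length(ei) || !nrow(g))
      stop("empty breakpoint side (", enh_chrom, " enhancers x ",
           gene_chrom, " genes)")
    rows <- list()
    for (i in ei) {
      eid <- enhancers$name[i]
      if (is.na(eid)) eid <- paste0("enh_", i)
      for (j in seq_len(nrow(g))) {
        gi <- match(g$gene_id[j], rownames(expr))
        if (is.na(gi)) next
        pt <- pearson_test(enh_signal[i, ], expr[gi, ])
        rows[[length(rows) + 1L]] <- data.frame(
          enhancer_id = eid, gene_id = g$gene_id[j], r = pt$r, p = pt$p,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$padj <- bh_adjust(ifelse(is.na(out$p), 1, out$p))
    out$star <- !is.na(out$p) & out$p < star_p
    out
  }
  list(
    a_enh_b_genes = side(breakpoint$chrom_a, breakpoint$pos_a,
                         breakpoint$chrom_b, breakpoint$pos_b),
    b_enh_a_genes = tryCatch(
      side(breakpoint$chrom_b, breakpoint$pos_b,
           breakpoint$chrom_a, breakpoint$pos_a),
      error = function(e) NULL)
  )
}

#' Join genes with a dependency-score table
#'
#' Inner join on gene id; "dependent" genes have an effect score below the
#' threshold (negative scores mean the gene is needed for growth). Output is
#' sorted ascending by effect.
#'
#' @param gene_ids character vector of gene ids.
#' @param scores data.frame with `gene_id` and `effect` columns.
#' @param threshold dependency threshold (default 0; -0.5 for a stricter
#'   call).
#' @return data.frame with `gene_id`, `effect`, `dependent`.
#' @export
dependency_join <- function(gene_ids, scores, threshold = 0) {
  if (!all(c("gene_id", "effect") %in% names(scores)))
    stop("score table needs gene_id and effect columns")
  if (anyDuplicated(scores$gene_id)) stop("duplicated gene ids in score table")
  idx <- match(unique(gene_ids), scores$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped) message(dropped, " gene(s) absent from the score table, dropped")
  out <- scores[idx[!is.na(idx)], c("gene_id", "effect")]
  out$dependent <- out$effect < threshold
  out[order(out$effect), ]
}

#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= observed overlap)` for two sets drawn from a common universe.
#'
#' @param n_a,n_b set sizes.
#' @param overlap observed overlap.
#' @param universe universe size.
#' @return p-value.
#' @export
hypergeometric_overlap <- function(n_a, n_b, overlap, universe) {
  if (n_a > universe || n_b > universe || overlap > min(n_a, n_b) ||
      overlap < 0)
    stop("inconsistent counts for hypergeometric test")
  stats::phyper(overlap - 1, n_a, universe - n_a, n_b, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene list
#'
#' Hypergeometric upper-tail test of the query against each gene set
#' (restricted to the universe), BH-corrected across sets.
#'
#' @param query character vector of gene ids.
#' @param gene_sets named list of character vectors (subsets of the
#'   universe).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with per-set overlap counts, `p` and `padj`, sorted by
#'   p.
#' @export
gene_set_ora <- function(query, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(query, set))
    p <- hypergeometric_overlap(length(set), length(query), ov,
                                length(universe))
    data.frame(set = nm, set_size = length(set), query_size = length(query),
               overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p), ]
}
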