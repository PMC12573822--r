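#' Gain/loss summary of a repressive mark within a state
#'
#' Counts gain-, loss- and ns-classified segments of a differential result
#' computed over one state's segments, and profiles the TE overlap of the
#' gained and lost sites.
#'
#' @param diff a classified `diff_result` over the state's segments (apply
#'   [classify()] or pass `p_cut`/`lfc_cut`).
#' @param te_track TE `interval_set` with `subfamily:class` names (optional).
#' @param p_cut,lfc_cut classification thresholds applied if the table is
#'   unclassified (default enhancer-style: padj < 0.05, |log2FC| >= 1).
#' @return list of class `gain_loss_summary`: `n_gain`, `n_loss`, `n_ns`,
#'   `gained`, `lost` (interval sets), plus TE profiles when a track is
#'   given.
#' @export
state_gain_loss <- function(diff, te_track = NULL, p_cut = 0.05, lfc_cut = 1) {
  if (all(diff$class == "ns"))
    diff <- classify(diff, p_cut = p_cut, lfc_cut = lfc_cut)
  regions <- diff_regions(diff)
  gained <- interval_set(cbind(regions[diff$class == "gain", , drop = FALSE],
                               name = diff$id[diff$class == "gain"]))
  lost <- interval_set(cbind(regions[diff$class == "loss", , drop = FALSE],
                             name = diff$id[diff$class == "loss"]))
  out <- list(n_gain = nrow(gained), n_loss = nrow(lost),
              n_ns = sum(diff$class == "ns"),
              gained = gained, lost = lost)
  if (!is.null(te_track)) {
    out$te_gain <- te_overlap_profile(gained, te_track)
    out$te_loss <- te_overlap_profile(lost, te_track)
  }
  class(out) <- "gain_loss_summary"
  out
}

#' @export
print.gain_loss_summary <- function(x, ...) {
  cat("gain/loss summary:", x$n_gain, "gained,", x$n_loss, "lost,",
      x$n_ns, "ns\n")
  if (!is.null(x$te_gain))
    cat("TE overlap of gains:", round(x$te_gain$fraction, 3), "\n")
  invisible(x)
}

parse_te_names <- function(te_track) {
  parts <- strsplit(ifelse(is.na(te_track$name), "other:other", te_track$name),
                    ":", fixed = TRUE)
  data.frame(subfamily = vapply(parts, `[`, "", 1),
             class = vapply(parts, function(p) if (length(p) > 1) p[2] else "other", ""),
             stringsAsFactors = FALSE)
}

#' TE overlap profile of a site set
#'
#' A site counts once for each TE class (and subfamily) it touches with at
#' least 1 bp; the overall fraction is the count-based [overlap_fraction()]
#' against the whole TE track. Fractions are invariant to interval order and
#' to splitting a TE into adjacent pieces.
#'
#' @param sites an `interval_set`.
#' @param te_track TE `interval_set` with `subfamily:class` names.
#' @return list with `fraction`, `by_class` and `by_subfamily` count tables.
#' @export
te_overlap_profile <- function(sites, te_track) {
  if (nrow(te_track) == 0L) stop("empty TE track")
  ann <- parse_te_names(te_track)
  frac <- overlap_fraction(sites, te_track)
  count_by <- function(key) {
    vals <- sort(unique(ann[[key]]))
    n <- vapply(vals, function(v) {
      sub <- te_track[ann[[key]] == v, , drop = FALSE]
      sum(overlaps_any(sites, interval_set(as.data.frame(sub))))
    }, 0L)
    data.frame(group = vals, n_sites = n, stringsAsFactors = FALSE)
  }
  list(fraction = frac,
       n_sites = nrow(sites),
       by_class = count_by("class"),
       by_subfamily = count_by("subfamily"))
}

#' TE enrichment per chromatin state
#'
#' [overlap_enrichment()] applied per TE class.
#'
#' @param seg a `segmentation`.
#' @param te_track TE `interval_set` with `subfamily:class` names.
#' @return data.frame with `class`, `state`, `label`, `fold`.
#' @export
te_state_enrichment <- function(seg, te_track) {
  ann <- parse_te_names(te_track)
  out <- lapply(sort(unique(ann$class)), function(cl) {
    sub <- te_track[ann$class == cl, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    e <- overlap_enrichment(seg, interval_set(as.data.frame(sub)))
    cbind(class = cl, e)
  })
  do.call(rbind, out)
}

#' Cross-tabulate marked genes against differential expression
#'
#' Genes whose body overlaps (>= 1 bp) a gained site (and, separately, a
#' lost site) are cross-tabulated against their differential-expression
#' class, reporting the `(n_marked, n_DE, n_down, n_up)` quadruple per
#' direction.
#'
#' @param gained,lost site `interval_set`s.
#' @param genes gene-model data.frame.
#' @param de classified gene-level `diff_result` (ids matching
#'   `genes$gene_id`; `gain` = upregulated, `loss` = downregulated).
#' @param mode `"body"` (gene-body overlap, default) or `"promoter"`
#'   (TSS +/- `promoter_pad` bp).
#' @param promoter_pad promoter half-window in bp.
#' @return data.frame with one row per direction.
#' @export
marked_gene_expression_crosstab <- function(gained, lost, genes, de,
                                            mode = c("body", "promoter"),
                                            promoter_pad = 2000) {
  mode <- match.arg(mode)
  gene_iv <- if (mode == "body") {
    interval_set(data.frame(chrom = genes$chrom, start = genes$start,
                            end = genes$end, name = genes$gene_id))
  } else {
    interval_set(data.frame(chrom = genes$chrom,
                            start = pmax(0, genes$tss - promoter_pad),
                            end = genes$tss + promoter_pad,
                            name = genes$gene_id))
  }
  one <- function(sites, direction) {
    marked <- gene_iv$name[overlaps_any(gene_iv, sites)]
    d <- de[de$id %in% marked, ]
    n_de <- sum(d$class != "ns")
    data.frame(direction = direction, n_marked = length(marked),
               n_de = n_de, n_down = sum(d$class == "loss"),
               n_up = sum(d$class == "gain"), stringsAsFactors = FALSE)
  }
  rbind(one(gained, "gain"), one(lost, "loss"))
}
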