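#' Fold enrichment of an annotation track per chromatin state
#'
#' For each state k: `fold(k) = [bp(state k & track) / bp(genome)] /
#' [(bp(state k) / bp(genome)) * (bp(track) / bp(genome))]`. Empty states
#' give `NA` (reported as missing).
#'
#' @param seg a `segmentation`.
#' @param track an `interval_set`.
#' @return data.frame with `state`, `label`, `state_bp`, `overlap_bp`,
#'   `fold`.
#' @export
overlap_enrichment <- function(seg, track) {
  layout <- seg$layout
  genome_bp <- total_bp(layout)
  cov <- track_bin_coverage(layout, track)
  track_bp <- sum(cov)
  bin_bp <- bin_bp_vector(layout)
  state_bp <- vapply(seq_len(seg$K), function(k) sum(bin_bp[seg$state == k]), 0)
  overlap_bp <- vapply(seq_len(seg$K), function(k) sum(cov[seg$state == k]), 0)
  fold <- ifelse(state_bp > 0 & track_bp > 0,
                 (overlap_bp / genome_bp) /
                   ((state_bp / genome_bp) * (track_bp / genome_bp)),
                 NA_real_)
  data.frame(state = seq_len(seg$K), label = seg$labels,
             state_bp = state_bp, overlap_bp = overlap_bp, fold = fold)
}

# bp of each bin covered by a track (track clipped to the genome, overlaps
# within the track flattened first)
track_bin_coverage <- function(layout, track) {
  cov <- numeric(n_bins(layout))
  if (nrow(track) == 0L) return(cov)
  red <- merge_within(track, 0)
  bs <- layout$bin_size
  for (i in seq_len(nrow(red))) {
    ci <- chrom_index(layout, red$chrom[i])
    s <- max(0, red$start[i]); e <- min(layout$length[ci], red$end[i])
    if (e <= s) next
    b0 <- floor(s / bs); b1 <- floor((e - 1) / bs)
    bins <- layout$offset[ci] + (b0:b1) + 1L
    lo <- pmax(s, (b0:b1) * bs); hi <- pmin(e, (b0:b1 + 1) * bs)
    cov[bins] <- cov[bins] + (hi - lo)
  }
  cov
}

bin_bp_vector <- function(layout) {
  bt_len <- rep(layout$bin_size, n_bins(layout))
  # last bin of each chromosome may be partial
  last <- layout$offset + layout$n_bins
  bt_len[last] <- layout$length - (layout$n_bins - 1) * layout$bin_size
  bt_len
}

#' Classify genes by expression level
#'
#' RPKM > 2 is high, RPKM < 0.01 low, in between mid (the study's expression
#' classes), evaluated on the per-gene median RPKM across samples.
#'
#' @param rpkm genes x samples RPKM matrix (rownames = gene ids) or a
#'   per-gene vector.
#' @param high,low class thresholds.
#' @return named factor with levels high/mid/low.
#' @export
expression_class <- function(rpkm, high = 2, low = 0.01) {
  v <- if (is.matrix(rpkm)) apply(rpkm, 1, stats::median) else rpkm
  cls <- ifelse(v > high, "high", ifelse(v < low, "low", "mid"))
  factor(stats::setNames(cls, names(v)), levels = c("high", "mid", "low"))
}

#' Neighborhood enrichment of states at TSSs by expression class
#'
#' For each expression class, the fold enrichment of each state in the bins
#' containing the class's TSSs: `fold = (fraction of class TSSs in state k) /
#' (fraction of genome bins in state k)`.
#'
#' @param seg a `segmentation`.
#' @param genes gene-model data.frame.
#' @param class named factor from [expression_class()] (names = gene ids).
#' @param window bins to each side of the TSS bin to include (default 0).
#' @return data.frame with `class`, `state`, `label`, `n_tss`, `fold`.
#' @export
neighborhood_enrichment <- function(seg, genes, class, window = 0) {
  layout <- seg$layout
  genome_frac <- vapply(seq_len(seg$K), function(k) mean(seg$state == k), 0)
  out <- list()
  for (cl in levels(class)) {
    ids <- names(class)[class == cl & !is.na(class)]
    g <- genes[genes$gene_id %in% ids, ]
    if (!nrow(g)) next
    b <- bin_of(layout, g$chrom, g$tss)
    if (window > 0) {
      b <- unique(as.integer(outer(b, -window:window, `+`)))
      b <- b[b >= 1 & b <= n_bins(layout)]
    }
    st <- seg$state[b]
    cls_frac <- vapply(seq_len(seg$K), function(k) mean(st == k), 0)
    out[[cl]] <- data.frame(class = cl, state = seq_len(seg$K),
                            label = seg$labels, n_tss = length(b),
                            fold = ifelse(genome_frac > 0,
                                          cls_frac / genome_frac, NA_real_))
  }
  do.call(rbind, out)
}

#' Default state-labeling rules
#'
#' An ordered rule table mapping emission probabilities (and optionally
#' annotation enrichments) to functional labels; the first matching rule
#' wins, and states matching no rule get the default label.
#'
#' @return list of rules, each with `label` and a predicate specification.
#' @export
default_label_rules <- function() {
  list(
    list(label = "TSSBiv", min = c(H3K4me3 = 0.5, H3K27me3 = 0.5)),
    list(label = "TSSActive", min = c(H3K4me3 = 0.5)),
    list(label = "EnhActive", min = c(H3K27ac = 0.35, H3K4me1 = 0.35),
         max = c(H3K4me3 = 0.5)),
    list(label = "EnhWeak", min = c(H3K4me1 = 0.5)),
    list(label = "HetLADS", min = c(H3K9me3 = 0.5)),
    list(label = "Het", min = c(H3K9me2 = 0.5)),
    list(label = "ReprPcG", min = c(H3K27me3 = 0.5))
  )
}

rule_matches <- function(rule, emis, enrich_row = NULL) {
  ok <- TRUE
  if (!is.null(rule$min))
    ok <- ok && all(emis[names(rule$min)] >= rule$min)
  if (!is.null(rule$max))
    ok <- ok && all(emis[names(rule$max)] < rule$max)
  if (!is.null(rule$min_fold) && !is.null(enrich_row))
    ok <- ok && all(enrich_row[names(rule$min_fold)] >= rule$min_fold,
                    na.rm = FALSE)
  isTRUE(ok)
}

#' Assign functional labels to the states of a model
#'
#' Applies a deterministic ordered rule table to each state's emission
#' vector (and optional per-state annotation enrichment folds). States
#' matching no rule receive `default`. With `exclusive = TRUE`, a state
#' matching two rules with different labels is an error listing the
#' conflict.
#'
#' @param model a `chromhmm_model`.
#' @param rules rule list (see [default_label_rules()]).
#' @param enrichment optional data.frame of per-state annotation folds
#'   (rows = states, columns named as in the rules' `min_fold`).
#' @param default label for unmatched states.
#' @param exclusive error on multiply-matching states instead of
#'   first-match-wins.
#' @return character vector of labels, one per state, made unique by an
#'   `E<k>_` prefix.
#' @export
assign_state_labels <- function(model, rules = default_label_rules(),
                                enrichment = NULL, default = "Other",
                                exclusive = FALSE) {
  K <- model$K
  labels <- character(K)
  for (k in seq_len(K)) {
    emis <- stats::setNames(model$emission[k, ], model$marks)
    er <- if (!is.null(enrichment)) unlist(enrichment[k, , drop = FALSE]) else NULL
    hits <- which(vapply(rules, rule_matches, TRUE, emis = emis,
                         enrich_row = er))
    hit_labels <- unique(vapply(rules[hits], `[[`, "", "label"))
    if (exclusive && length(hit_labels) > 1)
      stop("contradictory label rules for state ", k, ": ",
           paste(hit_labels, collapse = " vs "))
    labels[k] <- if (length(hit_labels)) hit_labels[1] else default
  }
  paste0("E", seq_len(K), "_", labels)
}

#' Functional label part of a segmentation's state labels
#' @param seg a `segmentation`.
#' @return character vector without the `E<k>_` prefix.
#' @export
label_class <- function(seg) sub("^E[0-9]+_", "", seg$labels)

#' Segments of all states sharing a functional label class
#' @param seg a `segmentation`.
#' @param class functional label (e.g. `"EnhActive"`).
#' @return an `interval_set`.
#' @export
segments_of_label_class <- function(seg, class) {
  ks <- which(label_class(seg) == class)
  if (!length(ks)) return(interval_set())
  mask <- seg$state %in% ks
  seg2 <- seg; seg2$state <- ifelse(mask, 1L, 2L); seg2$K <- 2L
  seg2$labels <- c(class, "other")
  segments_of_state(seg2, 1L)
}
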