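#' Default histone mark panel
#'
#' The eight-mark panel profiled by the emulated study design: five marks of
#' active chromatin (H2AZ, H3K4me1, H3K4me3, H3K18ac, H3K27ac) and three
#' repressive marks (H3K9me2, H3K9me3, H3K27me3).
#' @export
default_marks <- function() {
  c("H2AZ", "H3K4me1", "H3K4me3", "H3K9me2", "H3K9me3",
    "H3K18ac", "H3K27ac", "H3K27me3")
}

#' Cohort design for the synthetic study
#'
#' Describes the sample layout of the emulated cohort: a disease cohort of
#' interest ("APL"), a contrast cohort ("AML") and normal controls ("NBM"),
#' profiled for a panel of histone marks on a surrogate genome of two 20 Mb
#' autosomes binned at 1 kb.
#'
#' @param n_apl,n_aml,n_nbm samples per cohort (defaults 5, 9, 4).
#' @param marks character vector of mark names (default [default_marks()]).
#' @param chrom_lengths named vector of surrogate chromosome lengths.
#' @param bin_size bin width in bp.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_apl = 5, n_aml = 9, n_nbm = 4,
                          marks = default_marks(),
                          chrom_lengths = c(chrA = 2e7, chrB = 2e7),
                          bin_size = 1000) {
  stopifnot(n_apl >= 2, n_aml >= 2, n_nbm >= 0)
  if (anyDuplicated(marks)) stop("mark names must be unique")
  samples <- data.frame(
    sample_id = c(sprintf("APL%02d", seq_len(n_apl)),
                  sprintf("AML%02d", seq_len(n_aml)),
                  if (n_nbm > 0) sprintf("NBM%02d", seq_len(n_nbm))),
    cohort = c(rep("APL", n_apl), rep("AML", n_aml), rep("NBM", n_nbm)),
    stringsAsFactors = FALSE
  )
  structure(list(n_apl = n_apl, n_aml = n_aml, n_nbm = n_nbm,
                 marks = marks, layout = genome_layout(chrom_lengths, bin_size),
                 samples = samples),
            class = "cohort_design")
}

#' Planted-effect specification
#'
#' Defines the ground truth planted into the synthetic cohort: APL-specific
#' enhancer gains on H3K27ac (including clusters that stitch into
#' super-enhancers), fusion-protein binding sites, H3K9me3 gains in
#' LAD-annotated heterochromatin with a target transposable-element overlap
#' fraction, H3K27me3 gains over a HOX-like gene cluster with matched
#' expression repression, enhancer-gene links sharing a latent activity
#' factor, and one cross-breakpoint ("hijacked") enhancer-gene link.
#'
#' @param n_specific_enhancers total APL-specific enhancers (clustered +
#'   singleton).
#' @param enhancer_log2fc planted log2 effect on H3K27ac in the APL cohort.
#' @param n_se_clusters,se_cluster_size clusters of `se_cluster_size`
#'   enhancers within one 12.5 kb stitching span (counted inside
#'   `n_specific_enhancers`).
#' @param frac_enhancers_fusion_bound fraction of planted specific enhancers
#'   containing a fusion-protein binding site.
#' @param n_h3k9me3_lad_gains planted H3K9me3 gain regions in LAD-annotated
#'   heterochromatin.
#' @param te_overlap_target fraction of H3K9me3 gains overlapping a TE.
#' @param h3k9me3_log2fc,h3k27me3_log2fc planted log2 effects for the
#'   repressive marks.
#' @param n_h3k27me3_gains H3K27me3 gain regions over the HOX-like cluster
#'   (one per cluster gene).
#' @param hox_expression_log2fc planted expression effect for HOX-like genes
#'   in APL (negative: repression).
#' @param n_linked_genes planted enhancer-gene correlation links.
#' @param linked_gene_r_target target sample-level Pearson correlation of a
#'   planted link.
#' @param linked_gene_log2fc planted expression effect for linked genes.
#' @param hijack list with breakpoint coordinates (`chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`) and the analysis `flank` in bp.
#' @param nb_dispersion negative-binomial dispersion of the count noise.
#' @param n_shared_enhancers,n_shared_clusters,shared_cluster_size background
#'   enhancers active in all cohorts (the non-specific enhancer landscape).
#' @param n_fusion_sites total fusion-protein binding sites.
#' @param fusion_tss_frac fraction of fusion sites within 3 kb of a TSS.
#' @param n_background_de non-planted differentially expressed genes
#'   (split up/down) giving the expression contrast a realistic background.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n_specific_enhancers = 60, enhancer_log2fc = 2,
                       n_se_clusters = 8, se_cluster_size = 5,
                       frac_enhancers_fusion_bound = 0.3,
                       n_h3k9me3_lad_gains = 40, te_overlap_target = 0.7,
                       h3k9me3_log2fc = 2, h3k27me3_log2fc = 2,
                       n_h3k27me3_gains = 10, hox_expression_log2fc = -2,
                       n_linked_genes = 20, linked_gene_r_target = 0.85,
                       linked_gene_log2fc = 1.5,
                       hijack = list(chrom_a = "chrA", pos_a = 1e7,
                                     chrom_b = "chrB", pos_b = 1e7,
                                     flank = 2e6),
                       nb_dispersion = 0.1,
                       n_shared_enhancers = 200, n_shared_clusters = 6,
                       shared_cluster_size = 3,
                       n_fusion_sites = 200, fusion_tss_frac = 0.49,
                       n_background_de = 30) {
  n_clustered <- n_se_clusters * se_cluster_size
  if (n_clustered > n_specific_enhancers)
    stop("clustered enhancers exceed n_specific_enhancers")
  if (se_cluster_size < 3 && n_se_clusters > 0)
    stop("se_cluster_size must be >= 3")
  stopifnot(frac_enhancers_fusion_bound >= 0, frac_enhancers_fusion_bound <= 1,
            te_overlap_target >= 0, te_overlap_target <= 1,
            nb_dispersion > 0)
  structure(mget(names(formals())), class = "plant_spec")
}

## ---- placement machinery ---------------------------------------------------

new_allocator <- function(layout) {
  env <- new.env(parent = emptyenv())
  env$layout <- layout
  env$free <- lapply(layout$n_bins, function(n) rep(TRUE, n))
  names(env$free) <- layout$chrom
  env
}

# Sample one start bin (1-based, chromosome-local) for a span of `span` bins
# keeping `margin` free bins on each side; `ok` optionally restricts
# candidate bins. Returns NA if no slot exists.
alloc_span <- function(alloc, chrom, span, margin, ok = NULL) {
  f <- alloc$free[[chrom]]
  if (!is.null(ok)) f <- f & ok
  need <- span + 2L * margin
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (i in which(r$values & r$lengths >= need)) {
    cand <- c(cand, starts[i]:(ends[i] - need + 1L))
  }
  if (!length(cand)) return(NA_integer_)
  s <- cand[sample.int(length(cand), 1L)]
  occ <- s:(s + need - 1L)
  alloc$free[[chrom]][occ] <- FALSE
  s + margin
}

bins_to_interval <- function(layout, chrom, bin_start, n_bin) {
  bs <- layout$bin_size
  c(start = (bin_start - 1) * bs, end = (bin_start - 1 + n_bin) * bs)
}

# mark a bp interval (plus margin bins) as occupied
occupy <- function(alloc, chrom, start, end, margin = 2L) {
  bs <- alloc$layout$bin_size
  nb <- length(alloc$free[[chrom]])
  lo <- max(1L, floor(start / bs) + 1L - margin)
  hi <- min(nb, floor((end - 1) / bs) + 1L + margin)
  alloc$free[[chrom]][lo:hi] <- FALSE
}

## ---- genome + plant layout -------------------------------------------------

#' Generate the synthetic genome, annotations and planted layout
#'
#' Lays out a gene annotation (~800 genes including a 10-gene HOX-like
#' cluster), LAD, TE and CpG tracks, all planted elements (enhancers,
#' repressive-mark gain regions, fusion-protein binding sites,
#' enhancer-gene links, the hijack breakpoint pair) and the machine-readable
#' truth table. Planted element placement and the annotation tracks are
#' generated jointly so constraints such as the TE-overlap fraction of
#' H3K9me3 gains are realized exactly. Deterministic given `seed`.
#'
#' @param design a [cohort_design()].
#' @param plant a [plant_spec()].
#' @param seed integer seed.
#' @return an object of class `cohort_scaffold` with components `layout`,
#'   `genes`, `tracks` (te, lad, cpg, fusion_sites), `elements`, `links`,
#'   `truth`.
#' @export
generate_genome <- function(design, plant = plant_spec(), seed = 1) {
  set.seed(seed)
  layout <- design$layout
  bs <- layout$bin_size
  stopifnot(bs == 1000)  # the study design is 1 kb resolution

  hox_zone <- c(15.0e6, 15.3e6)  # reserved on the first chromosome
  alloc <- new_allocator(layout)

  ## LADs stay clear of the breakpoint windows and the HOX zone
  lad_ok <- lapply(layout$n_bins, function(n) rep(TRUE, n))
  names(lad_ok) <- layout$chrom
  hj <- plant$hijack
  win <- function(ch, lo, hi) {
    nb <- layout$n_bins[chrom_index(layout, ch)]
    lo <- max(1L, floor(lo / bs) + 1L); hi <- min(nb, ceiling(hi / bs))
    seq.int(lo, hi)
  }
  lad_ok[[hj$chrom_a]][win(hj$chrom_a, hj$pos_a - hj$flank - 5e5, hj$pos_a + hj$flank + 5e5)] <- FALSE
  lad_ok[[hj$chrom_b]][win(hj$chrom_b, hj$pos_b - hj$flank - 5e5, hj$pos_b + hj$flank + 5e5)] <- FALSE
  lad_ok[[layout$chrom[1]]][win(layout$chrom[1], hox_zone[1] - 2e5, hox_zone[2] + 2e5)] <- FALSE

  ## -- LAD cores (constitutive heterochromatin; gene-free) --------------
  lad_rows <- list()
  for (ci in seq_along(layout$chrom)) {
    ch <- layout$chrom[ci]
    for (k in 1:3) {
      span <- as.integer(round(stats::runif(1, 1000, 2000)))  # 1-2 Mb
      s <- alloc_span(alloc, ch, span, margin = 200L, ok = lad_ok[[ch]])
      if (is.na(s)) next
      iv <- bins_to_interval(layout, ch, s, span)
      lad_rows[[length(lad_rows) + 1L]] <-
        data.frame(chrom = ch, start = iv["start"], end = iv["end"],
                   kind = "core", stringsAsFactors = FALSE)
    }
  }
  lad_core <- do.call(rbind, lad_rows)

  ## -- LAD extensions carrying the planted H3K9me3 gains ----------------
  n_gain <- plant$n_h3k9me3_lad_gains
  ext_rows <- list(); gain_rows <- list()
  for (g in seq_len(n_gain)) {
    ch <- layout$chrom[(g %% length(layout$chrom)) + 1L]
    s <- alloc_span(alloc, ch, 30L, margin = 8L, ok = lad_ok[[ch]])
    if (is.na(s)) stop("could not place H3K9me3 gain region ", g)
    off <- sample(4:24, 1)
    iv <- bins_to_interval(layout, ch, s, 30L)
    gv <- bins_to_interval(layout, ch, s + off, 3L)
    ext_rows[[g]] <- data.frame(chrom = ch, start = iv["start"], end = iv["end"],
                                kind = "extension", stringsAsFactors = FALSE)
    gain_rows[[g]] <- data.frame(id = sprintf("k9gain%02d", g), chrom = ch,
                                 start = gv["start"], end = gv["end"],
                                 stringsAsFactors = FALSE)
  }
  lad_ext <- do.call(rbind, ext_rows)
  k9_gains <- do.call(rbind, gain_rows)
  k9_gains$te_overlap <- seq_len(n_gain) %in%
    sample.int(n_gain, round(plant$te_overlap_target * n_gain))

  ## -- genes (kept out of LADs, which are gene-poor) ---------------------
  lad_all_df <- rbind(lad_core[, c("chrom", "start", "end")],
                      lad_ext[, c("chrom", "start", "end")])
  genes <- list()
  gi <- 0L
  for (ci in seq_along(layout$chrom)) {
    ch <- layout$chrom[ci]
    L <- layout$length[ci]
    lads <- lad_all_df[lad_all_df$chrom == ch, , drop = FALSE]
    lads <- lads[order(lads$start), ]
    p <- 6e4
    while (TRUE) {
      len <- round(exp(stats::rnorm(1, log(18e3), 0.8)))
      len <- min(max(len, 2e3), 1e5)
      if (p + len > L - 6e4) break
      hit <- which(lads$start < p + len + 5e3 & lads$end > p - 5e3)
      if (length(hit)) { p <- max(lads$end[hit]) + 5e3; next }
      in_hox <- ci == 1 && p + len > hox_zone[1] - 5e4 && p < hox_zone[2] + 5e4
      if (!in_hox) {
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          gene_id = sprintf("G%04d", gi), gene_name = sprintf("G%04d", gi),
          chrom = ch, strand = sample(c("+", "-"), 1),
          start = p, end = p + len, stringsAsFactors = FALSE)
      }
      gap <- round(exp(stats::rnorm(1, log(22e3), 0.7)))
      p <- p + len + min(max(gap, 4e3), 1.5e5)
    }
  }
  genes <- do.call(rbind, genes)
  ## HOX-like cluster: 10 compact co-regulated genes
  n_hox <- plant$n_h3k27me3_gains
  hox <- data.frame(
    gene_id = sprintf("GHOX%02d", seq_len(n_hox)),
    gene_name = sprintf("HOXL%d", seq_len(n_hox)),
    chrom = layout$chrom[1], strand = "+",
    start = hox_zone[1] + (seq_len(n_hox) - 1) * 25e3,
    end = hox_zone[1] + (seq_len(n_hox) - 1) * 25e3 + 8e3,
    stringsAsFactors = FALSE)
  genes <- rbind(genes, hox)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  genes$length <- genes$end - genes$start
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL

  ## enhancers stay clear of promoters
  enh_ok <- lapply(layout$n_bins, function(n) rep(TRUE, n))
  names(enh_ok) <- layout$chrom
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    b <- floor(genes$tss[i] / bs) + 1L
    lo <- max(1L, b - 5L); hi <- min(layout$n_bins[chrom_index(layout, ch)], b + 5L)
    enh_ok[[ch]][lo:hi] <- FALSE
  }

  ## -- constitutive Polycomb domains (silent genes) ---------------------
  ## broad H3K27me3 over the body of transcriptionally silent genes; these
  ## carry no cohort effect and are the null family of the Polycomb
  ## differential analysis
  non_hox <- which(!grepl("^GHOX", genes$gene_id))
  silent_idx <- sample(non_hox, 30)
  pcg_rows <- lapply(silent_idx, function(i) {
    b <- floor(genes$tss[i] / bs) + 1L
    nb <- layout$n_bins[chrom_index(layout, genes$chrom[i])]
    nbody <- max(3L, min(15L, ceiling(genes$length[i] / bs)))
    lo <- max(1L, b - 1L); hi <- min(nb, b + nbody)
    data.frame(chrom = genes$chrom[i], start = (lo - 1) * bs, end = hi * bs,
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  })
  pcg_const <- do.call(rbind, pcg_rows)

  ## -- HOX-like H3K27me3 gain domains (one per cluster gene) ------------
  ## the whole gene domain gains the mark in APL, so each gene yields its
  ## own Polycomb-state segment
  hox_idx <- which(grepl("^GHOX", genes$gene_id))
  k27_gains <- do.call(rbind, lapply(seq_along(hox_idx), function(j) {
    i <- hox_idx[j]
    b <- floor(genes$tss[i] / bs) + 1L
    data.frame(id = sprintf("k27gain%02d", j), chrom = genes$chrom[i],
               start = (b - 2) * bs, end = (b + 9) * bs,
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }))

  for (i in seq_len(nrow(pcg_const)))
    occupy(alloc, pcg_const$chrom[i], pcg_const$start[i], pcg_const$end[i])
  for (i in seq_len(nrow(k27_gains)))
    occupy(alloc, k27_gains$chrom[i], k27_gains$start[i], k27_gains$end[i])

  ## -- enhancer units ---------------------------------------------------
  enh_rows <- list()
  add_unit <- function(kind, cluster_id, n_enh, level, apl_fold, within_ok = NULL) {
    span <- (n_enh - 1L) * 3L + 2L
    repeat {
      ch <- sample(layout$chrom, 1)
      ok <- enh_ok[[ch]]
      if (!is.null(within_ok)) {
        if (!is.null(within_ok[[ch]])) ok <- ok & within_ok[[ch]] else next
      }
      s <- alloc_span(alloc, ch, span, margin = 16L, ok = ok)
      if (!is.na(s)) break
    }
    for (e in seq_len(n_enh)) {
      b0 <- s + (e - 1L) * 3L
      iv <- bins_to_interval(layout, ch, b0, 2L)
      enh_rows[[length(enh_rows) + 1L]] <<- data.frame(
        id = sprintf("enh%03d", length(enh_rows) + 1L),
        chrom = ch, start = iv["start"], end = iv["end"],
        kind = kind, cluster_id = cluster_id, level = level,
        apl_fold = apl_fold, stringsAsFactors = FALSE)
    }
  }
  spec_fold <- 2^plant$enhancer_log2fc
  for (k in seq_len(plant$n_se_clusters))
    add_unit("specific_cluster", sprintf("secl%02d", k), plant$se_cluster_size,
             4 * exp(stats::rnorm(1, 0, 0.15)), spec_fold)
  n_spec_single <- plant$n_specific_enhancers -
    plant$n_se_clusters * plant$se_cluster_size
  for (k in seq_len(n_spec_single))
    add_unit("specific_single", NA_character_, 1L,
             6 * exp(stats::rnorm(1, 0, 0.3)), spec_fold)
  for (k in seq_len(plant$n_shared_clusters))
    add_unit("shared_cluster", sprintf("shcl%02d", k), plant$shared_cluster_size,
             exp(stats::rnorm(1, log(25), 0.45)), 1)
  for (k in seq_len(plant$n_shared_enhancers))
    add_unit("shared_single", NA_character_, 1L,
             exp(stats::rnorm(1, log(25), 0.45)), 1)
  ## the hijacked enhancer sits inside the breakpoint flank on side A
  hjw <- lapply(layout$n_bins, function(n) rep(FALSE, n))
  names(hjw) <- layout$chrom
  hjw[[hj$chrom_a]][win(hj$chrom_a, hj$pos_a - hj$flank + 1e5, hj$pos_a - 1e5)] <- TRUE
  add_unit("hijack", NA_character_, 1L, 4 * exp(stats::rnorm(1, 0, 0.15)),
           spec_fold, within_ok = hjw)
  enhancers <- do.call(rbind, enh_rows)
  rownames(enhancers) <- NULL

  ## -- enhancer-gene links ----------------------------------------------
  spec_single_ids <- enhancers$id[enhancers$kind == "specific_single"]
  link_enh <- sample(spec_single_ids, min(plant$n_linked_genes, length(spec_single_ids)))
  used_genes <- character(0)  # each planted link gets its own gene
  pick_gene <- function(eid, lo = 3e4, hi = 9e5) {
    e <- enhancers[enhancers$id == eid, ]
    ref <- (e$start + e$end) / 2
    cand <- genes[genes$chrom == e$chrom & !grepl("^GHOX", genes$gene_id) &
                    !genes$gene_id %in% used_genes, ]
    d <- abs(cand$tss - ref)
    cand <- cand[d >= lo & d <= hi, ]
    if (!nrow(cand)) stop("no candidate gene for link at ", eid)
    cand$gene_id[which.min(abs(cand$tss - ref))]
  }
  cis_genes <- character(length(link_enh))
  for (i in seq_along(link_enh)) {
    cis_genes[i] <- pick_gene(link_enh[i])
    used_genes <- c(used_genes, cis_genes[i])
  }
  links <- data.frame(enhancer_id = link_enh, gene_id = cis_genes,
                      kind = "cis", stringsAsFactors = FALSE)
  ## hijack link: enhancer on side A, gene on side B of the breakpoint
  hj_enh <- enhancers$id[enhancers$kind == "hijack"]
  bgenes <- genes[genes$chrom == hj$chrom_b &
                    abs(genes$tss - hj$pos_b) <= hj$flank - 1e5 &
                    abs(genes$tss - hj$pos_b) >= 2e5 &
                    !grepl("^GHOX", genes$gene_id) &
                    !genes$gene_id %in% used_genes, ]
  if (!nrow(bgenes)) stop("no candidate hijack gene on side B")
  hj_gene <- bgenes$gene_id[which.min(abs(bgenes$tss - (hj$pos_b + 6e5)))]
  links <- rbind(links, data.frame(enhancer_id = hj_enh, gene_id = hj_gene,
                                   kind = "hijack", stringsAsFactors = FALSE))
  links$r_target <- plant$linked_gene_r_target
  links$gene_log2fc <- plant$linked_gene_log2fc

  ## -- background differentially expressed genes ------------------------
  reserved <- unique(c(links$gene_id, genes$gene_id[silent_idx],
                       genes$gene_id[hox_idx]))
  pool <- setdiff(genes$gene_id, reserved)
  bg_de <- sample(pool, plant$n_background_de)
  de_genes <- data.frame(gene_id = bg_de,
                         log2fc = rep(c(1.5, -1.5), length.out = length(bg_de)),
                         stringsAsFactors = FALSE)

  ## -- transposable elements --------------------------------------------
  te_classes <- c("LINE", "SINE", "LTR", "DNA")
  te_probs <- c(0.35, 0.3, 0.2, 0.15)
  subfam_of <- function(cl) switch(cl,
    LINE = sample(c("L1", "L2"), 1, prob = c(0.8, 0.2)),
    SINE = sample(c("Alu", "MIR"), 1, prob = c(0.8, 0.2)),
    LTR = sample(c("ERV1", "ERVK", "ERVL"), 1, prob = c(0.45, 0.35, 0.2)),
    DNA = "hAT")
  n_te_bg <- 2500; n_te_lad <- 800
  rand_te <- function(n, chrom, lo, hi) {
    len <- round(exp(stats::rnorm(n, log(1200), 0.7)))
    len <- pmin(pmax(len, 200), 8000)
    start <- round(stats::runif(n, lo, hi - len))
    cl <- sample(te_classes, n, replace = TRUE, prob = te_probs)
    data.frame(chrom = chrom, start = start, end = start + len,
               class = cl, subfamily = vapply(cl, subfam_of, ""),
               stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, lapply(seq_along(layout$chrom), function(ci)
    rand_te(round(n_te_bg / length(layout$chrom)), layout$chrom[ci],
            0, layout$length[ci])))
  lad_te <- do.call(rbind, lapply(seq_len(nrow(lad_core)), function(i)
    rand_te(round(n_te_lad / nrow(lad_core)), lad_core$chrom[i],
            lad_core$start[i], lad_core$end[i])))
  te <- rbind(te, lad_te)
  ## keep the extension LADs TE-free so the planted overlap fraction is exact
  ext_set <- interval_set(lad_ext[, c("chrom", "start", "end")])
  te <- te[!overlaps_any(interval_set(te[, c("chrom", "start", "end")]), ext_set), ]
  planted_te <- do.call(rbind, lapply(which(k9_gains$te_overlap), function(i) {
    cl <- sample(c("LINE", "SINE", "LTR"), 1, prob = c(0.35, 0.3, 0.35))
    data.frame(chrom = k9_gains$chrom[i],
               start = k9_gains$start[i] + 500,
               end = k9_gains$start[i] + 2000,
               class = cl, subfamily = subfam_of(cl), stringsAsFactors = FALSE)
  }))
  te <- rbind(te, planted_te)
  te <- te[order(te$chrom, te$start), ]
  te_set <- interval_set(data.frame(chrom = te$chrom, start = te$start,
                                    end = te$end,
                                    name = paste0(te$subfamily, ":", te$class)))

  ## -- CpG islands -------------------------------------------------------
  cpg_idx <- sample(seq_len(nrow(genes)), round(0.6 * nrow(genes)))
  cpg <- interval_set(data.frame(
    chrom = genes$chrom[cpg_idx],
    start = pmax(0, genes$tss[cpg_idx] - 500),
    end = genes$tss[cpg_idx] + 500))

  ## -- fusion-protein binding sites --------------------------------------
  spec_all <- enhancers[enhancers$kind %in%
                          c("specific_single", "specific_cluster", "hijack"), ]
  n_bound <- round(plant$frac_enhancers_fusion_bound * nrow(spec_all))
  bound_enh <- if (n_bound > 0) sample(spec_all$id, n_bound) else character(0)
  enhancers$fusion_bound <- enhancers$id %in% bound_enh
  site_rows <- lapply(bound_enh, function(eid) {
    e <- enhancers[enhancers$id == eid, ]
    mid <- (e$start + e$end) / 2
    data.frame(chrom = e$chrom, start = mid - 300, end = mid + 300,
               kind = "enhancer", stringsAsFactors = FALSE)
  })
  n_tss <- round(plant$fusion_tss_frac * plant$n_fusion_sites)
  tss_pick <- sample(seq_len(nrow(genes)), n_tss)
  site_rows <- c(site_rows, lapply(tss_pick, function(i) {
    off <- round(stats::rnorm(1, 0, 900)); off <- min(max(off, -2300), 2300)
    s <- max(0, genes$tss[i] + off - 300)
    data.frame(chrom = genes$chrom[i], start = s, end = s + 600,
               kind = "tss", stringsAsFactors = FALSE)
  }))
  n_dist <- plant$n_fusion_sites - n_tss - length(bound_enh)
  d <- 0L
  while (d < n_dist) {
    ch <- sample(layout$chrom, 1)
    s <- alloc_span(alloc, ch, 1L, margin = 2L, ok = enh_ok[[ch]])
    if (is.na(s)) next
    iv <- bins_to_interval(layout, ch, s, 1L)
    site_rows[[length(site_rows) + 1L]] <-
      data.frame(chrom = ch, start = iv["start"] + 200, end = iv["start"] + 800,
                 kind = "distal", stringsAsFactors = FALSE)
    d <- d + 1L
  }
  sites <- do.call(rbind, site_rows)
  fusion_sites <- interval_set(data.frame(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = sprintf("site%03d_%s", seq_len(nrow(sites)), sites$kind)))

  ## -- truth table -------------------------------------------------------
  spec_enh <- enhancers[enhancers$kind %in%
                          c("specific_single", "specific_cluster", "hijack"), ]
  truth <- rbind(
    data.frame(id = spec_enh$id, kind = "enhancer", chrom = spec_enh$chrom,
               start = spec_enh$start, end = spec_enh$end, mark = "H3K27ac",
               direction = "gain", effect_log2 = plant$enhancer_log2fc,
               gene_id = NA_character_, r_target = NA_real_,
               fusion_bound = spec_enh$fusion_bound, stringsAsFactors = FALSE),
    do.call(rbind, lapply(split(spec_enh[spec_enh$kind == "specific_cluster", ],
                                spec_enh$cluster_id[spec_enh$kind == "specific_cluster"]),
                          function(cl) data.frame(
      id = cl$cluster_id[1], kind = "se_cluster", chrom = cl$chrom[1],
      start = min(cl$start), end = max(cl$end), mark = "H3K27ac",
      direction = "gain", effect_log2 = plant$enhancer_log2fc,
      gene_id = NA_character_, r_target = NA_real_,
      fusion_bound = any(cl$fusion_bound), stringsAsFactors = FALSE))),
    data.frame(id = k9_gains$id, kind = "h3k9me3_gain", chrom = k9_gains$chrom,
               start = k9_gains$start, end = k9_gains$end, mark = "H3K9me3",
               direction = "gain", effect_log2 = plant$h3k9me3_log2fc,
               gene_id = NA_character_, r_target = NA_real_,
               fusion_bound = FALSE, stringsAsFactors = FALSE),
    data.frame(id = k27_gains$id, kind = "h3k27me3_gain", chrom = k27_gains$chrom,
               start = k27_gains$start, end = k27_gains$end, mark = "H3K27me3",
               direction = "gain", effect_log2 = plant$h3k27me3_log2fc,
               gene_id = k27_gains$gene_id, r_target = NA_real_,
               fusion_bound = FALSE, stringsAsFactors = FALSE),
    data.frame(id = paste0("link_", links$enhancer_id),
               kind = ifelse(links$kind == "hijack", "hijack_link", "link"),
               chrom = enhancers$chrom[match(links$enhancer_id, enhancers$id)],
               start = enhancers$start[match(links$enhancer_id, enhancers$id)],
               end = enhancers$end[match(links$enhancer_id, enhancers$id)],
               mark = "H3K27ac", direction = "gain",
               effect_log2 = plant$linked_gene_log2fc, gene_id = links$gene_id,
               r_target = links$r_target, fusion_bound = FALSE,
               stringsAsFactors = FALSE)
  )
  rownames(truth) <- NULL

  ## planted regions must be mutually disjoint
  planted <- interval_set(data.frame(
    chrom = c(enhancers$chrom, k9_gains$chrom, k27_gains$chrom),
    start = c(enhancers$start, k9_gains$start, k27_gains$start),
    end = c(enhancers$end, k9_gains$end, k27_gains$end)))
  if (any(count_overlaps(planted, planted) > 1))
    stop("internal error: planted regions overlap")

  lad_all <- rbind(lad_core[, c("chrom", "start", "end")],
                   lad_ext[, c("chrom", "start", "end")])
  lad_set <- interval_set(data.frame(lad_all,
                                     name = c(rep("LAD_core", nrow(lad_core)),
                                              rep("LAD_ext", nrow(lad_ext)))))

  structure(list(
    design = design, plant = plant, layout = layout, genes = genes,
    tracks = list(te = te_set, lad = lad_set, cpg = cpg,
                  fusion_sites = fusion_sites),
    elements = list(enhancers = enhancers, k9_gains = k9_gains,
                    k27_gains = k27_gains, pcg_const = pcg_const,
                    lad_core = lad_core, lad_ext = lad_ext,
                    silent_genes = genes$gene_id[silent_idx],
                    de_genes = de_genes, hijack = hj),
    links = links, truth = truth, seed = seed
  ), class = "cohort_scaffold")
}

## ---- signal ---------------------------------------------------------------

# Baseline per-bin expected counts for each mark at unit library factor.
# Active marks are promoter/enhancer elevated, H3K9me2/3 LAD-elevated and
# H3K27me3 Polycomb-elevated; values chosen to give realistic binarization
# rates and differential power at ChIP-seq-like depth on the surrogate genome.
mark_rate_profile <- function(scaffold) {
  layout <- scaffold$layout
  nb <- n_bins(layout)
  marks <- scaffold$design$marks
  bg <- c(H2AZ = 2, H3K4me1 = 2, H3K4me3 = 2, H3K9me2 = 3, H3K9me3 = 3,
          H3K18ac = 2, H3K27ac = 2, H3K27me3 = 2)
  rate <- sapply(marks, function(m) rep(unname(bg[m]), nb))
  apl_fold <- sapply(marks, function(m) rep(1, nb))
  set_rate <- function(mark, bins, value) {
    if (mark %in% marks) rate[bins, mark] <<- pmax(rate[bins, mark], value)
  }
  bin_range <- function(df) bins_of_intervals(layout, interval_set(
    data.frame(chrom = df$chrom, start = df$start, end = df$end)))

  genes <- scaffold$genes
  silent <- genes$gene_id %in% scaffold$elements$silent_genes
  tss_bins <- bin_of(layout, genes$chrom, genes$tss)
  prom <- unique(as.integer(outer(tss_bins[!silent], -1:1, `+`)))
  prom <- prom[prom >= 1 & prom <= nb]
  set_rate("H3K4me3", prom, 50); set_rate("H2AZ", prom, 35)
  set_rate("H3K18ac", prom, 25); set_rate("H3K27ac", prom, 18)
  set_rate("H3K4me1", prom, 12)

  enh <- scaffold$elements$enhancers
  for (i in seq_len(nrow(enh))) {
    b <- bin_range(enh[i, ])
    set_rate("H3K27ac", b, enh$level[i])
    set_rate("H3K4me1", b, 30); set_rate("H3K18ac", b, 10)
    set_rate("H2AZ", b, 8)
    if ("H3K27ac" %in% marks) apl_fold[b, "H3K27ac"] <- enh$apl_fold[i]
  }

  core_b <- bin_range(scaffold$elements$lad_core)
  set_rate("H3K9me3", core_b, 30); set_rate("H3K9me2", core_b, 20)
  ## gain regions are K9me2-premarked islands in LAD-annotated extensions
  ## (the extensions themselves carry no constitutive signal, so each gain
  ## yields its own heterochromatin-state segment in the APL decoding)
  k9_b <- bin_range(scaffold$elements$k9_gains)
  set_rate("H3K9me2", k9_b, 20)
  set_rate("H3K9me3", k9_b, 8)
  if ("H3K9me3" %in% marks)
    apl_fold[k9_b, "H3K9me3"] <- 2^scaffold$plant$h3k9me3_log2fc

  pcg_b <- bin_range(scaffold$elements$pcg_const)
  set_rate("H3K27me3", pcg_b, 25)
  k27_b <- bin_range(scaffold$elements$k27_gains)
  set_rate("H3K27me3", k27_b, 8)
  if ("H3K27me3" %in% marks)
    apl_fold[k27_b, "H3K27me3"] <- 2^scaffold$plant$h3k27me3_log2fc

  list(rate = rate, apl_fold = apl_fold)
}

# Latent-factor loading that realizes the target enhancer-gene Pearson r at
# the study's sample size, accounting for the count noise of both channels
# (at each link's planted enhancer level) and the cohort shift both share.
# Returns one loading per link.
solve_link_sigma <- function(scaffold) {
  plant <- scaffold$plant
  links <- scaffold$links
  enh <- scaffold$elements$enhancers
  n1 <- scaffold$design$n_apl; n2 <- scaffold$design$n_aml
  p <- n1 / (n1 + n2); pq <- p * (1 - p)
  de <- log(2) * plant$enhancer_log2fc
  dg <- log(2) * plant$linked_gene_log2fc
  phi <- plant$nb_dispersion
  mu_g <- 150                        # typical linked-gene mean count
  cv2_g <- (n2 * (1 / mu_g + phi) +
              n1 * (1 / (mu_g * 2^plant$linked_gene_log2fc) + phi)) / (n1 + n2)
  target <- plant$linked_gene_r_target
  vapply(seq_len(nrow(links)), function(l) {
    mu_e <- 2 * enh$level[enh$id == links$enhancer_id[l]]
    cv2_e <- (n2 * (1 / mu_e + phi) +
                n1 * (1 / (mu_e * 2^plant$enhancer_log2fc) + phi)) / (n1 + n2)
    r_of <- function(s) (s^2 + pq * de * dg) /
      sqrt((s^2 + cv2_e + pq * de^2) * (s^2 + cv2_g + pq * dg^2))
    if (r_of(0.01) >= target) return(0.01)
    if (r_of(4) <= target) return(4)
    stats::uniroot(function(s) r_of(s) - target, c(0.01, 4))$root
  }, 0)
}

#' Generate the multi-mark binned count tensor
#'
#' Draws per-sample, per-mark negative-binomial counts over the layout's
#' bins: `count ~ NB(mean = lib_s * rate_b * fold_cohort_b * latent,
#' dispersion)`. Planted effects multiply the APL-cohort mean by
#' `2^effect_log2`; planted enhancer-gene links share a per-sample latent
#' activity factor with their gene (drawn here and reused by
#' [generate_expression()]).
#'
#' @param scaffold a `cohort_scaffold` from [generate_genome()].
#' @param seed integer seed.
#' @param marks optional subset of marks to simulate (defaults to all).
#' @return an object of class `mark_tensor`: `counts` (named list of
#'   bins-by-samples integer matrices), `samples`, `lib_sizes`, `layout`,
#'   plus the latent link factors in `latent`.
#' @export
generate_signal <- function(scaffold, seed = 1, marks = NULL) {
  set.seed(seed)
  design <- scaffold$design
  if (is.null(marks)) marks <- design$marks
  stopifnot(all(marks %in% design$marks))
  samples <- design$samples
  ns <- nrow(samples)
  nb <- n_bins(scaffold$layout)
  prof <- mark_rate_profile(scaffold)
  disp <- scaffold$plant$nb_dispersion

  links <- scaffold$links
  sigma <- solve_link_sigma(scaffold)
  z <- matrix(stats::rnorm(nrow(links) * ns), nrow(links), ns,
              dimnames = list(links$enhancer_id, samples$sample_id))
  ## latent activity multiplier, normalized to cohort mean 1: the planted
  ## cohort fold stays exact while the per-sample covariation that drives
  ## the enhancer-gene correlation is preserved
  M <- exp(sweep(z, 1, sigma, `*`))
  for (co in unique(samples$cohort)) {
    idx <- samples$cohort == co
    if (sum(idx) > 1)
      M[, idx] <- M[, idx, drop = FALSE] / rowMeans(M[, idx, drop = FALSE])
  }

  is_apl <- samples$cohort == "APL"
  counts <- vector("list", length(marks)); names(counts) <- marks
  for (m in marks) {
    libfac <- exp(stats::rnorm(ns, 0, 0.15))
    mu <- matrix(prof$rate[, m], nb, ns) * rep(libfac, each = nb)
    if (any(is_apl)) {
      fold <- prof$apl_fold[, m]
      mu[, is_apl] <- mu[, is_apl] * fold
    }
    if (m == "H3K27ac" && nrow(links)) {
      for (l in seq_len(nrow(links))) {
        e <- scaffold$elements$enhancers[
          scaffold$elements$enhancers$id == links$enhancer_id[l], ]
        b <- bins_of_intervals(scaffold$layout, interval_set(
          data.frame(chrom = e$chrom, start = e$start, end = e$end)))
        mu[b, ] <- mu[b, ] * rep(M[l, ], each = length(b))
      }
    }
    cnt <- matrix(stats::rnbinom(nb * ns, mu = as.numeric(mu), size = 1 / disp),
                  nb, ns)
    colnames(cnt) <- samples$sample_id
    counts[[m]] <- cnt
  }
  lib_sizes <- vapply(counts, colSums, numeric(ns))
  structure(list(counts = counts, samples = samples,
                 lib_sizes = t(lib_sizes), layout = scaffold$layout,
                 latent = list(z = z, M = M, sigma = sigma)),
            class = "mark_tensor")
}

#' @export
print.mark_tensor <- function(x, ...) {
  cat("mark_tensor:", length(x$counts), "mark(s) x", nrow(x$samples),
      "sample(s) x", nrow(x$counts[[1]]), "bins\n")
  invisible(x)
}

#' Generate the expression count and RPKM matrices
#'
#' Negative-binomial gene counts for all samples. Planted effects: HOX-like
#' genes repressed in APL, linked genes share the latent activity factor of
#' their enhancer (drawn in [generate_signal()]) plus an APL expression
#' shift, background DE genes shifted up/down. RPKM is
#' `reads / (gene kb x library millions)`.
#'
#' @param scaffold a `cohort_scaffold`.
#' @param signal the `mark_tensor` from [generate_signal()] (provides the
#'   shared latent link factors).
#' @param seed integer seed.
#' @return list with `counts`, `rpkm` (genes x samples) and `samples`.
#' @export
generate_expression <- function(scaffold, signal, seed = 1) {
  set.seed(seed)
  genes <- scaffold$genes
  samples <- scaffold$design$samples
  ns <- nrow(samples); ng <- nrow(genes)
  disp <- scaffold$plant$nb_dispersion

  grp <- stats::runif(ng)
  base <- ifelse(grp < 0.15, exp(stats::rnorm(ng, log(0.02), 0.5)),
          ifelse(grp < 0.30, exp(stats::rnorm(ng, log(2), 0.6)),
                 exp(stats::rnorm(ng, log(150), 1.0))))
  base[genes$gene_id %in% scaffold$elements$silent_genes] <-
    exp(stats::rnorm(sum(genes$gene_id %in% scaffold$elements$silent_genes),
                     log(0.02), 0.5))
  ## linked, hijacked and HOX genes must be quantifiable
  special <- unique(c(scaffold$links$gene_id,
                      genes$gene_id[grepl("^GHOX", genes$gene_id)],
                      scaffold$elements$de_genes$gene_id))
  idx <- match(special, genes$gene_id)
  base[idx] <- pmax(base[idx], exp(stats::rnorm(length(idx), log(150), 0.4)))

  lfc <- rep(0, ng)
  lfc[grepl("^GHOX", genes$gene_id)] <- scaffold$plant$hox_expression_log2fc
  de <- scaffold$elements$de_genes
  lfc[match(de$gene_id, genes$gene_id)] <- de$log2fc
  lk <- scaffold$links
  lfc[match(lk$gene_id, genes$gene_id)] <- lk$gene_log2fc

  is_apl <- samples$cohort == "APL"
  libfac <- exp(stats::rnorm(ns, 0, 0.1))
  mu <- outer(base, libfac)
  mu[, is_apl] <- mu[, is_apl] * 2^lfc

  M <- signal$latent$M
  for (l in seq_len(nrow(lk))) {
    gi <- match(lk$gene_id[l], genes$gene_id)
    mu[gi, ] <- mu[gi, ] * M[lk$enhancer_id[l], ]
  }

  counts <- matrix(stats::rnbinom(ng * ns, mu = as.numeric(mu), size = 1 / disp),
                   ng, ns, dimnames = list(genes$gene_id, samples$sample_id))
  rpkm_mat <- rpkm(counts, genes$length, colSums(counts))
  list(counts = counts, rpkm = rpkm_mat, samples = samples)
}

#' Fusion-protein binding sites of the synthetic cohort
#'
#' The binding-site track is laid out jointly with the genome in
#' [generate_genome()] (a configured fraction of planted enhancers carries a
#' site, a TSS-proximal pool realizes the target fraction of sites within
#' 3 kb of a TSS); this accessor returns it as an `interval_set`.
#'
#' @param scaffold a `cohort_scaffold`.
#' @return an `interval_set` of binding sites.
#' @export
generate_fusion_sites <- function(scaffold) {
  scaffold$tracks$fusion_sites
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_genome()], [generate_signal()] and
#' [generate_expression()] with substream seeds derived from one global
#' seed.
#'
#' @param design a [cohort_design()].
#' @param plant a [plant_spec()].
#' @param seed global integer seed.
#' @param marks optional subset of marks for the signal tensor.
#' @return an object of class `synthetic_cohort`: `scaffold`, `tensor`,
#'   `expression`, `fusion_sites`, `truth`.
#' @export
simulate_cohort <- function(design = cohort_design(), plant = plant_spec(),
                            seed = 1, marks = NULL) {
  set.seed(seed)
  sub <- sample.int(2^30, 3)
  scaffold <- generate_genome(design, plant, seed = sub[1])
  tensor <- generate_signal(scaffold, seed = sub[2], marks = marks)
  expr <- generate_expression(scaffold, tensor, seed = sub[3])
  structure(list(scaffold = scaffold, tensor = tensor, expression = expr,
                 fusion_sites = scaffold$tracks$fusion_sites,
                 truth = scaffold$truth, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the standard-format snapshot of a simulated study: GTF gene models,
#' BED annotation tracks (TE with `subfamily:class` names, LADs, CpG,
#' fusion sites, planted elements), per-mark count TSVs (bin x sample),
#' expression counts/RPKM TSVs, chrom sizes, the JSON truth table and a JSON
#' config snapshot.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cohort$scaffold
  write_gtf_genes(sc$genes, file.path(dir, "genes.gtf"))
  write_bed(sc$tracks$te, file.path(dir, "te.bed"))
  write_bed(sc$tracks$lad, file.path(dir, "lad.bed"))
  write_bed(sc$tracks$cpg, file.path(dir, "cpg.bed"))
  write_bed(sc$tracks$fusion_sites, file.path(dir, "fusion_sites.bed"))
  write_chrom_sizes(sc$layout, file.path(dir, "chrom.sizes"))
  enh <- sc$elements$enhancers
  write_bed(interval_set(data.frame(chrom = enh$chrom, start = enh$start,
                                    end = enh$end, name = enh$id)),
            file.path(dir, "planted_enhancers.bed"))
  bt <- bin_table(sc$layout)
  for (m in names(cohort$tensor$counts)) {
    df <- data.frame(bin = paste0(bt$chrom, ":", bt$start, "-", bt$end),
                     cohort$tensor$counts[[m]], check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("counts_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(gene_id = rownames(cohort$expression$counts),
                                cohort$expression$counts, check.names = FALSE),
                     file.path(dir, "expression_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(cohort$expression$rpkm),
                                round(cohort$expression$rpkm, 4),
                                check.names = FALSE),
                     file.path(dir, "expression_rpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$tensor$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- list(seed = cohort$seed,
              design = unclass(sc$design)[c("n_apl", "n_aml", "n_nbm", "marks")],
              plant = unclass(sc$plant))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Synthetic enhancer sequences with planted motif occurrences
#'
#' 500 bp of synthetic DNA per planted-specific (target) and shared
#' (background) enhancer; a consensus motif occurrence is planted into a
#' configurable fraction of target sequences for validating the motif
#' enrichment stage.
#'
#' @param scaffold a `cohort_scaffold`.
#' @param frac_with_motif fraction of target sequences carrying the motif.
#' @param bg_frac fraction of background sequences carrying it.
#' @param seed integer seed.
#' @return list with `target` and `background` named sequence vectors and
#'   the planted `motifs` (MEME-style probability matrices).
#' @export
generate_enhancer_sequences <- function(scaffold, frac_with_motif = 0.5,
                                        bg_frac = 0.01, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- "TGACTCAG"
  pwm <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    p <- rep(0.04, 4); p[match(b, bases)] <- 0.88; p
  }, numeric(4)))
  colnames(pwm) <- bases
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE,
                                       prob = c(0.275, 0.225, 0.225, 0.275)),
                                collapse = "")
  plant_motif <- function(s) {
    pos <- sample.int(nchar(s) - nchar(consensus), 1)
    paste0(substr(s, 1, pos - 1), consensus,
           substr(s, pos + nchar(consensus), nchar(s)))
  }
  enh <- scaffold$elements$enhancers
  tgt_ids <- enh$id[enh$kind %in% c("specific_single", "specific_cluster", "hijack")]
  bg_ids <- enh$id[enh$kind %in% c("shared_single", "shared_cluster")]
  target <- stats::setNames(vapply(tgt_ids, function(i) rand_seq(500), ""), tgt_ids)
  background <- stats::setNames(vapply(bg_ids, function(i) rand_seq(500), ""), bg_ids)
  with_m <- sample(length(target), round(frac_with_motif * length(target)))
  target[with_m] <- vapply(target[with_m], plant_motif, "")
  bg_m <- sample(length(background), round(bg_frac * length(background)))
  if (length(bg_m)) background[bg_m] <- vapply(background[bg_m], plant_motif, "")
  list(target = target, background = background,
       motifs = list(SYN_TGACTCAG = pwm))
}
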