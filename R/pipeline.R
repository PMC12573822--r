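#' Default pipeline configuration
#'
#' One structured list holding every stage parameter (all defaults named in
#' the stage functions), the cohort design, the plant specification and the
#' global seed. Unknown keys passed to [run_pipeline()] are rejected.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    design = list(n_apl = 5, n_aml = 9, n_nbm = 4, marks = default_marks(),
                  chrom_lengths = c(chrA = 2e7, chrB = 2e7), bin_size = 1000),
    plant = as.list(unclass(plant_spec())),
    chromstate = list(K = 8, n_restarts = 3, tol = 1e-4, max_iter = 200,
                      binarize_p = 1e-4, emission_min = 0.3),
    screen = list(top_n = 2000, offset = 0, n_resamples = 100,
                  item_subsample_fraction = 0.8, k_range = 2:5),
    diff = list(p_cut = 0.05, lfc_cut = 1),
    enhancers = list(min_tss_dist = 500, stitch_gap = 12500,
                     tss_exclusion = 500),
    linkage = list(window = 1e6, r_min = 0.7, p_max = 0.01, star_p = 0.05),
    hetero = list(het_labels = c("HetLADS", "Het"), pcg_labels = "ReprPcG"),
    dependency_scores = NULL
  )
}

merge_config <- function(user, defaults = default_config(), path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, "$", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys must be a subset of [default_config()].
#' @return full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$design$chrom_lengths))
    user$design$chrom_lengths <- unlist(user$design$chrom_lengths)
  merge_config(user)
}

log_stage <- function(stage, t0) {
  message(sprintf("[%s] %-12s %6.1fs", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0))
}

#' Run the full cohort-contrast pipeline
#'
#' Simulates the synthetic cohort, learns and decodes chromatin states,
#' runs the mark/state separation screen, calls cohort-specific enhancers
#' and super-enhancers, links enhancers and super-enhancers to genes,
#' computes the cross-breakpoint hijack grid, profiles repressive-mark gains
#' against TEs/LADs, and assembles the truth-recovery report.
#'
#' @param config configuration list (see [default_config()]); partial lists
#'   are merged with the defaults, unknown keys rejected.
#' @param out_dir optional output directory for TSV/BED/JSON artifacts.
#' @return a `pipeline_result` list with all stage outputs and `report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- merge_config(config)
  t0 <- as.numeric(Sys.time())
  set.seed(cfg$seed)
  sub <- sample.int(2^30, 8)

  design <- cohort_design(n_apl = cfg$design$n_apl, n_aml = cfg$design$n_aml,
                          n_nbm = cfg$design$n_nbm, marks = cfg$design$marks,
                          chrom_lengths = cfg$design$chrom_lengths,
                          bin_size = cfg$design$bin_size)
  plant <- do.call(plant_spec, cfg$plant)
  cohort <- simulate_cohort(design, plant, seed = sub[1])
  layout <- cohort$scaffold$layout
  genes <- cohort$scaffold$genes
  log_stage("simulate", t0)

  ## chromatin states: joint learning on cohort-pooled binarized tracks,
  ## per-cohort decoding
  binarized <- binarize_cohorts(cohort$tensor, cfg$chromstate$binarize_p)
  seqs <- unlist(lapply(binarized, function(B)
    lapply(seq_along(layout$chrom), function(ci)
      B[layout$offset[ci] + seq_len(layout$n_bins[ci]), , drop = FALSE])),
    recursive = FALSE)
  model <- baum_welch_train(seqs, K = cfg$chromstate$K, seed = sub[2],
                            n_restarts = cfg$chromstate$n_restarts,
                            tol = cfg$chromstate$tol,
                            max_iter = cfg$chromstate$max_iter)
  labels <- assign_state_labels(model)
  segs <- lapply(binarized, function(B)
    decode_segmentation(model, B, layout, labels))
  seg_apl <- segs[["APL"]]; seg_aml <- segs[["AML"]]
  log_stage("chromstate", t0)

  ## separation screen + state jaccard
  combos <- default_screen_combos(model, labels, cfg$chromstate$emission_min)
  scr_cfg <- consensus_config(top_n = cfg$screen$top_n,
                              offset = cfg$screen$offset,
                              n_resamples = cfg$screen$n_resamples,
                              item_subsample_fraction = cfg$screen$item_subsample_fraction,
                              k_range = cfg$screen$k_range, seed = sub[3])
  screen <- run_screen(cohort$tensor, seg_apl, combos, scr_cfg)
  jaccard <- cohort_state_jaccard(seg_apl, seg_aml)
  log_stage("screen", t0)

  ## differential H3K27ac on active-enhancer-state segments -> enhancer calls
  use <- design$samples$cohort %in% c("APL", "AML")
  use_ids <- design$samples$sample_id[use]
  group <- factor(design$samples$cohort[use], levels = c("AML", "APL"))
  enh_segs <- segments_of_label_class(seg_apl, "EnhActive")
  if (nrow(enh_segs) == 0L) stop("no active-enhancer state learned")
  k27_counts <- region_counts(layout, cohort$tensor$counts$H3K27ac[, use_ids],
                              enh_segs)
  rownames(k27_counts) <- paste0(enh_segs$chrom, ":", enh_segs$start, "-",
                                 enh_segs$end)
  norm <- tmm_factors(k27_counts,
                      lib_sizes = colSums(cohort$tensor$counts$H3K27ac[, use_ids]))
  diff_enh <- nb_wald_test(k27_counts, norm, group)
  attr(diff_enh, "segments") <- enh_segs
  calls <- call_specific_enhancers(diff_enh, genes,
                                   min_tss_dist = cfg$enhancers$min_tss_dist,
                                   p_cut = cfg$diff$p_cut,
                                   lfc_cut = cfg$diff$lfc_cut)
  log_stage("enhancers", t0)

  ## ROSE super-enhancers per cohort, unique SEs
  rose_one <- function(seg, cohort_label) {
    peaks <- segments_of_label_class(seg, "EnhActive")
    st <- rose_stitch(peaks, genes, stitch_gap = cfg$enhancers$stitch_gap,
                      tss_exclusion = cfg$enhancers$tss_exclusion)
    sc <- se_signal_score(cohort$tensor, st, "H3K27ac", cohort_label)
    curve <- rose_rank_and_cutoff(st, sc)
    st$score <- sc
    st$is_super <- curve$is_super
    list(stitched = st, curve = curve,
         super = interval_set(as.data.frame(st[st$is_super, , drop = FALSE])))
  }
  rose_apl <- rose_one(seg_apl, "APL")
  rose_aml <- rose_one(seg_aml, "AML")
  unique_se <- cohort_unique_super_enhancers(rose_apl$super, rose_aml$super,
                                             calls)
  fusion <- fusion_overlap(calls, cohort$fusion_sites, genes, seg_apl)
  log_stage("rose", t0)

  ## enhancer-gene and SE-gene linkage, hijack grid
  rpkm_expr <- cohort$expression$rpkm[, use_ids]
  enh_signal <- if (nrow(calls)) {
    m <- region_counts(layout, cohort$tensor$counts$H3K27ac[, use_ids], calls)
    kb <- (calls$end - calls$start) / 1000
    m <- m / (kb %o% (colSums(cohort$tensor$counts$H3K27ac[, use_ids]) / 1e6))
    colnames(m) <- use_ids
    m
  } else matrix(numeric(0), 0, length(use_ids),
                dimnames = list(NULL, use_ids))
  links <- guilt_by_association(enh_signal, calls, rpkm_expr, genes,
                                window = cfg$linkage$window,
                                r_min = cfg$linkage$r_min,
                                p_max = cfg$linkage$p_max)
  se_signal <- if (nrow(unique_se)) {
    m <- region_counts(layout, cohort$tensor$counts$H3K27ac[, use_ids],
                       unique_se)
    kb <- (unique_se$end - unique_se$start) / 1000
    m <- m / (kb %o% (colSums(cohort$tensor$counts$H3K27ac[, use_ids]) / 1e6))
    colnames(m) <- use_ids
    m
  } else matrix(numeric(0), 0, length(use_ids),
                dimnames = list(NULL, use_ids))
  se_links <- se_gene_association(se_signal, unique_se, rpkm_expr, genes,
                                  fusion_sites = cohort$fusion_sites,
                                  window = cfg$linkage$window,
                                  r_min = cfg$linkage$r_min,
                                  p_max = cfg$linkage$p_max)
  hj <- cohort$scaffold$elements$hijack
  hijack <- hijack_matrix(calls, enh_signal, rpkm_expr, genes,
                          breakpoint = hj, star_p = cfg$linkage$star_p)
  dependency <- NULL
  if (!is.null(cfg$dependency_scores)) {
    scores <- utils::read.delim(cfg$dependency_scores, stringsAsFactors = FALSE)
    dependency <- dependency_join(unique(se_links$gene_id), scores)
  }
  log_stage("linkage", t0)

  ## gene-level differential expression (for crosstabs and link annotation)
  expr_counts <- cohort$expression$counts[, use_ids]
  expr_counts <- expr_counts[rowSums(expr_counts) > 0, , drop = FALSE]
  de <- nb_wald_test(expr_counts, tmm_factors(expr_counts), group)
  de <- classify(de, p_cut = 0.05, lfc_cut = 0)

  ## heterochromatin / Polycomb gains and TE overlap
  hetero_one <- function(mark, label_classes) {
    segs_m <- do.call(rbind, lapply(label_classes, function(lc)
      as.data.frame(segments_of_label_class(seg_apl, lc))))
    segs_m <- segs_m[!duplicated(segs_m[, c("chrom", "start", "end")]), ,
                     drop = FALSE]
    if (is.null(segs_m) || !nrow(segs_m)) return(NULL)
    segs_m <- interval_set(segs_m)
    cnt <- region_counts(layout, cohort$tensor$counts[[mark]][, use_ids], segs_m)
    rownames(cnt) <- paste0(segs_m$chrom, ":", segs_m$start, "-", segs_m$end)
    ## library-size normalization: most segments of these families carry the
    ## cohort effect, which violates TMM's majority-null assumption
    nr <- colSums(cohort$tensor$counts[[mark]][, use_ids])
    d <- nb_wald_test(cnt, nr, group)
    attr(d, "segments") <- segs_m
    d <- classify(d, p_cut = cfg$diff$p_cut, lfc_cut = cfg$diff$lfc_cut)
    gl <- state_gain_loss(d, te_track = cohort$scaffold$tracks$te)
    gl$crosstab <- marked_gene_expression_crosstab(gl$gained, gl$lost, genes, de)
    gl$diff <- d
    gl
  }
  het_k9 <- hetero_one("H3K9me3", cfg$hetero$het_labels)
  het_k27 <- hetero_one("H3K27me3", cfg$hetero$pcg_labels)
  te_enrich <- te_state_enrichment(seg_apl, cohort$scaffold$tracks$te)
  lad_enrich <- overlap_enrichment(seg_apl, cohort$scaffold$tracks$lad)
  log_stage("hetero", t0)

  ## expression classes + neighborhood enrichment (state annotation QC)
  cls <- expression_class(cohort$expression$rpkm)
  names(cls) <- rownames(cohort$expression$rpkm)
  nbh <- neighborhood_enrichment(seg_apl, genes, cls)

  result <- structure(list(
    config = cfg, cohort = cohort, model = model, labels = labels,
    segmentations = segs, screen = screen, jaccard = jaccard,
    diff_enhancers = diff_enh, calls = calls,
    rose = list(APL = rose_apl, AML = rose_aml), unique_se = unique_se,
    fusion = fusion, links = links, se_links = se_links, hijack = hijack,
    dependency = dependency, de = de, het_k9 = het_k9, het_k27 = het_k27,
    te_enrichment = te_enrich, lad_enrichment = lad_enrich,
    neighborhood = nbh
  ), class = "pipeline_result")
  result$report <- pipeline_report(result)
  log_stage("report", t0)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

truth_of_kind <- function(truth, kind) {
  t <- truth[truth$kind == kind, , drop = FALSE]
  if (!nrow(t)) return(interval_set())
  interval_set(data.frame(chrom = t$chrom, start = t$start, end = t$end,
                          name = t$id))
}

#' Truth-recovery report of a pipeline run
#'
#' Joins every planted element kind against the stage output that targets
#' it and reports sensitivity (fraction of planted elements recovered) and,
#' where meaningful, precision (fraction of called elements explained by a
#' planted one).
#'
#' @param result a `pipeline_result`.
#' @return data.frame with one row per planted element kind.
#' @export
pipeline_report <- function(result) {
  truth <- result$cohort$truth
  rows <- list()
  rate <- function(x) if (length(x)) mean(x) else NA_real_

  t_enh <- truth_of_kind(truth, "enhancer")
  rows$enhancer <- data.frame(
    kind = "enhancer", n_planted = nrow(t_enh), n_called = nrow(result$calls),
    sensitivity = rate(overlaps_any(t_enh, result$calls)),
    precision = rate(overlaps_any(result$calls, t_enh)))

  t_se <- truth_of_kind(truth, "se_cluster")
  planted_any <- interval_set(data.frame(
    chrom = c(t_enh$chrom, t_se$chrom), start = c(t_enh$start, t_se$start),
    end = c(t_enh$end, t_se$end)))
  rows$se <- data.frame(
    kind = "se_cluster", n_planted = nrow(t_se),
    n_called = nrow(result$unique_se),
    sensitivity = rate(overlaps_any(t_se, result$unique_se)),
    precision = rate(overlaps_any(result$unique_se, planted_any)))

  t_k9 <- truth_of_kind(truth, "h3k9me3_gain")
  g9 <- if (!is.null(result$het_k9)) result$het_k9$gained else interval_set()
  rows$k9 <- data.frame(
    kind = "h3k9me3_gain", n_planted = nrow(t_k9), n_called = nrow(g9),
    sensitivity = rate(overlaps_any(t_k9, g9)),
    precision = rate(overlaps_any(g9, t_k9)))

  t_k27 <- truth_of_kind(truth, "h3k27me3_gain")
  g27 <- if (!is.null(result$het_k27)) result$het_k27$gained else interval_set()
  rows$k27 <- data.frame(
    kind = "h3k27me3_gain", n_planted = nrow(t_k27), n_called = nrow(g27),
    sensitivity = rate(overlaps_any(t_k27, g27)),
    precision = rate(overlaps_any(g27, t_k27)))

  t_link <- truth[truth$kind == "link", , drop = FALSE]
  link_hit <- vapply(seq_len(nrow(t_link)), function(i) {
    iv <- interval_set(data.frame(chrom = t_link$chrom[i],
                                  start = t_link$start[i], end = t_link$end[i]))
    pl <- result$links[result$links$passes &
                         result$links$gene_id == t_link$gene_id[i], ,
                       drop = FALSE]
    if (!nrow(pl)) return(FALSE)
    any(overlaps_any(result$calls[result$calls$name %in% pl$enhancer_id, ,
                                  drop = FALSE], iv))
  }, TRUE)
  rows$link <- data.frame(kind = "link", n_planted = nrow(t_link),
                          n_called = sum(result$links$passes),
                          sensitivity = rate(link_hit), precision = NA_real_)

  t_hj <- truth[truth$kind == "hijack_link", , drop = FALSE]
  hj_grid <- result$hijack$a_enh_b_genes
  hj_hit <- vapply(seq_len(nrow(t_hj)), function(i) {
    iv <- interval_set(data.frame(chrom = t_hj$chrom[i], start = t_hj$start[i],
                                  end = t_hj$end[i]))
    st <- hj_grid[hj_grid$star & hj_grid$gene_id == t_hj$gene_id[i], ,
                  drop = FALSE]
    if (!nrow(st)) return(FALSE)
    any(overlaps_any(result$calls[result$calls$name %in% st$enhancer_id, ,
                                  drop = FALSE], iv))
  }, TRUE)
  rows$hijack <- data.frame(kind = "hijack_link", n_planted = nrow(t_hj),
                            n_called = sum(hj_grid$star),
                            sensitivity = rate(hj_hit), precision = NA_real_)

  ## the disease-separating context is recovered if any H3K27ac combo over
  ## an active-enhancer state flags an exact cohort bipartition
  scr <- result$screen
  enh_flag <- scr$separation_flag[scr$mark == "H3K27ac" &
                                    grepl("EnhActive", scr$state)]
  rows$screen <- data.frame(kind = "screen_h3k27ac_enhancer",
                            n_planted = 1L, n_called = sum(enh_flag %in% TRUE),
                            sensitivity = as.numeric(any(enh_flag %in% TRUE)),
                            precision = NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline artifacts to a directory
#' @param result a `pipeline_result`.
#' @param out_dir output directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                             sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  wtsv(result$screen, "screen.tsv")
  wtsv(result$jaccard, "state_jaccard.tsv")
  wtsv(as.data.frame(result$diff_enhancers), "diff_enhancers.tsv")
  write_bed(result$calls, file.path(out_dir, "enhancer_calls.bed"))
  write_bed(result$unique_se, file.path(out_dir, "unique_super_enhancers.bed"))
  wtsv(result$rose$APL$curve$table, "se_curve_apl.tsv")
  wtsv(result$links, "links.tsv")
  wtsv(result$se_links, "se_links.tsv")
  wtsv(result$hijack$a_enh_b_genes, "hijack_grid.tsv")
  if (!is.null(result$het_k9)) {
    write_bed(result$het_k9$gained, file.path(out_dir, "h3k9me3_gained.bed"))
    wtsv(result$het_k9$crosstab, "h3k9me3_crosstab.tsv")
  }
  if (!is.null(result$het_k27)) {
    write_bed(result$het_k27$gained, file.path(out_dir, "h3k27me3_gained.bed"))
    wtsv(result$het_k27$crosstab, "h3k27me3_crosstab.tsv")
  }
  wtsv(result$te_enrichment, "te_state_enrichment.tsv")
  wtsv(result$report, "report.tsv")
  write_model_json(result$model, file.path(out_dir, "model.json"))
  for (co in names(result$segmentations))
    write_segmentation_bed(result$segmentations[[co]],
                           file.path(out_dir, paste0("segmentation_", co, ".bed")))
  jsonlite::write_json(result$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
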