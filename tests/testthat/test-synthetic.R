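# Generator-level checks of the synthetic cohort. The full study size
# (2 x 20 Mb, 18 samples) is only simulated where the check needs it;
# single-mark tensors keep these tests fast.

test_that("genome generation is deterministic and structurally sound", {
  sc1 <- generate_genome(cohort_design(), plant_spec(), seed = 42)
  sc2 <- generate_genome(cohort_design(), plant_spec(), seed = 42)
  expect_identical(sc1$truth, sc2$truth)
  expect_identical(sc1$genes, sc2$genes)
  expect_identical(as.data.frame(sc1$tracks$te), as.data.frame(sc2$tracks$te))

  # written files are byte-identical under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_gtf_genes(sc1$genes, file.path(d1, "g.gtf"))
  write_gtf_genes(sc2$genes, file.path(d2, "g.gtf"))
  write_bed(sc1$tracks$fusion_sites, file.path(d1, "f.bed"))
  write_bed(sc2$tracks$fusion_sites, file.path(d2, "f.bed"))
  expect_identical(unname(tools::md5sum(file.path(d1, "g.gtf"))),
                   unname(tools::md5sum(file.path(d2, "g.gtf"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "f.bed"))),
                   unname(tools::md5sum(file.path(d2, "f.bed"))))

  # TE classes cover the major repeat classes
  classes <- unique(chromcontrast:::parse_te_names(sc1$tracks$te)$class)
  expect_true(all(c("LINE", "SINE", "LTR") %in% classes))

  # gene TSSs inside chromosome bounds
  lens <- setNames(sc1$layout$length, sc1$layout$chrom)
  expect_true(all(sc1$genes$tss >= 0 &
                    sc1$genes$tss < lens[sc1$genes$chrom]))

  # planted regions are mutually disjoint
  planted <- interval_set(sc1$truth[sc1$truth$kind %in%
                                      c("enhancer", "h3k9me3_gain",
                                        "h3k27me3_gain"),
                                    c("chrom", "start", "end")])
  expect_true(all(count_overlaps(planted, planted) == 1))
})

test_that("planted effect sizes and track fractions are realized", {
  sc <- generate_genome(cohort_design(), plant_spec(), seed = 7)

  # fusion sites: ~49% within 3 kb of a TSS, ~30% of planted enhancers bound
  d <- distance_to_nearest_tss(sc$tracks$fusion_sites, sc$genes)
  expect_lt(abs(mean(d <= 3000) - 0.49), 0.05)
  spec <- sc$elements$enhancers[sc$elements$enhancers$kind %in%
                                  c("specific_single", "specific_cluster",
                                    "hijack"), ]
  spec_set <- interval_set(spec[, c("chrom", "start", "end")])
  expect_lt(abs(mean(overlaps_any(spec_set, sc$tracks$fusion_sites)) - 0.3),
            0.05)

  # H3K9me3 gain regions overlap TEs at the 0.7 target exactly by design
  gains <- interval_set(sc$elements$k9_gains[, c("chrom", "start", "end")])
  expect_lt(abs(overlap_fraction(gains, sc$tracks$te) - 0.7), 0.05)

  # zero fusion-bound fraction produces no bound enhancer
  sc0 <- generate_genome(cohort_design(),
                         plant_spec(frac_enhancers_fusion_bound = 0),
                         seed = 7)
  spec0 <- sc0$elements$enhancers[sc0$elements$enhancers$kind %in%
                                    c("specific_single", "specific_cluster",
                                      "hijack"), ]
  expect_equal(sum(overlaps_any(interval_set(spec0[, c("chrom", "start", "end")]),
                                sc0$tracks$fusion_sites)), 0L)
})

test_that("planted H3K27ac fold is recovered at the stated tolerance", {
  ratios <- vapply(1:3, function(seed) {
    co <- simulate_cohort(seed = seed, marks = "H3K27ac")
    sc <- co$scaffold
    enh <- sc$elements$enhancers
    spec <- enh[enh$kind %in% c("specific_single", "specific_cluster") &
                  !enh$id %in% sc$links$enhancer_id, ]
    b <- bins_of_intervals(sc$layout,
                           interval_set(spec[, c("chrom", "start", "end")]))
    cnt <- co$tensor$counts$H3K27ac
    norm <- sweep(cnt, 2, colSums(cnt) / mean(colSums(cnt)), `/`)
    apl <- sc$design$samples$cohort == "APL"
    aml <- sc$design$samples$cohort == "AML"
    log2(mean(norm[b, apl]) / mean(norm[b, aml]))
  }, 0)
  expect_true(all(abs(ratios - 2) < 0.3))
})

test_that("no-effect generation leaves planted regions null", {
  co <- simulate_cohort(plant = plant_spec(enhancer_log2fc = 0),
                        seed = 11, marks = "H3K27ac")
  sc <- co$scaffold
  enh <- sc$elements$enhancers
  spec <- enh[enh$kind %in% c("specific_single", "specific_cluster") &
                !enh$id %in% sc$links$enhancer_id, ]
  b <- bins_of_intervals(sc$layout,
                         interval_set(spec[, c("chrom", "start", "end")]))
  cnt <- co$tensor$counts$H3K27ac
  norm <- sweep(cnt, 2, colSums(cnt) / mean(colSums(cnt)), `/`)
  apl <- sc$design$samples$cohort == "APL"
  aml <- sc$design$samples$cohort == "AML"
  expect_lt(abs(log2(mean(norm[b, apl]) / mean(norm[b, aml]))), 0.2)
})

test_that("expression links share the latent factor and nulls stay weak", {
  co <- simulate_cohort(seed = 13, marks = "H3K27ac")
  sc <- co$scaffold
  use <- sc$design$samples$cohort %in% c("APL", "AML")
  cnt <- co$tensor$counts$H3K27ac
  rp <- co$expression$rpkm
  link_r <- vapply(seq_len(nrow(sc$links)), function(i) {
    l <- sc$links[i, ]
    e <- sc$elements$enhancers[sc$elements$enhancers$id == l$enhancer_id, ]
    b <- bins_of_intervals(sc$layout, interval_set(e[, c("chrom", "start", "end")]))
    sig <- colSums(cnt[b, , drop = FALSE]) / (colSums(cnt) / 1e6)
    cor(log2(sig[use] + 1), log2(rp[l$gene_id, use] + 1))
  }, 0)
  expect_gt(mean(link_r), 0.7)

  # null pairs: planted enhancers vs random unrelated genes
  set.seed(1)
  null_genes <- setdiff(rownames(rp),
                        c(sc$links$gene_id, sc$elements$de_genes$gene_id,
                          sc$elements$silent_genes,
                          sc$genes$gene_id[grepl("^GHOX", sc$genes$gene_id)]))
  e1 <- sc$elements$enhancers[sc$elements$enhancers$kind == "shared_single", ][1:40, ]
  null_r <- vapply(1:40, function(i) {
    b <- bins_of_intervals(sc$layout,
                           interval_set(e1[i, c("chrom", "start", "end")]))
    sig <- colSums(cnt[b, , drop = FALSE]) / (colSums(cnt) / 1e6)
    g <- sample(null_genes, 1)
    suppressWarnings(cor(log2(sig[use] + 1), log2(rp[g, use] + 1)))
  }, 0)
  expect_gte(mean(abs(null_r) < 0.7, na.rm = TRUE), 0.95)
})

test_that("cohort outputs re-parse through the interval and GTF readers", {
  co <- simulate_cohort(seed = 3, marks = "H3K27ac")
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_gt(nrow(read_bed(file.path(d, "te.bed"))), 1000)
  expect_gt(nrow(read_bed(file.path(d, "lad.bed"))), 5)
  expect_equal(nrow(read_bed(file.path(d, "fusion_sites.bed"))), 200)
  g <- read_gtf_genes(file.path(d, "genes.gtf"))
  expect_equal(nrow(g), nrow(co$scaffold$genes))
  expect_equal(sort(g$tss), sort(co$scaffold$genes$tss))
  layout <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(n_bins(layout), n_bins(co$scaffold$layout))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(co$truth))
})

test_that("enhancer sequences plant the motif at the configured fraction", {
  sc <- generate_genome(cohort_design(), plant_spec(), seed = 5)
  sq <- generate_enhancer_sequences(sc, frac_with_motif = 0.5, seed = 5)
  expect_true(all(nchar(sq$target) == 500))
  has_motif <- grepl("TGACTCAG", sq$target, fixed = TRUE)
  expect_equal(sum(has_motif), round(0.5 * length(sq$target)),
               tolerance = 0.1)
})
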