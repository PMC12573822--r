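test_that("enhancer calls apply the gain rule and the strict TSS distance", {
  genes <- toy_genes()  # TSSs at c1:1000, c1:5999, c2:2000
  d <- data.frame(id = c("c1:2600-2700", "c1:6499-6600", "c1:9000-9100",
                         "c1:12000-12100"),
                  base_mean = 50,
                  log2fc = c(1.5, 1.2, 0.5, 1.2),
                  wald_p = 1e-4,
                  padj = c(0.01, 0.04, 0.01, 0.2),
                  class = "ns", stringsAsFactors = FALSE)
  class(d) <- c("diff_result", "data.frame")
  calls <- call_specific_enhancers(d, genes, min_tss_dist = 500)
  # row 1: dist to TSS 5999 is 3299 -> kept; row 2: dist is exactly 500 -> dropped
  # row 3 fails lfc; row 4 fails padj
  expect_equal(calls$name, "c1:2600-2700")

  d$padj[2] <- 0.01; d$id[2] <- "c1:6500-6600"  # dist 501 -> kept
  calls2 <- call_specific_enhancers(d, genes, min_tss_dist = 500)
  expect_setequal(calls2$name, c("c1:2600-2700", "c1:6500-6600"))
})

test_that("ROSE stitching excludes TSS-contained peaks and merges by gap", {
  genes <- toy_genes()
  peaks <- interval_set(chrom = "c1",
                        start = c(900, 20000, 32000, 60000),
                        end = c(1200, 21000, 33000, 61000),
                        name = c("tss_peak", "p1", "p2", "p3"))
  st <- rose_stitch(peaks, genes, stitch_gap = 12500, tss_exclusion = 500)
  # the peak inside TSS +/- 500 of gene g1 (TSS 1000) is dropped,
  # p1 and p2 (gap 11 kb) merge, p3 stays apart
  expect_equal(nrow(st), 2L)
  expect_equal(st$name[1], "p1,p2")

  # stitching equals the plain interval merge once the TSS filter is off
  set.seed(1)
  r <- random_interval_set(30, max_pos = 5000)
  st2 <- rose_stitch(r, genes[0, ], stitch_gap = 100, tss_exclusion = 0)
  m <- merge_within(r, 100)
  expect_equal(st2[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")])
})

test_that("the tangent cutoff isolates outliers and degenerates sanely", {
  regions <- interval_set(chrom = "c1", start = (0:99) * 1000,
                          end = (0:99) * 1000 + 500)
  scores <- c(rep(1, 99), 1000)
  curve <- rose_rank_and_cutoff(regions, scores)
  expect_equal(sum(curve$is_super), 1L)
  expect_true(curve$is_super[100])

  lin <- rose_rank_and_cutoff(regions, 1:100)
  expect_equal(sum(lin$is_super), 0L)

  const <- rose_rank_and_cutoff(regions, rep(7, 100))
  expect_equal(sum(const$is_super), 0L)

  # scale invariance of the super flags
  set.seed(2)
  sc <- cumsum(sort(rexp(100)))
  c1 <- rose_rank_and_cutoff(regions, sc)
  c2 <- rose_rank_and_cutoff(regions, sc * 37.5)
  expect_equal(c1$is_super, c2$is_super)

  expect_error(rose_rank_and_cutoff(regions[1:2, ], c(1, 2)), "at least 3")
})

test_that("the tangent cutoff equals the brute-force search on hockey-stick curves", {
  set.seed(3)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    scores <- if (i %% 2 == 0) {
      cumsum(sort(rexp(n)))                  # convex increasing curve
    } else {
      k <- sample(1:5, 1)
      c(rep(runif(1, 1, 5), n - k), sort(runif(k, 50, 100)))  # step curve
    }
    regions <- interval_set(chrom = "c1", start = seq_len(n) * 1000,
                            end = seq_len(n) * 1000 + 500)
    curve <- rose_rank_and_cutoff(regions, scores)
    oi <- oracle_tangent_index(scores)
    expect_equal(curve$cutoff_index, oi)
    # the unit-slope line through the cutoff point supports the curve
    tab <- curve$table
    d <- tab$scaled_score - tab$scaled_rank
    expect_gte(min(d) + 1e-12, d[curve$cutoff_index])
  }
})

test_that("cohort-unique SEs require zero overlap and a specific enhancer", {
  se_a <- interval_set(chrom = "c1", start = c(0, 10000, 20000),
                       end = c(5000, 15000, 25000), name = c("a1", "a2", "a3"))
  se_b <- interval_set(chrom = "c1", start = 14999, end = 16000)  # 1 bp overlap with a2
  spec <- interval_set(chrom = "c1", start = 1000, end = 1500)
  u <- cohort_unique_super_enhancers(se_a, se_b, spec)
  # a2 is excluded by the 1 bp overlap, a3 contains no specific enhancer
  expect_equal(u$name, "a1")
  expect_equal(u$n_specific_enhancers, 1)
})

test_that("fusion overlap flags calls and measures TSS proximity", {
  genes <- toy_genes()
  calls <- interval_set(chrom = "c1", start = c(10000, 30000),
                        end = c(11000, 31000), name = c("e1", "e2"))
  sites <- interval_set(chrom = c("c1", "c1"), start = c(10200, 3500),
                        end = c(10400, 3700))
  fo <- fusion_overlap(calls, sites, genes)
  expect_equal(fo$calls$fusion_bound, c(TRUE, FALSE))
  expect_equal(fo$bound_fraction, 0.5)
  # site 1 is 4201 bp from the nearest TSS; site 2 is 2299 bp away
  expect_equal(fo$tss_proximal_fraction, 0.5)

  fo2 <- fusion_overlap(calls, interval_set(), genes)
  expect_equal(fo2$calls$fusion_bound, c(FALSE, FALSE))
  expect_true(is.na(fo2$tss_proximal_fraction))
})
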