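toy_seg <- function(states, labels, bin = 1000) {
  layout <- genome_layout(c(c1 = length(states) * bin), bin_size = bin)
  structure(list(layout = layout, state = states, K = length(labels),
                 labels = labels), class = "segmentation")
}

toy_tensor <- function(counts_list, cohorts, layout) {
  samples <- data.frame(sample_id = colnames(counts_list[[1]]),
                        cohort = cohorts, stringsAsFactors = FALSE)
  structure(list(counts = counts_list, samples = samples, layout = layout),
            class = "mark_tensor")
}

test_that("region signal matrix normalizes to RPKM-like units", {
  states <- rep(2L, 100); states[5] <- 1L
  seg <- toy_seg(states, c("A", "B"))
  cnt <- matrix(1L, 100, 2, dimnames = list(NULL, c("s1", "s2")))
  cnt[5, 1] <- 100L
  cnt[, 2] <- 0L; cnt[5, 2] <- 100L
  lib1 <- sum(cnt[, 1])
  tn <- toy_tensor(list(M = cnt), c("APL", "AML"), seg$layout)
  m <- region_signal_matrix(tn, seg, 1L, "M")
  # 100 counts over a 1 kb segment at library lib1 reads
  expect_equal(m[1, 1], 100 / (1 * lib1 / 1e6))
  # scale invariance: doubling every count of one sample leaves it unchanged
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 2L
  tn2 <- toy_tensor(list(M = cnt2), c("APL", "AML"), seg$layout)
  expect_equal(region_signal_matrix(tn2, seg, 1L, "M")[, 1], m[, 1])
  expect_error(region_signal_matrix(tn, seg, "nope", "M"))
})

test_that("region counts match brute-force per-segment summation", {
  layout <- genome_layout(c(c1 = 20000), bin_size = 1000)
  set.seed(1)
  cnt <- matrix(rpois(20 * 3, 10), 20, 3)
  regions <- interval_set(chrom = "c1", start = c(0, 5000, 12000),
                          end = c(3000, 6000, 20000))
  m <- chromcontrast:::region_counts(layout, cnt, regions)
  expect_equal(m[1, ], colSums(cnt[1:3, ]))
  expect_equal(m[2, ], cnt[6, ])
  expect_equal(m[3, ], colSums(cnt[13:20, ]))
})

test_that("top_variable ranks by log-scale variance with stable ties", {
  set.seed(2)
  mat <- rbind(matrix(5, 3, 6),                       # constant rows
               matrix(rnbinom(50 * 6, mu = 50, size = 2), 50, 6))
  cfg <- consensus_config(top_n = 10, k_range = 2:3)
  tv <- top_variable(mat, cfg)
  v <- apply(log2(mat + 1), 1, var)
  expect_equal(rownames(tv), NULL)
  expect_equal(unname(tv), unname(mat[order(-v, seq_along(v))[1:10], ]))
  # constant rows rank last
  expect_false(any(apply(tv, 1, var) == 0))

  cfg2 <- consensus_config(top_n = 10, offset = 2000, k_range = 2:3)
  expect_error(top_variable(mat[1:20, ], cfg2), "beyond")
})

test_that("consensus matrices are symmetric with unit diagonal and duplicates co-cluster", {
  set.seed(3)
  mat <- matrix(rnbinom(100 * 6, mu = 40, size = 5), 100, 6)
  mat[, 4] <- mat[, 3]  # duplicate sample
  colnames(mat) <- paste0("s", 1:6)
  cc <- consensus_cluster(mat, consensus_config(top_n = 80, n_resamples = 30,
                                                k_range = 2:3, seed = 1))
  for (k in names(cc$consensus)) {
    m <- cc$consensus[[k]]
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(1, 6), ignore_attr = TRUE)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m["s3", "s4"], 1)
  }
})

test_that("well-separated groups are recovered at k = 2", {
  set.seed(4)
  # feature-specific group effect, 5 sd apart on half the features
  base <- runif(200, 2, 6)
  delta <- c(rep(5, 100), rep(0, 100))
  grp <- rep(c(0, 1), each = 7)
  mat <- sapply(grp, function(g) base + delta * g + rnorm(200, 0, 1))
  colnames(mat) <- paste0("s", 1:14)
  cc <- consensus_cluster(mat, consensus_config(top_n = 150, n_resamples = 50,
                                                k_range = 2:3, seed = 2))
  part <- cc$partition[["2"]]
  expect_equal(length(unique(part[1:7])), 1L)
  expect_equal(length(unique(part[8:14])), 1L)
  expect_false(part[1] == part[8])
})

test_that("separation flag demands exact cohort purity and ignores order", {
  labels <- setNames(rep(c("APL", "AML"), c(5, 9)), paste0("s", 1:14))
  pure <- setNames(c(rep(1, 5), rep(2, 9)), names(labels))
  mixed <- pure; mixed["s14"] <- 1
  expect_true(separation_flag(list(`2` = pure), labels)$separation_flag)
  expect_false(separation_flag(list(`2` = mixed), labels)$separation_flag)
  shuffled <- pure[sample(names(pure))]
  expect_true(separation_flag(list(`2` = shuffled), labels)$separation_flag)
  # a k=3 partition that splits one cohort is still pure
  k3 <- pure; k3[c("s1", "s2")] <- 3
  expect_true(separation_flag(list(`3` = k3), labels)$separation_flag)
})

test_that("run_screen requires combinations and logs per-combo errors", {
  states <- rep(c(1L, 1L, 2L, 2L), 10)  # ten separate two-bin A segments
  seg <- toy_seg(states, c("A", "B"))
  set.seed(5)
  cnt <- matrix(rpois(40 * 6, 30), 40, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  tn <- toy_tensor(list(M1 = cnt), rep(c("APL", "AML"), each = 3), seg$layout)
  expect_error(run_screen(tn, seg, data.frame()), "empty")
  combos <- data.frame(mark = c("M1", "M1"), state = c("A", "C"))
  out <- suppressWarnings(
    run_screen(tn, seg, combos,
               consensus_config(top_n = 10, n_resamples = 10, k_range = 2:3)))
  expect_true(is.na(out$separation_flag[2]))
  expect_match(out$error[2], "segments")
  expect_false(is.na(out$separation_flag[1]))
})

test_that("cohort state Jaccard matches hand-computed overlaps", {
  a <- toy_seg(c(rep(1L, 100), rep(2L, 100)), c("X", "Y"))
  b <- toy_seg(c(rep(2L, 50), rep(1L, 100), rep(2L, 50)), c("X", "Y"))
  j <- cohort_state_jaccard(a, a)
  expect_equal(j$jaccard, c(1, 1))
  j2 <- cohort_state_jaccard(a, b)
  expect_equal(j2$jaccard[j2$label == "X"], 50 / 150)
})
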