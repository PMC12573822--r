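test_that("pearson_test matches cor.test to high precision", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    pt <- pearson_test(x, y)
    ct <- cor.test(x, y)
    expect_equal(pt$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(pt$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("pearson_test handles the documented conventions", {
  # construct an exact correlation by mixing orthogonal unit vectors
  exact_r <- function(r, n = 14) {
    set.seed(2)
    x <- scale(rnorm(n))[, 1]
    e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  }
  v <- exact_r(0.76)
  pt <- pearson_test(v$x, v$y)
  expect_equal(pt$r, 0.76, tolerance = 1e-12)
  expect_gt(pt$p, 1.2e-3)
  expect_lt(pt$p, 2.2e-3)

  v0 <- exact_r(0)
  expect_equal(pearson_test(v0$x, v0$y)$p, 1, tolerance = 1e-10)

  expect_equal(pearson_test(1:5, (1:5) * 2)$p, 0)
  expect_true(is.na(pearson_test(rep(1, 5), rnorm(5))$r))
  expect_error(pearson_test(1:4, 1:5), "length")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

make_link_fixture <- function(r_planted = 0.95, n = 14) {
  set.seed(3)
  enh <- interval_set(chrom = "c1", start = c(100000, 3e6),
                      end = c(101000, 3e6 + 1000), name = c("e1", "e2"))
  x <- matrix(abs(rnorm(2 * n, 50, 10)), 2, n,
              dimnames = list(NULL, paste0("s", 1:n)))
  genes <- data.frame(
    gene_id = c("gNear", "gFar", "gLinked"),
    gene_name = c("gNear", "gFar", "gLinked"),
    chrom = "c1", strand = "+",
    start = c(600000, 1200000 + 101000, 150000),
    end = c(610000, 1350000, 160000),
    tss = c(600000, 1101001, 150000), length = c(1e4, 1e4, 1e4))
  expr <- matrix(abs(rnorm(3 * n, 20, 5)), 3, n,
                 dimnames = list(genes$gene_id, colnames(x)))
  lx <- log2(x[1, ] + 1)
  expr["gLinked", ] <- 2^(r_planted * scale(lx)[, 1] * 2 + 4)
  list(enh = enh, signal = x, genes = genes, expr = expr)
}

test_that("guilt-by-association windows and thresholds behave as stated", {
  fx <- make_link_fixture()
  links <- guilt_by_association(fx$signal, fx$enh, fx$expr, fx$genes,
                                window = 1e6)
  # gFar's TSS is 1,000,001 bp from e1's end: outside the inclusive 1 Mb window
  expect_false(any(links$enhancer_id == "e1" & links$gene_id == "gFar"))
  expect_true(any(links$enhancer_id == "e1" & links$gene_id == "gNear"))
  # the planted strong link passes
  got <- links[links$enhancer_id == "e1" & links$gene_id == "gLinked", ]
  expect_true(got$passes)

  # boundary: exactly 1 Mb from the edge is a candidate
  g <- fx$genes; g$tss[2] <- 101000 + 1e6
  links2 <- guilt_by_association(fx$signal, fx$enh, fx$expr, g, window = 1e6)
  expect_true(any(links2$enhancer_id == "e1" & links2$gene_id == "gFar"))

  expect_error(guilt_by_association(fx$signal[, 1:13], fx$enh,
                                    fx$expr, fx$genes), "sample names")
})

test_that("link passing is monotone in the thresholds", {
  fx <- make_link_fixture()
  loose <- guilt_by_association(fx$signal, fx$enh, fx$expr, fx$genes,
                                r_min = 0.5, p_max = 0.05)
  tight <- guilt_by_association(fx$signal, fx$enh, fx$expr, fx$genes,
                                r_min = 0.8, p_max = 0.01)
  key <- function(d) paste(d$enhancer_id, d$gene_id)[d$passes]
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("candidate pairs equal brute-force distance filtering", {
  fx <- make_link_fixture()
  links <- guilt_by_association(fx$signal, fx$enh, fx$expr, fx$genes,
                                window = 1e6)
  brute <- expand.grid(e = seq_len(nrow(fx$enh)),
                       g = seq_len(nrow(fx$genes)))
  keep <- mapply(function(e, g) {
    tss <- fx$genes$tss[g]
    fx$genes$chrom[g] == fx$enh$chrom[e] &&
      tss >= fx$enh$start[e] - 1e6 && tss <= fx$enh$end[e] + 1e6
  }, brute$e, brute$g)
  expect_equal(nrow(links), sum(keep))
})

test_that("SE-gene association carries the fusion-bound flag", {
  fx <- make_link_fixture()
  sites <- interval_set(chrom = "c1", start = 100100, end = 100200)
  se_links <- se_gene_association(fx$signal, fx$enh, fx$expr, fx$genes,
                                  fusion_sites = sites, r_min = 0,
                                  p_max = 1)
  expect_true(all(se_links$fusion_bound[se_links$enhancer_id == "e1"]))
  expect_false(any(se_links$fusion_bound[se_links$enhancer_id == "e2"]))
  empty <- se_gene_association(fx$signal[0, , drop = FALSE], interval_set(),
                               fx$expr, fx$genes)
  expect_equal(nrow(empty), 0L)
})

test_that("hijack grid covers both directions with raw-p stars", {
  fx <- make_link_fixture()
  genes <- fx$genes
  genes$chrom <- "c2"; genes$tss <- c(5e5, 8e5, 1.2e6); genes$start <- genes$tss
  genes$end <- genes$start + 1e4
  bp <- list(chrom_a = "c1", pos_a = 2e6, chrom_b = "c2", pos_b = 1e6,
             flank = 2e6)
  hm <- hijack_matrix(fx$enh, fx$signal, fx$expr, genes, bp)
  expect_equal(nrow(hm$a_enh_b_genes), nrow(fx$enh) * nrow(genes))
  expect_equal(hm$a_enh_b_genes$star,
               !is.na(hm$a_enh_b_genes$p) & hm$a_enh_b_genes$p < 0.05)
  expect_null(hm$b_enh_a_genes)  # no enhancers on side B

  bp_bad <- list(chrom_a = "c9", pos_a = 1e6, chrom_b = "c2", pos_b = 1e6)
  expect_error(hijack_matrix(fx$enh, fx$signal, fx$expr, genes, bp_bad),
               "empty breakpoint side")
})

test_that("dependency join filters to negative effects and validates input", {
  scores <- data.frame(gene_id = c("g1", "g2", "g3"),
                       effect = c(-1.2, 0.3, -0.1))
  out <- dependency_join(c("g1", "g2", "g4"), scores)
  expect_equal(out$gene_id, c("g1", "g2"))
  expect_equal(out$dependent, c(TRUE, FALSE))
  # brute-force lookup agreement
  expect_equal(out$effect, scores$effect[match(out$gene_id, scores$gene_id)])
  expect_error(dependency_join("g1", rbind(scores, scores[1, ])),
               "duplicated")
})

test_that("hypergeometric overlap matches exact enumeration", {
  # N=10, |A|=4, |B|=5, overlap 4: only C(6,1) of C(10,5) draws work
  expect_equal(hypergeometric_overlap(4, 5, 4, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(4, 5, 0, 10), 1)
  expect_equal(hypergeometric_overlap(10, 5, 5, 10), 1)
  expect_error(hypergeometric_overlap(4, 5, 6, 10), "inconsistent")
})

test_that("gene-set ORA ranks a planted set first with BH correction", {
  set.seed(4)
  universe <- sprintf("g%03d", 1:400)
  planted <- universe[1:40]
  sets <- c(list(planted = planted),
            lapply(1:6, function(i) sample(universe, 40)))
  names(sets) <- c("planted", paste0("rand", 1:6))
  query <- c(planted[1:20], sample(universe[41:400], 20))
  ora <- gene_set_ora(query, sets, universe)
  expect_equal(ora$set[1], "planted")
  expect_lt(ora$padj[1], 0.01)
  # disjoint query
  ora2 <- gene_set_ora(universe[300:320], list(s = universe[1:10]), universe)
  expect_equal(ora2$p, 1)
  # BH monotone in p
  expect_true(all(diff(ora$padj[order(ora$p)]) >= -1e-12))
})
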