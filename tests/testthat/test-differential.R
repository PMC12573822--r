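test_that("TMM factors are 1 for identical columns and pure depth shifts", {
  set.seed(1)
  base <- rnbinom(500, mu = 100, size = 10) + 1
  cnt <- cbind(base, base, base)
  f <- tmm_factors(cnt)
  expect_equal(f$factors, rep(1, 3), tolerance = 1e-12)

  cnt2 <- cbind(base, 2 * base, base)
  f2 <- tmm_factors(cnt2)
  expect_equal(f2$factors, rep(1, 3), tolerance = 1e-9)
})

test_that("TMM factors agree with the edgeR implementation", {
  set.seed(2)
  cnt <- matrix(rnbinom(2000 * 6, mu = exp(runif(2000, 1, 6)), size = 5),
                2000, 6)
  cnt[1:100, 1:3] <- cnt[1:100, 1:3] * 4L  # some asymmetric DE
  ours <- tmm_factors(cnt)
  ref <- edgeR::calcNormFactors(cnt, method = "TMM")
  expect_equal(ours$factors, as.numeric(ref), tolerance = 0.02)
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(3)
  n1 <- 5; n2 <- 9
  group <- factor(rep(c("A", "B"), c(n1, n2)), levels = c("A", "B"))
  pois <- matrix(rpois(2000 * 14, 100), 2000, 14)
  dp <- nb_dispersion(pois, colSums(pois), group)
  expect_lte(median(dp), 0.01)

  nb <- matrix(rnbinom(2000 * 14, mu = 100, size = 10), 2000, 14)
  dn <- nb_dispersion(nb, colSums(nb), group)
  expect_gte(median(dn), 0.05)
  expect_lte(median(dn), 0.2)

  const <- matrix(5, 30, 14)
  expect_equal(min(nb_dispersion(const, rep(70, 14) * 2, group)), 1e-8)
})

test_that("Wald test is symmetric under group relabeling", {
  set.seed(4)
  cnt <- matrix(rnbinom(300 * 10, mu = 80, size = 10), 300, 10)
  cnt[1:50, 6:10] <- matrix(rnbinom(50 * 5, mu = 320, size = 10), 50, 5)
  g1 <- factor(rep(c("A", "B"), each = 5), levels = c("A", "B"))
  g2 <- factor(rep(c("A", "B"), each = 5), levels = c("B", "A"))
  norm <- tmm_factors(cnt)
  d1 <- nb_wald_test(cnt, norm, g1)
  d2 <- nb_wald_test(cnt, norm, g2)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-8)
  expect_equal(d1$wald_p, d2$wald_p, tolerance = 1e-8)
})

test_that("degenerate features follow the documented conventions", {
  cnt <- rbind(rep(0L, 6), c(5L, 8L, 6L, 7L, 9L, 4L))
  g <- factor(rep(c("A", "B"), each = 3))
  d <- nb_wald_test(cnt, rep(100, 6), g, dispersions = c(0.1, 0.1))
  expect_equal(d$wald_p[1], 1)
  expect_equal(d$log2fc[1], 0)
  expect_error(nb_wald_test(matrix(1.5, 2, 6), rep(1, 6), g), "integers")
})

test_that("BH adjustment equals the explicit step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")

  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(3:400, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("classification respects the published boundary operators", {
  d <- data.frame(id = letters[1:4],
                  base_mean = 10, log2fc = c(1.0, 3.0, 2.0, -2.5),
                  wald_p = 0.001, padj = c(0.04, 0.05, 0.01, 0.01),
                  class = "ns")
  enh <- classify_preset(d, "enhancer")
  expect_equal(enh$class, c("gain", "ns", "gain", "loss"))

  atra <- classify_preset(d, "atra")
  # |log2FC| > 2 strict: 2.0 stays ns, -2.5 is a loss
  expect_equal(atra$class, c("ns", "ns", "ns", "loss"))
})

test_that("rpkm follows the definition and is linear in counts", {
  expect_equal(rpkm(matrix(100), 2000, 1e7)[1, 1], 5)
  expect_equal(rpkm(matrix(0), 2000, 1e7)[1, 1], 0)
  set.seed(6)
  cnt <- matrix(rpois(20, 50), 10, 2)
  len <- runif(10, 500, 5000); lib <- c(2e6, 8e6)
  expect_equal(rpkm(3 * cnt, len, lib), 3 * rpkm(cnt, len, lib))
  expect_error(rpkm(matrix(1), 0, 1e6), "length")
})

test_that("doubling one library leaves TMM-normalized group ratios stable", {
  set.seed(7)
  cnt <- matrix(rnbinom(3000 * 8, mu = 120, size = 10), 3000, 8)
  cnt2 <- cnt
  cnt2[, 1] <- rnbinom(3000, mu = 240, size = 10)  # doubled depth
  g <- factor(rep(c("A", "B"), each = 4))
  r1 <- nb_wald_test(cnt, tmm_factors(cnt), g)
  r2 <- nb_wald_test(cnt2, tmm_factors(cnt2), g)
  expect_lt(abs(mean(r2$log2fc) - mean(r1$log2fc)), 0.03)
})
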