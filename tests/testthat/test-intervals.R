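test_that("BED parsing handles valid lines, comments and malformed input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment",
               "chr1\t0\t100",
               "chr1\t200\t300\tpeak1\t5\t+"), f)
  s <- read_bed(f)
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0, 200))
  expect_equal(s$name, c(NA, "peak1"))
  expect_equal(s$strand, c(".", "+"))

  writeLines("chr1\t100\t100", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t100", "chr1\tabc\t200"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("BED6 content round-trips losslessly", {
  set.seed(1)
  s <- interval_set(chrom = c("chr2", "chr1", "chr1"),
                    start = c(10, 0, 50), end = c(20, 5, 99),
                    name = c("a", "b", "c"), score = c(1, 2.5, 0),
                    strand = c("+", "-", "."))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, f)
  s2 <- read_bed(f)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})

test_that("GTF gene parsing converts coordinates and computes strand-aware TSS", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "##comment",
    paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
          'gene_id "gA"; gene_name "A";', sep = "\t"),
    paste("chr1", "src", "gene", "101", "200", ".", "-", ".",
          'gene_id "gB";', sep = "\t")), f)
  g <- read_gtf_genes(f)
  expect_equal(g$start, c(100, 100))
  expect_equal(g$end, c(200, 200))
  expect_equal(g$tss, c(100, 199))
  expect_equal(g$gene_name, c("A", "gB"))

  writeLines(paste("chr1", "src", "gene", "1", "10", ".", "+", ".",
                   'foo "bar";', sep = "\t"), f)
  expect_error(read_gtf_genes(f), "gene_id")
})

test_that("merge_within uses an inclusive gap and is idempotent", {
  s <- interval_set(chrom = "c1", start = c(0, 12600), end = c(100, 12700),
                    name = c("a", "b"))
  m <- merge_within(s, 12500)  # gap is exactly 12500 -> merges
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 12700))
  expect_equal(m$name, "a,b")

  s2 <- interval_set(chrom = "c1", start = c(0, 12601), end = c(100, 12700))
  expect_equal(nrow(merge_within(s2, 12500)), 2L)

  set.seed(7)
  for (i in 1:5) {
    r <- random_interval_set(25)
    m1 <- merge_within(r, 10)
    m2 <- merge_within(m1, 10)
    expect_equal(as.data.frame(m2)[, c("chrom", "start", "end")],
                 as.data.frame(m1)[, c("chrom", "start", "end")])
  }
})

test_that("jaccard_index matches hand values and the bp-enumeration oracle", {
  a <- interval_set(chrom = "c1", start = 0, end = 10)
  b <- interval_set(chrom = "c1", start = 5, end = 15)
  expect_equal(jaccard_index(a, b), 5 / 15)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(interval_set(), interval_set()), 0)

  set.seed(11)
  for (i in 1:8) {
    x <- random_interval_set(12)
    y <- random_interval_set(12)
    expect_equal(jaccard_index(x, y), oracle_jaccard(x, y), tolerance = 1e-12)
    expect_equal(jaccard_index(x, y), jaccard_index(y, x))
  }
})

test_that("distance_to_nearest_tss handles edges, containment and empty chroms", {
  genes <- toy_genes()
  iv <- interval_set(chrom = "c1", start = 1000, end = 2000)
  g2400 <- genes; g2400$tss[1] <- 2400; g2400 <- g2400[1, ]
  expect_equal(distance_to_nearest_tss(iv, g2400), 400)
  g_in <- genes[1, ]; g_in$tss <- 1500
  expect_equal(distance_to_nearest_tss(iv, g_in), 0)
  expect_equal(distance_to_nearest_tss(
    interval_set(chrom = "c9", start = 0, end = 10), genes), Inf)
})

test_that("overlap_fraction is count-based and matches the quadratic oracle", {
  q <- interval_set(chrom = "c1", start = seq(0, 90, 10), end = seq(5, 95, 10))
  s <- interval_set(chrom = "c1", start = seq(0, 60, 10), end = seq(3, 63, 10))
  expect_equal(overlap_fraction(q, s), 0.7)
  expect_equal(overlap_fraction(q, interval_set()), 0)

  set.seed(3)
  for (i in 1:8) {
    x <- random_interval_set(15)
    y <- random_interval_set(15)
    expect_equal(overlap_fraction(x, y), oracle_overlap_fraction(x, y))
  }
})

test_that("interval_set enforces invariants", {
  expect_error(interval_set(chrom = "c1", start = 5, end = 5), "empty")
  expect_error(interval_set(chrom = "c1", start = -1, end = 5), "negative")
  expect_error(interval_set(chrom = "c1", start = 0, end = 5, strand = "x"),
               "strand")
})
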