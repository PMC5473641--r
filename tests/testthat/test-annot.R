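toy_models <- function() {
  # + strand gene: translation start 13000, two CDS blocks with an intron
  # [14000,15000); - strand gene: CDS [40000,43000), translation start at
  # 43000
  list(genes = data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(12500L, 39500L), tx_end = c(16500L, 43500L)),
    cds = data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                     start = c(13000L, 15000L, 40000L),
                     end = c(14000L, 16000L, 43000L)))
}

test_that("gene models round-trip through GFF3", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(toy_models(), f)
  back <- read_gene_models(f)
  expect_equal(back$genes$gene_id, c("gA", "gB"))
  expect_equal(back$genes$tx_start, c(12500L, 39500L))
  expect_equal(back$genes$tx_end, c(16500L, 43500L))
  expect_equal(back$genes$strand, c("+", "-"))
  expect_equal(back$cds$start, c(13000L, 15000L, 40000L))
  expect_equal(back$cds$end, c(14000L, 16000L, 43000L))
})

test_that("region classes follow the priority order and the window anchors", {
  md <- toy_models()
  el <- data.frame(
    chrom = "chr1",
    start = c(13500L,  # inside CDS
              12500L,  # 5' window of gA (translation start 13000)
              2500L,   # > 10 kb upstream: intergenic
              14200L,  # intron between the two CDS blocks
              17000L,  # 3' window of gA (translation stop 16000)
              43200L,  # 5' side of - strand gene gB (upstream = right)
              12950L), # overlaps CDS and 5' window: coding wins
    end = c(13530L, 12530L, 2530L, 14230L, 17030L, 43230L, 13050L))
  cls <- classify_region(el, md)
  expect_equal(cls, c("coding", "five_prime_10kb", "intergenic",
                      "intronic", "three_prime_10kb", "five_prime_10kb",
                      "coding"))
  # empty gene set: everything intergenic
  empty <- list(genes = md$genes[0, ], cds = md$cds[0, ])
  expect_equal(classify_region(el[1:2, ], empty), rep("intergenic", 2))
})

test_that("nearest-gene association respects the 10 kb window and ties", {
  md <- toy_models()
  el <- data.frame(chrom = "chr1",
                   start = c(14000L, 26500L, 2498L, 25000L),
                   end = c(14050L, 26510L, 2499L, 25010L))
  # element 2: exactly 10 kb from gA end (26500 - 16500) -> kept
  # element 3: ends 10001 bp before gA tx_start (12500 - 2499) -> dropped
  assoc <- associate_genes(el, md)
  expect_equal(assoc$gene_id[assoc$element == 1], "gA")
  expect_equal(assoc$distance[assoc$element == 1], 0L)
  expect_equal(assoc$gene_id[assoc$element == 2], "gA")
  expect_equal(assoc$distance[assoc$element == 2], 10000L)
  expect_false(3 %in% assoc$element)
  # element 4 sits between the genes; gA (8.5 kb) is nearer than gB
  expect_equal(assoc$gene_id[assoc$element == 4], "gA")

  # equal distances tie-break to the lexicographically smaller id
  md2 <- list(genes = data.frame(gene_id = c("gZ", "gM"), chrom = "chr1",
                                 strand = "+",
                                 tx_start = c(0L, 2000L),
                                 tx_end = c(500L, 2500L)),
              cds = data.frame(gene_id = c("gZ", "gM"), chrom = "chr1",
                               start = c(0L, 2000L), end = c(500L, 2500L)))
  mid <- data.frame(chrom = "chr1", start = 1000L, end = 1500L)
  expect_equal(associate_genes(mid, md2)$gene_id, "gM")
})

test_that("gene ranking takes the max element score and an oracle ordering", {
  el <- data.frame(chrom = "chr1", start = 1:4 * 100L,
                   end = 1:4 * 100L + 50L,
                   score = c(3.2, 7.1, 5.0, 2.0))
  assoc <- data.frame(element = 1:4,
                      gene_id = c("g1", "g1", "g2", "g3"))
  r <- rank_associated_genes(el, assoc, top_n = 10)
  expect_equal(r$gene_id, c("g1", "g2", "g3"))
  expect_equal(r$score, c(7.1, 5.0, 2.0))

  set.seed(31)
  n <- 1000
  el2 <- data.frame(chrom = "chr1", start = seq_len(n) * 10L,
                    end = seq_len(n) * 10L + 5L,
                    score = round(runif(n, 0, 50), 3))
  assoc2 <- data.frame(element = seq_len(n),
                       gene_id = sprintf("g%04d", seq_len(n)))
  top <- rank_associated_genes(el2, assoc2, top_n = 100)
  oracle <- assoc2$gene_id[order(-el2$score, assoc2$gene_id)][1:100]
  expect_equal(top$gene_id, oracle)
  expect_equal(nrow(rank_associated_genes(el, assoc, top_n = 500)), 3)
})

test_that("SNP density contrast matches a hand-computed chi-squared", {
  tg <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  # exactly proportional counts: chi2 = 0, p = 1
  snps_prop <- data.frame(chrom = "chr1",
                          pos = c(seq(0, 999, by = 100),
                                  seq(1000, 999000, length.out = 9990)))
  r0 <- snp_density_test(snps_prop, tg, 1e6)
  expect_equal(r0$chisq, 0, tolerance = 1e-6)
  expect_equal(r0$p_value, 1, tolerance = 1e-6)

  # 10 SNPs in 1 kb target, 10 in the 999 kb remainder
  snps <- data.frame(chrom = "chr1",
                     pos = c(seq(0, 999, by = 100) + 5,
                             seq(2000, 998000, length.out = 10)))
  r <- snp_density_test(snps, tg, 1e6)
  expect_equal(r$density_in, 10)
  expect_equal(r$density_out, 10 / 999, tolerance = 1e-6)
  tab <- matrix(c(10, 990, 10, 998990), 2, 2, byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  # an expected cell is < 5 here, so the documented continuity
  # correction kicks in; the oracle applies the same correction by hand
  corr <- pmin(0.5, abs(tab - expd))
  oracle <- sum((abs(tab - expd) - corr)^2 / expd)
  expect_equal(r$chisq, oracle, tolerance = 1e-8)

  expect_error(snp_density_test(snps[0, ], tg, 1e6), "no variants")
  expect_error(snp_density_test(snps, data.frame(chrom = "chr1",
                                                 start = 0L, end = 1e6),
                                1e6), "part")
})

test_that("snp density p-values are calibrated under the null", {
  el <- data.frame(start = seq(0, 90000, by = 10000),
                   end = seq(0, 90000, by = 10000) + 2000)
  ps <- vapply(1:200, function(i) {
    s <- simulate_snps(1e5, el, 2, 2, seed = 5000 + i)
    snp_density_test(s, data.frame(chrom = "chr1", el), 1e5)$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("interval merge and intersect agree with a bitmap oracle", {
  set.seed(77)
  len <- 10000L
  for (rep in 1:5) {
    a <- data.frame(chrom = "chr1",
                    start = sample(0:(len - 200), 30))
    a$end <- a$start + sample(1:200, 30, replace = TRUE)
    b <- data.frame(chrom = "chr1",
                    start = sample(0:(len - 200), 30))
    b$end <- b$start + sample(1:200, 30, replace = TRUE)
    expect_equal(oracle_bitmap(merge_intervals(a), len), oracle_bitmap(a, len))
    expect_equal(oracle_bitmap(intersect_intervals(a, b), len),
                 oracle_bitmap(a, len) & oracle_bitmap(b, len))
    expect_equal(interval_overlap_bp(a, b),
                 sum(oracle_bitmap(a, len) & oracle_bitmap(b, len)))
  }
})

test_that("BED round-trips intervals and converts scores to 10*log10", {
  f <- withr::local_tempfile(fileext = ".bed")
  df <- data.frame(chrom = "chr1", start = c(10L, 300L),
                   end = c(60L, 420L), name = c("e1", "e2"),
                   score = c(2.302585, 23.02585))  # 1 and 10 in log10
  write_bed(df, f)
  back <- read_bed(f)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$score, c(10, 100))
})
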