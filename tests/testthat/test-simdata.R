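test_that("alignment simulation is deterministic and respects the tree", {
  tr <- tree6()
  m <- jc_model()
  a1 <- simulate_alignment(tr, m, 200, seed = 5)
  a2 <- simulate_alignment(tr, m, 200, seed = 5)
  expect_identical(a1$mat, a2$mat)
  expect_false(identical(a1$mat, simulate_alignment(tr, m, 200, seed = 6)$mat))

  tr0 <- tr
  tr0$edge.length[] <- 0
  a0 <- simulate_alignment(tr0, m, 100, seed = 1)
  expect_true(all(apply(a0$mat, 2, function(x) length(unique(x)) == 1)))

  # generators do not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_alignment(tr, m, 10, seed = 2))
  expect_identical(runif(1), x1)
})

test_that("simulated base frequencies obey the law of large numbers", {
  tr <- tree6()
  a <- simulate_alignment(tr, jc_model(), 100000, seed = 8)
  freq <- table(a$mat) / length(a$mat)
  expect_true(all(abs(freq - 0.25) < 0.005))
})

test_that("planted elements have the constructed conservation structure", {
  tr <- tree6()
  m <- hky_model(3)
  clade <- c("s1", "s2", "s3", "s4")
  a <- simulate_alignment(tr, m, 2000, seed = 2)
  el <- data.frame(start = c(100, 400, 800),
                   length = c(100, 100, 100),
                   rho = c(0, 0.2, 0.2),
                   type = c("shared-conserved", "clade-specific-I",
                            "clade-specific-II"))
  pl <- plant_elements(a, tr, m, el, clade = clade, seed = 3)
  expect_equal(nrow(pl$truth), 3)
  expect_equal(pl$truth$end - pl$truth$start, rep(100, 3))

  # rho = 0: all rows identical within the element
  block0 <- pl$aln$mat[, 101:200]
  expect_true(all(apply(block0, 2, function(x) length(unique(x)) == 1)))
  # type I: outgroup rows all gaps
  blockI <- pl$aln$mat[c("s5", "s6"), 401:500]
  expect_true(all(blockI == "-"))
  # type II: clade rows more similar than outgroup rows
  blockII <- pl$aln$mat[, 801:900]
  ident <- function(x, y) mean(x == y)
  clade_id <- mean(c(ident(blockII["s1", ], blockII["s2", ]),
                     ident(blockII["s3", ], blockII["s4", ])))
  out_id <- ident(blockII["s5", ], blockII["s6", ])
  expect_gt(clade_id, out_id)

  expect_error(
    plant_elements(a, tr, m,
                   data.frame(start = c(0, 50), length = c(100, 100),
                              rho = 0.2, type = "shared-conserved"),
                   clade = clade, seed = 1),
    "overlapping")
})

test_that("stem-onset simulation yields the piecewise-clock stem length", {
  tr <- onset_tree(4L)
  m <- jc_model()
  ing <- paste0("b", 1:4)
  expect_error(simulate_stem_onset(tr, m, ing, onset = 120, rate = 0.002,
                                   rho = 0.1, columns = 10, seed = 1),
               "outside the stem interval")
  # endpoints: T = t0 fully conserved stem; T = t1 fully neutral stem
  for (cs in list(c(100, 0.1 * 0.002 * 34), c(66, 0.002 * 34))) {
    sim <- simulate_stem_onset(tr, m, ing, onset = cs[1], rate = 0.002,
                               rho = 0.1, columns = 4000, seed = 17)
    fit <- fit_branch_scales(sim$aln, m, sim$neutral_tree)
    se <- cladecons:::stem_edge(fit$tree, ing)
    sd3 <- 3 * sqrt(cs[2] / 4000)
    expect_lt(abs(fit$tree$edge.length[se] - cs[2]), 3 * sd3)
  }
})

test_that("SNP simulation places sorted unique positions at the set densities", {
  el <- data.frame(start = c(1000, 5000), end = c(2000, 6000))
  expect_equal(nrow(simulate_snps(10000, el, 0, 0, seed = 1)), 0)
  s <- simulate_snps(1e6, el, 2.59, 2.59, seed = 4)
  expect_false(is.unsorted(s$pos, strictly = TRUE))
  expect_true(all(s$pos >= 0 & s$pos < 1e6))
  expect_lt(abs(nrow(s) - 2590), 3 * sqrt(2590))
  expect_identical(s, simulate_snps(1e6, el, 2.59, 2.59, seed = 4))
})

test_that("interval simulation honours the enrichment fraction", {
  ws <- data.frame(chrom = "chr1", start = 0, end = 100000)
  tg <- data.frame(chrom = "chr1", start = c(10000, 50000),
                   end = c(20000, 60000))
  all_in <- simulate_intervals(ws, 50, 100, tg, fraction_inside = 1,
                               seed = 3)
  contained <- vapply(seq_len(50), function(i)
    any(tg$start <= all_in$intervals$start[i] &
          tg$end >= all_in$intervals$end[i]), logical(1))
  expect_true(all(contained))
  unif <- simulate_intervals(ws, 200, 100, tg, fraction_inside = 0,
                             seed = 4)
  expect_true(all(unif$intervals$start >= 0 &
                    unif$intervals$end <= 100000))
  # expected overlap fraction ~ target fraction of the workspace (20%)
  ov <- interval_overlap_bp(unif$intervals, tg)
  expect_lt(abs(ov / (200 * 100) - 0.2), 3 * sqrt(0.2 * 0.8 / 200))
})

test_that("expression simulation plants tau-1 genes and tau-0 housekeeping", {
  ex <- simulate_expression(100, c("a", "b", "c", "d"), n_specific = 5,
                            fold = 8, noise = 0, seed = 6)
  taus <- apply(ex$expr, 1, tau_specificity)
  planted <- rownames(ex$expr) %in% ex$specific$gene
  expect_true(all(taus[planted] == 1))
  expect_true(all(taus[!planted] == 0))
})
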