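test_that("annotation equal to the workspace gives fold 1 and p 1", {
  ws <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  q <- data.frame(chrom = "chr1", start = c(100L, 30000L),
                  end = c(600L, 30500L))
  r <- permute_interval_overlap(q, ws, ws, n_sims = 200L, seed = 1)
  expect_equal(r$observed, 1000)
  expect_equal(r$expected, 1000)
  expect_equal(r$fold, 1)
  expect_equal(r$p_enriched, 1)
})

test_that("point-query overlap matches the analytic expectation", {
  ws <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  ann <- data.frame(chrom = "chr1", start = c(10000L, 70000L),
                    end = c(20000L, 90000L))  # 30% of the workspace
  q <- data.frame(chrom = "chr1", start = seq(0, 99000, by = 500L))
  q$end <- q$start + 1L
  r <- permute_interval_overlap(q, ann, ws, n_sims = 2000L, seed = 7)
  expected <- nrow(q) * 0.3
  se <- r$sd / sqrt(r$n_sims)
  expect_lt(abs(r$expected - expected), max(3 * se, 3 * sqrt(expected)))
  # deterministic under a fixed seed
  r2 <- permute_interval_overlap(q, ann, ws, n_sims = 2000L, seed = 7)
  expect_identical(unclass(r), unclass(r2))
})

test_that("permutation p-values detect planted enrichment", {
  ws <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  tg <- data.frame(chrom = "chr1", start = seq(0, 90000, by = 10000L))
  tg$end <- tg$start + 1000L  # 10% of the workspace
  hits <- 0L
  for (i in 1:20) {
    q <- simulate_intervals(ws, 40, 50, tg, fraction_inside = 0.5,
                            seed = 100 + i)$intervals
    r <- permute_interval_overlap(q, tg, ws, n_sims = 2000L,
                                  seed = 200 + i)
    hits <- hits + (r$p_enriched < 0.01)
  }
  expect_gte(hits, 19L)
})

test_that("a query segment longer than every workspace interval errors", {
  ws <- data.frame(chrom = "chr1", start = c(0L, 5000L),
                   end = c(1000L, 6000L))
  q <- data.frame(chrom = "chr1", start = 0L, end = 900L)
  expect_error(
    permute_interval_overlap(data.frame(chrom = "chr1", start = 0L,
                                        end = 2000L),
                             ws, ws, n_sims = 10L, seed = 1),
    "longer than every workspace interval|outside the workspace")
})

test_that("chi-squared term enrichment matches a hand-computed table", {
  bg <- sprintf("g%05d", 1:15000)
  lst <- bg[1:500]
  term <- c(bg[1:30], bg[601:670])  # 30 in list, 70 outside
  tm <- data.frame(term_id = "T1", gene_id = term)
  r <- chi2_term_enrichment(lst, tm, bg)
  tab <- matrix(c(30, 470, 70, 14430), 2, 2)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  # smallest expected cell is 3.3, so the continuity correction applies;
  # the oracle reproduces it by hand
  corr <- pmin(0.5, abs(tab - expd))
  expect_equal(r$chisq, sum((abs(tab - expd) - corr)^2 / expd),
               tolerance = 1e-8)
  expect_equal(r$direction, "enriched")
  expect_equal(r$q_value, bh_fdr(r$p_value))

  # proportional representation: chi2 = 0, p = 1
  tm2 <- data.frame(term_id = "T2",
                    gene_id = c(bg[1:10], bg[501:790]))  # 10/500 = 300/15000
  r2 <- chi2_term_enrichment(lst, tm2, bg)
  expect_equal(r2$chisq, 0, tolerance = 1e-10)
  expect_equal(r2$p_value, 1, tolerance = 1e-10)
  expect_warning(chi2_term_enrichment(lst,
                                      data.frame(term_id = "T3",
                                                 gene_id = "nope"), bg),
                 "no background members")
})

test_that("fisher p-values match margin-fixed enumeration for n <= 40", {
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_true(fisher_2x2(tab)$degenerate)
      next
    }
    p <- fisher_2x2(tab)$p_value
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(fisher_2x2(t(tab))$p_value, p, tolerance = 1e-12)
  }
  d <- fisher_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("fisher and chi-squared point the same way on random tables", {
  set.seed(23)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    ft <- fisher_2x2(tab)
    expect_true(ft$p_value >= 0 && ft$p_value <= 1)
    # both tests call the same tables (non-)significant at mild levels
    agree <- (ct$p.value < 0.05) == (ft$p_value < 0.05) ||
      abs(ct$p.value - ft$p_value) < 0.05
    expect_true(agree)
  }
})

test_that("tau takes its documented values on reference vectors", {
  expect_equal(tau_specificity(c(0, 0, 5, 0)), 1)
  expect_equal(tau_specificity(c(2, 2, 2)), 0)
  expect_equal(tau_specificity(c(1, 2)), 0.5)
  expect_equal(tau_specificity(c(0, 1, 2)), 0.75)
  expect_warning(expect_true(is.na(tau_specificity(c(0, 0)))),
                 "all-zero")
  expect_error(tau_specificity(c(1)), "length")
  expect_error(tau_specificity(c(-1, 2)), ">= 0")
})

test_that("stage-specific calls use the tau threshold and argmax stage", {
  expr <- rbind(one = c(0, 0, 9), hk = c(3, 3, 3), mid = c(1, 4, 1))
  colnames(expr) <- c("s1", "s2", "s3")
  calls <- stage_specific_genes(expr, threshold = 0.8)
  expect_true(calls$specific[calls$gene == "one"])
  expect_false(calls$specific[calls$gene == "hk"])
  expect_equal(calls$stage[calls$gene == "one"], "s3")
  expect_equal(calls$stage[calls$gene == "mid"], "s2")
})

test_that("the cross-species filter applies strict fold thresholds", {
  fc <- rbind(kept = c(6, 1), turtle_high = c(6, 1), boundary = c(5, 1),
              not_deg = c(8, 1), no_orth = c(7, 1))
  colnames(fc) <- c("HH28", "HH38")
  deg <- fc > 5
  deg["not_deg", ] <- FALSE
  tfc <- rbind(t_kept = c(1.5, 1), t_turtle_high = c(2.5, 3),
               t_boundary = c(1, 1))
  colnames(tfc) <- c("TK15", "TK23")
  orth <- data.frame(chicken = c("kept", "turtle_high", "boundary",
                                 "not_deg"),
                     turtle = c("t_kept", "t_turtle_high", "t_boundary",
                                "t_not_deg"))
  r <- cross_species_candidate_filter(fc, deg, tfc, orth)
  expect_equal(r$candidates, "kept")
  expect_equal(r$no_ortholog, "no_orth")
})

test_that("planted cross-species candidates are recovered exactly", {
  sim <- simulate_cross_species_fc(200, 12, frac_no_ortholog = 0.1,
                                   seed = 9)
  r <- cross_species_candidate_filter(sim$chicken_fc, sim$chicken_deg,
                                      sim$turtle_fc, sim$orthology)
  expect_setequal(r$candidates, sim$truth)
})

test_that("stage over-representation reduces to a 2x2 fisher test", {
  calls <- data.frame(gene = sprintf("g%03d", 1:100),
                      tau = 1, stage = rep(c("A", "B"), each = 50),
                      specific = rep(c(TRUE, FALSE), 50))
  lst <- sprintf("g%03d", 1:20)
  r <- stage_overrepresentation(lst, calls, "A",
                                sprintf("g%03d", 1:100))
  expect_true(r$p_value <= 1 && r$p_value > 0)
  expect_equal(r$observed, sum(lst %in%
                                 calls$gene[calls$specific &
                                              calls$stage == "A"]))
})
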