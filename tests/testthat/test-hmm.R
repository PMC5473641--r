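test_that("emissions delegate to the pruning likelihood", {
  tr <- tree6()
  m <- hky_model(3)
  a <- simulate_alignment(tr, m, 40, seed = 2)
  em <- emission_table(a, m, tr, rho = 0.3)
  for (i in c(1, 17, 40)) {
    expect_equal(unname(em[i, "conserved"]),
                 column_log_likelihood(tr, m, a$mat[, i], scale = 0.3),
                 tolerance = 1e-12)
    expect_equal(unname(em[i, "nonconserved"]),
                 column_log_likelihood(tr, m, a$mat[, i]),
                 tolerance = 1e-12)
  }
  # rho = 1: the two states are the same model
  em1 <- emission_table(a, m, tr, rho = 1)
  expect_equal(em1[, 1], em1[, 2], tolerance = 1e-12)
  # an invariant column on a deep tree favours the conserved state
  inv <- msa(matrix("A", 6, 1, dimnames = list(tr$tip.label, NULL)))
  emi <- emission_table(inv, m, tr, rho = 0.2)
  expect_gt(emi[1, "conserved"], emi[1, "nonconserved"])
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(4)
  p <- phylo_hmm_params(0.3, mu = 0.08, nu = 0.02)
  for (rep in 1:5) {
    em <- matrix(log(runif(16)), 8, 2,
                 dimnames = list(NULL, c("conserved", "nonconserved")))
    fb <- forward_backward(em, p)
    or <- oracle_hmm_posterior(em, p)
    expect_equal(fb$posterior, or$posterior, tolerance = 1e-10)
    expect_equal(fb$loglik, or$loglik, tolerance = 1e-10)
  }
  expect_error(forward_backward(matrix(0, 0, 2), p), "empty")
})

test_that("uninformative emissions give the stationary posterior", {
  p <- phylo_hmm_params(1, mu = 0.05, nu = 0.01)
  em <- matrix(rep(c(-3.1, -3.1), each = 100), 100, 2)
  fb <- forward_backward(em, p)
  expect_equal(fb$posterior, rep(p$stationary[["conserved"]], 100),
               tolerance = 1e-12)
})

test_that("reversing columns with symmetric transitions reverses posteriors", {
  p <- phylo_hmm_params(0.3, mu = 0.03, nu = 0.03)
  set.seed(9)
  em <- matrix(log(runif(60)), 30, 2)
  fwd <- forward_backward(em, p)$posterior
  rev_post <- forward_backward(em[30:1, , drop = FALSE], p)$posterior
  expect_equal(rev_post, rev(fwd), tolerance = 1e-12)
})

test_that("forward-backward is stable on very long inputs", {
  p <- phylo_hmm_params(0.3)
  set.seed(2)
  em <- matrix(log(runif(2e6)), 1e6, 2)
  fb <- forward_backward(em, p)
  expect_true(is.finite(fb$loglik))
  expect_true(all(fb$posterior >= 0 & fb$posterior <= 1))
})

test_that("a uniform nonconserved tilt never yields elements", {
  # with mu = nu = 0.01 the transition penalty can never be overcome by
  # emissions that all favour nonconserved by 1 nat
  p <- phylo_hmm_params(0.3, mu = 0.01, nu = 0.01)
  em <- cbind(conserved = rep(-1, 500), nonconserved = rep(0, 500))
  expect_equal(nrow(viterbi_elements(em, p, min_length = 1)), 0)
})

test_that("the minimum-length filter drops 19 and keeps 20 columns", {
  p <- phylo_hmm_params(0.2, mu = 0.05, nu = 0.005)
  for (runlen in c(19L, 20L)) {
    em <- cbind(conserved = rep(-8, 200), nonconserved = rep(-1, 200))
    em[100 + seq_len(runlen), ] <- rep(c(-1, -8), each = runlen)
    els <- viterbi_elements(em, p, min_length = 20L)
    if (runlen == 19L) expect_equal(nrow(els), 0)
    else {
      expect_equal(nrow(els), 1)
      expect_equal(els$end - els$start, 20)
    }
  }
})

test_that("elements split at columns without a reference coordinate", {
  p <- phylo_hmm_params(0.2, mu = 0.05, nu = 0.005)
  em <- cbind(conserved = rep(-1, 100), nonconserved = rep(-8, 100))
  ref_pos <- c(0:49, NA, 51:99 - 1L)
  els <- viterbi_elements(em, p, ref_pos = ref_pos, min_length = 20L)
  expect_equal(nrow(els), 2)
  expect_true(all(els$end - els$start >= 20))
})

test_that("element log-odds is the summed emission contrast", {
  tr <- tree6()
  m <- hky_model(3)
  inv <- msa(matrix("G", 6, 50, dimnames = list(tr$tip.label, NULL)))
  em <- emission_table(inv, m, tr, rho = 0.3)
  oracle <- 0
  for (i in 1:50) oracle <- oracle + unname(em[i, 1] - em[i, 2])
  expect_equal(element_log_odds(1:50, em), oracle, tolerance = 1e-12)
  expect_equal(element_log_odds(1:20, em) + element_log_odds(21:50, em),
               element_log_odds(1:50, em), tolerance = 1e-12)
  em1 <- emission_table(inv, m, tr, rho = 1)
  expect_equal(element_log_odds(1:50, em1), 0, tolerance = 1e-12)
  expect_error(element_log_odds(45:55, em), "outside emission range")
})

test_that("EM recovers the conserved scale and never decreases loglik", {
  tr <- tree6()
  m <- hky_model(3)
  a <- simulate_alignment(tr, m, 50000, seed = 12)
  starts <- seq(500, 49000, by = 1000)  # 30% of columns conserved
  el <- data.frame(start = starts, length = 300, rho = 0.25,
                   type = "shared-conserved")
  pl <- plant_elements(a, tr, m, el, clade = tr$tip.label[1:4], seed = 13)
  fit <- estimate_rho(pl$aln, m, tr)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_gt(fit$params$rho, 0.15)
  expect_lt(fit$params$rho, 0.4)
  expect_false(fit$warning_flag)
})

test_that("wholly neutral data drives the EM to a flagged boundary", {
  tr <- tree6()
  m <- hky_model(3)
  a <- simulate_alignment(tr, m, 5000, seed = 14)
  fit <- suppressWarnings(estimate_rho(a, m, tr))
  expect_true(fit$warning_flag)
})

test_that("posterior decoding and Viterbi agree under strong signal", {
  tr <- tree6()
  m <- hky_model(3)
  a <- simulate_alignment(tr, m, 5000, seed = 15)
  el <- data.frame(start = seq(200, 4500, by = 430), length = 80,
                   rho = 0.15, type = "shared-conserved")
  pl <- plant_elements(a, tr, m, el, clade = tr$tip.label[1:4], seed = 16)
  em <- emission_table(pl$aln, m, tr, rho = 0.15)
  p <- phylo_hmm_params(0.15)
  fb <- forward_backward(em, p)
  vit <- cladecons:::viterbi_path(em, p)
  agree <- mean((fb$posterior >= 0.5) == (vit == 1L))
  expect_gte(agree, 0.95)
  # total posterior mass tracks the planted conserved fraction
  planted_frac <- sum(el$length) / 5000
  expect_lt(abs(mean(fb$posterior) / planted_frac - 1), 0.2)
})
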