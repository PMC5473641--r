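# Enrichment and downstream statistics: permutation-based interval
# overlap (GAT-style), categorical enrichment, Fisher's exact test, the
# tau stage-specificity index and the cross-species candidate filter.

#' Permutation test for interval overlap within a workspace
#'
#' Re-places every query segment (lengths preserved) uniformly at random
#' within the workspace `n_sims` times — segments never cross workspace
#' gaps, and placed segments may overlap each other — and compares the
#' observed nucleotide overlap with an annotation against the simulated
#' distribution. Empirical p-values use the add-one formulation
#' `(1 + #{sim >= obs}) / (n_sims + 1)` and are therefore never 0.
#'
#' @param query,annotation,workspace data.frames (chrom, start, end),
#'   0-based half-open. The annotation is intersected with the workspace
#'   first; the query must lie within the workspace.
#' @param n_sims Number of simulations (a typical production setting is
#'   100000; scale down for interactive use).
#' @param seed Integer seed; same seed, bit-identical result.
#' @return An `enrichment_result`: observed, expected (mean), sd, fold,
#'   p_enriched, p_depleted, n_sims, seed.
#' @export
permute_interval_overlap <- function(query, annotation, workspace,
                                     n_sims = 100000L, seed) {
  ws <- merge_intervals(workspace)
  ann <- intersect_intervals(annotation, ws)
  qmerged <- merge_intervals(query)
  if (interval_bp(intersect_intervals(qmerged, ws)) < interval_bp(qmerged))
    stop("query extends outside the workspace")
  wlen <- ws$end - ws$start
  qlen <- query$end - query$start
  if (any(qlen > max(wlen)))
    stop("a query segment is longer than every workspace interval")
  # concatenated workspace coordinate: annotation indicator cumulative sum
  offs <- cumsum(c(0, wlen))
  total <- offs[length(offs)]
  ind <- logical(total)
  for (i in seq_len(nrow(ann))) {
    wi <- which(ws$chrom == ann$chrom[i] & ws$start <= ann$start[i] &
                  ws$end >= ann$end[i])[1L]
    a <- offs[wi] + (ann$start[i] - ws$start[wi])
    ind[(a + 1L):(a + ann$end[i] - ann$start[i])] <- TRUE
  }
  cum <- c(0, cumsum(ind))
  observed <- interval_overlap_bp(query, ann)
  nq <- length(qlen)
  # placement: workspace interval weighted by how many start positions can
  # hold the segment, then a uniform offset; vectorised across simulations
  sims <- with_rng(seed, {
    ov <- numeric(n_sims)
    for (k in seq_len(nq)) {
      room <- pmax(wlen - qlen[k] + 1L, 0L)
      wi <- sample.int(length(wlen), n_sims, replace = TRUE, prob = room)
      off <- floor(stats::runif(n_sims) * room[wi])
      a <- offs[wi] + off
      ov <- ov + (cum[a + qlen[k] + 1L] - cum[a + 1L])
    }
    ov
  })
  structure(list(observed = observed, expected = mean(sims),
                 sd = stats::sd(sims),
                 fold = if (mean(sims) > 0) observed / mean(sims) else NA,
                 p_enriched = (1 + sum(sims >= observed)) / (n_sims + 1),
                 p_depleted = (1 + sum(sims <= observed)) / (n_sims + 1),
                 n_sims = n_sims, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d bp (expected %.1f +/- %.1f); fold %.2f; p_enriched %.3g; p_depleted %.3g (%d sims)\n",
    x$observed, x$expected, x$sd, x$fold, x$p_enriched, x$p_depleted,
    x$n_sims))
  invisible(x)
}

#' Chi-squared term enrichment for a gene list
#'
#' Per-term 2x2 chi-squared tests (in-list vs in-term) against a
#' background gene universe, with BH FDR across terms — the GO-enrichment
#' machinery for ranked associated-gene lists.
#'
#' @param gene_list Character vector (subset of `background`).
#' @param term_map data.frame(term_id, gene_id).
#' @param background Character vector of all genes.
#' @return data.frame(term_id, n_list, n_term, expected, chisq, p_value,
#'   q_value, direction).
#' @export
chi2_term_enrichment <- function(gene_list, term_map, background) {
  stopifnot(all(gene_list %in% background))
  N <- length(background)
  nl <- length(gene_list)
  terms <- unique(term_map$term_id)
  rows <- lapply(terms, function(tm) {
    tg <- intersect(term_map$gene_id[term_map$term_id == tm], background)
    if (length(tg) == 0L) {
      warning("term ", tm, " has no background members; skipped")
      return(NULL)
    }
    a <- length(intersect(gene_list, tg))
    tab <- matrix(c(a, nl - a, length(tg) - a, N - nl - length(tg) + a),
                  2, 2)
    expd <- outer(rowSums(tab), colSums(tab)) / N
    ct <- suppressWarnings(stats::chisq.test(tab, correct = any(expd < 5)))
    data.frame(term_id = tm, n_list = a, n_term = length(tg),
               expected = nl * length(tg) / N,
               chisq = unname(ct$statistic), p_value = ct$p.value,
               direction = if (a >= nl * length(tg) / N) "enriched"
               else "depleted")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (sum over margin-fixed tables
#' whose probability does not exceed the observed table's). Degenerate
#' tables (a zero margin) return p = 1 with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list(p_value, degenerate).
#' @export
fisher_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p_value = 1, degenerate = TRUE))
  list(p_value = stats::fisher.test(table)$p.value, degenerate = FALSE)
}

#' Tau expression-specificity index
#'
#' `tau = sum_i(1 - x_i / max(x)) / (N - 1)`: 1 for expression confined to
#' a single condition, 0 for uniform expression.
#'
#' @param x Non-negative expression vector over >= 2 stages.
#' @return Tau in \[0, 1\]; `NA` with a warning for an all-zero vector.
#' @export
tau_specificity <- function(x) {
  stopifnot(length(x) >= 2, all(x >= 0))
  m <- max(x)
  if (m == 0) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Call stage-specific genes from an expression matrix
#'
#' @param expr Numeric matrix, genes x stages.
#' @param threshold Tau threshold for calling a gene stage-specific
#'   (default 0.8).
#' @return data.frame(gene, tau, stage, specific); `stage` is the argmax
#'   stage.
#' @export
stage_specific_genes <- function(expr, threshold = 0.8) {
  tau <- apply(expr, 1, function(x)
    if (max(x) == 0) NA_real_ else tau_specificity(x))
  data.frame(gene = rownames(expr), tau = tau,
             stage = colnames(expr)[apply(expr, 1, which.max)],
             specific = !is.na(tau) & tau >= threshold,
             row.names = NULL)
}

#' Cross-species expression candidate filter
#'
#' Keeps genes that are differentially expressed in the focal species with
#' a fold change strictly greater than `fc_focal` in at least one
#' late-vs-phylotypic contrast, while their ortholog in the comparison
#' species changes strictly less than `fc_other`-fold in the corresponding
#' contrast. Genes without an ortholog are excluded and reported
#' separately.
#'
#' @param chicken_fc Numeric matrix, focal genes x contrasts (fold
#'   changes, > 0).
#' @param chicken_deg Logical matrix, same shape: DEG flags per contrast.
#' @param turtle_fc Numeric matrix, ortholog genes x paired contrasts.
#' @param orthology data.frame(chicken, turtle).
#' @param fc_focal,fc_other Fold-change thresholds (defaults 5 and 2;
#'   strict inequalities).
#' @return list(candidates = character vector, no_ortholog = genes that
#'   passed the focal filter but lack an ortholog).
#' @export
cross_species_candidate_filter <- function(chicken_fc, chicken_deg,
                                           turtle_fc, orthology,
                                           fc_focal = 5, fc_other = 2) {
  stopifnot(all(dim(chicken_fc) == dim(chicken_deg)),
            all(chicken_fc > 0))
  nc <- ncol(chicken_fc)
  stopifnot(ncol(turtle_fc) == nc)
  pass_focal <- chicken_deg & (chicken_fc > fc_focal)
  focal_genes <- rownames(chicken_fc)[rowSums(pass_focal) > 0]
  has_orth <- focal_genes %in% orthology$chicken
  cands <- character(0)
  for (g in focal_genes[has_orth]) {
    tg <- orthology$turtle[match(g, orthology$chicken)]
    contrasts <- which(pass_focal[g, ])
    if (any(turtle_fc[tg, contrasts] < fc_other)) cands <- c(cands, g)
  }
  list(candidates = cands, no_ortholog = focal_genes[!has_orth])
}

#' Fisher test for stage over-representation of a gene list
#'
#' Tests whether stage-specific genes at one stage are over-represented in
#' a gene list relative to the background (2x2 Fisher).
#'
#' @param gene_list Character vector.
#' @param stage_calls data.frame from [stage_specific_genes()].
#' @param stage Stage name to test.
#' @param background All genes.
#' @return list(p_value, observed, expected).
#' @export
stage_overrepresentation <- function(gene_list, stage_calls, stage,
                                     background) {
  spec <- stage_calls$gene[stage_calls$specific &
                             stage_calls$stage == stage]
  a <- length(intersect(gene_list, spec))
  b <- length(gene_list) - a
  c <- length(setdiff(spec, gene_list))
  d <- length(background) - a - b - c
  ft <- fisher_2x2(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))
  list(p_value = ft$p_value, observed = a,
       expected = length(gene_list) * length(spec) / length(background))
}
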