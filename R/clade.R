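# Clade-specific classification of conserved elements: outgroup presence,
# subtree-rate likelihood-ratio tests across several outgroup sets, and
# FDR control. The classification mirrors the two-type definition used for
# avian-specific elements: Type I = conserved in the ingroup with no
# outgroup sequence aligned; Type II = aligned in outgroups but evolving
# significantly faster there.

#' Define the ingroup / outgroup-set scheme
#'
#' @param ingroup Tip labels of the conserved clade.
#' @param outgroup_sets Named list of character vectors; the default
#'   three-set design mirrors nested outgroup sampling (nearest relative;
#'   close relatives; all outgroups).
#' @return An object of class `outgroup_scheme`.
#' @export
outgroup_scheme <- function(ingroup, outgroup_sets) {
  stopifnot(length(ingroup) >= 2, is.list(outgroup_sets),
            length(outgroup_sets) >= 1)
  if (is.null(names(outgroup_sets)))
    names(outgroup_sets) <- paste0("set", seq_along(outgroup_sets))
  for (s in outgroup_sets) {
    if (length(intersect(s, ingroup)))
      stop("outgroup species also in ingroup: ",
           intersect(s, ingroup)[1L])
  }
  structure(list(ingroup = ingroup, outgroup_sets = outgroup_sets),
            class = "outgroup_scheme")
}

#' Outgroup presence within an element
#'
#' An outgroup set is "absent" when every one of its species has fewer
#' than `threshold` (fraction) resolved characters (non-gap, non-N) across
#' the element. Species missing from the alignment count as all-gap.
#'
#' @param element An `msa` or character matrix of element columns.
#' @param outgroup Character vector of outgroup species.
#' @param threshold Presence threshold as a fraction of element columns
#'   (default 0.1).
#' @return `"present"` or `"absent"`.
#' @export
outgroup_presence <- function(element, outgroup, threshold = 0.1) {
  mat <- if (inherits(element, "msa")) element$mat else element
  frac <- vapply(outgroup, function(sp) {
    if (!sp %in% rownames(mat)) return(0)
    mean(mat[sp, ] %in% DNA_BASES4)
  }, 0)
  if (all(frac < threshold)) "absent" else "present"
}

#' Subtree-rate likelihood-ratio test for outgroup acceleration
#'
#' Contrasts a shared-rate null against ingroup/outgroup-specific rate
#' scales on the fixed neutral tree. H0 fits one scale applied to every
#' branch; H1 fits `lambda_in` on the ingroup branches (crown plus stem)
#' and `lambda_out` on all remaining branches. The one-sided acceleration
#' p-value is `0.5 * P(chi2_1 > LRT)` when the outgroup scale exceeds the
#' ingroup scale, and 1 otherwise.
#'
#' @param element An `msa` or character matrix of element columns.
#' @param tree Neutral `phylo` tree (all species).
#' @param model Neutral `subst_model`.
#' @param ingroup Ingroup tip labels.
#' @param outgroup Outgroup tip labels for this test (other species are
#'   masked to missing data).
#' @return list(lambda_in, lambda_out, lrt, p_value, untestable).
#' @export
subtree_rate_lrt <- function(element, tree, model, ingroup, outgroup) {
  mat <- if (inherits(element, "msa")) element$mat else element
  if (ncol(mat) < 5L)
    return(list(lambda_in = NA_real_, lambda_out = NA_real_,
                lrt = NA_real_, p_value = NA_real_, untestable = TRUE))
  keep <- intersect(rownames(mat), c(ingroup, outgroup))
  ctx <- peel_context(tree, mat[keep, , drop = FALSE])
  nl <- ctx$tr$edge.length
  in_edges <- clade_edges(ctx$tr, intersect(ingroup, ctx$tr$tip.label),
                          stem = TRUE)
  out_edges <- setdiff(seq_len(nrow(ctx$tr$edge)), in_edges)
  h0 <- fit_group_scales_ctx(ctx, model, nl,
                             list(seq_len(nrow(ctx$tr$edge))))
  h1 <- fit_group_scales_ctx(ctx, model, nl, list(in_edges, out_edges))
  lrt <- max(2 * (h1$loglik - h0$loglik), 0)
  p <- if (h1$scales[2L] <= h1$scales[1L]) 1 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  list(lambda_in = h1$scales[1L], lambda_out = h1$scales[2L],
       lrt = lrt, p_value = p, untestable = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction; a thin validating wrapper over
#' `stats::p.adjust(method = "BH")`, order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify conserved elements as clade-specific Type I / Type II
#'
#' Applies the two-type definition across a multi-set outgroup scheme:
#' * Type I (`ASHCE-I`): no outgroup species (union of all sets) reaches
#'   the presence threshold within the element.
#' * Type II (`ASHCE-II`): present in at least one set, and the outgroup
#'   acceleration test is significant at `q < q_threshold` in **all**
#'   sets, with the FDR computed within each set across elements.
#' * Otherwise `non-specific`. Elements shorter than `min_length` bp are
#'   never labelled clade-specific.
#'
#' @param elements data.frame of elements (chrom, start, end, ...) from
#'   [viterbi_elements()].
#' @param aln The full `msa` the elements were called on.
#' @param tree,model Neutral tree and model.
#' @param scheme An [outgroup_scheme()].
#' @param q_threshold FDR threshold (default 0.01).
#' @param presence_threshold Presence fraction (default 0.1).
#' @param min_length Minimum element length for a clade-specific label.
#' @return The elements data.frame with a `label` column in
#'   `{ASHCE-I, ASHCE-II, non-specific}` plus a `tests` attribute: one row
#'   per element x outgroup set with scales, LRT, p and q.
#' @export
classify_ashce <- function(elements, aln, tree, model, scheme,
                           q_threshold = 0.01, presence_threshold = 0.1,
                           min_length = 20L) {
  stopifnot(inherits(scheme, "outgroup_scheme"))
  ne <- nrow(elements)
  all_out <- unique(unlist(scheme$outgroup_sets))
  sets <- scheme$outgroup_sets
  slices <- lapply(seq_len(ne), function(i)
    msa_slice(aln, start = elements$start[i], end = elements$end[i]))
  absent_all <- vapply(slices, function(s)
    outgroup_presence(s, all_out, presence_threshold) == "absent",
    logical(1))
  tests <- do.call(rbind, lapply(seq_len(ne), function(i) {
    do.call(rbind, lapply(names(sets), function(sn) {
      pres <- outgroup_presence(slices[[i]], sets[[sn]],
                                presence_threshold)
      if (absent_all[i] || pres == "absent") {
        return(data.frame(element = i, set = sn, present = FALSE,
                          lambda_in = NA_real_, lambda_out = NA_real_,
                          lrt = NA_real_, p_value = NA_real_,
                          untestable = TRUE))
      }
      r <- subtree_rate_lrt(slices[[i]], tree, model, scheme$ingroup,
                            sets[[sn]])
      data.frame(element = i, set = sn, present = TRUE,
                 lambda_in = r$lambda_in, lambda_out = r$lambda_out,
                 lrt = r$lrt, p_value = r$p_value,
                 untestable = r$untestable)
    }))
  }))
  # per-set FDR across testable elements
  tests$q_value <- NA_real_
  for (sn in names(sets)) {
    idx <- which(tests$set == sn & !tests$untestable)
    if (length(idx)) tests$q_value[idx] <- bh_fdr(tests$p_value[idx])
  }
  label <- rep("non-specific", ne)
  long_enough <- (elements$end - elements$start) >= min_length
  label[absent_all & long_enough] <- "ASHCE-I"
  type2 <- vapply(seq_len(ne), function(i) {
    rows <- tests[tests$element == i, , drop = FALSE]
    any(rows$present) && !any(rows$untestable) &&
      all(rows$q_value < q_threshold)
  }, logical(1))
  label[type2 & !absent_all & long_enough] <- "ASHCE-II"
  elements$label <- label
  attr(elements, "tests") <- tests
  elements
}
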