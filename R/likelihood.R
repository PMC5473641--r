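#' Log-likelihood of a single alignment column under a phylogeny
#'
#' Felsenstein pruning over the tree. Gaps and `N` are missing data and are
#' marginalised; a column that is missing at every leaf has probability 1
#' (log-likelihood 0). `scale` multiplies every branch length, which is the
#' mechanism used by the conserved state of the phylo-HMM.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A `subst_model`.
#' @param column Named character vector, names are species (a subset of the
#'   tree's tips); characters in `{A,C,G,T,-,N}`.
#' @param scale Positive factor applied to every branch length.
#' @return Log-probability (natural log); `-Inf` for impossible columns.
#' @export
column_log_likelihood <- function(tree, model, column, scale = 1) {
  stopifnot(scale > 0)
  bad <- !(toupper(column) %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) stop("character outside alphabet {A,C,G,T,-,N}: '",
                     column[bad][1L], "'")
  if (!all(names(column) %in% tree$tip.label))
    stop("column species not in tree: ",
         setdiff(names(column), tree$tip.label)[1L])
  m <- matrix(toupper(column), ncol = 1, dimnames = list(names(column), NULL))
  peel_columns(tree, model, m, scale = scale)
}

# Vectorised pruning over a character matrix (species x columns); returns
# per-column log-likelihoods. Rows absent from the tree are an error; tree
# tips absent from the matrix are treated as missing data.
peel_columns <- function(tree, model, mat, scale = 1) {
  tips_coded <- encode_tips(mat, tree$tip.label)
  peel_coded(tree, model, tips_coded, scale = scale)
}

peel_coded <- function(tree, model, tips_coded, scale = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  lens <- tr$edge.length * scale
  pm <- edge_pmats(model, lens)
  root <- ape::Ntip(tr) + 1L
  peel_loglik_cpp(tr$edge, pm, tips_coded, model$pi,
                  ape::Ntip(tr) + tr$Nnode, root)
}

#' Total log-likelihood of an alignment
#'
#' Sum of per-column log-likelihoods with site-pattern compression.
#'
#' @inheritParams column_log_likelihood
#' @param aln An `msa` or a species-by-column character matrix.
#' @return Total log-likelihood.
#' @export
alignment_log_likelihood <- function(tree, model, aln, scale = 1) {
  mat <- if (inherits(aln, "msa")) aln$mat else aln
  pat <- compress_patterns(encode_tips(mat, tree$tip.label))
  ll <- peel_coded(tree, model, pat$tips, scale = scale)
  sum(ll * pat$weights)
}
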