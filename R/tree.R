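#' Parse a newick string into a validated rooted tree
#'
#' Thin validation layer over [ape::read.tree()]. The returned object is an
#' `ape::phylo` tree in which every edge carries a finite, non-negative
#' branch length in expected substitutions per site. Trees are the shared
#' scaffold of all likelihood computations in the package.
#'
#' @param text A newick string (terminated by `;`).
#' @return An object of class `phylo`, rooted, with `edge.length` set.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # 5
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: could not read tree")
  validate_tree(tr)
  tr
}

#' @rdname parse_newick
#' @param path Path to a newick file (first tree is used).
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1L]
    stop("newick parse error: duplicate leaf label '", dup, "'")
  }
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length))) stop("non-finite branch length")
  if (any(tr$edge.length < 0)) {
    stop("newick parse error: negative branch length ",
         min(tr$edge.length))
  }
  invisible(tr)
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Attach node ages (Myr before present) to a tree
#'
#' Ages calibrate conservation-onset dating and per-Myr substitution rates.
#' Tip ages default to 0 when only internal nodes are supplied. Ages must
#' decrease from parent to child.
#'
#' @param tree A `phylo` tree.
#' @param ages Named numeric vector of ages in Myr. Names are tip labels
#'   and/or internal node labels (`tree$node.label`); alternatively a full
#'   unnamed vector of length `Ntip + Nnode` in ape node order.
#' @return The tree with a `node_ages` attribute (length `Ntip + Nnode`).
#' @export
set_node_ages <- function(tree, ages) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  full <- rep(NA_real_, ntot)
  if (is.null(names(ages))) {
    stopifnot(length(ages) == ntot)
    full <- as.numeric(ages)
  } else {
    full[seq_len(ape::Ntip(tree))] <- 0
    idx <- match(names(ages), c(tree$tip.label, tree$node.label))
    if (anyNA(idx)) stop("unknown node label: ",
                         names(ages)[is.na(idx)][1L])
    full[idx] <- as.numeric(ages)
  }
  if (any(full < 0, na.rm = TRUE)) stop("ages must be >= 0")
  par <- tree$edge[, 1]; chl <- tree$edge[, 2]
  bad <- !is.na(full[par]) & !is.na(full[chl]) & full[chl] >= full[par]
  if (any(bad)) stop("child age must be < parent age (edge ",
                     which(bad)[1L], ")")
  attr(tree, "node_ages") <- full
  tree
}

#' @rdname set_node_ages
#' @export
node_ages <- function(tree) attr(tree, "node_ages")

# 1-based ape node id of the MRCA of a set of tips
clade_mrca <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tip not in tree: ", tips[is.na(idx)][1L])
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Edge indices (rows of tree$edge) inside a clade. `stem = TRUE` also
# includes the branch leading into the clade's MRCA.
clade_edges <- function(tree, tips, stem = TRUE) {
  mrca <- clade_mrca(tree, tips)
  desc <- if (mrca <= ape::Ntip(tree)) integer(0) else
    phangorn_descendants(tree, mrca)
  inside <- which(tree$edge[, 1] %in% c(mrca, desc))
  if (stem) inside <- sort(unique(c(inside, which(tree$edge[, 2] == mrca))))
  inside
}

# all descendant nodes (internal + tips) of `node`, excluding node itself
phangorn_descendants <- function(tree, node) {
  out <- integer(0)
  todo <- node
  while (length(todo)) {
    kids <- tree$edge[tree$edge[, 1] %in% todo, 2]
    out <- c(out, kids)
    todo <- kids[kids > ape::Ntip(tree)]
  }
  unique(out)
}

# stem edge index of a clade (the edge whose child is the clade MRCA)
stem_edge <- function(tree, tips) {
  mrca <- clade_mrca(tree, tips)
  e <- which(tree$edge[, 2] == mrca)
  if (length(e) != 1L) stop("clade has no stem branch (is it the root?)")
  e
}
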