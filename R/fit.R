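# Maximum-likelihood fitting of neutral models and branch lengths.
#
# All fits operate on site-pattern-compressed alignments and optimise
# log-transformed parameters with bounded quasi-Newton (L-BFGS-B), using
# two deterministic starts; no randomness is involved.

# postorder context reused across likelihood evaluations
peel_context <- function(tree, mat_or_coded, coded = FALSE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- if (coded) mat_or_coded else encode_tips(mat_or_coded, tr$tip.label)
  pat <- compress_patterns(tips)
  list(tr = tr, pat = pat, root = ape::Ntip(tr) + 1L,
       nnode = ape::Ntip(tr) + tr$Nnode)
}

ctx_loglik <- function(ctx, model, lens) {
  e <- model$eig
  ll <- peel_loglik_eig_cpp(ctx$tr$edge, e$V, e$Vinv, e$values, lens,
                            ctx$pat$tips, model$pi, ctx$nnode, ctx$root)
  sum(ll * ctx$pat$weights)
}

BL_MIN <- 1e-9
BL_MAX <- 1e2

#' Fit a neutral substitution model and branch lengths by maximum likelihood
#'
#' Estimates the nonconserved model of the conservation analysis from
#' putatively neutral alignment columns (typically fourfold-degenerate
#' sites supplied by the caller; see [fourfold_degenerate_columns()]).
#' Equilibrium frequencies are estimated empirically from the columns;
#' exchangeability parameters and all branch lengths are optimised jointly
#' on a fixed topology.
#'
#' @param aln An `msa` (or character matrix) of neutral columns.
#' @param topology A `phylo` tree whose tips cover the alignment rows;
#'   branch lengths, if present, are ignored.
#' @param family Model family passed to [substitution_model()].
#' @return A list with `model` (`subst_model`), `tree` (topology with ML
#'   branch lengths; lengths below 1e-8 are clamped to 0), `loglik`, and
#'   `convergence` (0 = converged).
#' @export
fit_neutral_model <- function(aln, topology, family = "HKY85") {
  mat <- if (inherits(aln, "msa")) aln$mat else aln
  stopifnot(ncol(mat) >= 1)
  if (!all(rownames(mat) %in% topology$tip.label))
    stop("alignment rows not covered by topology: ",
         setdiff(rownames(mat), topology$tip.label)[1L])
  ctx <- peel_context(topology, mat)
  # empirical base frequencies (pseudocount guards all-one-base corners)
  cnt <- table(factor(mat[mat %in% DNA_BASES4], levels = DNA_BASES4)) + 0.5
  pi_hat <- as.numeric(cnt / sum(cnt))

  n_var <- n_variable_patterns(ctx)
  if (n_var == 0L)
    warning("no variable columns: branch lengths collapse to the boundary")

  nedge <- nrow(ctx$tr$edge)
  npar_fam <- switch(family, JC69 = 0L, HKY85 = 1L, GTR = 5L)
  build <- function(fpar) {
    switch(family,
           JC69 = substitution_model("JC69"),
           HKY85 = substitution_model("HKY85", pi = pi_hat,
                                      kappa = exp(fpar[1L])),
           GTR = substitution_model("GTR", pi = pi_hat,
                                    rates = c(exp(fpar), 1)))
  }
  nll <- function(p) {
    lens <- exp(p[seq_len(nedge)])
    m <- build(p[nedge + seq_len(npar_fam)])
    -ctx_loglik(ctx, m, lens)
  }
  starts <- list(c(rep(log(0.1), nedge), rep(log(2), npar_fam)),
                 c(rep(log(0.5), nedge), rep(log(4), npar_fam)))
  fits <- lapply(starts, function(s)
    stats::optim(s, nll, method = "L-BFGS-B",
                 lower = c(rep(log(BL_MIN), nedge), rep(log(0.01), npar_fam)),
                 upper = c(rep(log(BL_MAX), nedge), rep(log(100), npar_fam)),
                 control = list(maxit = 500, factr = 1e7)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  lens <- exp(best$par[seq_len(nedge)])
  lens[lens < 1e-8] <- 0
  tree <- ctx$tr
  tree$edge.length <- lens
  list(model = build(best$par[nedge + seq_len(npar_fam)]),
       tree = tree, loglik = -best$value, convergence = best$convergence)
}

n_variable_patterns <- function(ctx) {
  obs <- apply(ctx$pat$tips, 2, function(s) length(unique(s[s >= 0])))
  sum(obs > 1)
}

#' Fit element-specific branch lengths on a fixed topology
#'
#' Re-estimates every branch length from an element alignment, holding the
#' substitution model and topology fixed — the per-locus rate estimation
#' step behind both clade-specific classification and onset dating.
#' Species present in the tree but absent from the alignment are treated as
#' missing data.
#'
#' @param element An `msa` (or character matrix) of element columns.
#' @param model A `subst_model` (the neutral model).
#' @param neutral_tree A `phylo` with neutral branch lengths (used as the
#'   optimisation start and for edge identity).
#' @param min_columns Warn when the element is shorter than this.
#' @return A list with `tree` (element-specific lengths, values below 1e-8
#'   clamped to 0) and `loglik`.
#' @export
fit_branch_scales <- function(element, model, neutral_tree,
                              min_columns = 20L) {
  mat <- if (inherits(element, "msa")) element$mat else element
  if (ncol(mat) < min_columns)
    warning("element has only ", ncol(mat), " columns (< ", min_columns,
            "); branch-length estimates will be noisy")
  ctx <- peel_context(neutral_tree, mat)
  fit <- fit_lengths_ctx(ctx, model,
                         start = pmax(ctx$tr$edge.length, 1e-4))
  tree <- ctx$tr
  tree$edge.length <- fit$lens
  list(tree = tree, loglik = fit$loglik)
}

# shared worker: optimise all branch lengths given a prepared context
fit_lengths_ctx <- function(ctx, model, start) {
  nedge <- nrow(ctx$tr$edge)
  nll <- function(p) -ctx_loglik(ctx, model, exp(p))
  fit <- stats::optim(log(pmin(pmax(start, BL_MIN), BL_MAX)), nll,
                      method = "L-BFGS-B",
                      lower = rep(log(BL_MIN), nedge),
                      upper = rep(log(BL_MAX), nedge),
                      control = list(maxit = 500, factr = 1e9))
  lens <- exp(fit$par)
  lens[lens < 1e-8] <- 0
  list(lens = lens, loglik = -fit$value)
}

# optimise one scale per edge group (list of edge-index vectors, in the
# postorder edge numbering of ctx$tr); scales multiply the neutral lengths
fit_group_scales_ctx <- function(ctx, model, neutral_lens, groups,
                                 lam_min = 1e-4, lam_max = 1e3) {
  ng <- length(groups)
  lens_for <- function(loglam) {
    lens <- neutral_lens
    for (g in seq_len(ng)) lens[groups[[g]]] <-
        lens[groups[[g]]] * exp(loglam[g])
    lens
  }
  if (ng == 1L) {
    opt <- stats::optimize(function(x) -ctx_loglik(ctx, model, lens_for(x)),
                           lower = log(lam_min), upper = log(lam_max),
                           tol = 1e-8)
    return(list(scales = exp(opt$minimum), loglik = -opt$objective))
  }
  nll <- function(p) -ctx_loglik(ctx, model, lens_for(p))
  fit <- stats::optim(rep(0, ng), nll, method = "L-BFGS-B",
                      lower = rep(log(lam_min), ng),
                      upper = rep(log(lam_max), ng),
                      control = list(maxit = 200, factr = 1e9))
  list(scales = exp(fit$par), loglik = -fit$value)
}

#' Extract fourfold-degenerate columns from a coding alignment
#'
#' Helper for preparing neutral-model input from annotated coding sequence:
#' takes codon phase from gene models and returns the third-position
#' columns of codons whose first two reference positions make every third
#' base synonymous (4-fold degenerate families).
#'
#' @param aln An `msa` whose reference row is coding sequence.
#' @param cds_frame 0-based frame of the first alignment column within its
#'   codon (0 = codon start), as given by the annotation's phase.
#' @return An `msa` of fourfold-degenerate third-position columns.
#' @export
fourfold_degenerate_columns <- function(aln, cds_frame = 0L) {
  ffd_pref <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")
  refrow <- aln$mat[aln$ref, ]
  n <- ncol(aln$mat)
  third <- which((seq_len(n) - 1L + cds_frame) %% 3L == 2L)
  third <- third[third >= 3L]
  keep <- third[paste0(refrow[third - 2L], refrow[third - 1L]) %in% ffd_pref]
  msa_slice(aln, cols = keep)
}
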