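# Synthetic-data generators. Every generator is a pure function of its
# parameters and `seed`: the RNG state is localised, so generators never
# perturb each other or the caller. A single pipeline seed expands into
# per-stage substreams via `substream_seed()` (documented order: alignment,
# elements, snps, intervals, expression, onset, hmm, enrichment).

with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

substream_seed <- function(seed, stream) {
  offsets <- c(alignment = 1L, elements = 2L, snps = 3L, intervals = 4L,
               expression = 5L, onset = 6L, hmm = 7L, enrichment = 8L)
  s <- (as.numeric(seed) * 1009L + offsets[[stream]]) %% 2147483647
  as.integer(s)
}

#' Simulate a gapless alignment along a tree
#'
#' Forward simulation of the neutral substitution process: root states are
#' drawn from the model's equilibrium frequencies and each branch mutates
#' them through the transition kernel `P(t)`.
#'
#' @param tree A `phylo` with branch lengths (expected substitutions/site).
#' @param model A `subst_model`.
#' @param length Number of columns.
#' @param seed Integer seed; same seed, same alignment.
#' @param ref Reference species (defaults to the first tip).
#' @param chrom,start Reference coordinates of the simulated block.
#' @return An `msa`.
#' @export
simulate_alignment <- function(tree, model, length, seed,
                               ref = tree$tip.label[1L],
                               chrom = "chr1", start = 0L) {
  stopifnot(length >= 1)
  with_rng(seed, {
    states <- simulate_states(tree, model, length)
    m <- matrix(DNA_BASES4[states[seq_len(ape::Ntip(tree)), , drop = FALSE]],
                nrow = ape::Ntip(tree))
    rownames(m) <- tree$tip.label
    msa(m, ref = ref, chrom = chrom, start = start)
  })
}

# integer state matrix (all nodes x columns), preorder evolution; assumes
# an active RNG (callers wrap in with_rng)
simulate_states <- function(tree, model, length) {
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntot <- ape::Ntip(tr) + tr$Nnode
  root <- ape::Ntip(tr) + 1L
  states <- matrix(0L, ntot, length)
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tr$edge))) {
    P <- transition_matrix(model, tr$edge.length[e])
    par <- states[tr$edge[e, 1L], ]
    chl <- integer(length)
    for (s in 1:4) {
      idx <- which(par == s)
      if (length(idx))
        chl[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[tr$edge[e, 2L], ] <- chl
  }
  states
}

#' Plant conserved elements with known ground truth
#'
#' Overwrites chosen intervals of a neutral alignment with columns
#' re-simulated under reduced substitution rates, creating the three
#' element classes the detection stack must distinguish:
#' * `shared-conserved` — every branch scaled by `rho`;
#' * `clade-specific-II` — only branches inside `clade` (crown plus stem)
#'   scaled by `rho`, outgroups neutral;
#' * `clade-specific-I` — as type II, and additionally every non-clade row
#'   is gapped out inside the element (no outgroup sequence aligned).
#'
#' @param aln Neutral `msa` from [simulate_alignment()].
#' @param tree,model The tree and model that generated `aln`.
#' @param elements data.frame with columns `start` (0-based alignment
#'   column), `length`, `rho`, `type` (one of the labels above).
#' @param clade Character vector of tip labels forming the conserved clade.
#' @param seed Integer seed.
#' @return A list with `aln` (modified alignment) and `truth` (data.frame
#'   of planted intervals: chrom, start, end, type, rho).
#' @export
plant_elements <- function(aln, tree, model, elements, clade, seed) {
  stopifnot(is.data.frame(elements),
            all(c("start", "length", "rho", "type") %in% names(elements)))
  types <- c("shared-conserved", "clade-specific-II", "clade-specific-I")
  if (!all(elements$type %in% types))
    stop("unknown element type: ",
         setdiff(elements$type, types)[1L])
  o <- order(elements$start)
  el <- elements[o, , drop = FALSE]
  if (any(el$start < 0) || any(el$start + el$length > ncol(aln$mat)))
    stop("element outside alignment bounds")
  if (nrow(el) > 1L &&
      any(el$start[-1L] < (el$start + el$length)[-nrow(el)]))
    stop("overlapping planted elements")
  cl_edges <- clade_edges(tree, clade, stem = TRUE)
  outgroup_rows <- setdiff(rownames(aln$mat), clade)
  with_rng(seed, {
    for (i in seq_len(nrow(el))) {
      cols <- el$start[i] + seq_len(el$length[i])
      tr2 <- tree
      if (el$type[i] == "shared-conserved") {
        tr2$edge.length <- tree$edge.length * el$rho[i]
      } else {
        tr2$edge.length[cl_edges] <- tree$edge.length[cl_edges] * el$rho[i]
      }
      st <- simulate_states(tr2, model, el$length[i])
      block <- matrix(DNA_BASES4[st[seq_len(ape::Ntip(tr2)), , drop = FALSE]],
                      nrow = ape::Ntip(tr2))
      rownames(block) <- tr2$tip.label
      aln$mat[rownames(block), cols] <- block
      if (el$type[i] == "clade-specific-I" && length(outgroup_rows))
        aln$mat[outgroup_rows, cols] <- "-"
    }
    truth <- data.frame(chrom = aln$chrom,
                        start = aln$ref_pos[el$start + 1L],
                        end = aln$ref_pos[el$start + 1L] + el$length,
                        type = el$type, rho = el$rho,
                        stringsAsFactors = FALSE)
    list(aln = aln, truth = truth)
  })
}

#' Simulate an element whose conservation began part-way down a stem branch
#'
#' Generates the input of the onset-dating analysis: a clade that is
#' conserved from onset time `onset` (Myr) onwards. The stem branch of the
#' clade carries `r*(t0 - onset) + rho*r*(onset - t1)` expected
#' substitutions per site (neutral before onset, conserved after); crown
#' branches inside the clade evolve at `rho * r` per Myr and all other
#' branches at the neutral rate `r`.
#'
#' @param tree A `phylo` (topology only; lengths are derived from ages)
#'   carrying node ages via [set_node_ages()].
#' @param model A `subst_model`.
#' @param ingroup Tip labels of the conserved clade.
#' @param onset Onset age T in Myr, with `t1 <= T <= t0` where `t0`/`t1`
#'   are the ages of the stem's top and bottom nodes.
#' @param rate Neutral substitution rate r (subs/site/Myr), > 0.
#' @param rho Conserved branch scale in (0, 1].
#' @param columns Element length in columns.
#' @param seed Integer seed.
#' @return A list with `aln` (the element alignment), `neutral_tree` (the
#'   fully neutral clock tree, lengths `r * duration`), and `truth`
#'   (onset, rate, rho, t0, t1).
#' @export
simulate_stem_onset <- function(tree, model, ingroup, onset, rate, rho,
                                columns, seed) {
  ages <- node_ages(tree)
  if (is.null(ages)) stop("tree has no node ages; use set_node_ages()")
  stopifnot(rate > 0, rho > 0, rho <= 1)
  dur <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  neutral <- tree
  neutral$edge.length <- rate * dur
  se <- stem_edge(tree, ingroup)
  t0 <- ages[tree$edge[se, 1]]
  t1 <- ages[tree$edge[se, 2]]
  if (onset < t1 || onset > t0)
    stop("onset T=", onset, " outside the stem interval [", t1, ", ", t0, "]")
  crown <- setdiff(clade_edges(tree, ingroup, stem = TRUE), se)
  simtree <- neutral
  simtree$edge.length[crown] <- rho * rate * dur[crown]
  simtree$edge.length[se] <- rate * (t0 - onset) + rho * rate * (onset - t1)
  aln <- simulate_alignment(simtree, model, columns, seed)
  list(aln = aln, neutral_tree = neutral,
       truth = list(onset = onset, rate = rate, rho = rho, t0 = t0, t1 = t1))
}

#' Simulate SNP positions with element-dependent density
#'
#' Poisson placement of variant positions at one density inside a set of
#' element intervals and another outside, emulating the reduced
#' polymorphism expected inside constrained elements.
#'
#' @param genome_length Workspace length in bp.
#' @param elements data.frame with 0-based half-open `start`, `end`.
#' @param density_in,density_out SNPs per kb inside/outside elements.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return data.frame(chrom, pos) of sorted, unique 0-based positions.
#' @export
simulate_snps <- function(genome_length, elements, density_in, density_out,
                          seed, chrom = "chr1") {
  stopifnot(density_in >= 0, density_out >= 0)
  el <- merge_intervals(data.frame(chrom = chrom,
                                   start = elements$start,
                                   end = elements$end))
  inside <- unlist(mapply(seq.int, el$start, el$end - 1L,
                          SIMPLIFY = FALSE))
  outside <- setdiff(seq_len(genome_length) - 1L, inside)
  with_rng(seed, {
    n_in <- stats::rpois(1L, density_in * length(inside) / 1000)
    n_out <- stats::rpois(1L, density_out * length(outside) / 1000)
    pos <- c(if (length(inside)) sample(inside, min(n_in, length(inside))),
             if (length(outside)) sample(outside, min(n_out, length(outside))))
    pos <- sort(unique(as.integer(pos)))
    data.frame(chrom = rep(chrom, length(pos)), pos = pos)
  })
}

#' Simulate an annotation interval set with controlled enrichment
#'
#' Places `n` intervals in a workspace, a fraction of them inside target
#' intervals, recording the ground-truth enrichment fraction — fixtures
#' for the permutation-enrichment statistics.
#'
#' @param workspace data.frame(chrom, start, end), 0-based half-open.
#' @param n Number of intervals.
#' @param mean_length Interval length (constant).
#' @param targets data.frame of target intervals, or `NULL`.
#' @param fraction_inside Fraction of intervals forced inside targets.
#' @param seed Integer seed.
#' @return list(intervals = data.frame(chrom, start, end),
#'   fraction_inside).
#' @export
simulate_intervals <- function(workspace, n, mean_length, targets = NULL,
                               fraction_inside = 0, seed) {
  stopifnot(fraction_inside >= 0, fraction_inside <= 1)
  with_rng(seed, {
    place_in <- function(regions, k, len) {
      w <- pmax(regions$end - regions$start - len + 1, 0)
      if (all(w == 0)) stop("no region can hold an interval of length ", len)
      ri <- sample.int(nrow(regions), k, replace = TRUE, prob = w)
      off <- floor(stats::runif(k) * w[ri])
      data.frame(chrom = regions$chrom[ri],
                 start = regions$start[ri] + off,
                 end = regions$start[ri] + off + len)
    }
    k_in <- rbinom_det(n, fraction_inside)
    out <- list()
    if (k_in > 0L) out[[1L]] <- place_in(targets, k_in, mean_length)
    if (n - k_in > 0L) out[[2L]] <- place_in(workspace, n - k_in, mean_length)
    iv <- do.call(rbind, out)
    iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    list(intervals = iv, fraction_inside = fraction_inside)
  })
}

# deterministic split: exactly round(n * f) intervals inside targets
rbinom_det <- function(n, f) as.integer(round(n * f))

#' Simulate a gene-by-stage expression table with planted stage-specific genes
#'
#' Housekeeping genes are expressed uniformly across stages; each stage
#' receives `n_specific` genes expressed only at that stage (level `fold`).
#' Gaussian noise (sd `noise`, clipped at 0) is added throughout, so at
#' `noise = 0` the planted genes have tau exactly 1 and housekeeping genes
#' tau exactly 0.
#'
#' @param n_genes Total number of genes.
#' @param stages Character vector of stage names.
#' @param n_specific Stage-specific genes per stage.
#' @param fold Expression level of a specific gene at its stage.
#' @param noise Gaussian noise sd.
#' @param seed Integer seed.
#' @return list(expr = numeric matrix genes x stages,
#'   specific = data.frame(gene, stage)).
#' @export
simulate_expression <- function(n_genes, stages, n_specific, fold = 10,
                                noise = 0, seed) {
  ns <- length(stages)
  stopifnot(n_specific * ns <= n_genes)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  with_rng(seed, {
    expr <- matrix(1, n_genes, ns, dimnames = list(genes, stages))
    spec <- data.frame(gene = character(0), stage = character(0))
    k <- 0L
    for (s in seq_len(ns)) {
      idx <- k + seq_len(n_specific)
      expr[idx, ] <- 0
      expr[idx, s] <- fold
      spec <- rbind(spec, data.frame(gene = genes[idx], stage = stages[s]))
      k <- k + n_specific
    }
    if (noise > 0)
      expr <- pmax(expr + matrix(stats::rnorm(length(expr), sd = noise),
                                 nrow(expr)), 0)
    list(expr = expr, specific = spec)
  })
}

#' Simulate cross-species fold-change tables with planted candidates
#'
#' Fixture for the cross-species expression filter: chicken fold changes
#' at two post-phylotypic stages with DEG flags, turtle fold changes at the
#' corresponding stages, and a partial orthology map. Planted candidates
#' have chicken fold change > 5 (DEG) and turtle fold change < 2.
#'
#' @param n_genes Number of chicken genes.
#' @param n_candidates Planted candidate genes.
#' @param frac_no_ortholog Fraction of genes without a turtle ortholog.
#' @param seed Integer seed.
#' @param contrasts,turtle_contrasts Stage-contrast names (paired in
#'   order).
#' @return list(chicken_fc, chicken_deg, turtle_fc, orthology, truth).
#' @export
simulate_cross_species_fc <- function(n_genes, n_candidates,
                                      frac_no_ortholog = 0.1, seed,
                                      contrasts = c("HH28", "HH38"),
                                      turtle_contrasts = c("TK15", "TK23")) {
  stopifnot(n_candidates <= n_genes)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  with_rng(seed, {
    nc <- length(contrasts)
    chicken_fc <- matrix(stats::runif(n_genes * nc, 0.5, 4), n_genes, nc,
                         dimnames = list(genes, contrasts))
    chicken_deg <- matrix(FALSE, n_genes, nc,
                          dimnames = list(genes, contrasts))
    cand <- genes[seq_len(n_candidates)]
    ci <- seq_len(n_candidates)
    cc <- 1L + (ci %% nc)  # contrast carrying the signal
    chicken_fc[cbind(ci, cc)] <- stats::runif(n_candidates, 5.5, 20)
    chicken_deg[cbind(ci, cc)] <- TRUE
    n_orth <- n_genes - as.integer(round(n_genes * frac_no_ortholog))
    orth_idx <- sort(c(ci, sample(setdiff(seq_len(n_genes), ci),
                                  max(n_orth - n_candidates, 0L))))
    orthology <- data.frame(chicken = genes[orth_idx],
                            turtle = paste0("t_", genes[orth_idx]))
    turtle_fc <- matrix(stats::runif(length(orth_idx) * nc, 0.5, 1.9),
                        length(orth_idx), nc,
                        dimnames = list(orthology$turtle, turtle_contrasts))
    # a decoy: some non-candidate orthologs mimic the chicken signal
    decoy <- setdiff(orth_idx, ci)
    if (length(decoy) >= 3L) {
      d <- decoy[1:3]
      chicken_fc[cbind(d, 1L + (d %% nc))] <- stats::runif(3, 5.5, 20)
      chicken_deg[cbind(d, 1L + (d %% nc))] <- TRUE
      turtle_fc[match(genes[d], orthology$chicken), ] <-
        stats::runif(3 * nc, 2.5, 6)
    }
    list(chicken_fc = chicken_fc, chicken_deg = chicken_deg,
         turtle_fc = turtle_fc, orthology = orthology,
         truth = cand)
  })
}
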