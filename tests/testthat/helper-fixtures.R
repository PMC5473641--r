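# Shared fixtures and independent oracles. Oracles are deliberately
# naive (full enumeration, bitmaps, direct summation) and never call the
# code paths they check.

jc_model <- function() substitution_model("JC69")

hky_model <- function(kappa = 3)
  substitution_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3), kappa = kappa)

# six-taxon ingroup tree, total length 2.0 subs/site
tree6 <- function() parse_newick(paste0(
  "(((s1:0.13,s2:0.20):0.07,(s3:0.26,s4:0.13):0.13):0.07,",
  "(s5:0.40,s6:0.26):0.13);"))

# 11-species tree: 8 ingroup birds + alligator/turtle/lizard outgroups
tree11 <- function() parse_newick(paste0(
  "(((((((bird1:0.04,bird2:0.04):0.03,(bird3:0.05,bird4:0.05):0.02):",
  "0.02,(bird5:0.06,bird6:0.06):0.03):0.02,(bird7:0.08,bird8:0.08):",
  "0.03):0.10,alligator:0.25):0.08,turtle:0.30):0.10,lizard:0.45);"))

birds8 <- function() paste0("bird", 1:8)

outgroups3 <- function() list(nearest = "alligator",
                              reptiles = c("alligator", "turtle", "lizard"),
                              all = c("alligator", "turtle", "lizard"))

# calibrated onset tree: 8 ingroup tips (crown 66 Myr), stem split at
# 100 Myr, further outgroups at 125 and 140 Myr; a rich crown pins the
# crown-ancestor state down and keeps the stem-length estimate tight
onset_tree <- function(ingroup_tips = 8L) {
  if (ingroup_tips == 4L) {
    tr <- parse_newick(paste0(
      "(((((b1:1,b2:1):1,(b3:1,b4:1):1):1,alligator:1):1,turtle:1):1,",
      "lizard:1);"))
    tr$node.label <- c("root", "n_t", "split", "crown", "n1", "n2")
    return(set_node_ages(tr, c(root = 140, n_t = 120, split = 100,
                               crown = 66, n1 = 40, n2 = 35, b1 = 0,
                               b2 = 0, b3 = 0, b4 = 0, alligator = 0,
                               turtle = 0, lizard = 0)))
  }
  tr <- parse_newick(paste0(
    "(((((((b1:1,b2:1):1,(b3:1,b4:1):1):1,(b5:1,b6:1):1):1,",
    "(b7:1,b8:1):1):1,alligator:1):1,turtle:1):1,lizard:1);"))
  ages <- rep(0, ape::Ntip(tr) + tr$Nnode)
  g <- function(...) ape::getMRCA(tr, c(...))
  ages[g("b1", "lizard")] <- 140
  ages[g("b1", "turtle")] <- 125
  ages[g("b1", "alligator")] <- 100
  ages[g("b1", "b8")] <- 66
  ages[g("b1", "b6")] <- 55
  ages[g("b1", "b4")] <- 45
  ages[g("b1", "b2")] <- 30
  ages[g("b3", "b4")] <- 32
  ages[g("b5", "b6")] <- 35
  ages[g("b7", "b8")] <- 38
  set_node_ages(tr, ages)
}

# --- oracles ---------------------------------------------------------

# column likelihood by exhaustive enumeration over internal-node states
# (leaves with missing data marginalised via per-leaf sums)
oracle_column_loglik <- function(tree, model, column, scale = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  root <- ntip + 1L
  Pm <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_matrix(model, tr$edge.length[e] * scale))
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  leaf_states <- lapply(tr$tip.label, function(sp) {
    ch <- toupper(column[sp])
    if (is.na(ch) || ch %in% c("-", "N")) 1:4 else codes[[ch]]
  })
  internal <- (ntip + 1L):ntot
  grid <- expand.grid(rep(list(1:4), length(internal)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- integer(ntot)
    asg[internal] <- as.integer(grid[g, ])
    p <- model$pi[asg[root]]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]
      chl <- tr$edge[e, 2L]
      p <- p * if (chl <= ntip)
        sum(Pm[[e]][asg[par], leaf_states[[chl]]]) else
          Pm[[e]][asg[par], asg[chl]]
      if (p == 0) break
    }
    tot <- tot + p
  }
  log(tot)
}

# HMM posterior by brute-force enumeration of all 2^L state paths
oracle_hmm_posterior <- function(emissions, params) {
  L <- nrow(emissions)
  A <- matrix(c(1 - params$mu, params$mu, params$nu, 1 - params$nu),
              2, 2, byrow = TRUE)
  init <- c(params$stationary)
  paths <- expand.grid(rep(list(1:2), L))
  probs <- apply(paths, 1, function(st) {
    p <- init[st[1L]] * exp(emissions[1L, st[1L]])
    for (t in seq_len(L - 1L))
      p <- p * A[st[t], st[t + 1L]] * exp(emissions[t + 1L, st[t + 1L]])
    p
  })
  post <- vapply(seq_len(L), function(t)
    sum(probs[paths[, t] == 1L]) / sum(probs), 0)
  list(posterior = post, loglik = log(sum(probs)))
}

# two-sided Fisher p by enumeration over all margin-fixed tables
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# per-base bitmap versions of interval merge/intersect (chrom <= 10 kb)
oracle_bitmap <- function(df, len) {
  v <- logical(len)
  for (i in seq_len(nrow(df)))
    if (df$end[i] > df$start[i])
      v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

random_column <- function(species, p_gap = 0.15) {
  chars <- sample(c("A", "C", "G", "T", "-", "N"), length(species),
                  replace = TRUE,
                  prob = c(rep((1 - p_gap) / 4, 4), p_gap * 0.7,
                           p_gap * 0.3))
  names(chars) <- species
  chars
}

# nucleotide-level Jaccard between two interval data.frames
jaccard_bp <- function(a, b) {
  inter <- interval_overlap_bp(a, b)
  union_bp <- interval_bp(merge_intervals(rbind(a[c("chrom", "start", "end")],
                                                b[c("chrom", "start", "end")])))
  if (union_bp == 0) return(NA_real_)
  inter / union_bp
}
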