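# End-to-end orchestration: neutral-model fitting -> HMM element calling
# -> clade-specific classification -> annotation/association/ranking ->
# SNP and enrichment statistics -> optional onset dating. All stage seeds
# derive from one global seed; re-running a config reproduces every
# seeded output bit-exactly.

#' Build a run configuration
#'
#' Thresholds default to the conventions of the clade-specific
#' conservation analysis: minimum element length 20 bp, per-set FDR
#' threshold 0.01, tau threshold 0.8, cross-species fold thresholds 5 and
#' 2.
#'
#' @param alignment,neutral_sites,tree,annotation,snps,expression Paths:
#'   MAF alignment, MAF of neutral (fourfold-degenerate) columns, newick
#'   tree, GFF3 gene models, SNP TSV (chrom, pos 1-based), expression TSV.
#'   `annotation`, `snps` and `expression` may be `NA` to skip those
#'   stages.
#' @param ingroup Character vector of ingroup species.
#' @param outgroup_sets Named list of outgroup sets.
#' @param family Substitution model family.
#' @param rho Conserved-state scale; `NA` estimates it from the data.
#' @param expected_length,coverage HMM tuning: expected element length
#'   (1/mu) in columns, stationary conserved coverage.
#' @param min_length,q_threshold,presence_threshold,tau_threshold,
#'   fc_focal,fc_other Thresholds (documented defaults).
#' @param n_sims Permutation count for enrichment tests.
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(alignment, neutral_sites, tree,
                       ingroup, outgroup_sets,
                       annotation = NA, snps = NA, expression = NA,
                       family = "HKY85", rho = NA,
                       expected_length = 45, coverage = 0.05,
                       min_length = 20L, q_threshold = 0.01,
                       presence_threshold = 0.1, tau_threshold = 0.8,
                       fc_focal = 5, fc_other = 2,
                       n_sims = 10000L, seed = 1L) {
  cfg <- list(alignment = alignment, neutral_sites = neutral_sites,
              tree = tree, ingroup = ingroup,
              outgroup_sets = outgroup_sets, annotation = annotation,
              snps = snps, expression = expression, family = family,
              rho = rho, expected_length = expected_length,
              coverage = coverage, min_length = as.integer(min_length),
              q_threshold = q_threshold,
              presence_threshold = presence_threshold,
              tau_threshold = tau_threshold, fc_focal = fc_focal,
              fc_other = fc_other, n_sims = as.integer(n_sims),
              seed = as.integer(seed))
  stopifnot(cfg$min_length >= 1, cfg$q_threshold > 0, cfg$q_threshold < 1,
            cfg$tau_threshold >= 0, cfg$tau_threshold <= 1,
            cfg$coverage > 0, cfg$coverage < 1, cfg$expected_length > 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) if (is.null(v)) NA else v)  # JSON null -> NA
  do.call(run_config, x)
}

#' Run the full detection pipeline
#'
#' Executes every stage on the inputs named in the config and writes all
#' outputs plus a machine-readable manifest into `out_dir`. Inputs are
#' validated up front, so a missing file fails before any computation.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created; must not exist or be empty).
#' @return Invisibly, a list of in-memory results (elements, tests,
#'   annotation, ...).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  req <- c(alignment = cfg$alignment, neutral_sites = cfg$neutral_sites,
           tree = cfg$tree)
  for (nm in names(req)) {
    if (!file.exists(req[[nm]]))
      stop("input file for '", nm, "' not found: ", req[[nm]])
  }
  opt <- c(annotation = cfg$annotation, snps = cfg$snps,
           expression = cfg$expression)
  for (nm in names(opt)) {
    if (!is.na(opt[[nm]]) && !file.exists(opt[[nm]]))
      stop("input file for '", nm, "' not found: ", opt[[nm]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  tree <- read_tree_file(cfg$tree)
  aln <- read_maf(cfg$alignment)
  neutral_aln <- read_maf(cfg$neutral_sites)

  # 1. neutral model from fourfold-degenerate columns
  fit <- fit_neutral_model(neutral_aln, tree, family = cfg$family)
  res$neutral <- fit
  write_model_json(fit$model, file.path(out_dir, "neutral_model.json"))
  writeLines(write_newick(fit$tree), file.path(out_dir, "neutral_tree.nwk"))

  # 2. conserved-element calling on the ingroup alignment only: the
  # conservation scan sees the clade; outgroups enter at classification
  ing_tree <- ape::keep.tip(fit$tree, cfg$ingroup)
  ing_aln <- aln
  ing_aln$mat <- aln$mat[intersect(rownames(aln$mat), cfg$ingroup), ,
                         drop = FALSE]
  mu <- 1 / cfg$expected_length
  if (is.na(cfg$rho)) {
    rfit <- estimate_rho(ing_aln, fit$model, ing_tree,
                         init = phylo_hmm_params(0.3, mu = mu,
                                                 coverage = cfg$coverage))
    params <- rfit$params
  } else {
    params <- phylo_hmm_params(cfg$rho, mu = mu, coverage = cfg$coverage)
  }
  res$hmm_params <- params
  em <- emission_table(ing_aln, fit$model, ing_tree, params$rho)
  fb <- forward_backward(em, params)
  elements <- viterbi_elements(em, params, ref_pos = aln$ref_pos,
                               chrom = aln$chrom,
                               min_length = cfg$min_length)
  write_wig(fb$posterior, aln$chrom,
            aln$ref_pos[which(!is.na(aln$ref_pos))[1L]],
            file.path(out_dir, "posterior.wig"))
  write_bed(elements, file.path(out_dir, "elements.bed"))

  # 3. clade-specific classification
  scheme <- outgroup_scheme(cfg$ingroup, cfg$outgroup_sets)
  classified <- classify_ashce(elements, aln, fit$tree, fit$model, scheme,
                               q_threshold = cfg$q_threshold,
                               presence_threshold = cfg$presence_threshold,
                               min_length = cfg$min_length)
  res$elements <- classified
  res$tests <- attr(classified, "tests")
  write_bed(classified, file.path(out_dir, "elements_classified.bed"))
  utils::write.table(res$tests, file.path(out_dir, "clade_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ashce <- classified[classified$label %in% c("ASHCE-I", "ASHCE-II"), ,
                      drop = FALSE]

  # 4. genomic context
  if (!is.na(cfg$annotation)) {
    models <- read_gene_models(cfg$annotation)
    classified$region <- classify_region(classified, models)
    assoc <- associate_genes(classified, models)
    ranked <- rank_associated_genes(classified, assoc, top_n = 500L)
    res$annotation <- classified$region
    res$association <- assoc
    res$ranked_genes <- ranked
    utils::write.table(
      data.frame(classified[, c("chrom", "start", "end", "label")],
                 region = classified$region),
      file.path(out_dir, "annotation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ranked, file.path(out_dir, "gene_ranks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # 5. SNP density contrast (inside clade-specific elements vs genome)
  if (!is.na(cfg$snps) && nrow(ashce)) {
    snps <- utils::read.table(cfg$snps, header = TRUE, sep = "\t")
    snps$pos <- snps$pos - 1L  # 1-based TSV -> 0-based
    glen <- max(aln$ref_pos, na.rm = TRUE) + 1L
    res$snp_test <- snp_density_test(snps, ashce, glen)
    jsonlite::write_json(res$snp_test[c("density_in", "density_out",
                                        "chisq", "p_value")],
                         file.path(out_dir, "snp_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # 6. expression stage-specificity
  if (!is.na(cfg$expression)) {
    expr <- as.matrix(utils::read.table(cfg$expression, header = TRUE,
                                        sep = "\t", row.names = 1L))
    calls <- stage_specific_genes(expr, threshold = cfg$tau_threshold)
    res$stage_calls <- calls
    utils::write.table(calls, file.path(out_dir, "tau.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cladecons")),
    seed = cfg$seed,
    config = unclass(cfg),
    inputs = lapply(req, function(p) unname(tools::md5sum(p))),
    n_elements = nrow(classified),
    n_clade_specific = nrow(ashce))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Generate the bundled demonstration dataset
#'
#' Simulates the full input set for a small end-to-end run: an ingroup of
#' 8 species with 3 successively deeper outgroups on a fixed tree, a
#' reference chromosome with planted conserved elements of all three
#' classes, matching neutral fourfold-degenerate columns, toy gene models,
#' SNPs at a 1.27 vs 2.59 per-kb density contrast, and a stage-expression
#' table.
#'
#' @param dir Directory to write inputs into.
#' @param seed Global seed.
#' @param genome_kb Reference length in kb (default 200).
#' @param n_elements Planted elements (default 30).
#' @return A [run_config()] pointing at the generated files, with the
#'   ground truth in attribute `truth`.
#' @export
demo_inputs <- function(dir, seed = 1L, genome_kb = 200L,
                        n_elements = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- demo_tree()
  model <- substitution_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3),
                              kappa = 3)
  ingroup <- paste0("bird", 1:8)
  L <- genome_kb * 1000L
  aln <- simulate_alignment(tree, model, L,
                            seed = substream_seed(seed, "alignment"))
  # planted elements: evenly spaced, alternating classes, rho = 0.2
  types <- rep(c("shared-conserved", "clade-specific-II",
                 "clade-specific-I"), length.out = n_elements)
  gap <- L %/% (n_elements + 1L)
  el <- data.frame(start = gap * seq_len(n_elements),
                   length = rep(c(60L, 100L, 150L),
                                length.out = n_elements),
                   rho = 0.2, type = types)
  planted <- plant_elements(aln, tree, model, el, clade = ingroup,
                            seed = substream_seed(seed, "elements"))
  write_maf(planted$aln, file.path(dir, "alignment.maf"))
  write_bed(planted$truth, file.path(dir, "truth_elements.bed"),
            score_in_nats = FALSE)
  neutral <- simulate_alignment(tree, model, 10000L,
                                seed = substream_seed(seed, "hmm"))
  write_maf(neutral, file.path(dir, "neutral_sites.maf"))
  writeLines(write_newick(tree), file.path(dir, "tree.nwk"))

  truth_cs <- planted$truth[planted$truth$type != "shared-conserved", ]
  snps <- simulate_snps(L, truth_cs, density_in = 1.27,
                        density_out = 2.59,
                        seed = substream_seed(seed, "snps"))
  utils::write.table(data.frame(chrom = snps$chrom, pos = snps$pos + 1L),
                     file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  models <- demo_gene_models(L)
  write_gene_models(models, file.path(dir, "genes.gff3"))

  ex <- simulate_expression(400L, c("HH16", "HH21", "HH28", "HH38"),
                            n_specific = 20L, fold = 10, noise = 0.05,
                            seed = substream_seed(seed, "expression"))
  utils::write.table(ex$expr, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  cfg <- run_config(
    alignment = file.path(dir, "alignment.maf"),
    neutral_sites = file.path(dir, "neutral_sites.maf"),
    tree = file.path(dir, "tree.nwk"),
    ingroup = ingroup,
    outgroup_sets = list(nearest = "alligator",
                         reptiles = c("alligator", "turtle", "lizard"),
                         all = c("alligator", "turtle", "lizard")),
    annotation = file.path(dir, "genes.gff3"),
    snps = file.path(dir, "snps.tsv"),
    expression = file.path(dir, "expression.tsv"),
    seed = seed)
  attr(cfg, "truth") <- planted$truth
  cfg
}

# fixed 11-species demo tree: 8 ingroup birds (crown depth ~0.12
# subs/site), alligator / turtle / lizard outgroups at increasing depth
demo_tree <- function() {
  parse_newick(paste0(
    "(((((((bird1:0.04,bird2:0.04):0.03,(bird3:0.05,bird4:0.05):0.02):",
    "0.02,(bird5:0.06,bird6:0.06):0.03):0.02,(bird7:0.08,bird8:0.08):",
    "0.03):0.10,alligator:0.25):0.08,turtle:0.30):0.10,lizard:0.45);"))
}

demo_gene_models <- function(L) {
  n_genes <- max(4L, L %/% 25000L)
  span <- L %/% n_genes
  starts <- span * (seq_len(n_genes) - 1L) + span %/% 4L
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    chrom = "chr1", strand = rep(c("+", "-"), length.out = n_genes),
    tx_start = starts, tx_end = starts + span %/% 2L)
  cds <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
               start = c(genes$tx_start[i] + 200L,
                         genes$tx_end[i] - 1000L),
               end = c(genes$tx_start[i] + 800L,
                       genes$tx_end[i] - 200L))
  }))
  list(genes = genes, cds = cds)
}
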