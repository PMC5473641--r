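# Genomic context of conserved elements: annotation class, nearest-gene
# association, ranked gene lists and the SNP-density contrast.

#' Read protein-coding gene models from GFF3
#'
#' Imports `gene`/`mRNA`/`CDS` features via rtracklayer, keeps one
#' transcript per gene (the one with the longest total CDS), and converts
#' to the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return list(genes = data.frame(gene_id, chrom, strand, tx_start,
#'   tx_end), cds = data.frame(gene_id, chrom, start, end)).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  cds <- gr[typ == "CDS"]
  if (length(mrna) == 0L || length(cds) == 0L)
    stop("GFF3 has no mRNA/CDS features")
  tx_id <- S4Vectors::mcols(mrna)$ID
  tx_parent <- as.character(unlist(S4Vectors::mcols(mrna)$Parent))
  cds_parent <- as.character(unlist(S4Vectors::mcols(cds)$Parent))
  cds_len <- tapply(GenomicRanges::width(cds), cds_parent, sum)
  # longest-CDS transcript per gene
  tx_tab <- data.frame(tx = tx_id, gene = tx_parent,
                       len = as.numeric(cds_len[tx_id]))
  tx_tab <- tx_tab[order(tx_tab$gene, -tx_tab$len, tx_tab$tx), ]
  tx_tab <- tx_tab[!duplicated(tx_tab$gene), ]
  keep_mrna <- mrna[match(tx_tab$tx, tx_id)]
  genes <- data.frame(
    gene_id = tx_tab$gene,
    chrom = as.character(GenomicRanges::seqnames(keep_mrna)),
    strand = as.character(GenomicRanges::strand(keep_mrna)),
    tx_start = GenomicRanges::start(keep_mrna) - 1L,
    tx_end = GenomicRanges::end(keep_mrna),
    stringsAsFactors = FALSE)
  keep_cds <- cds[cds_parent %in% tx_tab$tx]
  cdsdf <- data.frame(
    gene_id = tx_tab$gene[match(
      as.character(unlist(S4Vectors::mcols(keep_cds)$Parent)), tx_tab$tx)],
    chrom = as.character(GenomicRanges::seqnames(keep_cds)),
    start = GenomicRanges::start(keep_cds) - 1L,
    end = GenomicRanges::end(keep_cds),
    stringsAsFactors = FALSE)
  cdsdf <- cdsdf[order(cdsdf$gene_id, cdsdf$start), ]
  rownames(genes) <- rownames(cdsdf) <- NULL
  list(genes = genes, cds = cdsdf)
}

#' Write toy gene models as GFF3
#'
#' Inverse of [read_gene_models()] for simulated annotations.
#'
#' @param models list(genes, cds) as returned by [read_gene_models()].
#' @param path Output file.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tcladecons\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$tx_start[i] + 1L, g$tx_end[i], g$strand[i], gid),
      sprintf("%s\tcladecons\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom[i], g$tx_start[i] + 1L, g$tx_end[i], g$strand[i],
              gid, gid))
    cds <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\tcladecons\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                cds$chrom[j], cds$start[j] + 1L, cds$end[j], g$strand[i],
                gid, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# translation start/stop anchored windows per strand, 0-based half-open
translation_anchors <- function(models) {
  g <- models$genes
  cds_min <- tapply(models$cds$start, models$cds$gene_id, min)
  cds_max <- tapply(models$cds$end, models$cds$gene_id, max)
  g$cds_start <- as.integer(cds_min[g$gene_id])
  g$cds_end <- as.integer(cds_max[g$gene_id])
  g
}

#' Classify elements into the five annotation groups
#'
#' Priority order: coding > 5'/3' 10 kb > intronic > intergenic. "Coding"
#' means CDS overlap; the 5' window extends `window` bp upstream of the
#' translation start and the 3' window `window` bp downstream of the
#' translation stop, strand-aware. Elements inside a transcript span that
#' touch no CDS are intronic (UTR exons fall into this class).
#'
#' @param elements data.frame(chrom, start, end), 0-based half-open.
#' @param models Gene models from [read_gene_models()].
#' @param window Flanking window size in bp (default 10000).
#' @return Character vector in `{coding, five_prime_10kb, three_prime_10kb,
#'   intronic, intergenic}`, one per element.
#' @export
classify_region <- function(elements, models, window = 10000L) {
  if (nrow(elements) == 0L) return(character(0))
  if (nrow(models$genes) == 0L)
    return(rep("intergenic", nrow(elements)))
  g <- translation_anchors(models)
  plus <- g$strand != "-"
  five <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, g$cds_start - window, g$cds_end),
                     end = ifelse(plus, g$cds_start, g$cds_end + window))
  three <- data.frame(chrom = g$chrom,
                      start = ifelse(plus, g$cds_end, g$cds_start - window),
                      end = ifelse(plus, g$cds_end + window, g$cds_start))
  five$start <- pmax(five$start, 0L); three$start <- pmax(three$start, 0L)
  genic <- data.frame(chrom = g$chrom, start = g$tx_start, end = g$tx_end)
  el <- as_granges0(elements)
  hit <- function(df) {
    if (nrow(df) == 0L) return(rep(FALSE, nrow(elements)))
    IRanges::overlapsAny(el, as_granges0(df))
  }
  in_cds <- hit(models$cds)
  in_five <- hit(five)
  in_three <- hit(three)
  in_genic <- hit(genic)
  ifelse(in_cds, "coding",
         ifelse(in_five, "five_prime_10kb",
                ifelse(in_three, "three_prime_10kb",
                       ifelse(in_genic, "intronic", "intergenic"))))
}

#' Associate elements with their nearest gene
#'
#' Maps each element to the nearest protein-coding gene when the distance
#' from the element to the transcript span (transcription-anchored) is at
#' most `window` bp; distance 0 inside the span. Ties break to the smaller
#' distance, then the lexicographically smaller gene id.
#'
#' @param elements data.frame(chrom, start, end).
#' @param models Gene models.
#' @param window Maximum association distance in bp (default 10000).
#' @return data.frame(element = row index, gene_id, distance); elements
#'   farther than `window` from every gene are omitted.
#' @export
associate_genes <- function(elements, models, window = 10000L) {
  g <- models$genes
  out <- list()
  for (i in seq_len(nrow(elements))) {
    same <- g[g$chrom == elements$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    d <- pmax(same$tx_start - elements$end[i],
              elements$start[i] - same$tx_end, 0L)
    ord <- order(d, same$gene_id)
    if (d[ord[1L]] <= window) {
      out[[length(out) + 1L]] <-
        data.frame(element = i, gene_id = same$gene_id[ord[1L]],
                   distance = d[ord[1L]])
    }
  }
  if (!length(out))
    return(data.frame(element = integer(0), gene_id = character(0),
                      distance = integer(0)))
  do.call(rbind, out)
}

#' Rank associated genes by their best element score
#'
#' Each gene's score is the maximum log-odds score over its associated
#' elements; genes are sorted by descending score with ties broken by gene
#' id — the basis of the "top N associated genes" lists.
#'
#' @param elements data.frame with a `score` column (nats).
#' @param association Output of [associate_genes()].
#' @param top_n Keep the first `top_n` genes (no padding if fewer).
#' @return data.frame(gene_id, score) sorted by rank.
#' @export
rank_associated_genes <- function(elements, association,
                                  top_n = c(100L, 200L, 500L)[3L]) {
  stopifnot(all(is.finite(elements$score[association$element])))
  sc <- tapply(elements$score[association$element], association$gene_id,
               max)
  df <- data.frame(gene_id = names(sc), score = as.numeric(sc))
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_n)
}

#' SNP density contrast between a target interval set and its complement
#'
#' Treats every base as a Bernoulli trial for carrying a SNP and compares
#' densities inside vs outside the targets with a Pearson chi-squared test
#' on the 2x2 table (SNPs vs non-SNP bases, in vs out). Yates continuity
#' correction is applied only when an expected cell drops below 5.
#'
#' @param snps data.frame(chrom, pos), 0-based positions.
#' @param target data.frame(chrom, start, end) of target intervals.
#' @param genome_length Total workspace length in bp.
#' @return list(density_in, density_out) in SNPs/kb, `chisq`, `p_value`,
#'   and the underlying `table`.
#' @export
snp_density_test <- function(snps, target, genome_length) {
  if (nrow(snps) == 0L) stop("no variants")
  tg <- merge_intervals(target)
  bp_in <- interval_bp(tg)
  bp_out <- genome_length - bp_in
  if (bp_in <= 0 || bp_out <= 0)
    stop("target must cover part (not all) of the workspace")
  snp_gr <- as_granges0(data.frame(chrom = snps$chrom, start = snps$pos,
                                   end = snps$pos + 1L))
  n_in <- sum(IRanges::overlapsAny(snp_gr, as_granges0(tg)))
  n_out <- nrow(snps) - n_in
  tab <- matrix(c(n_in, bp_in - n_in, n_out, bp_out - n_out), 2, 2,
                byrow = TRUE,
                dimnames = list(c("in", "out"), c("snp", "no_snp")))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = any(expd < 5)))
  list(density_in = 1000 * n_in / bp_in,
       density_out = 1000 * n_out / bp_out,
       chisq = unname(ct$statistic), p_value = ct$p.value, table = tab)
}
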