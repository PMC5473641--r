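# Interval algebra on 0-based half-open data.frames (chrom, start, end),
# delegated to IRanges/GenomicRanges. All coordinates are 0-based
# half-open internally; GFF3's 1-based closed convention is converted at
# the I/O boundary.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

from_granges0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals
#'
#' @param df data.frame(chrom, start, end), 0-based half-open.
#' @return Sorted, merged data.frame of the same shape.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  out <- from_granges0(GenomicRanges::reduce(as_granges0(df)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect two interval sets
#'
#' @param a,b data.frames (chrom, start, end), 0-based half-open.
#' @return data.frame of intersection intervals.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  from_granges0(GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges0(a)),
    GenomicRanges::reduce(as_granges0(b))))
}

interval_bp <- function(df) if (nrow(df) == 0L) 0 else sum(df$end - df$start)

#' Total overlap between two interval sets in bp
#' @inheritParams intersect_intervals
#' @return Number of shared bases.
#' @export
interval_overlap_bp <- function(a, b) interval_bp(intersect_intervals(a, b))

#' Read / write BED intervals
#'
#' BED6 writer: `name` and `score` columns are taken from the data.frame
#' when present. Scores held in nats internally are written as
#' `round(10 * log10-odds)` per BED convention.
#'
#' @param df data.frame with chrom, start, end and optional name, score
#'   (nats), label.
#' @param path File path.
#' @param score_in_nats Convert `score` from nats to 10*log10 units.
#' @return `read_bed` returns a data.frame(chrom, start, end, name, score,
#'   strand) with as many columns as the file holds.
#' @export
write_bed <- function(df, path, score_in_nats = TRUE) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  out$name <- if (!is.null(df$label)) df$label else
    if (!is.null(df$name)) df$name else "."
  out$score <- if (!is.null(df$score)) {
    if (score_in_nats) round(10 * df$score / log(10)) else df$score
  } else 0
  out$strand <- if (!is.null(df$strand)) df$strand else "+"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  df
}

#' Write a fixedStep wiggle track of per-base scores
#'
#' @param scores Numeric vector (e.g. posterior conserved probability).
#' @param chrom Chromosome name.
#' @param start 0-based position of the first score.
#' @param path File path.
#' @export
write_wig <- function(scores, chrom, start, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom,
                     start + 1L), con)
  writeLines(formatC(scores, format = "g", digits = 6), con)
  invisible(path)
}
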