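#' Multiple alignment container with reference coordinates
#'
#' A species-by-column character matrix over the alphabet `{A,C,G,T,-,N}`
#' with MAF-like semantics: one row is the reference species, and every
#' column at which the reference is ungapped carries a 0-based reference
#' coordinate. Conserved elements are intervals on the reference genome.
#'
#' @param mat Character matrix, one row per species (rownames required),
#'   single characters from `A,C,G,T,-,N` (case-insensitive).
#' @param ref Reference species name (must be a rowname).
#' @param chrom Reference chromosome name.
#' @param start 0-based reference coordinate of the first ungapped
#'   reference column.
#' @return An object of class `msa`.
#' @export
msa <- function(mat, ref = rownames(mat)[1], chrom = "chr1", start = 0L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate species rows")
  mat[] <- toupper(mat)
  bad <- !(mat %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) stop("character outside alphabet {A,C,G,T,-,N}: '",
                     mat[bad][1L], "'")
  if (!ref %in% rownames(mat)) stop("reference species '", ref,
                                    "' not an alignment row")
  ref_gap <- mat[ref, ] == "-"
  ref_pos <- rep(NA_integer_, ncol(mat))
  ref_pos[!ref_gap] <- start + seq_len(sum(!ref_gap)) - 1L
  structure(list(mat = mat, ref = ref, chrom = chrom,
                 ref_pos = ref_pos),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple alignment:", nrow(x$mat), "species x", ncol(x$mat),
      "columns; ref", x$ref, "on", x$chrom, "\n")
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' Extract alignment columns by column index or reference interval
#'
#' @param aln An `msa`.
#' @param cols Column indices (1-based), or `NULL` to select by interval.
#' @param start,end 0-based half-open reference interval.
#' @return An `msa` restricted to the selected columns.
#' @export
msa_slice <- function(aln, cols = NULL, start = NULL, end = NULL) {
  if (is.null(cols)) {
    stopifnot(!is.null(start), !is.null(end))
    cols <- which(!is.na(aln$ref_pos) & aln$ref_pos >= start &
                    aln$ref_pos < end)
  }
  out <- aln
  out$mat <- aln$mat[, cols, drop = FALSE]
  out$ref_pos <- aln$ref_pos[cols]
  out
}

# integer encoding for the C peeler: 0..3 = A,C,G,T; -1 = gap/N/absent.
# Rows are reordered to the tree's tip order; tree tips missing from the
# alignment become all-missing rows.
encode_tips <- function(aln_mat, tip_labels) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, `-` = -1L, N = -1L)
  npat <- ncol(aln_mat)
  out <- matrix(-1L, length(tip_labels), npat)
  hit <- match(tip_labels, rownames(aln_mat))
  for (i in seq_along(tip_labels)) {
    if (!is.na(hit[i])) out[i, ] <- unname(code[aln_mat[hit[i], ]])
  }
  out
}

# collapse identical columns into patterns with weights; returns
# list(tips = coded pattern matrix, weights, index = pattern id per column)
compress_patterns <- function(tips_coded) {
  key <- apply(tips_coded, 2, paste, collapse = ",")
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  list(tips = tips_coded[, keep, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(keep))),
       index = idx)
}

#' Write / read a reference-anchored alignment in MAF
#'
#' Minimal MAF support: one or more blocks of `s` lines with the reference
#' row first. Sequence sources are written as `species.chrom`.
#'
#' @param aln An `msa` (single block).
#' @param path File path.
#' @return `read_maf` returns an `msa`; multiple blocks are concatenated
#'   when their reference coordinates are contiguous, otherwise an error.
#' @export
write_maf <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("a score=0.0", con)
  sp <- c(aln$ref, setdiff(rownames(aln$mat), aln$ref))
  start0 <- aln$ref_pos[which(!is.na(aln$ref_pos))[1L]]
  for (s in sp) {
    seq <- paste(aln$mat[s, ], collapse = "")
    n_res <- sum(aln$mat[s, ] != "-")
    st <- if (s == aln$ref) start0 else 0L
    writeLines(sprintf("s %s.%s %d %d + %d %s", s, aln$chrom, st, n_res,
                       max(st + n_res, 1L), seq), con)
  }
  writeLines("", con)
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  s_lines <- grep("^s ", lines, value = TRUE)
  a_idx <- grep("^a", lines)
  if (length(a_idx) == 0L) stop("no alignment blocks in MAF")
  blocks <- list()
  cur <- integer(0)
  block_of <- findInterval(grep("^s ", lines), a_idx)
  for (b in sort(unique(block_of))) {
    fl <- s_lines[block_of == b]
    parts <- strsplit(trimws(fl), "[[:space:]]+")
    src <- vapply(parts, `[[`, "", 2L)
    species <- sub("\\..*$", "", src)
    chrom <- sub("^[^.]*\\.", "", src)
    start <- as.integer(vapply(parts, `[[`, "", 3L))
    seqs <- vapply(parts, `[[`, "", 7L)
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- species
    blocks[[length(blocks) + 1L]] <-
      msa(m, ref = species[1L], chrom = chrom[1L], start = start[1L])
  }
  if (length(blocks) == 1L) return(blocks[[1L]])
  ref <- blocks[[1L]]$ref
  ends <- vapply(blocks, function(b) max(b$ref_pos, na.rm = TRUE) + 1L, 0L)
  starts <- vapply(blocks, function(b) min(b$ref_pos, na.rm = TRUE), 0L)
  if (any(starts[-1L] != ends[-length(ends)]))
    stop("non-contiguous MAF blocks; read them separately")
  sp <- unique(unlist(lapply(blocks, function(b) rownames(b$mat))))
  mats <- lapply(blocks, function(b) {
    m <- matrix("-", length(sp), ncol(b$mat), dimnames = list(sp, NULL))
    m[rownames(b$mat), ] <- b$mat
    m
  })
  msa(do.call(cbind, mats), ref = ref, chrom = blocks[[1L]]$chrom,
      start = starts[1L])
}

#' Write / read an alignment as multi-FASTA
#'
#' Fallback interchange format for single-block alignments (reference
#' coordinates restart at `start`).
#'
#' @inheritParams write_maf
#' @param ref,chrom,start Reference metadata applied on read.
#' @export
write_msa_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path, ref = NULL, chrom = "chr1", start = 0L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(m) <- names(ss)
  msa(m, ref = if (is.null(ref)) names(ss)[1L] else ref,
      chrom = chrom, start = start)
}
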