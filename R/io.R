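# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED6, bedGraph, FASTA/FASTQ (via Biostrings) and TSV tables.
# Intervals are held as GRanges (1-based closed) internally and converted
# to/from BED's 0-based half-open convention at the boundary.

#' Read a BED file into a sorted GRanges
#'
#' Accepts 3+ column tab-separated BED. Coordinates are converted from BED's
#' 0-based half-open convention to the 1-based GRanges convention. Strand is
#' taken from column 6 when present ("." becomes "*"). Overlapping records
#' are retained as-is; no merging is performed.
#'
#' @param path path to a BED file.
#' @return `GRanges` sorted by (chrom, start), with `name` and `score`
#'   metadata columns when the file has 4+ columns.
#' @export
load_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED parse error at line ", which(ncol < 3L)[1L],
         ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    stop("BED parse error at line ", which(bad)[1L],
         ": need 0 <= start < end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  if (all(ncol >= 4L)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  }
  if (all(ncol >= 5L)) {
    S4Vectors::mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(ncol >= 6L)) {
    s <- vapply(fields, `[[`, "", 6L)
    s[!s %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- s
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Emits BED3 (or BED6 when `six = TRUE`) with 0-based half-open coordinates.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param six write name/score/strand columns.
#' @export
write_intervals <- function(gr, path, six = FALSE) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  if (six) {
    nm <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name else "."
    sc <- if (!is.null(S4Vectors::mcols(gr)$score)) S4Vectors::mcols(gr)$score else 0
    st <- as.character(BiocGenerics::strand(gr))
    st[st == "*"] <- "."
    lines <- paste(chrom, start, end, nm, sc, st, sep = "\t")
  } else {
    lines <- paste(chrom, start, end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Total interval length of a peak set in bp
#'
#' Sum of interval widths; overlapping intervals are not merged first.
#'
#' @param gr a `GRanges`.
#' @return numeric total length in bp.
#' @export
total_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(gr)))
}

#' Read a bedGraph coverage track
#'
#' Four-column bedGraph. Segments on a chromosome must not overlap; gaps are
#' implicitly value 0. Returns a GRanges with a `score` metadata column.
#'
#' @param path path to a bedGraph file.
#' @return `GRanges` with numeric `score`, sorted.
#' @export
load_signal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "[\t ]+")
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph parse error at line ", which(lengths(fields) < 4L)[1L],
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  value <- as.numeric(vapply(fields, `[[`, "", 4L))
  if (any(is.na(value)) || any(!is.finite(value)) || any(value < 0)) {
    stop("bedGraph values must be finite and non-negative", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$score <- value
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  cov <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
  if (any(cov > 1L)) {
    stop("bedGraph parse error: overlapping segments on ",
         as.character(GenomicRanges::seqnames(gr))[which(cov > 1L)[1L]],
         call. = FALSE)
  }
  gr
}

#' Write a coverage track as bedGraph
#' @param track `GRanges` with a `score` column.
#' @param path output path.
#' @export
write_signal <- function(track, path) {
  lines <- paste(as.character(GenomicRanges::seqnames(track)),
                 GenomicRanges::start(track) - 1L,
                 GenomicRanges::end(track),
                 S4Vectors::mcols(track)$score,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read sequencing reads from FASTA/FASTQ
#'
#' Wraps Biostrings; format is inferred from the file extension (`.fq`,
#' `.fastq`, optionally gzipped, are FASTQ). Returns plain character vectors
#' so downstream code can use fast string operations.
#'
#' @param path path to a FASTA or FASTQ file (optionally .gz).
#' @return list with `seq` (character) and `qual` (character or NULL).
#' @export
load_reads <- function(path) {
  is_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  if (is_fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    list(seq = unname(as.character(x)), qual = NULL)
  }
}

#' Write reads as FASTQ with uniform qualities
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param qual per-base quality character (default "?" = Phred 30) or a
#'   character vector of full quality strings matching `seqs`.
#' @export
write_fastq <- function(seqs, path, qual = "?") {
  n <- length(seqs)
  quals <- if (length(qual) == 1L && nchar(qual) == 1L) {
    vapply(nchar(seqs), function(k) strrep(qual, k), character(1L))
  } else {
    qual
  }
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@read", seq_len(n))
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased on load, so softmasked bases participate in
#' scanning like their uppercase counterparts; non-ACGT bases fail every
#' informative pattern position.
#'
#' @param path path to a FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
load_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read a differential-expression table
#'
#' Tab-separated with a header row containing at least `gene`, `log2fc`
#' and `padj` columns. Missing `padj` values are treated as 1.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns gene, log2fc, padj.
#' @export
load_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(de))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  de$padj[is.na(de$padj)] <- 1
  de
}
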