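# Genomic paired-motif stage: non-overlapping degenerate scanning of peak
# sequences on the positive strand, per-Mb frequencies against a background
# peak set, one-sided exact binomial enrichment, gap-size profiles, and
# blacklist subtraction. In genomic scans the spacer between the two
# half-sites is matched as N^gap (the oligo library's TCGA spacer is a
# library artifact, not a binding requirement).

#' Greedy non-overlapping scan of a degenerate pattern
#'
#' Left-to-right scan; after a match at offset i the search resumes at
#' i + pattern length, so matches of one pattern never overlap. Matches of
#' different patterns may overlap freely (each pattern is scanned
#' independently).
#'
#' @param seq DNA string.
#' @param pattern IUPAC pattern.
#' @return integer vector of 0-based match offsets.
#' @export
scan_nonoverlapping <- function(seq, pattern) {
  if (nchar(pattern) > nchar(seq)) return(integer(0))
  m <- gregexpr(.iupac_regex(pattern), toupper(seq), perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

# Scan many sequences for many patterns in one pass per pattern: sequences
# are concatenated with "X" separators (X matches no pattern position, not
# even N-across-boundary because the greedy regex cannot span it for
# informative positions; N-only patterns are still confined because X fails
# the explicit [ACGT] class used for N in concatenated mode).
.scan_many <- function(seqs, patterns, labels = NULL) {
  if (length(seqs) == 0L || length(patterns) == 0L) {
    return(data.frame(pattern_id = integer(0), seq_id = integer(0),
                      offset = integer(0)))
  }
  sep <- "XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX"  # longer than any pattern
  blob <- paste(toupper(seqs), collapse = sep)
  starts <- cumsum(c(0L, nchar(seqs) + nchar(sep)))[seq_along(seqs)]
  out <- vector("list", length(patterns))
  for (p in seq_along(patterns)) {
    rx <- gsub(".", "[ACGTN]", .iupac_regex(patterns[p]), fixed = TRUE)
    m <- gregexpr(rx, blob, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    pos <- as.integer(m) - 1L
    sid <- findInterval(pos, starts)
    out[[p]] <- data.frame(pattern_id = p, seq_id = sid,
                           offset = pos - starts[sid])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(pattern_id = integer(0), seq_id = integer(0),
                      offset = integer(0))
  }
  res
}

#' Scan a peak set for oriented motif-pair occurrences
#'
#' Extracts each peak's sequence from the genome (positive strand only) and
#' scans it, non-overlapping per pattern, for every dictionary pair rebuilt
#' with an unconstrained N^gap spacer for each requested gap size.
#'
#' @param peaks `GRanges` peak set.
#' @param genome named character vector of chromosome sequences (or
#'   `DNAStringSet`).
#' @param dictionary data.frame with motif_a, motif_b, orientation columns
#'   (gapless pair definitions).
#' @param gap_sizes integer vector of spacer lengths to scan (default 4).
#' @return data.frame of occurrences: motif_a, motif_b, orientation, gap,
#'   chrom, start, end (1-based closed, genomic), peak (index into `peaks`).
#' @export
scan_peakset <- function(peaks, genome, dictionary, gap_sizes = 4L) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(chrom %in% names(genome))) {
    stop("peak chromosome missing from genome: ",
         setdiff(chrom, names(genome))[1L], call. = FALSE)
  }
  if (length(peaks) &&
      any(GenomicRanges::end(peaks) > nchar(genome[chrom]))) {
    bad <- which(GenomicRanges::end(peaks) > nchar(genome[chrom]))[1L]
    stop("peak ", bad, " extends beyond chromosome end", call. = FALSE)
  }
  seqs <- substr(genome[chrom], GenomicRanges::start(peaks),
                 GenomicRanges::end(peaks))
  grid <- expand.grid(row = seq_len(nrow(dictionary)), gap = gap_sizes,
                      KEEP.OUT.ATTRS = FALSE)
  patterns <- pair_pattern(dictionary$motif_a[grid$row],
                           dictionary$motif_b[grid$row],
                           dictionary$orientation[grid$row],
                           gap = strrep("N", grid$gap))
  hits <- .scan_many(seqs, patterns)
  if (nrow(hits) == 0L) {
    return(data.frame(motif_a = character(0), motif_b = character(0),
                      orientation = character(0), gap = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), peak = integer(0)))
  }
  row <- grid$row[hits$pattern_id]
  data.frame(
    motif_a = dictionary$motif_a[row],
    motif_b = dictionary$motif_b[row],
    orientation = dictionary$orientation[row],
    gap = grid$gap[hits$pattern_id],
    chrom = chrom[hits$seq_id],
    start = GenomicRanges::start(peaks)[hits$seq_id] + hits$offset,
    end = GenomicRanges::start(peaks)[hits$seq_id] + hits$offset +
      nchar(patterns[hits$pattern_id]) - 1L,
    peak = hits$seq_id,
    stringsAsFactors = FALSE
  )
}

# occurrences -> counts per (motif_a, motif_b, orientation, gap), aligned
# with a reference key table
.pair_counts <- function(occ, keys) {
  if (nrow(occ) == 0L) return(integer(nrow(keys)))
  k_occ <- paste(occ$motif_a, occ$motif_b, occ$orientation, occ$gap, sep = "|")
  k_ref <- paste(keys$motif_a, keys$motif_b, keys$orientation, keys$gap, sep = "|")
  as.integer(table(factor(k_occ, levels = k_ref)))
}

#' Exact binomial enrichment of motif pairs in foreground vs background
#'
#' For each pair key, the background per-bp rate p = bg_count / bg_len_bp
#' (floored at 1/bg_len_bp when the background count is 0) parameterizes a
#' one-sided exact binomial test of the foreground count over fg_len_bp
#' trials: p_value = P\[X >= fg_count\]. Frequencies are per Mb of total peak
#' length; when the background count is 0 the fold change uses a 0.5
#' continuity correction on both counts.
#'
#' @param fg_occ,bg_occ occurrence tables from [scan_peakset()].
#' @param fg_len_bp,bg_len_bp total peak lengths in bp.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param keys optional key table (motif_a, motif_b, orientation, gap); by
#'   default the union of keys observed in either occurrence table.
#' @param adjust apply Benjamini-Hochberg correction before thresholding
#'   (off by default, matching a raw p < alpha call).
#' @return data.frame with counts, per-Mb frequencies, fold_change, p_value
#'   and significance flag per pair key.
#' @export
pair_enrichment <- function(fg_occ, fg_len_bp, bg_occ, bg_len_bp,
                            alpha = 0.05, keys = NULL, adjust = FALSE) {
  if (fg_len_bp <= 0) stop("fg_len_bp must be positive", call. = FALSE)
  if (is.null(keys)) {
    keys <- unique(rbind(fg_occ[c("motif_a", "motif_b", "orientation", "gap")],
                         bg_occ[c("motif_a", "motif_b", "orientation", "gap")]))
    rownames(keys) <- NULL
  }
  cf <- .pair_counts(fg_occ, keys)
  cb <- .pair_counts(bg_occ, keys)
  out <- keys
  out$count_fg <- cf
  out$count_bg <- cb
  out$freq_fg <- cf / (fg_len_bp / 1e6)
  out$freq_bg <- cb / (bg_len_bp / 1e6)
  p_hat <- pmax(cb, 1L) / bg_len_bp
  out$p_value <- stats::pbinom(cf - 1L, size = round(fg_len_bp),
                               prob = p_hat, lower.tail = FALSE)
  fc_f <- ifelse(cb == 0L, cf + 0.5, cf)
  fc_b <- ifelse(cb == 0L, cb + 0.5, cb)
  out$fold_change <- (fc_f / (fg_len_bp / 1e6)) / (fc_b / (bg_len_bp / 1e6))
  p_eff <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_eff < alpha
  out
}

#' Gap-size profile of motif pairs in foreground and background peaks
#'
#' Rebuilds each pair pattern with an N^g spacer for every gap size in
#' `gap_range`, scans both peak sets, and reports per-Mb frequencies plus
#' the foreground/background frequency ratio (0.5-count continuity
#' correction when the background count is 0). The per-pair argmax gap of
#' the ratio summarizes the preferred spacing.
#'
#' @param peaks_fg,peaks_bg `GRanges` peak sets.
#' @param genome named character vector of chromosome sequences.
#' @param pairs data.frame with motif_a, motif_b, orientation rows to
#'   profile.
#' @param gap_range integer gaps to scan (default 1:10).
#' @return list with `profile` (per pair x gap frequencies and ratio) and
#'   `argmax` (per pair, the gap with maximal fg/bg ratio).
#' @export
gap_profile <- function(peaks_fg, peaks_bg, genome, pairs, gap_range = 1:10) {
  stopifnot(all(gap_range >= 0L), all(gap_range <= 20L))
  if (length(gap_range) == 0L) {
    empty <- data.frame(motif_a = character(0), motif_b = character(0),
                        orientation = character(0), gap = integer(0))
    return(list(profile = empty, argmax = empty))
  }
  fg_occ <- scan_peakset(peaks_fg, genome, pairs, gap_sizes = gap_range)
  bg_occ <- scan_peakset(peaks_bg, genome, pairs, gap_sizes = gap_range)
  keys <- expand.grid(row = seq_len(nrow(pairs)), gap = as.integer(gap_range),
                      KEEP.OUT.ATTRS = FALSE)
  keys <- data.frame(motif_a = pairs$motif_a[keys$row],
                     motif_b = pairs$motif_b[keys$row],
                     orientation = pairs$orientation[keys$row],
                     gap = keys$gap, stringsAsFactors = FALSE)
  fg_len <- total_bp(peaks_fg)
  bg_len <- total_bp(peaks_bg)
  cf <- .pair_counts(fg_occ, keys)
  cb <- .pair_counts(bg_occ, keys)
  prof <- keys
  prof$count_fg <- cf
  prof$count_bg <- cb
  prof$freq_fg <- cf / (fg_len / 1e6)
  prof$freq_bg <- cb / (bg_len / 1e6)
  fc_f <- ifelse(cb == 0L, cf + 0.5, cf)
  fc_b <- ifelse(cb == 0L, cb + 0.5, cb)
  prof$ratio <- (fc_f / (fg_len / 1e6)) / (fc_b / (bg_len / 1e6))
  key_pair <- paste(prof$motif_a, prof$motif_b, prof$orientation, sep = "|")
  am <- do.call(rbind, lapply(split(seq_len(nrow(prof)), key_pair), function(ix) {
    best <- ix[which.max(prof$ratio[ix])]
    data.frame(motif_a = prof$motif_a[best], motif_b = prof$motif_b[best],
               orientation = prof$orientation[best],
               argmax_gap = prof$gap[best], stringsAsFactors = FALSE)
  }))
  rownames(am) <- NULL
  list(profile = prof, argmax = am)
}

#' Remove peaks overlapping a blacklist
#'
#' Whole-peak removal: any peak overlapping any blacklist interval by at
#' least 1 bp is dropped (no trimming).
#'
#' @param peaks,blacklist `GRanges`.
#' @return filtered `GRanges`.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0L || length(peaks) == 0L) return(peaks)
  # a blacklist confined to other chromosomes is simply a no-op, not worth
  # the disjoint-seqlevels warning
  drop <- suppressWarnings(
    IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE))
  peaks[!drop]
}
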