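# Pull-down-seq enrichment stage for structured oligo libraries:
# read parsing by exact match of the fixed regions, dense/sparse count
# tables in RPM, per-sequence fold enrichment, and 2N-motif discovery
# (7-mers with two degenerate positions, aggregated over their 16
# concrete instantiations).

#' Extract variable regions from structured library reads
#'
#' Locates the library template within each read by exact match of all fixed
#' regions (flanks, gap, and site 2 when fixed), then extracts the variable
#' site sequence(s). Reads are rejected — with a reason code, never an error
#' — when the fixed structure cannot be located, a variable region contains a
#' non-ACGT base, or (when qualities are supplied) the minimum Phred score in
#' a variable region falls below `min_phred`.
#'
#' @param reads character vector of read sequences.
#' @param design a [library_design()].
#' @param quals optional character vector of Phred+33 quality strings.
#' @param min_phred minimum per-base Phred score in the variable regions.
#' @return data.frame with columns `site1`, `site2` (NA for fixed-site-2
#'   designs), `offset` (0-based template offset) and `reject` (NA when
#'   accepted, else one of "structure_mismatch", "ambiguous_base",
#'   "low_quality").
#' @export
parse_library_reads <- function(reads, design, quals = NULL, min_phred = 20L) {
  n <- length(reads)
  reads <- toupper(reads)
  pat <- .design_pattern(design)
  plen <- nchar(pat)
  offset <- rep(NA_integer_, n)

  # fast path: template anchored at offset 0 (full-length reads)
  full <- nchar(reads) == plen
  if (any(full)) {
    wb <- .encode_bits_matrix(reads[full], plen)
    hit <- .match_windows(pat, wb)
    offset[which(full)[hit]] <- 0L
  }
  # general path: scan remaining reads for the template
  todo <- which(is.na(offset) & nchar(reads) >= plen)
  rx <- .iupac_regex(pat)
  for (i in todo) {
    m <- regexpr(rx, reads[i], perl = TRUE)
    if (m > 0L) offset[i] <- as.integer(m) - 1L
  }

  reject <- rep(NA_character_, n)
  reject[is.na(offset)] <- "structure_mismatch"

  s1 <- rep(NA_character_, n)
  s2 <- rep(NA_character_, n)
  ok <- !is.na(offset)
  s1[ok] <- substr(reads[ok], offset[ok] + design$site1_start + 1L,
                   offset[ok] + design$site1_start + design$site1_len)
  var_s2 <- is.na(design$site2)
  if (var_s2) {
    s2[ok] <- substr(reads[ok], offset[ok] + design$site2_start + 1L,
                     offset[ok] + design$site2_start + design$site2_len)
  }
  amb <- ok & (grepl("[^ACGT]", s1) | (var_s2 & grepl("[^ACGT]", s2)))
  reject[amb] <- "ambiguous_base"

  if (!is.null(quals)) {
    qok <- which(ok & !amb)
    for (i in qok) {
      q1 <- utf8ToInt(substr(quals[i], offset[i] + design$site1_start + 1L,
                             offset[i] + design$site1_start + design$site1_len)) - 33L
      qmin <- min(q1)
      if (var_s2) {
        q2 <- utf8ToInt(substr(quals[i], offset[i] + design$site2_start + 1L,
                               offset[i] + design$site2_start + design$site2_len)) - 33L
        qmin <- min(qmin, q2)
      }
      if (qmin < min_phred) reject[i] <- "low_quality"
    }
  }

  bad <- !is.na(reject)
  s1[bad] <- NA_character_
  s2[bad] <- NA_character_
  data.frame(site1 = s1, site2 = s2, offset = offset, reject = reject,
             stringsAsFactors = FALSE)
}

# base-4 integer code of concrete k-mers (A=0,C=1,G=2,T=3), 0-based
.kmer_code <- function(seqs, k) {
  digit <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  codes <- matrix(digit[strsplit(paste(seqs, collapse = ""), "")[[1L]]],
                  nrow = k)
  as.integer(colSums(codes * 4L^((k - 1L):0L)))
}

.code_to_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(code))
  m <- matrix("", nrow = length(code), ncol = k)
  for (j in k:1) {
    m[, j] <- bases[code %% 4L + 1L]
    code <- code %/% 4L
  }
  apply(m, 1L, paste, collapse = "")
}

#' Tabulate unique variable-region sequences
#'
#' Builds a count table of unique sequences with reads-per-million
#' normalization. In dense mode every possible k-mer is enumerated (4^k rows,
#' zero-filled), which is required for unbiased 2N-motif aggregation; sparse
#' mode keeps only observed sequences (appropriate for long concatenated
#' keys).
#'
#' @param seqs character vector of equal-length accepted sequences.
#' @param dense enumerate the full 4^k key universe.
#' @return data.frame with columns `seq`, `count`, `rpm` (class
#'   `count_table`; `attr(,"total_reads")` holds the accepted-read total).
#' @export
tabulate_counts <- function(seqs, dense = FALSE) {
  k <- if (length(seqs)) unique(nchar(seqs)) else NA_integer_
  if (length(k) > 1L) stop("sequences must all have the same length", call. = FALSE)
  total <- length(seqs)
  if (dense) {
    if (is.na(k)) k <- 7L
    counts <- tabulate(.kmer_code(seqs, k) + 1L, nbins = 4L^k)
    tab <- data.frame(seq = .code_to_kmer(0:(4L^k - 1L), k),
                      count = counts, stringsAsFactors = FALSE)
  } else {
    t0 <- table(seqs)
    tab <- data.frame(seq = names(t0), count = as.integer(t0),
                      stringsAsFactors = FALSE)
  }
  tab$rpm <- if (total > 0) tab$count / total * 1e6 else 0
  attr(tab, "total_reads") <- total
  class(tab) <- c("count_table", class(tab))
  tab
}

#' Per-sequence fold enrichment of pull-down over input
#'
#' Enrichment = (pd_rpm + pseudocount) / (input_rpm + pseudocount), computed
#' over the shared key universe (dense tables) or the union of observed keys
#' (sparse tables, absent keys counted 0). Rows are ranked by descending
#' enrichment.
#'
#' @param pd,input count tables from [tabulate_counts()].
#' @param pseudocount additive smoothing in RPM units (default 0.5).
#' @return data.frame with per-sequence counts, RPM, enrichment and rank.
#' @export
fold_enrichment <- function(pd, input, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  keys <- union(pd$seq, input$seq)
  ip <- match(keys, pd$seq)
  ii <- match(keys, input$seq)
  out <- data.frame(
    seq = keys,
    count_pd = ifelse(is.na(ip), 0L, pd$count[ip]),
    count_input = ifelse(is.na(ii), 0L, input$count[ii]),
    rpm_pd = ifelse(is.na(ip), 0, pd$rpm[ip]),
    rpm_input = ifelse(is.na(ii), 0, input$rpm[ii]),
    stringsAsFactors = FALSE
  )
  out$enrichment <- (out$rpm_pd + pseudocount) / (out$rpm_input + pseudocount)
  out <- out[order(-out$enrichment, out$seq), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate the 2N motifs of a 7-mer
#'
#' All C(7,2) = 21 degenerate patterns obtained by replacing two positions of
#' a concrete 7-mer with N.
#'
#' @param seq a concrete 7-nt sequence.
#' @return character vector of 21 IUPAC patterns.
#' @export
enumerate_2n_patterns <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) != 7L || grepl("[^ACGT]", seq)) {
    stop("seq must be a concrete 7-mer", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1L]]
  pairs <- utils::combn(7L, 2L)
  apply(pairs, 2L, function(ij) {
    x <- chars
    x[ij] <- "N"
    paste(x, collapse = "")
  })
}

#' Aggregate dense count tables over 2N motifs
#'
#' Builds the deduplicated universe of 7-nt patterns with exactly two N
#' positions (21 position pairs x 4^5 concrete backbones = 21,504 patterns),
#' sums pull-down and input counts over each pattern's 16 concrete
#' instantiations, and ranks patterns by RPM fold enrichment. Also reports
#' the "coverage rank": the minimal number of top-ranked 2N motifs, taken
#' greedily in descending enrichment order, whose instantiation sets cover
#' every sequence in the top `top_quantile` fraction of per-sequence
#' enrichment.
#'
#' @param pd,input dense count tables over all 4^7 7-mers.
#' @param pseudocount smoothing in RPM units for enrichment ratios.
#' @param top_quantile fraction of top-enriched sequences for coverage rank.
#' @return list with `records` (data.frame: pattern, count_pd, count_input,
#'   rpm_pd, rpm_input, enrichment, rank) and `coverage_rank` (integer).
#' @export
aggregate_2n <- function(pd, input, pseudocount = 0.5, top_quantile = 0.10) {
  k <- 7L
  if (nrow(pd) != 4L^k || nrow(input) != 4L^k) {
    stop("2N aggregation requires dense tables over all 4^7 sequences",
         call. = FALSE)
  }
  codes <- 0:(4L^k - 1L)
  digits <- matrix(0L, nrow = 4L^k, ncol = k)
  tmp <- codes
  for (j in k:1) {
    digits[, j] <- tmp %% 4L
    tmp <- tmp %/% 4L
  }
  place <- 4L^((k - 1L):0L)
  pairs <- utils::combn(k, 2L)

  rec_pattern <- character(0)
  rec_pd <- integer(0); rec_in <- integer(0)
  rec_rpm_pd <- numeric(0); rec_rpm_in <- numeric(0)
  # per-sequence pattern membership for coverage ranking: pattern id of each
  # sequence under each of the 21 maskings
  membership <- matrix(0L, nrow = 4L^k, ncol = ncol(pairs))
  offset <- 0L
  for (p in seq_len(ncol(pairs))) {
    ij <- pairs[, p]
    masked <- codes - digits[, ij[1L]] * place[ij[1L]] -
      digits[, ij[2L]] * place[ij[2L]]
    fid <- match(masked, sort(unique(masked)))    # 1..4^5 backbone id
    membership[, p] <- offset + fid
    cnt_pd <- as.integer(rowsum(pd$count, fid))
    cnt_in <- as.integer(rowsum(input$count, fid))
    rpm_pd <- as.numeric(rowsum(pd$rpm, fid))
    rpm_in <- as.numeric(rowsum(input$rpm, fid))
    backbone <- .code_to_kmer(sort(unique(masked)), k)
    pat <- backbone
    substr(pat, ij[1L], ij[1L]) <- "N"
    substr(pat, ij[2L], ij[2L]) <- "N"
    rec_pattern <- c(rec_pattern, pat)
    rec_pd <- c(rec_pd, cnt_pd); rec_in <- c(rec_in, cnt_in)
    rec_rpm_pd <- c(rec_rpm_pd, rpm_pd); rec_rpm_in <- c(rec_rpm_in, rpm_in)
    offset <- offset + length(backbone)
  }
  records <- data.frame(pattern = rec_pattern,
                        count_pd = rec_pd, count_input = rec_in,
                        rpm_pd = rec_rpm_pd, rpm_input = rec_rpm_in,
                        stringsAsFactors = FALSE)
  records$enrichment <- (records$rpm_pd + pseudocount) /
    (records$rpm_input + pseudocount)
  ord <- order(-records$enrichment, records$pattern)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL

  # coverage rank: greedy cover of the top-quantile sequences
  fe <- fold_enrichment(pd, input, pseudocount)
  n_top <- max(1L, ceiling(top_quantile * nrow(fe)))
  top_codes <- .kmer_code(fe$seq[seq_len(n_top)], k) + 1L
  need <- membership[top_codes, , drop = FALSE]   # patterns covering each top seq
  covered <- rep(FALSE, n_top)
  pattern_id_by_rank <- match(records$pattern, rec_pattern)  # original id order
  coverage_rank <- NA_integer_
  for (r in seq_len(nrow(records))) {
    pid <- pattern_id_by_rank[r]
    covered <- covered | (rowSums(need == pid) > 0L)
    if (all(covered)) { coverage_rank <- r; break }
  }
  list(records = records, coverage_rank = coverage_rank)
}
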