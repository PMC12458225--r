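# Independent reference implementations used as oracles. These deliberately
# avoid the package's bitmask/regex machinery: membership tables and loops
# only, so agreement is informative.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# position-by-position set membership; pattern N additionally matches any
# non-ACGT text character
oracle_iupac_match <- function(pattern, text, offset = 0L) {
  pc <- strsplit(pattern, "")[[1L]]
  tc <- strsplit(text, "")[[1L]][(offset + 1L):(offset + length(pc))]
  for (i in seq_along(pc)) {
    if (pc[i] == "N") next
    if (!(tc[i] %in% ORACLE_IUPAC[[pc[i]]])) return(FALSE)
  }
  TRUE
}

# expand a pattern to its full concrete k-mer set (k small)
oracle_expand <- function(pattern) {
  sets <- ORACLE_IUPAC[strsplit(pattern, "")[[1L]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1L,
        paste, collapse = "")
}

# quadratic reference scanner: greedy left-to-right, resume at i + k
oracle_scan <- function(seq, pattern) {
  k <- nchar(pattern)
  n <- nchar(seq)
  hits <- integer(0)
  i <- 0L
  while (i + k <= n) {
    if (oracle_iupac_match(pattern, seq, i)) {
      hits <- c(hits, i)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  hits
}

# one-sided upper-tail binomial probability by direct pmf summation
oracle_binom_tail <- function(q, size, prob) {
  if (q <= 0) return(1)
  sum(stats::dbinom(q:size, size, prob))
}

# random IUPAC pattern and random DNA string generators for property tests
random_pattern <- function(k, codes = names(ORACLE_IUPAC)) {
  paste(sample(codes, k, replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# anchored regex for a pattern, built from the oracle membership table
oracle_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  body <- vapply(chars, function(ch) {
    s <- ORACLE_IUPAC[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1L))
  paste0("^", paste(body, collapse = ""), "$")
}

random_dna_vec <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Monte-Carlo estimate of a pair-pattern baseline probability: draw uniform
# variable regions, build the shifted windows from the design layout by
# plain substring arithmetic, and test each with an oracle-derived regex.
oracle_baseline_mc <- function(pattern, design, shifts, n_mc) {
  wlen <- design$site1_len + nchar(design$gap) + design$site2_len
  s1 <- random_dna_vec(n_mc, design$site1_len)
  s2 <- if (is.na(design$site2)) random_dna_vec(n_mc, design$site2_len) else design$site2
  oligo <- paste0(design$nbs1, s1, design$gap, s2, design$nbs2)
  rx <- oracle_regex(pattern)
  hit <- rep(FALSE, n_mc)
  for (s in shifts) {
    w <- substr(oligo, design$site1_start + s + 1L,
                design$site1_start + s + wlen)
    hit <- hit | grepl(rx, w)
  }
  mean(hit)
}

# small handmade coverage track: list of (chrom, bed_start, bed_end, value)
make_track <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), value = as.numeric(r[[4]]))
  }))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  S4Vectors::mcols(gr)$score <- df$value
  gr
}

# GRanges shorthand from 0-based half-open coordinates (BED convention)
bedr <- function(chrom, start, end, strand = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (!is.null(strand)) BiocGenerics::strand(gr) <- strand
  gr
}
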