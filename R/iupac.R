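# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
# Bit 16 marks a non-ACGT text base: it matches only a pattern 'N'
# (whose mask carries bit 16 as well), so softmasked or ambiguous
# genome bases fail every informative pattern position.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 31L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.iupac_letters <- function() names(.IUPAC_BITS)

.check_iupac <- function(x, what = "pattern") {
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", x)
  if (any(bad)) {
    stop(sprintf("invalid IUPAC character in %s: '%s'", what, x[bad][1L]),
         call. = FALSE)
  }
  invisible(x)
}

# Pattern lookup: every IUPAC letter maps to its degeneracy mask.
.char_bits_table <- local({
  tab <- rep(16L, 256L)
  tab[utf8ToInt(paste(names(.IUPAC_BITS), collapse = "")) + 1L] <- .IUPAC_BITS
  low <- utf8ToInt("acgt")
  tab[low + 1L] <- .IUPAC_BITS[c("A", "C", "G", "T")]
  tab
})

# Text lookup: only concrete ACGT bases carry base bits; anything else
# (including an ambiguity code in a genome) is a foreign base matched only
# by a pattern N.
.text_bits_table <- local({
  tab <- rep(16L, 256L)
  acgt <- .IUPAC_BITS[c("A", "C", "G", "T")]
  tab[utf8ToInt("ACGT") + 1L] <- acgt
  tab[utf8ToInt("acgt") + 1L] <- acgt
  tab
})

# Encode a pattern string as an integer vector of degeneracy masks.
.encode_bits <- function(x) .char_bits_table[utf8ToInt(x) + 1L]

# Encode a vector of equal-length text strings as a len x n integer matrix.
.encode_bits_matrix <- function(x, len = nchar(x[1L])) {
  stopifnot(all(nchar(x) == len))
  matrix(.text_bits_table[utf8ToInt(paste(x, collapse = "")) + 1L],
         nrow = len)
}

#' Reverse complement of IUPAC DNA strings
#'
#' Complements every IUPAC code (N stays N, K maps to M, Y to R, H to D, and
#' so on) and reverses the string, so that applying the function twice is the
#' identity. Vectorized over its input.
#'
#' @param x character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("TGTTTAC")  # "GTAAACA"
#' reverse_complement("TGTTTNN")  # "NNAAACA"
#' @export
reverse_complement <- function(x) {
  .check_iupac(toupper(x), "sequence")
  x <- toupper(x)
  comp <- chartr(paste(names(.IUPAC_COMPLEMENT), collapse = ""),
                 paste(.IUPAC_COMPLEMENT, collapse = ""), x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1L),
         USE.NAMES = FALSE)
}

#' Match a degenerate IUPAC pattern at a fixed offset
#'
#' Tests whether `pattern` matches `text` starting at a 0-based `offset`:
#' every pattern position's allowed-base set must contain the corresponding
#' text base. Pattern `N` matches any base (including non-ACGT characters in
#' the text); all other codes match only concrete ACGT bases in their set.
#'
#' @param pattern IUPAC pattern string.
#' @param text DNA string to test against.
#' @param offset 0-based start position within `text`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("TGTTKNN", "TGTTGAA", 0)  # TRUE, K = {G,T}
#' @export
iupac_match <- function(pattern, text, offset = 0L) {
  pattern <- toupper(pattern)
  .check_iupac(pattern)
  k <- nchar(pattern)
  if (offset < 0L || offset + k > nchar(text)) {
    stop("offset out of range for pattern of length ", k, call. = FALSE)
  }
  pb <- .encode_bits(pattern)
  tb <- .text_bits_table[utf8ToInt(substr(text, offset + 1L, offset + k)) + 1L]
  all(bitwAnd(pb, tb) > 0L)
}

#' Expand a degenerate pattern to all concrete sequences
#'
#' Enumerates every ACGT string matched by an IUPAC pattern. Intended for
#' short patterns (the result grows as the product of the degeneracies).
#'
#' @param pattern IUPAC pattern string.
#' @return character vector of concrete DNA strings.
#' @export
expand_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  .check_iupac(pattern)
  sets <- lapply(strsplit(pattern, "")[[1L]], function(ch) {
    bits <- .IUPAC_BITS[[ch]]
    c("A", "C", "G", "T")[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
  })
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# Number of concrete ACGT bases allowed at each pattern position.
.pattern_cardinality <- function(pattern) {
  bits <- .encode_bits(toupper(pattern))
  vapply(bits, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), 1L)
}

# Convert an IUPAC pattern to a PCRE character-class regex.
.iupac_regex <- function(pattern) {
  pattern <- toupper(pattern)
  .check_iupac(pattern)
  chars <- strsplit(pattern, "")[[1L]]
  paste(vapply(chars, function(ch) {
    if (ch == "N") return(".")
    allowed <- c("A", "C", "G", "T")[bitwAnd(.IUPAC_BITS[[ch]], c(1L, 2L, 4L, 8L)) > 0L]
    if (length(allowed) == 1L) allowed else paste0("[", paste(allowed, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# Vectorized matcher: which of the equal-length strings in `windows` match
# `pattern` over their full length? Uses the bitmask encoding, narrowing
# the candidate set position by position.
.match_windows <- function(pattern, windows_bits) {
  pb <- .encode_bits(toupper(pattern))
  stopifnot(length(pb) == nrow(windows_bits))
  idx <- seq_len(ncol(windows_bits))
  for (j in seq_along(pb)) {
    if (pb[j] == 31L) next                # N constrains nothing
    idx <- idx[bitwAnd(pb[j], windows_bits[j, idx]) > 0L]
    if (length(idx) == 0L) break
  }
  ok <- logical(ncol(windows_bits))
  ok[idx] <- TRUE
  ok
}
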