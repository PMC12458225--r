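# Oligo library architectures for pull-down sequencing.
#
# A library oligo is NBS1 (fixed 27-nt flank) + site 1 (7 nt) + gap (TCGA) +
# site 2 (fixed rcFKHM "GTAAACA", or a second variable 7-mer) + NBS2 (fixed
# 35-nt flank). The flank sequences shipped here are arbitrary GC-balanced
# non-binding sequences (they are configurable; only their identity at the
# window borders feeds the baseline probabilities, never the binding model).

.DEFAULT_NBS1 <- "CAGCTGACGATCGTACGATCGCTAGCA"              # 27 nt
.DEFAULT_NBS2 <- "ACGGATCCTGAGCTCAAGCTTGGCACGTCGACTAA"      # 35 nt

#' Construct an oligo library design
#'
#' @param site2 fixed site-2 sequence (e.g. the reverse-complement forkhead
#'   motif "GTAAACA") or `NA` for a variable 7-nt site 2.
#' @param nbs1,nbs2 fixed flank sequences.
#' @param site1_len,site2_len lengths of the variable sites.
#' @param gap fixed spacer sequence between the sites.
#' @return a `library_design` list with layout offsets.
#' @export
library_design <- function(site2 = "GTAAACA",
                           nbs1 = .DEFAULT_NBS1,
                           nbs2 = .DEFAULT_NBS2,
                           site1_len = 7L,
                           site2_len = 7L,
                           gap = "TCGA") {
  site2_fixed <- !is.na(site2)
  if (site2_fixed) site2_len <- nchar(site2)
  d <- list(
    nbs1 = toupper(nbs1),
    site1_len = as.integer(site1_len),
    gap = toupper(gap),
    site2 = if (site2_fixed) toupper(site2) else NA_character_,
    site2_len = as.integer(site2_len),
    nbs2 = toupper(nbs2)
  )
  # 0-based offsets of each segment within the oligo
  d$site1_start <- nchar(d$nbs1)
  d$gap_start <- d$site1_start + d$site1_len
  d$site2_start <- d$gap_start + nchar(d$gap)
  d$nbs2_start <- d$site2_start + d$site2_len
  d$total_len <- d$nbs2_start + nchar(d$nbs2)
  class(d) <- "library_design"
  d
}

#' Default library designs
#'
#' `"random_rcfkhm"`: variable 7-nt site 1, fixed rcFKHM site 2 — an
#' inverted-repeat forkhead arrangement when site 1 is FKHM-like.
#' `"random_random"`: both sites variable.
#'
#' @param name one of "random_rcfkhm", "random_random".
#' @return a `library_design`.
#' @export
default_design <- function(name = c("random_rcfkhm", "random_random")) {
  name <- match.arg(name)
  if (name == "random_rcfkhm") library_design(site2 = "GTAAACA")
  else library_design(site2 = NA)
}

# Template of the full oligo with variable positions marked "?", used for
# structure anchoring and baseline probabilities.
.design_template <- function(design) {
  paste0(design$nbs1,
         strrep("?", design$site1_len),
         design$gap,
         if (is.na(design$site2)) strrep("?", design$site2_len) else design$site2,
         design$nbs2)
}

# IUPAC pattern of the full oligo (variable positions as N), for locating the
# design structure within a read by exact match of the fixed regions.
.design_pattern <- function(design) {
  gsub("?", "N", .design_template(design), fixed = TRUE)
}

#' Assemble full oligo sequences from variable-region sequences
#'
#' @param design a `library_design`.
#' @param site1 character vector of site-1 sequences.
#' @param site2 character vector of site-2 sequences (ignored for designs
#'   with a fixed site 2).
#' @return character vector of full-length oligo sequences.
#' @export
assemble_oligo <- function(design, site1, site2 = NULL) {
  s2 <- if (is.na(design$site2)) site2 else design$site2
  paste0(design$nbs1, site1, design$gap, s2, design$nbs2)
}

#' @export
print.library_design <- function(x, ...) {
  cat("oligo library design:", x$total_len, "nt\n")
  cat("  NBS1 [", nchar(x$nbs1), "] + site1 [", x$site1_len, "] + ",
      x$gap, " + ",
      if (is.na(x$site2)) paste0("site2 [", x$site2_len, "]") else x$site2,
      " + NBS2 [", nchar(x$nbs2), "]\n", sep = "")
  invisible(x)
}
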