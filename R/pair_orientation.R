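# Orientation-resolved motif-pair analysis of random-random pull-down
# libraries: the 400-pattern pair dictionary (10 motifs x 10 motifs x 4
# orientations), shifted-window extraction around the central spacer,
# once-per-read pair counting, and normalization by the baseline
# probability of matching under the design's fixed bases.

.ORIENTATIONS <- c("HH", "HT", "TH", "TT")

#' Construct the 18-nt pattern of an oriented motif pair
#'
#' On the positive strand: HH = a + gap + rc(b) (inverted repeat),
#' HT = a + gap + b (direct repeat), TH = rc(a) + gap + rc(b),
#' TT = rc(a) + gap + b.
#'
#' @param motif_a,motif_b 7-nt IUPAC motifs (vectorized).
#' @param orientation one of "HH", "HT", "TH", "TT" (vectorized).
#' @param gap spacer sequence (default "TCGA").
#' @return character vector of patterns of length 7 + nchar(gap) + 7.
#' @export
pair_pattern <- function(motif_a, motif_b, orientation, gap = "TCGA") {
  stopifnot(all(orientation %in% .ORIENTATIONS))
  a <- ifelse(orientation %in% c("HH", "HT"), motif_a, reverse_complement(motif_a))
  b <- ifelse(orientation %in% c("HT", "TT"), motif_b, reverse_complement(motif_b))
  paste0(a, gap, b)
}

#' Build the orientation-resolved motif-pair dictionary
#'
#' All ordered pairs of the supplied motifs in four orientations; with the
#' standard 10-motif set this yields 10 x 10 x 4 = 400 patterns, each
#' 7 + gap + 7 nt long.
#'
#' @param motifs character vector of 7-nt IUPAC motifs.
#' @param gap spacer sequence placed between the two half-sites.
#' @return data.frame with columns motif_a, motif_b, orientation, pattern.
#' @export
build_pair_dictionary <- function(motifs, gap = "TCGA") {
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != 7L)) stop("motifs must be 7 nt", call. = FALSE)
  .check_iupac(motifs, "motif")
  grid <- expand.grid(motif_a = motifs, motif_b = motifs,
                      orientation = .ORIENTATIONS,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$pattern <- pair_pattern(grid$motif_a, grid$motif_b, grid$orientation, gap)
  grid
}

#' Default 10-motif set
#'
#' The textually attested patterns recovered by 2N-motif discovery: group 1
#' (forkhead-like, containing TGTTT or TGTTG) and group 2 (GCAT-core motifs
#' flanked by T or C). Several group members beyond the attested forms are
#' representative placeholders; substitute the full discovery table from a
#' run of [aggregate_2n()] on real data when available.
#'
#' @return data.frame with columns motif and group ("G1"/"G2").
#' @export
default_motifs <- function() {
  data.frame(
    motif = c("TGTTTNN", "TGTTKNN", "TGTTGNN", "NTGTTTA", "NNTGTTT",
              "NNGCATY", "NNGCATC", "TGTGCAT", "GCGCATC", "NGCATCN"),
    group = c(rep("G1", 5L), rep("G2", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Extract shifted 18-nt windows around the central spacer
#'
#' Locates the design structure in the read, then returns the window of
#' length site1 + gap + site2 starting at (site-1 start + shift) for each
#' shift. Negative shifts pull known flank bases from NBS1 into the window;
#' positive shifts pull bases from NBS2.
#'
#' @param read a read sequence.
#' @param design a [library_design()].
#' @param shifts integer shifts (default -2:2, the five offsets 0, ±1, ±2).
#' @return character vector of windows (length `length(shifts)`), or `NULL`
#'   when the structure cannot be located.
#' @export
extract_shifted_windows <- function(read, design, shifts = -2:2) {
  parsed <- parse_library_reads(read, design)
  if (!is.na(parsed$reject[1L])) return(NULL)
  off <- parsed$offset[1L]
  wlen <- design$site1_len + nchar(design$gap) + design$site2_len
  starts <- off + design$site1_start + shifts
  substring(toupper(read), starts + 1L, starts + wlen)
}

# All shifted windows of many already-validated reads, built from the
# variable regions plus the fixed context, as a bitmask matrix.
# Returns list(bits = wlen x (n*length(shifts)) matrix, n = reads).
.shifted_window_bits <- function(site1, site2, design, shifts = -2:2) {
  n <- length(site1)
  s2 <- if (is.na(design$site2)) site2 else design$site2
  lo <- min(shifts); hi <- max(shifts)
  ctx <- paste0(substr(design$nbs1, nchar(design$nbs1) + 1L + lo, nchar(design$nbs1)),
                site1, design$gap, s2,
                substr(design$nbs2, 1L, hi))
  wlen <- design$site1_len + nchar(design$gap) + design$site2_len
  ctx_len <- (-lo) + wlen + hi
  bits <- .encode_bits_matrix(ctx, ctx_len)
  cols <- lapply(shifts, function(s) {
    bits[(s - lo + 1L):(s - lo + wlen), , drop = FALSE]
  })
  list(bits = do.call(cbind, cols), n = n, n_shifts = length(shifts))
}

#' Count reads supporting each oriented motif pair
#'
#' Each read is expanded into its shifted windows; a read increments the
#' count of a pair by exactly 1 if any of its windows matches the pair's
#' pattern (never once per shift). A read may support multiple distinct
#' pairs. Reads whose structure cannot be located are dropped and tallied.
#'
#' @param reads character vector of read sequences.
#' @param dictionary data.frame from [build_pair_dictionary()].
#' @param design a [library_design()].
#' @param shifts integer shifts around the spacer (default -2:2).
#' @return the dictionary with an added `raw_count` column;
#'   `attr(,"n_reads")` is the number of structurally valid reads.
#' @export
count_pair_matches <- function(reads, dictionary, design, shifts = -2:2) {
  parsed <- parse_library_reads(reads, design)
  keep <- is.na(parsed$reject)
  sw <- .shifted_window_bits(parsed$site1[keep], parsed$site2[keep],
                             design, shifts)
  counts <- integer(nrow(dictionary))
  if (sw$n > 0L) {
    for (r in seq_len(nrow(dictionary))) {
      hit <- .match_windows(dictionary$pattern[r], sw$bits)
      # windows are laid out shift-block by shift-block: fold to per-read
      per_read <- matrix(hit, nrow = sw$n)
      counts[r] <- sum(rowSums(per_read) > 0L)
    }
  }
  out <- dictionary
  out$raw_count <- counts
  attr(out, "n_reads") <- sw$n
  out
}

#' Baseline probability of a pair pattern matching under random shifts
#'
#' For each shift, the probability that a uniformly random variable region
#' produces a window matching the pattern, given the design's fixed bases:
#' the product over window positions of 1 (fixed base in the pattern's
#' allowed set), 0 (fixed base excluded), or |allowed|/4 (variable
#' position). Per-shift probabilities are combined with the independence
#' approximation 1 - prod(1 - p_s). A pattern that conflicts with the fixed
#' bases at every shift has baseline 0 ("unobservable").
#'
#' @param pattern IUPAC pattern(s) of window length (vectorized).
#' @param design a [library_design()].
#' @param shifts integer shifts (default -2:2).
#' @return numeric vector of baseline probabilities in \[0, 1\].
#' @export
pair_baseline_probability <- function(pattern, design, shifts = -2:2) {
  wlen <- design$site1_len + nchar(design$gap) + design$site2_len
  stopifnot(all(nchar(pattern) == wlen))
  template <- .design_template(design)
  tchars <- strsplit(template, "")[[1L]]
  vapply(pattern, function(pat) {
    pb <- .encode_bits(toupper(pat))
    card <- .pattern_cardinality(pat)
    p_shift <- vapply(shifts, function(s) {
      idx <- design$site1_start + s + seq_len(wlen)   # 1-based template pos
      tw <- tchars[idx]
      m <- numeric(wlen)
      fixed <- tw != "?"
      if (any(fixed)) {
        fb <- .char_bits_table[utf8ToInt(paste(tw[fixed], collapse = "")) + 1L]
        m[fixed] <- as.numeric(bitwAnd(fb, pb[fixed]) > 0L)
      }
      m[!fixed] <- card[!fixed] / 4
      prod(m)
    }, numeric(1L))
    1 - prod(1 - p_shift)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Normalize pair counts by baseline probabilities
#'
#' Divides each raw count by the pair's baseline match probability; cells
#' with baseline 0 are set to 0 and flagged. Optionally applies a joint
#' 0-100 display scaling across this table and a second one (e.g. two
#' proteins compared on a common color scale), using their shared maximum.
#'
#' @param counts dictionary data.frame with a `raw_count` column.
#' @param baselines numeric vector of baselines aligned with `counts`.
#' @param joint_scale_with optional second normalized table (output of this
#'   function) whose `normalized` column participates in the shared maximum.
#' @return `counts` with added `baseline`, `normalized`, `unobservable` and
#'   `scaled` columns (scaled max = 100 over the jointly-scaled set).
#' @export
normalize_pair_counts <- function(counts, baselines, joint_scale_with = NULL) {
  stopifnot(length(baselines) == nrow(counts))
  out <- counts
  out$baseline <- baselines
  out$unobservable <- baselines <= 0
  out$normalized <- ifelse(out$unobservable, 0, out$raw_count / baselines)
  ref <- out$normalized
  if (!is.null(joint_scale_with)) ref <- c(ref, joint_scale_with$normalized)
  mx <- max(ref, 0)
  out$scaled <- if (mx > 0) out$normalized / mx * 100 else 0
  out
}
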