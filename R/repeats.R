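# Tandem-repeat (TnG microsatellite) stage: position weight matrix scanning
# with exact p-values computed by positional dynamic programming, the
# degenerate-run filters, region merging, head-to-head site / repeat
# adjacency geometry (signed border-to-border distance, aligned/divergent
# orientation), signal-free background definition, and 200-bp coverage AUC
# comparisons stratified by repeat length.

#' Construct a position weight matrix
#'
#' @param probs numeric matrix, width x 4, columns A C G T; rows are
#'   renormalized after adding `pseudocount`.
#' @param background length-4 background base frequencies (default uniform).
#' @param pseudocount additive pseudocount applied to `probs`.
#' @return a `pwm` object with probability and log2-odds score matrices.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L)
  colnames(probs) <- c("A", "C", "G", "T")
  if (any(background <= 0)) {
    stop("background frequencies must be positive (use a pseudocount)",
         call. = FALSE)
  }
  background <- background / sum(background)
  p <- probs + pseudocount
  p <- p / rowSums(p)
  obj <- list(width = nrow(p), probs = p, background = background,
              score = log2(sweep(p, 2L, background, "/")))
  class(obj) <- "pwm"
  obj
}

#' Default TnG-repeat position weight matrix
#'
#' A 12-position matrix built by equal-weight stacking of T2G, T3G and T4G
#' register shifts (tandem TTG / TTTG / TTTTG tracts in all phases), with
#' pseudocount 0.01 and uniform background. It is a configurable stand-in
#' with the same width and T/G composition bias as a TnG query motif; all
#' correctness tests use small synthetic matrices with exhaustive oracles,
#' so nothing downstream depends on this particular default.
#'
#' @return a `pwm` of width 12.
#' @export
default_tng_pwm <- function() {
  width <- 12L
  units <- c("TTG", "TTTG", "TTTTG")
  counts <- matrix(0, nrow = width, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (u in units) {
    tract <- strrep(u, ceiling((width + nchar(u)) / nchar(u)))
    for (phase in seq_len(nchar(u))) {
      win <- substr(tract, phase, phase + width - 1L)
      ch <- strsplit(win, "")[[1L]]
      for (i in seq_len(width)) counts[i, ch[i]] <- counts[i, ch[i]] + 1
    }
  }
  pwm(counts / rowSums(counts))
}

#' Exact p-value table for a PWM under its background model
#'
#' Discretizes the log2-odds scores to integer bins (`granularity` bins
#' spanning the largest per-position score range) and computes the exact
#' distribution of the total discretized score of a random background
#' sequence by positional dynamic programming (convolution of per-position
#' score distributions). The p-value of a score is the tail mass at or above
#' it. Scanning uses the same discretization, so reported p-values are exact
#' for the discretized score.
#'
#' @param x a [pwm()].
#' @param granularity minimum number of bins per position (default 1000).
#' @return a `pwm_pvalue_table` with the binned score matrix and tail
#'   probabilities.
#' @export
pwm_pvalue_table <- function(x, granularity = 1000L) {
  stopifnot(inherits(x, "pwm"), granularity >= 100L)
  rng <- max(apply(x$score, 1L, function(r) diff(range(r))))
  binwidth <- if (rng > 0) rng / granularity else 1
  bins <- round(x$score / binwidth)
  offset <- apply(bins, 1L, min)
  rel <- sweep(bins, 1L, offset, "-")          # non-negative integers
  max_rel <- apply(rel, 1L, max)
  # DP over positions: dist[s+1] = P[sum of relative bins == s]
  dist <- 1
  for (i in seq_len(x$width)) {
    nxt <- numeric(length(dist) + max_rel[i])
    for (b in 1:4) {
      k <- rel[i, b]
      idx <- seq_along(dist) + k
      nxt[idx] <- nxt[idx] + dist * x$background[b]
    }
    dist <- nxt
  }
  tail_p <- rev(cumsum(rev(dist)))
  obj <- list(pwm = x, binwidth = binwidth, bins = bins,
              min_rel_total = sum(offset), dist = dist, tail_p = tail_p)
  class(obj) <- "pwm_pvalue_table"
  obj
}

# p-value of total binned scores (vector of integer bin sums)
.pwm_pvalue <- function(table, total_bins) {
  rel <- total_bins - table$min_rel_total
  rel <- pmax(pmin(rel, length(table$tail_p) - 1L), 0L)
  table$tail_p[rel + 1L]
}

# total binned score of every window of `seq` (NA where window has non-ACGT)
.window_scores <- function(seq, bins) {
  w <- nrow(bins)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)[strsplit(toupper(seq), "")[[1L]]]
  L <- length(code)
  if (L < w) return(integer(0))
  n_win <- L - w + 1L
  tot <- numeric(n_win)
  for (i in seq_len(w)) {
    sc <- bins[i, code[i:(i + n_win - 1L)]]
    tot <- tot + sc
  }
  tot  # NA propagates from non-ACGT bases
}

# reverse-complemented bin matrix: scoring the forward window with it equals
# scoring the reverse complement of that window with the original matrix
.rc_bins <- function(bins) {
  bins[rev(seq_len(nrow(bins))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Scores every window on the positive strand and, when `both_strands`, the
#' reverse complement of every window (reported at the same positive-strand
#' coordinates with strand "-"). Matches with p-value < `p_threshold` are
#' returned.
#'
#' @param genome named character vector of chromosome sequences.
#' @param x a [pwm()] or a precomputed [pwm_pvalue_table()].
#' @param p_threshold report windows with p-value strictly below this
#'   (default 8e-5).
#' @param both_strands scan the minus strand too.
#' @param peaks optional `GRanges`; restrict the scan to these intervals.
#' @return `GRanges` of matches with `score` (log2-odds, binned scale) and
#'   `pvalue` metadata columns and strand set.
#' @export
scan_repeats <- function(genome, x, p_threshold = 8e-5, both_strands = TRUE,
                         peaks = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  tab <- if (inherits(x, "pwm_pvalue_table")) x else pwm_pvalue_table(x)
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  w <- tab$pwm$width
  regions <- if (is.null(peaks)) {
    GenomicRanges::GRanges(names(genome),
                           IRanges::IRanges(1L, nchar(genome)))
  } else {
    peaks
  }
  res <- list()
  for (i in seq_along(regions)) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    rstart <- GenomicRanges::start(regions)[i]
    seq <- substr(genome[[chrom]], rstart, GenomicRanges::end(regions)[i])
    if (nchar(seq) < w) next
    for (str in c("+", if (both_strands) "-")) {
      bins <- if (str == "+") tab$bins else .rc_bins(tab$bins)
      tot <- .window_scores(seq, bins)
      pv <- .pwm_pvalue(tab, tot)
      # threshold 1 is the degenerate report-everything setting
      hit <- which(!is.na(pv) & (pv < p_threshold | p_threshold >= 1))
      if (length(hit)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = rstart + hit - 1L,
          end = rstart + hit + w - 2L, strand = str,
          score = tot[hit] * tab$binwidth, pvalue = pv[hit])
      }
    }
  }
  if (length(res) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$pvalue <- numeric(0)
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$score <- df$score
  S4Vectors::mcols(gr)$pvalue <- df$pvalue
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.DEGENERATE_RUNS <- c(
  strrep(c("TG", "AC", "TA", "TC", "AG", "CG"), 6L),  # 12-nt dinucleotide runs
  strrep(c("T", "G", "C", "A"), 12L)                  # 12-nt homopolymers
)

#' Remove matches containing degenerate repeat runs
#'
#' Drops any match whose sequence contains a 12-nt dinucleotide run of TG,
#' AC, TA, TC, AG or CG, or a 12-nt homopolymer of T, G, C or A — sequence
#' classes inconsistent with TnG (n = 2-5) specificity. Idempotent.
#'
#' @param matches `GRanges` of PWM matches.
#' @param genome named character vector of chromosome sequences.
#' @return filtered `GRanges`.
#' @export
filter_degenerate <- function(matches, genome) {
  if (length(matches) == 0L) return(matches)
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  seqs <- substr(genome[as.character(GenomicRanges::seqnames(matches))],
                 GenomicRanges::start(matches), GenomicRanges::end(matches))
  drop <- rep(FALSE, length(seqs))
  for (run in .DEGENERATE_RUNS) {
    drop <- drop | grepl(run, seqs, fixed = TRUE)
  }
  matches[!drop]
}

#' Merge overlapping matches into repeat regions
#'
#' Transitive union of matches overlapping by at least 1 bp (abutting
#' matches are kept separate). Region strand is the strand of the
#' best-scoring constituent match (ties broken toward "+"); `n_matches`
#' counts constituents and `pvalue` keeps the best constituent p-value.
#'
#' @param matches `GRanges` with `score` (and optionally `pvalue`) columns.
#' @return `GRanges` of merged regions with strand, `n_matches`, `pvalue`.
#' @export
merge_regions <- function(matches) {
  if (length(matches) == 0L) return(matches)
  red <- GenomicRanges::reduce(matches, min.gapwidth = 0L,
                               ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(red, matches, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  n_matches <- as.integer(table(factor(qh, levels = seq_along(red))))
  has_score <- !is.null(S4Vectors::mcols(matches)$score)
  strand_out <- rep("+", length(red))
  pv_out <- rep(NA_real_, length(red))
  for (r in seq_along(red)) {
    ix <- sh[qh == r]
    if (has_score) {
      sc <- S4Vectors::mcols(matches)$score[ix]
      best <- ix[sc == max(sc)]
      st <- as.character(BiocGenerics::strand(matches))[best]
      strand_out[r] <- if ("+" %in% st) "+" else st[1L]
    }
    if (!is.null(S4Vectors::mcols(matches)$pvalue)) {
      pv_out[r] <- min(S4Vectors::mcols(matches)$pvalue[ix])
    }
  }
  BiocGenerics::strand(red) <- strand_out
  S4Vectors::mcols(red)$n_matches <- n_matches
  S4Vectors::mcols(red)$pvalue <- pv_out
  red
}

#' Merge overlapping head-to-head occurrences into unique sites
#'
#' H-H occurrences of similar motif structure often overlap; this collapses
#' them (>= 1 bp overlap, transitive) into unique dimer sites.
#'
#' @param occ occurrence data.frame from [scan_peakset()] (H-H rows), or a
#'   `GRanges`.
#' @return `GRanges` of merged sites.
#' @export
merge_hh_sites <- function(occ) {
  gr <- if (methods::is(occ, "GRanges")) occ else
    GenomicRanges::GRanges(occ$chrom, IRanges::IRanges(occ$start, occ$end))
  GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
}

#' Nearest repeat to each head-to-head site, with signed distance
#'
#' Border-to-border distance: 0 when the intervals overlap or abut, positive
#' when the repeat lies downstream of the H-H site (end of H-H to start of
#' repeat), negative when upstream. Orientation is "aligned" when a
#' positive-strand repeat (TnG face) lies upstream or a negative-strand
#' repeat (CAn face) lies downstream — i.e. when the proximal H-H half-site
#' can extend seamlessly into the repeat — and "divergent" otherwise. For
#' distance-0 records the side is taken from the repeat midpoint relative to
#' the H-H midpoint. Equal-distance ties prefer the downstream repeat.
#'
#' @param hh_sites `GRanges` of merged H-H sites.
#' @param repeat_regions `GRanges` of repeat regions with strand.
#' @return data.frame: chrom, hh_start, hh_end, repeat_index, distance,
#'   repeat_strand, alignment; rows with no repeat on the chromosome are
#'   flagged `absent`.
#' @export
nearest_repeat <- function(hh_sites, repeat_regions) {
  n <- length(hh_sites)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hh_sites)),
    hh_start = GenomicRanges::start(hh_sites),
    hh_end = GenomicRanges::end(hh_sites),
    repeat_index = NA_integer_, distance = NA_integer_,
    repeat_strand = NA_character_, alignment = NA_character_,
    absent = TRUE, stringsAsFactors = FALSE
  )
  if (n == 0L || length(repeat_regions) == 0L) return(out)
  rchrom <- as.character(GenomicRanges::seqnames(repeat_regions))
  rstart <- GenomicRanges::start(repeat_regions)
  rend <- GenomicRanges::end(repeat_regions)
  rstrand <- as.character(BiocGenerics::strand(repeat_regions))
  for (i in seq_len(n)) {
    same <- which(rchrom == out$chrom[i])
    if (length(same) == 0L) next
    hs <- out$hh_start[i]; he <- out$hh_end[i]
    # border-to-border gap (0 on overlap or abutment), sign by side
    gap_down <- rstart[same] - he - 1L      # >0 when repeat strictly downstream
    gap_up <- hs - rend[same] - 1L          # >0 when repeat strictly upstream
    d <- pmax(gap_down, gap_up, 0L)
    # prefer downstream on ties: order by (distance, upstream-flag)
    upstream <- gap_up > 0L | (d == 0L &
      (rstart[same] + rend[same]) < (hs + he))
    ord <- order(d, upstream)
    j <- same[ord[1L]]
    dist_signed <- if (d[ord[1L]] == 0L) 0L else
      if (upstream[ord[1L]]) -d[ord[1L]] else d[ord[1L]]
    side_up <- upstream[ord[1L]]
    aligned <- (rstrand[j] == "+" && side_up) ||
      (rstrand[j] == "-" && !side_up)
    out$repeat_index[i] <- j
    out$distance[i] <- dist_signed
    out$repeat_strand[i] <- rstrand[j]
    out$alignment[i] <- if (aligned) "aligned" else "divergent"
    out$absent[i] <- FALSE
  }
  out
}

#' Coverage AUC over a fixed window around genomic positions
#'
#' Sum of per-base coverage over \[center - halfwidth, center + halfwidth)
#' of a piecewise-constant track. Windows truncated at the chromosome start
#' produce a warning.
#'
#' @param track `GRanges` with a `score` column (a bedGraph track).
#' @param chrom chromosome name(s).
#' @param center 1-based center position(s).
#' @param halfwidth half window size in bp (default 100, a 200-bp window).
#' @return numeric vector of AUC values.
#' @export
window_auc <- function(track, chrom, center, halfwidth = 100L) {
  start <- center - halfwidth
  if (any(start < 1L)) {
    warning("window truncated at chromosome start")
    start <- pmax(start, 1L)
  }
  end <- center + halfwidth - 1L
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (length(track) == 0L) return(numeric(length(win)))
  ov <- GenomicRanges::findOverlaps(win, track, ignore.strand = TRUE)
  if (length(ov) == 0L) return(numeric(length(win)))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ints <- IRanges::pintersect(IRanges::ranges(win)[qh], IRanges::ranges(track)[sh])
  contrib <- IRanges::width(ints) * S4Vectors::mcols(track)$score[sh]
  auc <- numeric(length(win))
  agg <- rowsum(contrib, qh)
  auc[as.integer(rownames(agg))] <- agg[, 1L]
  auc
}

#' Define signal-free background regions
#'
#' Open chromatin regions located at least `min_dist_bp` from any foreground
#' peak and whose window AUC (around the OCR center) is below the minimum
#' window AUC observed over the foreground peaks.
#'
#' @param ocrs `GRanges` of open chromatin regions.
#' @param fg_peaks `GRanges` of foreground (factor-bound) peaks.
#' @param track `GRanges` coverage track.
#' @param min_dist_bp minimum distance to any foreground peak (default 10 kb).
#' @param fg_min_auc signal ceiling; computed as the minimum foreground peak
#'   window AUC when not supplied.
#' @param halfwidth AUC window half-size (default 100).
#' @return filtered `GRanges` of signal-free OCRs.
#' @export
define_signal_free_background <- function(ocrs, fg_peaks, track,
                                          min_dist_bp = 10000L,
                                          fg_min_auc = NULL,
                                          halfwidth = 100L) {
  if (length(fg_peaks) == 0L) stop("foreground peak set is empty", call. = FALSE)
  if (is.null(fg_min_auc)) {
    centers <- (GenomicRanges::start(fg_peaks) + GenomicRanges::end(fg_peaks)) %/% 2L
    fg_min_auc <- min(window_auc(track,
                                 as.character(GenomicRanges::seqnames(fg_peaks)),
                                 centers, halfwidth))
  }
  d2n <- GenomicRanges::distanceToNearest(ocrs, fg_peaks, ignore.strand = TRUE)
  dist <- rep(Inf, length(ocrs))
  dist[S4Vectors::queryHits(d2n)] <- S4Vectors::mcols(d2n)$distance
  centers <- (GenomicRanges::start(ocrs) + GenomicRanges::end(ocrs)) %/% 2L
  auc <- window_auc(track, as.character(GenomicRanges::seqnames(ocrs)),
                    centers, halfwidth)
  ocrs[dist >= min_dist_bp & auc < fg_min_auc]
}

#' Stratified AUC comparison of repeats by length and H-H adjacency
#'
#' Stratifies repeat regions into short (length <= `short_max`) and long
#' (length >= `long_min`) groups, and within each group compares coverage
#' AUC at repeats immediately adjacent to an H-H site (border distance 0 in
#' the aligned orientation) against repeats at least `far_min` bp from any
#' H-H site.
#'
#' @param repeat_regions `GRanges` of repeat regions with strand.
#' @param hh_sites `GRanges` of merged H-H sites.
#' @param track `GRanges` coverage track.
#' @param short_max,long_min repeat length strata bounds (bp).
#' @param far_min minimum distance for the "far" group (default 1000).
#' @param halfwidth AUC window half-size (default 100).
#' @return list with `values` (per-repeat data.frame: length_class,
#'   adjacency, auc, log2_auc) and `summary` (per-group n and median
#'   log2 AUC; empty groups flagged with NA).
#' @export
stratified_auc_compare <- function(repeat_regions, hh_sites, track,
                                   short_max = 20L, long_min = 40L,
                                   far_min = 1000L, halfwidth = 100L) {
  len <- GenomicRanges::width(repeat_regions)
  length_class <- ifelse(len <= short_max, "short",
                         ifelse(len >= long_min, "long", NA_character_))
  # repeat-centric adjacency: reuse the H-H-centric geometry with roles
  # swapped, then flip the sign convention and the aligned rule accordingly
  adj <- rep(NA_character_, length(repeat_regions))
  if (length(hh_sites) > 0L && length(repeat_regions) > 0L) {
    rchrom <- as.character(GenomicRanges::seqnames(repeat_regions))
    rstart <- GenomicRanges::start(repeat_regions)
    rend <- GenomicRanges::end(repeat_regions)
    rstrand <- as.character(BiocGenerics::strand(repeat_regions))
    hchrom <- as.character(GenomicRanges::seqnames(hh_sites))
    hstart <- GenomicRanges::start(hh_sites)
    hend <- GenomicRanges::end(hh_sites)
    for (i in seq_along(repeat_regions)) {
      same <- which(hchrom == rchrom[i])
      if (length(same) == 0L) { adj[i] <- "far"; next }
      gap_down <- hstart[same] - rend[i] - 1L
      gap_up <- rstart[i] - hend[same] - 1L
      d <- pmax(gap_down, gap_up, 0L)
      jmin <- which.min(d)
      if (d[jmin] >= far_min) { adj[i] <- "far"; next }
      if (d[jmin] > 0L) next     # near but not abutting: outside both groups
      j <- same[jmin]
      hh_down <- (hstart[j] + hend[j]) > (rstart[i] + rend[i])
      aligned <- (rstrand[i] == "+" && hh_down) ||
        (rstrand[i] == "-" && !hh_down)
      if (aligned) adj[i] <- "adjacent"
    }
  } else {
    adj[] <- "far"
  }
  centers <- (GenomicRanges::start(repeat_regions) +
                GenomicRanges::end(repeat_regions)) %/% 2L
  auc <- window_auc(track, as.character(GenomicRanges::seqnames(repeat_regions)),
                    centers, halfwidth)
  values <- data.frame(length_class = length_class, adjacency = adj,
                       length_bp = len, auc = auc,
                       log2_auc = log2(auc + 1), stringsAsFactors = FALSE)
  groups <- expand.grid(length_class = c("short", "long"),
                        adjacency = c("adjacent", "far"),
                        stringsAsFactors = FALSE)
  groups$n <- NA_integer_
  groups$median_log2_auc <- NA_real_
  for (g in seq_len(nrow(groups))) {
    sel <- which(values$length_class == groups$length_class[g] &
                   values$adjacency == groups$adjacency[g])
    groups$n[g] <- length(sel)
    if (length(sel)) groups$median_log2_auc[g] <- stats::median(values$log2_auc[sel])
  }
  list(values = values, summary = groups)
}
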