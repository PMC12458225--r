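test_that("non-overlapping scan: abutting, resumption, degenerate cases", {
  expect_equal(scan_nonoverlapping("TGTGTG", "TG"), c(0L, 2L, 4L))
  expect_equal(scan_nonoverlapping("TGTGTG", "TGT"), 0L)
  expect_equal(scan_nonoverlapping("ACGT", "NN"), c(0L, 2L))
  expect_equal(scan_nonoverlapping("ACG", "ACGT"), integer(0))
  expect_equal(scan_nonoverlapping("AAAA", "TT"), integer(0))
})

test_that("non-overlapping scan agrees with quadratic reference scanner", {
  set.seed(23)
  for (i in 1:1000) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1),
                        replace = TRUE, prob = c(.4, .1, .1, .4)),
                 collapse = "")
    pat <- random_pattern(sample(2:5, 1),
                          codes = c("A", "T", "G", "K", "W", "N"))
    expect_identical(scan_nonoverlapping(seq, pat), oracle_scan(seq, pat),
                     info = paste(seq, pat))
  }
})

test_that("peak scanning recovers a planted pair and respects bounds", {
  pairs <- data.frame(motif_a = "TGTTTAC", motif_b = "TGTTTAC",
                      orientation = "HH", stringsAsFactors = FALSE)
  insert <- "TGTTTACTTTTGTAAACA"          # HH with 4-nt genomic (non-TCGA) gap
  chrom <- paste0(strrep("C", 50), insert, strrep("C", 50))
  genome <- c(chr1 = chrom)
  peaks <- bedr("chr1", 30, 100)
  occ <- scan_peakset(peaks, genome, pairs, gap_sizes = 4L)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 51L)            # 1-based genomic
  expect_equal(occ$end, 68L)
  expect_equal(occ$orientation, "HH")

  # empty dictionary -> empty table
  occ0 <- scan_peakset(peaks, genome, pairs[0, ], gap_sizes = 4L)
  expect_equal(nrow(occ0), 0L)

  # all-A chromosome vs T-containing pattern -> nothing
  occA <- scan_peakset(bedr("chrA", 0, 80), c(chrA = strrep("A", 100)),
                       pairs, gap_sizes = 4L)
  expect_equal(nrow(occA), 0L)

  expect_error(scan_peakset(bedr("chr1", 90, 500), genome, pairs),
               "beyond chromosome end")
  expect_error(scan_peakset(bedr("chrX", 0, 10), genome, pairs),
               "missing from genome")
})

test_that("strand symmetry: reverse-complementing the genome swaps HT/TH and
           transposes HH/TT", {
  set.seed(31)
  motifs <- c("TGTTTNN", "NNGCATY")
  dict <- build_pair_dictionary(motifs)[, c("motif_a", "motif_b", "orientation")]
  chrom <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                 collapse = "")
  genome_f <- c(chr1 = chrom)
  genome_r <- c(chr1 = reverse_complement(chrom))
  peaks_f <- bedr("chr1", 0, 20000)
  occ_f <- scan_peakset(peaks_f, genome_f, dict, gap_sizes = 4L)
  occ_r <- scan_peakset(peaks_f, genome_r, dict, gap_sizes = 4L)
  count_of <- function(occ, a, b, o) {
    sum(occ$motif_a == a & occ$motif_b == b & occ$orientation == o)
  }
  for (a in motifs) {
    for (b in motifs) {
      expect_equal(count_of(occ_r, a, b, "HT"), count_of(occ_f, b, a, "TH"))
      expect_equal(count_of(occ_r, a, b, "TH"), count_of(occ_f, b, a, "HT"))
      expect_equal(count_of(occ_r, a, b, "HH"), count_of(occ_f, b, a, "HH"))
      expect_equal(count_of(occ_r, a, b, "TT"), count_of(occ_f, b, a, "TT"))
    }
  }
})

test_that("binomial enrichment: arithmetic, null center, pmf-summation oracle", {
  keyed <- function(cf, cb) {
    fg <- data.frame(motif_a = rep("TGTTTAC", cf), motif_b = "TGTTTAC",
                     orientation = "HH", gap = 4L)
    bg <- data.frame(motif_a = rep("TGTTTAC", cb), motif_b = "TGTTTAC",
                     orientation = "HH", gap = 4L)
    pair_enrichment(fg, 1e6, bg, 1e6)
  }
  r <- keyed(10L, 2L)
  expect_equal(r$fold_change, 5.0)
  expect_equal(r$freq_fg, 10)
  expect_equal(r$freq_bg, 2)

  # fg count equal to its expectation sits near the null center
  r0 <- keyed(50L, 50L)
  expect_equal(r0$fold_change, 1.0)
  expect_gt(r0$p_value, 0.4)
  expect_lt(r0$p_value, 0.65)

  # oracle: direct pmf summation at small n
  set.seed(13)
  occ_n <- function(k) data.frame(motif_a = rep("A", k), motif_b = rep("B", k),
                                  orientation = rep("HH", k), gap = rep(4L, k),
                                  stringsAsFactors = FALSE)
  for (i in 1:25) {
    n <- sample(100:10000, 1)
    cb <- sample(0:20, 1)
    cf <- sample(0:20, 1)
    keys <- data.frame(motif_a = "A", motif_b = "B",
                       orientation = "HH", gap = 4L)
    r <- pair_enrichment(occ_n(cf), n, occ_n(cb), n, keys = keys)
    p_hat <- max(cb, 1) / n
    expect_equal(r$p_value, oracle_binom_tail(cf, n, p_hat), tolerance = 1e-10)
  }
  expect_error(pair_enrichment(data.frame(), 0, data.frame(), 10), "positive")
})

test_that("gap profile is flat in background and peaked at the planted gap", {
  set.seed(41)
  pairs <- data.frame(motif_a = "TGTTTAC", motif_b = "TGTTTAC",
                      orientation = "HH", stringsAsFactors = FALSE)
  # foreground: plants only at gap 4; background: uniform gaps 1..10
  mk_peak <- function(gap) {
    ins <- pair_pattern("TGTTTAC", "TGTTTAC", "HH", strrep("C", gap))
    paste0(strrep("A", 20), ins, strrep("A", 42 - gap))
  }
  fg_seq <- vapply(rep(4L, 300), mk_peak, character(1))
  bg_seq <- vapply(rep(1:10, 200), mk_peak, character(1))
  genome <- c(stats::setNames(fg_seq, paste0("fg", seq_along(fg_seq))),
              stats::setNames(bg_seq, paste0("bg", seq_along(bg_seq))))
  fg <- GenomicRanges::GRanges(names(genome)[seq_along(fg_seq)],
                               IRanges::IRanges(1, nchar(fg_seq)))
  bg <- GenomicRanges::GRanges(names(genome)[-seq_along(fg_seq)],
                               IRanges::IRanges(1, nchar(bg_seq)))
  gp <- gap_profile(fg, bg, genome, pairs, 1:10)
  expect_equal(gp$argmax$argmax_gap, 4L)
  # background alone is flat: max/min frequency ratio < 1.5 at 2,000 plants
  bgf <- gp$profile$freq_bg
  expect_lt(max(bgf) / min(bgf), 1.5)
  # empty gap range -> empty table
  gp0 <- gap_profile(fg, bg, genome, pairs, integer(0))
  expect_equal(nrow(gp0$profile), 0L)
})

test_that("blacklist subtraction removes whole peaks on any overlap", {
  peaks <- c(bedr("chr1", 0, 100), bedr("chr1", 200, 300),
             bedr("chr1", 400, 500))
  bl <- c(bedr("chr1", 220, 260), bedr("chr1", 499, 600))
  out <- subtract_blacklist(peaks, bl)
  expect_length(out, 1L)                  # 1-bp overlap also removed
  expect_equal(GenomicRanges::start(out), 1L)
  expect_identical(subtract_blacklist(peaks, bedr("chr2", 0, 1000)), peaks)
  inside <- subtract_blacklist(bedr("chr1", 230, 240), bl)
  expect_length(inside, 0L)
})
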