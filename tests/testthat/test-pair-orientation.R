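design_rr <- default_design("random_random")
motifs10 <- default_motifs()$motif

test_that("pair dictionary has 400 orientation-resolved 18-nt patterns", {
  dict <- build_pair_dictionary(motifs10)
  expect_equal(nrow(dict), 400L)
  expect_true(all(nchar(dict$pattern) == 18L))
  expect_equal(pair_pattern("TGTTTNN", "TGTTTNN", "HH"), "TGTTTNNTCGANNAAACA")
  expect_error(build_pair_dictionary(c("ACGT")), "7 nt")
})

test_that("orientation symmetry identities hold over the full dictionary", {
  dict <- build_pair_dictionary(motifs10)
  key <- function(a, b, o) dict$pattern[dict$motif_a == a & dict$motif_b == b &
                                          dict$orientation == o]
  for (a in motifs10) {
    for (b in motifs10) {
      expect_equal(reverse_complement(key(a, b, "HT")), key(b, a, "TH"))
      expect_equal(reverse_complement(key(a, b, "HH")), key(b, a, "HH"))
      expect_equal(reverse_complement(key(a, b, "TT")), key(b, a, "TT"))
    }
  }
})

test_that("shifted windows are the expected substrings of the oligo", {
  read <- assemble_oligo(design_rr, "GATTACA", "CCGGTTA")
  w <- extract_shifted_windows(read, design_rr)
  expect_length(w, 5L)
  expect_equal(w[3], paste0("GATTACA", "TCGA", "CCGGTTA"))  # shift 0
  # shift +2 drops the first 2 site-1 bases and appends 2 NBS2 bases
  expect_equal(w[5], paste0("TTACA", "TCGA", "CCGGTTA",
                            substr(design_rr$nbs2, 1, 2)))
  # shift -2 prepends the last 2 NBS1 bases
  expect_equal(w[1], paste0(substr(design_rr$nbs1, 26, 27),
                            "GATTACA", "TCGA", "CCGGT"))
  expect_null(extract_shifted_windows("ACGTACGT", design_rr))
})

test_that("a read counts once per pair even when matching several shifts", {
  dict <- build_pair_dictionary(motifs10)
  # shift-0 window TGTTTACTCGAGTAAACA supports (TGTTTNN, TGTTTNN, HH)
  read <- assemble_oligo(design_rr, "TGTTTAC", "GTAAACA")
  cm <- count_pair_matches(read, dict, design_rr)
  hh <- cm$raw_count[cm$motif_a == "TGTTTNN" & cm$motif_b == "TGTTTNN" &
                       cm$orientation == "HH"]
  expect_equal(hh, 1L)
  expect_true(all(cm$raw_count <= 1L))     # once-per-read bound

  # a window matching the same pair at two shifts still counts once:
  # site1+gap = TGTTTAC TCGA; shifting by -1 with NBS1 ending in A and a
  # pattern degenerate at the edges can double-match; use an N-heavy pair
  d2 <- build_pair_dictionary(c("NNTGTTT"))
  r2 <- assemble_oligo(design_rr, "TGTTTTG", "TTTACAA")
  c2 <- count_pair_matches(r2, d2, design_rr)
  expect_true(all(c2$raw_count <= 1L))
})

test_that("baseline probabilities: closed forms, monotonicity, zero flag", {
  expect_equal(pair_baseline_probability("TGTTTACTCGANNNNNNN", design_rr,
                                         shifts = 0L), (1 / 4)^7)
  expect_equal(pair_baseline_probability(strrep("N", 18), design_rr,
                                         shifts = 0L), 1.0)
  # a pattern conflicting with the fixed gap at every shift is unobservable
  p0 <- pair_baseline_probability(paste0("AAAAAAA", "GGGG", "AAAAAAA"),
                                  design_rr, shifts = 0L)
  expect_equal(p0, 0)

  # monotone: adding an N can never decrease the baseline
  set.seed(11)
  for (i in 1:30) {
    pat <- paste0(random_pattern(7, c("A", "C", "G", "T", "K", "Y")),
                  "TCGA",
                  random_pattern(7, c("A", "C", "G", "T", "R", "W")))
    pos <- sample(c(1:7, 12:18), 1)
    pat2 <- pat
    substr(pat2, pos, pos) <- "N"
    expect_gte(pair_baseline_probability(pat2, design_rr),
               pair_baseline_probability(pat, design_rr))
  }
})

test_that("combined-shift baseline matches a Monte-Carlo estimate to 3 SE", {
  set.seed(19)
  pats <- c("TGTNNNNTCGANNNNNNN",            # high baseline, shift-0 driven
            "NNNTTACTCGANNNNNNN",            # partially degenerate
            "TGTTTNNTCGANNAAACA")            # dictionary-style pair
  n_mc <- 200000L
  for (pat in pats) {
    p_hat <- oracle_baseline_mc(pat, design_rr, shifts = -2:2, n_mc = n_mc)
    p <- pair_baseline_probability(pat, design_rr, shifts = -2:2)
    se <- sqrt(max(p_hat, 1 / n_mc) * (1 - min(p_hat, 1 - 1e-12)) / n_mc)
    expect_lt(abs(p - p_hat), 3 * se + 1e-12)
  }
})

test_that("normalization divides by baselines and joint scaling tops at 100", {
  dict <- build_pair_dictionary(motifs10)[1:10, ]
  dict$raw_count <- rep(10L, 10L)
  nm <- normalize_pair_counts(dict, rep(0.5, 10))
  expect_true(all(nm$normalized == 20))
  expect_true(all(nm$scaled == 100))       # uniform matrix scales to 100

  dict2 <- dict
  dict2$raw_count <- c(40L, rep(10L, 9L))
  nm2 <- normalize_pair_counts(dict2, rep(0.5, 10))
  nm1 <- normalize_pair_counts(dict, rep(0.5, 10), joint_scale_with = nm2)
  expect_equal(max(c(nm1$scaled, nm2$scaled)), 100)
  expect_equal(max(nm1$scaled), 25)        # jointly scaled against the 80

  # zero baseline: flagged, set to 0
  nz <- normalize_pair_counts(dict, c(0, rep(0.5, 9)))
  expect_true(nz$unobservable[1])
  expect_equal(nz$normalized[1], 0)
})
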