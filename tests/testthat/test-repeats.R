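# exhaustive PWM p-value oracle: score every k-mer with the table's binned
# matrix and accumulate background-weighted tail mass
oracle_pwm_pvalues <- function(tab) {
  w <- tab$pwm$width
  kmers <- expand.grid(rep(list(1:4), w))[, w:1, drop = FALSE]
  totals <- apply(kmers, 1L, function(codes) {
    sum(tab$bins[cbind(seq_len(w), as.integer(codes))])
  })
  probs <- apply(kmers, 1L, function(codes) {
    prod(tab$pwm$background[as.integer(codes)])
  })
  list(totals = totals, probs = probs,
       pval = vapply(totals, function(s) sum(probs[totals >= s]), 0))
}

test_that("PWM p-values match exhaustive enumeration for widths 1, 2 and 6", {
  set.seed(17)
  for (w in c(1L, 2L, 6L)) {
    probs <- matrix(stats::rgamma(4 * w, 1), ncol = 4)
    bg <- if (w == 2L) c(0.2, 0.3, 0.3, 0.2) else rep(0.25, 4)
    x <- pwm(probs, background = bg)
    tab <- pwm_pvalue_table(x, granularity = 200L)
    oracle <- oracle_pwm_pvalues(tab)
    got <- pairdimer:::.pwm_pvalue(tab, oracle$totals)
    expect_lt(max(abs(got - oracle$pval)), 1e-12)
  }
})

test_that("width-1 uniform-background p-value of the max score is its mass", {
  x <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 1), pseudocount = 0)
  tab <- pwm_pvalue_table(x, granularity = 100L)
  top <- max(tab$bins)
  expect_equal(pairdimer:::.pwm_pvalue(tab, top), 0.25)
})

test_that("p-values are non-increasing in score over the full table", {
  x <- default_tng_pwm()
  tab <- pwm_pvalue_table(x)
  scores <- seq(tab$min_rel_total,
                tab$min_rel_total + length(tab$tail_p) - 1L)
  pv <- pairdimer:::.pwm_pvalue(tab, scores)
  expect_true(all(diff(pv) <= 1e-15))
})

test_that("repeat scanning: strand mirror, degenerate thresholds, empties", {
  tab <- pwm_pvalue_table(default_tng_pwm())
  tract <- strrep("TTTG", 10)
  g1 <- c(c1 = paste0(strrep("CAGCT", 6), tract, strrep("AGCTG", 6)))
  g2 <- c(c1 = reverse_complement(g1[[1]]))
  m1 <- scan_repeats(g1, tab)
  m2 <- scan_repeats(g2, tab)
  expect_gt(sum(as.character(BiocGenerics::strand(m1)) == "+"), 0L)
  expect_equal(length(m1), length(m2))
  # mirrored coordinates with flipped strands
  L <- nchar(g1[[1]])
  mirrored_starts <- sort(L - GenomicRanges::end(m1) + 1L)
  expect_equal(sort(GenomicRanges::start(m2)), mirrored_starts)
  s1 <- table(as.character(BiocGenerics::strand(m1)))
  s2 <- table(as.character(BiocGenerics::strand(m2)))
  expect_equal(unname(s1[["+"]]), unname(s2[["-"]]))

  # an all-A sequence reads as poly-T on the minus strand, which a T-rich
  # repeat matrix does score; the degenerate-run filter (12 As) is what
  # guarantees such sequences contribute no repeat calls
  gA <- c(c1 = strrep("A", 200))
  expect_length(filter_degenerate(scan_repeats(gA, tab), gA), 0L)
  expect_length(scan_repeats(c(c1 = "ACGT"), tab), 0L)   # shorter than width
  # threshold 1.0 reports every window on both strands
  all_m <- scan_repeats(c(c1 = strrep("ACGT", 10)), tab, p_threshold = 1.0)
  expect_equal(length(all_m), 2L * (40L - 12L + 1L))
})

test_that("degenerate-run filter removes listed classes and is idempotent", {
  genome <- c(chr1 = paste0("TGTGTGTGTGTG",            # (TG)6        1..12
                            "TTTGTTTGTTTGTTTG",        # (TTTG)4     13..28
                            "TTTTTTTTTTTT",            # 12 T        29..40
                            "ACACACACACAC",            # (AC)6       41..52
                            "GCATGCATGCAT"))           # none        53..64
  m <- c(bedr("chr1", 0, 12, "+"), bedr("chr1", 12, 28, "+"),
         bedr("chr1", 28, 40, "+"), bedr("chr1", 40, 52, "+"),
         bedr("chr1", 52, 64, "+"))
  S4Vectors::mcols(m)$score <- 1
  kept <- filter_degenerate(m, genome)
  expect_equal(GenomicRanges::start(kept), c(13L, 53L))
  expect_identical(filter_degenerate(kept, genome), kept)
})

test_that("region merging: transitive union of overlaps, strand from best", {
  m <- c(bedr("chr1", 0, 12, "+"), bedr("chr1", 8, 20, "-"),
         bedr("chr1", 30, 40, "-"))
  S4Vectors::mcols(m)$score <- c(5, 9, 3)
  S4Vectors::mcols(m)$pvalue <- c(1e-5, 1e-7, 1e-4)
  reg <- merge_regions(m)
  expect_length(reg, 2L)
  expect_equal(GenomicRanges::start(reg), c(1L, 31L))
  expect_equal(GenomicRanges::end(reg), c(20L, 40L))
  expect_equal(as.character(BiocGenerics::strand(reg)), c("-", "-"))
  expect_equal(S4Vectors::mcols(reg)$n_matches, c(2L, 1L))
  expect_equal(S4Vectors::mcols(reg)$pvalue, c(1e-7, 1e-4))
  # abutting intervals are NOT merged; disjoint unchanged; idempotent
  ab <- c(bedr("chr1", 0, 10, "+"), bedr("chr1", 10, 20, "+"))
  S4Vectors::mcols(ab)$score <- c(1, 2)
  expect_length(merge_regions(ab), 2L)
  expect_length(merge_regions(merge_regions(m)), 2L)
})

test_that("nearest repeat: sign convention, alignment rule, tie-break", {
  # spec-style half-open fixtures translated through the BED helper
  hh <- bedr("chr1", 200, 218)
  up_plus <- bedr("chr1", 100, 150, "+")
  down_minus <- bedr("chr1", 300, 340, "-")
  r1 <- nearest_repeat(hh, up_plus)
  expect_equal(r1$distance, -50L)
  expect_equal(r1$alignment, "aligned")
  r2 <- nearest_repeat(hh, down_minus)
  expect_equal(r2$distance, 82L)
  expect_equal(r2$alignment, "aligned")
  # flipped strands become divergent
  expect_equal(nearest_repeat(hh, bedr("chr1", 100, 150, "-"))$alignment,
               "divergent")
  expect_equal(nearest_repeat(hh, bedr("chr1", 300, 340, "+"))$alignment,
               "divergent")
  # abutting -> distance 0; overlap -> 0
  expect_equal(nearest_repeat(bedr("chr1", 100, 118),
                              bedr("chr1", 118, 150, "+"))$distance, 0L)
  expect_equal(nearest_repeat(hh, bedr("chr1", 210, 230, "+"))$distance, 0L)
  # equidistant up/downstream: downstream preferred
  both <- c(bedr("chr1", 150, 170, "+"), bedr("chr1", 248, 268, "+"))
  r3 <- nearest_repeat(hh, both)
  expect_equal(r3$repeat_index, 2L)
  expect_equal(r3$distance, 30L)
  # no repeat on the chromosome -> flagged absent
  r4 <- nearest_repeat(hh, bedr("chr2", 0, 50, "+"))
  expect_true(r4$absent)
})

test_that("reflecting the chromosome flips distance signs and the aligned
           clauses", {
  L <- 1000L
  reflect <- function(gr) {
    st <- as.character(BiocGenerics::strand(gr))
    st[st == "+"] <- "x"; st[st == "-"] <- "+"; st[st == "x"] <- "-"
    out <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(L - GenomicRanges::end(gr) + 1L,
                       L - GenomicRanges::start(gr) + 1L))
    BiocGenerics::strand(out) <- st
    out
  }
  set.seed(53)
  for (i in 1:20) {
    hs <- sample(300:700, 1)
    hh <- bedr("chr1", hs, hs + 18)
    rs <- sample(c(50:250, 750:950), 1)
    rep1 <- bedr("chr1", rs, rs + 30, sample(c("+", "-"), 1))
    a <- nearest_repeat(hh, rep1)
    b <- nearest_repeat(reflect(hh), reflect(rep1))
    expect_equal(b$distance, -a$distance)
    expect_equal(b$alignment, a$alignment)
  }
})

test_that("signal-free background applies both distance and signal rules", {
  track <- make_track(list("chr1", 0, 100000, 1), list("chr2", 0, 100000, 1),
                      list("chr1", 30050, 30250, 9))
  fg <- bedr("chr1", 30000, 30300)                   # AUC at center: 200+9*200
  # near (5 kb, excluded), far-and-quiet (kept), far-but-loud (excluded)
  ocrs <- GenomicRanges::GRanges(
    c("chr1", "chr2", "chr1"),
    IRanges::IRanges(c(35001, 50001, 80001), c(35200, 50200, 80200)))
  track2 <- suppressWarnings(
    c(track, make_track(list("chr1", 80000, 80200, 30))))
  out <- define_signal_free_background(ocrs, fg, track2, min_dist_bp = 10000)
  expect_length(out, 1L)
  expect_equal(as.character(GenomicRanges::seqnames(out)), "chr2")
  expect_error(define_signal_free_background(ocrs, fg[0], track2), "empty")
})

test_that("stratified AUC groups behave on handmade tracks", {
  # identical coverage everywhere -> all group medians equal
  reps <- c(bedr("chr1", 1000, 1015, "+"), bedr("chr1", 5000, 5060, "+"),
            bedr("chr1", 9000, 9016, "+"), bedr("chr1", 20000, 20070, "+"))
  hh <- c(bedr("chr1", 1015, 1033), bedr("chr1", 5060, 5078))
  flat <- make_track(list("chr1", 0, 50000, 2))
  sc <- stratified_auc_compare(reps, hh, flat)
  expect_equal(sc$values$length_class, c("short", "long", "short", "long"))
  expect_equal(sc$values$adjacency, c("adjacent", "adjacent", "far", "far"))
  meds <- sc$summary$median_log2_auc
  expect_true(all(abs(meds - meds[1]) < 1e-12))
  # single repeat in a group: median equals its own AUC
  one <- stratified_auc_compare(reps[1], hh, flat)
  expect_equal(one$summary$median_log2_auc[one$summary$length_class == "short" &
                                             one$summary$adjacency == "adjacent"],
               log2(400 + 1))
  # empty groups are flagged NA, no crash
  expect_true(any(is.na(one$summary$median_log2_auc)))
})
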