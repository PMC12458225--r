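small_cfg <- function(seed = 7L, ...) {
  args <- list(n_chrom = 3L, chrom_len = 80000L, n_fg_peaks = 30L,
               n_bg_peaks = 60L, n_repeats = 30L, n_genes = 60L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(genome_config, args)
}

test_that("identical seeds give byte-identical genome bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_genome(small_cfg(), out_dir = d1)
  simulate_genome(small_cfg(), out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  simulate_genome(small_cfg(seed = 8L), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("identical seeds give identical oligo read sets", {
  d <- default_design("random_rcfkhm")
  s1 <- simulate_oligo_pdseq(d, foxp3_model(), n_input = 500, n_pd = 500,
                             seed = 5L, pool_factor = 4L)
  s2 <- simulate_oligo_pdseq(d, foxp3_model(), n_input = 500, n_pd = 500,
                             seed = 5L, pool_factor = 4L)
  expect_identical(s1$input, s2$input)
  expect_identical(s1$pd, s2$pd)
})

test_that("planted foreground pairs are recovered one-for-one by scanning", {
  sim <- simulate_genome(small_cfg())
  tr <- sim$truth
  pairs <- data.frame(motif_a = tr$pair$motif_a, motif_b = tr$pair$motif_b,
                      orientation = tr$pair$orientation,
                      stringsAsFactors = FALSE)
  occ <- scan_peakset(sim$fg, sim$genome, pairs, gap_sizes = tr$pair$fg_gap)
  expect_equal(nrow(occ), nrow(tr$fg_plants))
  expect_setequal(paste(occ$chrom, occ$start),
                  paste(tr$fg_plants$chrom, tr$fg_plants$start))

  # planted repeat tracts: k tracts -> k merged regions on a quiet backbone
  cfgA <- small_cfg()
  simA <- simulate_genome(cfgA)
  tab <- pwm_pvalue_table(default_tng_pwm())
  # restrict the scan to the planted tract neighborhoods, where ground truth
  # is exact; spurious background hits are a property of the random genome,
  # not of the planting
  tract_gr <- GenomicRanges::GRanges(
    simA$truth$repeats$chrom,
    IRanges::IRanges(simA$truth$repeats$start, simA$truth$repeats$end))
  m <- scan_repeats(simA$genome, tab, peaks = tract_gr)
  m <- filter_degenerate(m, simA$genome)
  reg <- merge_regions(m)
  covered <- IRanges::overlapsAny(tract_gr, reg, ignore.strand = TRUE)
  expect_true(all(covered))
})

test_that("zero planting rates leave nothing for the scans to find", {
  cfg <- small_cfg(fg_plant_rate = 0, bg_plant_rate = 0,
                   adjacency_fraction = 0, n_repeats = 0L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$fg_plants), 0L)
  expect_equal(nrow(sim$truth$bg_plants), 0L)
  expect_equal(nrow(sim$truth$repeats), 0L)
  pairs <- data.frame(motif_a = "TGTTTAC", motif_b = "TGTTTAC",
                      orientation = "HH", stringsAsFactors = FALSE)
  occ <- scan_peakset(sim$fg, sim$genome, pairs, gap_sizes = 4L)
  expect_equal(nrow(occ), 0L)
})

test_that("a binding model without bonuses degenerates to uniform with a
           warning, and 2N enrichment stays flat", {
  d <- default_design("random_rcfkhm")
  expect_warning(
    sim <- simulate_oligo_pdseq(d, binding_model(), n_input = 100000,
                                n_pd = 100000, seed = 21L, pool_factor = 4L),
    "uniform")
  pin <- parse_library_reads(sim$input, d)
  ppd <- parse_library_reads(sim$pd, d)
  expect_true(all(is.na(pin$reject)))
  tin <- tabulate_counts(pin$site1, dense = TRUE)
  tpd <- tabulate_counts(ppd$site1, dense = TRUE)
  agg <- aggregate_2n(tpd, tin)
  # a flat library is multiplicative counting noise around 1: each 2N
  # pattern pools ~98 reads per table, finite-pool duplication inflates the
  # pull-down variance by 1 + n_pd/n_pool, so the log-enrichment noise
  # floor is sigma0 = sqrt((1 + 1/4)/98 + 1/98) ~ 0.15. Flatness means no
  # dispersion beyond that floor and no outlier beyond its extreme order
  # statistic over 21,504 patterns (~4.5 sigma; 6 sigma as the bound).
  sigma0 <- sqrt((1 + 1 / 4) / 98 + 1 / 98)
  le <- log(agg$records$enrichment)
  expect_lt(stats::sd(le), 1.5 * sigma0)
  expect_lt(max(agg$records$enrichment), exp(6 * sigma0))
  expect_lt(abs(stats::median(agg$records$enrichment) - 1), 0.02)
})

test_that("FoxP3-like and FoxP1-like models produce the expected orientation
           and site-1 dependence contrast", {
  d_rr <- default_design("random_random")
  dict <- build_pair_dictionary(default_motifs()$motif)

  sim3 <- simulate_oligo_pdseq(d_rr, foxp3_model(), n_input = 1000,
                               n_pd = 200000, seed = 31L)
  cm3 <- count_pair_matches(sim3$pd, dict, d_rr)
  tot3 <- tapply(cm3$raw_count, cm3$orientation, sum)
  # HH strictly exceeds every other orientation total
  expect_true(all(tot3["HH"] > tot3[c("HT", "TH", "TT")]))

  sim1 <- simulate_oligo_pdseq(d_rr, foxp1_model(), n_input = 1000,
                               n_pd = 200000, seed = 31L)
  cm1 <- count_pair_matches(sim1$pd, dict, d_rr)
  tot1 <- tapply(cm1$raw_count, cm1$orientation, sum)
  # orientation bias is markedly more pronounced for the FoxP3-like model;
  # the FoxP1-like totals are statistically consistent with uniform
  bias3 <- tot3[["HH"]] / max(tot3[c("HT", "TH", "TT")])
  bias1 <- tot1[["HH"]] / max(tot1[c("HT", "TH", "TT")])
  expect_gt(bias3, 2)
  expect_gt(bias3, 5 * bias1)
  expect_gt(stats::chisq.test(tot1)$p.value, 0.001)

  # planted HH pair tops the normalized matrix in the FoxP3-like run
  bl <- pair_baseline_probability(dict$pattern, d_rr)
  nm <- normalize_pair_counts(cm3, bl)
  top <- nm[which.max(nm$normalized), ]
  expect_equal(top$orientation, "HH")
})

test_that("FoxP1-like pull-down shows markedly lower site-1 reliance", {
  d_fk <- default_design("random_rcfkhm")
  n <- 400000
  simp1 <- simulate_oligo_pdseq(d_fk, foxp1_model(), n_input = n, n_pd = n,
                                seed = 41L, pool_factor = 4L)
  simp3 <- simulate_oligo_pdseq(d_fk, foxp3_model(), n_input = n, n_pd = n,
                                seed = 41L, pool_factor = 4L)
  # spread of the site-1 enrichment profile, measured on 2N-aggregated
  # counts (16-fold pooling keeps counting noise well below the bound)
  spread <- function(sim) {
    tin <- tabulate_counts(parse_library_reads(sim$input, d_fk)$site1,
                           dense = TRUE)
    tpd <- tabulate_counts(parse_library_reads(sim$pd, d_fk)$site1,
                           dense = TRUE)
    agg <- aggregate_2n(tpd, tin)
    q <- stats::quantile(agg$records$enrichment, c(0.01, 0.99))
    unname(q[2] / q[1])
  }
  s1 <- spread(simp1)
  s3 <- spread(simp3)
  expect_lt(s1, 1.5)       # site-2-only binder: site-1 profile essentially flat
  expect_gt(s3, 2 * s1)    # pair binder: strong site-1 dependence
})
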