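# pairdimer

Composite-motif analysis for forkhead-family transcription factors that
bind DNA two ways: as **head-to-head (H-H) dimers** on inverted-repeat
arrangements of forkhead-like half-sites, and as **multimers on
TnG-repeat microsatellites**. FoxP3 — the regulatory-T-cell master
regulator — is the motivating case: it binds isolated forkhead motifs
(FKHM, `TGTTTAC`) poorly, and instead recognizes pairs of relaxed
half-sites at a preferred 4-nt gap, with H-H sites frequently seeding
multimerization on adjacent short repeats.

The package is aimed at computational biologists analysing pull-down
sequencing (PD-seq) of degenerate oligo libraries and peak-set genomics
around such factors. It provides, as an R package plus a numbered
analysis workflow:

- **Oligo PD-seq enrichment** (`parse_library_reads`, `tabulate_counts`,
  `fold_enrichment`): structured-read parsing, dense count tables over
  all 4^7 site-1 sequences, RPM normalization, pull-down/input fold
  enrichment with pseudocount ε = 0.5 RPM.
- **2N-motif discovery** (`enumerate_2n_patterns`, `aggregate_2n`):
  7-mers with two degenerate positions (21 per sequence, 21,504 after
  deduplication); aggregate counts sum each pattern's 16 instantiations.
- **Orientation analysis** (`build_pair_dictionary`,
  `count_pair_matches`, `pair_baseline_probability`,
  `normalize_pair_counts`): the 10 × 10 × 4 = 400-pattern dictionary
  (`HH = a + gap + rc(b)`, `HT = a + gap + b`, `TH = rc(a) + gap +
  rc(b)`, `TT = rc(a) + gap + b`), five shifted windows (0, ±1, ±2)
  counted once per read, and normalization by the baseline probability
  `1 − Π(1 − p_s)` of matching under the design's fixed bases.
- **Genomic pair enrichment** (`scan_peakset`, `pair_enrichment`,
  `gap_profile`, `subtract_blacklist`): positive-strand non-overlapping
  scans with `N^gap` spacers, per-Mb frequencies, one-sided exact
  binomial tests of foreground counts against the background rate
  (`P[X ≥ k]`, `X ~ Bin(fg_bp, bg_count/bg_bp)`), and gap-size profiles
  over 1–10 nt.
- **Repeat detection and adjacency** (`pwm`, `pwm_pvalue_table`,
  `scan_repeats`, `filter_degenerate`, `merge_regions`,
  `nearest_repeat`, `window_auc`, `stratified_auc_compare`): FIMO-style
  PWM scanning with *exact* p-values by positional dynamic programming
  (cutoff 8e-5), degenerate-run filters ((TG)₆-type runs, 12-nt
  homopolymers), signed border-to-border distances with
  aligned/divergent orientation calls, and 200-bp coverage AUC
  comparisons stratified by repeat length (short ≤ 20 bp, long ≥ 40 bp).
- **Gene proximity** (`feature_density_windows`,
  `fraction_with_feature`): feature density (bp/Mb) in 1 kb–1 Mb
  windows around genes and 2-kb feature fractions by
  differential-expression significance bin.
- **Synthetic data** (`simulate_oligo_pdseq`, `simulate_genome`): every
  input the pipeline consumes, generated with planted ground truth and
  byte-identical under a fixed seed.

## Worked example

Simulate a genome whose foreground peaks carry one planted H-H pair at a
4-nt gap while background peaks use gaps uniform on 1–10, then recover
the spacing preference and the enriched pairs:

```r
library(pairdimer)

cfg <- genome_config(n_fg_peaks = 200, n_bg_peaks = 800, seed = 7)
sim <- simulate_genome(cfg)

pairs <- data.frame(motif_a = "TGTTTAC", motif_b = "TGTTTAC",
                    orientation = "HH")
gp <- gap_profile(sim$fg, sim$bg, sim$genome, pairs, gap_range = 1:10)
gp$profile[, c("gap", "count_fg", "count_bg", "freq_fg", "freq_bg", "ratio")]
#>    gap count_fg count_bg freq_fg freq_bg ratio
#> 1    1        0       35       0     146   0.0
#> 4    4      163       39    2717     162  16.7
#> 7    7        0       52       0     217   0.0
#> ...
gp$argmax$argmax_gap
#> [1] 4
```

The planted pair is found 163 times in foreground peaks, only at the
planted 4-nt spacing (2,717 occurrences/Mb against 162/Mb in
background, ratio 16.7), while background frequencies are flat across
gaps — the signature distinguishing genuine spacing preference from
peak-definition artifacts.

```r
dict <- build_pair_dictionary(default_motifs()$motif)
fg_occ <- scan_peakset(sim$fg, sim$genome, dict, gap_sizes = 4L)
bg_occ <- scan_peakset(sim$bg, sim$genome, dict, gap_sizes = 4L)
keys <- dict[, c("motif_a", "motif_b", "orientation")]; keys$gap <- 4L
enr <- pair_enrichment(fg_occ, total_bp(sim$fg), bg_occ, total_bp(sim$bg),
                       keys = keys)
head(enr[enr$significant & enr$count_fg > 5, ], 3)
#>    motif_a motif_b orientation count_fg count_bg fold_change   p_value
#> 1  TGTTTNN TGTTTNN          HH      164       39        16.8 2.43e-136
#> 2  TGTTKNN TGTTTNN          HH      164       39        16.8 2.43e-136
#> 11 TGTTTNN TGTTKNN          HH      164       41        16.0 5.41e-133
```

The dictionary cells compatible with the planted concrete pair
(`TGTTTAC` half-sites in H-H arrangement) are the significantly
enriched ones; their fold change is foreground-per-Mb over
background-per-Mb and the p-value is the one-sided exact binomial tail.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study on synthetic
data; each writes tables under `results/` and regenerable reads/bundles
under `scratch/`:

1. `01_simulate_oligo.R` — PD-seq libraries (random-rcFKHM and
   random-random; FoxP3-like and FoxP1-like binding models).
2. `02_oligo_enrichment.R` — per-sequence enrichment and 2N-motif
   discovery; site-1 dependence contrast between the two models.
3. `03_pair_orientation.R` — 400-pattern counts, baselines, jointly
   scaled orientation matrices.
4. `04_simulate_genome.R` — the genome bundle (FASTA, peak BEDs,
   blacklist, bedGraph, genes, DE table, truth manifest).
5. `05_genomic_pairs.R` — blacklist subtraction, gap-4 pair enrichment,
   gap profile, merged H-H sites.
6. `06_repeats_adjacency.R` — PWM repeat scan and filters, H-H/repeat
   adjacency, signal-free background, stratified AUC.
7. `07_gene_proximity.R` — density windows and 2-kb fractions against
   the DE table.

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

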