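#!/usr/bin/env Rscript
# Stage 4 — generate the synthetic genome bundle.
#
# Standard conditions: 500 foreground (factor-bound) peaks planting one
# head-to-head pair at the preferred 4-nt spacing, 2,000 background/OCR
# peaks planting the same pair with gaps uniform over 1-10, TnG repeat
# tracts (short <= 20 bp, long >= 40 bp) with half receiving an aligned
# abutting H-H neighbor, occupancy signal boosts per element class, genes
# and a differential-expression table tied to element proximity.

suppressPackageStartupMessages(library(pairdimer))
cfg <- genome_config(seed = 7L)
sim <- simulate_genome(cfg, out_dir = "scratch/genome_bundle")
message("bundle written to scratch/genome_bundle/")
message(sprintf("  fg peaks: %d (%d planted at gap %d)", length(sim$fg),
                nrow(sim$truth$fg_plants), sim$truth$pair$fg_gap))
message(sprintf("  bg peaks: %d (%d planted, gaps 1-10)", length(sim$bg),
                nrow(sim$truth$bg_plants)))
message(sprintf("  repeat tracts: %d (%d with aligned H-H neighbor)",
                nrow(sim$truth$repeats), sum(sim$truth$repeats$has_hh)))
message(sprintf("  genes: %d (%d significant)", length(sim$genes),
                length(sim$truth$significant_genes)))
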