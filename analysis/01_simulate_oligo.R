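#!/usr/bin/env Rscript
# Stage 1 — simulate the oligo pull-down libraries.
#
# Two library designs: random-rcFKHM (variable site 1, fixed reverse-
# complement forkhead motif in site 2) and random-random (both sites
# variable). Two binding models: FoxP3-like (head-to-head bonus on pairs of
# forkhead-like half-sites) and FoxP1-like (site-2-only binding). Reads are
# written to scratch/ (regenerable at any time from the seed); the planted
# truth goes alongside them.

suppressPackageStartupMessages(library(pairdimer))
dir.create("scratch/oligo", recursive = TRUE, showWarnings = FALSE)
seed <- 7L

d_fk <- default_design("random_rcfkhm")
d_rr <- default_design("random_random")

message("simulating random-rcFKHM libraries (FoxP3-like and FoxP1-like) ...")
sim_a <- simulate_oligo_pdseq(d_fk, foxp3_model(), n_input = 400000, n_pd = 400000,
                     seed = seed, pool_factor = 4L,
                     out_dir = "scratch/oligo/rcfkhm_foxp3")
sim_b <- simulate_oligo_pdseq(d_fk, foxp1_model(), n_input = 400000, n_pd = 400000,
                     seed = seed, pool_factor = 4L,
                     out_dir = "scratch/oligo/rcfkhm_foxp1")

message("simulating random-random libraries ...")
sim_c <- simulate_oligo_pdseq(d_rr, foxp3_model(), n_input = 1000, n_pd = 200000,
                     seed = seed, out_dir = "scratch/oligo/rr_foxp3")
sim_d <- simulate_oligo_pdseq(d_rr, foxp1_model(), n_input = 1000, n_pd = 200000,
                     seed = seed, out_dir = "scratch/oligo/rr_foxp1")

message("done; reads and truth manifests under scratch/oligo/")
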