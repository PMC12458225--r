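#!/usr/bin/env Rscript
# Stage 5 — paired-motif enrichment in peaks and the gap-size profile.
#
# Scans foreground and background peak sequences (positive strand,
# non-overlapping per pattern, N^gap spacer) for the 400 dictionary pairs,
# tests foreground enrichment per pair with a one-sided exact binomial test
# on per-Mb normalized counts, and profiles the planted pair over gap sizes
# 1-10. Expected outcome: head-to-head pairs of forkhead-like motifs
# significantly enriched, with the gap profile peaking at 4 nt in
# foreground but flat in background.

suppressPackageStartupMessages(library(pairdimer))
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/genome_bundle/genome.fa")
fg <- load_intervals("scratch/genome_bundle/fg.bed")
bg <- load_intervals("scratch/genome_bundle/bg.bed")
bl <- load_intervals("scratch/genome_bundle/blacklist.bed")
fg <- subtract_blacklist(fg, bl)
bg <- subtract_blacklist(bg, bl)
message(sprintf("peaks after blacklist: fg %d (%.0f kb), bg %d (%.0f kb)",
                length(fg), total_bp(fg) / 1e3, length(bg), total_bp(bg) / 1e3))

dict <- build_pair_dictionary(default_motifs()$motif)
fg_occ <- scan_peakset(fg, genome, dict, gap_sizes = 4L)
bg_occ <- scan_peakset(bg, genome, dict, gap_sizes = 4L)
keys <- dict[, c("motif_a", "motif_b", "orientation")]
keys$gap <- 4L
enr <- pair_enrichment(fg_occ, total_bp(fg), bg_occ, total_bp(bg), keys = keys)
write.table(enr, "results/05_pair_enrichment_gap4.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- enr[enr$significant, ]
sig <- sig[order(-sig$fold_change), ]
message(sprintf("significant pairs at gap 4 (p < 0.05): %d of %d", nrow(sig),
                nrow(enr)))
message("top by fold change:")
for (i in seq_len(min(5, nrow(sig)))) {
  message(sprintf("  %s / %s %s  FC %.1f  p %.2e", sig$motif_a[i],
                  sig$motif_b[i], sig$orientation[i], sig$fold_change[i],
                  sig$p_value[i]))
}

planted <- data.frame(motif_a = "TGTTTAC", motif_b = "TGTTTAC",
                      orientation = "HH", stringsAsFactors = FALSE)
gp <- gap_profile(fg, bg, genome, planted, gap_range = 1:10)
write.table(gp$profile, "results/05_gap_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("gap-profile argmax for the planted pair: %d nt",
                gp$argmax$argmax_gap[1]))

# merged unique H-H sites feed the adjacency stage
hh_occ <- fg_occ[fg_occ$orientation == "HH", ]
hh_sites <- merge_hh_sites(hh_occ)
write_intervals(hh_sites, "results/05_hh_sites.bed")
message(sprintf("H-H occurrences: %d in %d merged unique sites",
                nrow(hh_occ), length(hh_sites)))
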