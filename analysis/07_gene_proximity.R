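#!/usr/bin/env Rscript
# Stage 7 — feature proximity to differentially expressed genes.
#
# Feature density (bp per Mb) in expanding windows around gene bodies,
# split by differential-expression significance, and the fraction of genes
# with a repeat region or H-H site within 2 kb, by adjusted-p bin and
# fold-change direction.

suppressPackageStartupMessages(library(pairdimer))
dir.create("results", showWarnings = FALSE)

genes <- load_intervals("scratch/genome_bundle/genes.bed")
de <- load_de_table("scratch/genome_bundle/de.tsv")
genes <- annotate_genes(genes, de)
repeats <- load_intervals("results/06_repeat_regions.bed")
hh_sites <- load_intervals("results/05_hh_sites.bed")
features <- c(GenomicRanges::granges(repeats), GenomicRanges::granges(hh_sites))

d <- feature_density_windows(genes, features,
                             windows = c(1e3, 5e3, 2e4, 1e5))
write.table(d$profile, "results/07_density_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean feature density (bp/Mb) by group and window:")
p <- d$profile
for (i in seq_len(nrow(p))) {
  message(sprintf("  %-16s w=%-7d %8.0f", p$group[i], p$window[i],
                  p$mean_density[i]))
}

fr <- fraction_with_feature(genes, features, expand_bp = 2000,
                            padj_bins = c(0, 0.001, 0.05, 1),
                            direction_split = TRUE)
write.table(fr, "results/07_fraction_2kb.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("fraction of genes with a feature within 2 kb, by padj bin:")
for (i in seq_len(nrow(fr))) {
  message(sprintf("  %-14s %-5s n=%-4d %s", fr$bin[i], fr$direction[i],
                  fr$n[i],
                  ifelse(is.na(fr$fraction[i]), "NA",
                         sprintf("%.2f", fr$fraction[i]))))
}
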