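#!/usr/bin/env Rscript
# Stage 3 — orientation analysis of the random-random libraries.
#
# Builds the 400-pattern dictionary (10 motifs x 10 motifs x 4
# orientations), counts reads supporting each pair across the five shifted
# windows (once per read), normalizes by the baseline probability of each
# pattern under the design's fixed bases, and applies a joint 0-100 scale
# across the two proteins for a common heatmap scale.

suppressPackageStartupMessages(library(pairdimer))
dir.create("results", showWarnings = FALSE)
design <- default_design("random_random")
dict <- build_pair_dictionary(default_motifs()$motif)
baselines <- pair_baseline_probability(dict$pattern, design)

count_one <- function(label) {
  pd <- load_reads(sprintf("scratch/oligo/rr_%s/pd.fastq", label))
  count_pair_matches(pd$seq, dict, design)
}
cm3 <- count_one("foxp3")
cm1 <- count_one("foxp1")
nm1 <- normalize_pair_counts(cm1, baselines)
nm3 <- normalize_pair_counts(cm3, baselines, joint_scale_with = nm1)
nm1 <- normalize_pair_counts(cm1, baselines, joint_scale_with = nm3)

for (x in list(list("foxp3", nm3), list("foxp1", nm1))) {
  out <- x[[2]][, c("motif_a", "motif_b", "orientation", "raw_count",
                    "baseline", "normalized", "scaled")]
  write.table(out, sprintf("results/03_pair_matrix_%s.tsv", x[[1]]),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

tot3 <- tapply(nm3$raw_count, nm3$orientation, sum)
tot1 <- tapply(nm1$raw_count, nm1$orientation, sum)
message("orientation totals, FoxP3-like: ",
        paste(names(tot3), tot3, collapse = "  "))
message("orientation totals, FoxP1-like: ",
        paste(names(tot1), tot1, collapse = "  "))
top <- nm3[which.max(nm3$normalized), ]
message(sprintf("top normalized cell (FoxP3-like): %s / %s %s",
                top$motif_a, top$motif_b, top$orientation))
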