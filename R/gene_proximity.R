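# Gene-proximity stage: relate dimer sites and repeat regions to a
# differential-expression table. Density is measured in feature bp per Mb
# of the expanded gene window (feature base pairs clipped to the window,
# not feature counts); windows expand from the gene body borders.

#' Attach differential-expression results to gene intervals
#'
#' @param genes `GRanges` of gene bodies with a `name` metadata column.
#' @param de data.frame with columns gene, log2fc, padj (see
#'   [load_de_table()]).
#' @return `GRanges` with `gene`, `log2fc`, `padj` metadata; genes missing
#'   from the table get padj 1 and log2fc 0; missing padj values become 1.
#' @export
annotate_genes <- function(genes, de) {
  ix <- match(S4Vectors::mcols(genes)$name, de$gene)
  S4Vectors::mcols(genes)$gene <- S4Vectors::mcols(genes)$name
  S4Vectors::mcols(genes)$log2fc <- ifelse(is.na(ix), 0, de$log2fc[ix])
  padj <- ifelse(is.na(ix), 1, de$padj[ix])
  padj[is.na(padj)] <- 1
  S4Vectors::mcols(genes)$padj <- padj
  genes
}

# expand gene bodies by w bp on each side, clipped at position 1 and at the
# chromosome end when lengths are known
.expand_genes <- function(genes, w, chrom_len = NULL) {
  start <- pmax(GenomicRanges::start(genes) - w, 1L)
  end <- GenomicRanges::end(genes) + w
  if (!is.null(chrom_len)) {
    end <- pmin(end, chrom_len[as.character(GenomicRanges::seqnames(genes))])
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(start, end))
}

#' Feature density around genes over expanding windows
#'
#' For each gene the body is expanded by `w` bp on both sides; the density
#' is the total feature bp overlapping the expanded interval (clipped to
#' it), per Mb of expanded interval length. Group means are reported per
#' (gene group, window size), with genes grouped by differential-expression
#' significance (padj < `sig_alpha`).
#'
#' @param genes annotated `GRanges` from [annotate_genes()].
#' @param features `GRanges` of features (e.g. repeat regions, H-H sites).
#' @param windows integer window sizes in bp (e.g. `c(1e3, 1e4, 1e5, 1e6)`).
#' @param sig_alpha significance cut on padj (default 0.05).
#' @param chrom_len optional named chromosome lengths for clipping.
#' @return list with `per_gene` (gene x window densities) and `profile`
#'   (data.frame: group, window, mean_density in bp/Mb).
#' @export
feature_density_windows <- function(genes, features, windows,
                                    sig_alpha = 0.05, chrom_len = NULL) {
  stopifnot(all(windows > 0), !is.unsorted(windows))
  group <- ifelse(S4Vectors::mcols(genes)$padj < sig_alpha,
                  "significant", "non_significant")
  per_gene <- matrix(0, nrow = length(genes), ncol = length(windows),
                     dimnames = list(NULL, paste0("w", windows)))
  for (k in seq_along(windows)) {
    exp_gr <- .expand_genes(genes, windows[k], chrom_len)
    if (length(features)) {
      ov <- GenomicRanges::findOverlaps(exp_gr, features, ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov)
        ints <- IRanges::pintersect(
          IRanges::ranges(exp_gr)[qh],
          IRanges::ranges(features)[S4Vectors::subjectHits(ov)])
        bp <- rowsum(IRanges::width(ints), qh)
        per_gene[as.integer(rownames(bp)), k] <- bp[, 1L]
      }
    }
    per_gene[, k] <- per_gene[, k] / (GenomicRanges::width(exp_gr) / 1e6)
  }
  profile <- do.call(rbind, lapply(unique(group), function(g) {
    data.frame(group = g, window = windows,
               mean_density = colMeans(per_gene[group == g, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(profile) <- NULL
  list(per_gene = per_gene, profile = profile)
}

#' Fraction of genes with a feature within a fixed expansion
#'
#' Expands each gene body by `expand_bp` and reports, per padj bin (and per
#' log2 fold-change direction when `direction_split`), the fraction of genes
#' whose expanded interval overlaps at least one feature. Empty bins are
#' reported as NA, not 0.
#'
#' @param genes annotated `GRanges` from [annotate_genes()].
#' @param features `GRanges` of features.
#' @param expand_bp expansion from the gene borders (default 2000).
#' @param padj_bins increasing breaks partitioning \[0, 1\].
#' @param direction_split split bins by sign of log2fc.
#' @param chrom_len optional named chromosome lengths for clipping.
#' @return data.frame: bin, direction (when split), n, fraction.
#' @export
fraction_with_feature <- function(genes, features, expand_bp = 2000L,
                                  padj_bins = c(0, 0.001, 0.01, 0.05, 0.25, 1),
                                  direction_split = FALSE,
                                  chrom_len = NULL) {
  stopifnot(padj_bins[1L] == 0, padj_bins[length(padj_bins)] == 1,
            !is.unsorted(padj_bins))
  exp_gr <- .expand_genes(genes, expand_bp, chrom_len)
  has <- IRanges::overlapsAny(exp_gr, features, ignore.strand = TRUE)
  padj <- S4Vectors::mcols(genes)$padj
  bin <- cut(padj, breaks = padj_bins, include.lowest = TRUE)
  direction <- if (direction_split) {
    ifelse(S4Vectors::mcols(genes)$log2fc >= 0, "up", "down")
  } else {
    rep("all", length(genes))
  }
  grid <- expand.grid(bin = levels(bin), direction = unique(direction),
                      stringsAsFactors = FALSE)
  grid$n <- NA_integer_
  grid$fraction <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- which(as.character(bin) == grid$bin[i] & direction == grid$direction[i])
    grid$n[i] <- length(sel)
    if (length(sel)) grid$fraction[i] <- mean(has[sel])
  }
  grid
}
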