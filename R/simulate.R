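# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth. Two stages: (i) oligo pull-down libraries under a planted
# multiplicative binding model, and (ii) a genome bundle (FASTA, peak BEDs,
# blacklist, bedGraph coverage, gene BED, differential-expression TSV and a
# truth manifest) with planted motif pairs, TnG repeat tracts, adjacency
# structure and occupancy signal. All randomness flows from a single master
# seed via named substreams so stages can be regenerated independently.

.substream_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m <- matrix(sample(names(p), n * len, replace = TRUE, prob = p),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# one long random chromosome string (memory-friendly for Mb scale)
.random_chrom <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# draw a concrete instance of an IUPAC pattern uniformly over its degeneracy
.instantiate_pattern <- function(pattern, n = 1L) {
  sets <- lapply(strsplit(toupper(pattern), "")[[1L]], function(ch) {
    c("A", "C", "G", "T")[bitwAnd(.IUPAC_BITS[[ch]], c(1L, 2L, 4L, 8L)) > 0L]
  })
  vapply(seq_len(n), function(i) {
    paste(vapply(sets, function(s) if (length(s) == 1L) s else sample(s, 1L),
                 character(1L)), collapse = "")
  }, character(1L))
}

#' Construct a planted binding model for oligo simulations
#'
#' A molecule's sampling weight is `base_weight` times the product of the
#' bonuses of every satisfied condition: a pair bonus applies when any
#' shifted window of the molecule matches the pair's pattern; the
#' site-2-only bonus applies when the site-2 half (any shift) matches the
#' reverse-complement forkhead motif regardless of site 1 (the
#' FoxP1-like mode).
#'
#' @param pair_bonuses data.frame with motif_a, motif_b, orientation, bonus
#'   columns (bonus >= 1), or NULL.
#' @param site2_only_bonus multiplicative bonus for an rcFKHM-bearing site 2
#'   alone (>= 1).
#' @param shifts window shifts the binder tolerates (default -2:2).
#' @param base_weight baseline weight (default 1).
#' @param gap spacer used when building bonus patterns (default "TCGA").
#' @return a `binding_model` list.
#' @export
binding_model <- function(pair_bonuses = NULL, site2_only_bonus = 1,
                          shifts = -2:2, base_weight = 1, gap = "TCGA") {
  if (!is.null(pair_bonuses)) {
    stopifnot(all(pair_bonuses$bonus >= 1))
    pair_bonuses$pattern <- pair_pattern(pair_bonuses$motif_a,
                                         pair_bonuses$motif_b,
                                         pair_bonuses$orientation, gap)
  }
  stopifnot(site2_only_bonus >= 1, base_weight > 0)
  structure(list(pair_bonuses = pair_bonuses,
                 site2_only_bonus = site2_only_bonus,
                 shifts = shifts, base_weight = base_weight),
            class = "binding_model")
}

#' FoxP3-like binding model
#'
#' Head-to-head bonus on every ordered pair of the supplied motifs: binding
#' depends on both half-sites in inverted-repeat arrangement. The default
#' motif set is the degenerate forkhead-like (group 1) half-sites, so a
#' realistic fraction of a finite random pool carries a bonus-eligible
#' site.
#'
#' @param motifs half-site motifs (default the group-1 set from
#'   [default_motifs()]).
#' @param hh_bonus multiplicative head-to-head bonus (default 50).
#' @return a `binding_model`.
#' @export
foxp3_model <- function(motifs = NULL, hh_bonus = 50) {
  if (is.null(motifs)) {
    dm <- default_motifs()
    motifs <- dm$motif[dm$group == "G1"]
  }
  grid <- expand.grid(motif_a = motifs, motif_b = motifs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$orientation <- "HH"
  grid$bonus <- hh_bonus
  binding_model(pair_bonuses = grid)
}

#' FoxP1-like binding model
#'
#' Site-2-only bonus: binding requires only the rcFKHM half, with no
#' dependence on site 1 and no orientation preference.
#'
#' @param site2_bonus multiplicative bonus (default 20).
#' @return a `binding_model`.
#' @export
foxp1_model <- function(site2_bonus = 20) {
  binding_model(site2_only_bonus = site2_bonus)
}

# multiplicative weight of each molecule under the model, chunked
.model_weights <- function(site1, site2, design, model, chunk = 200000L) {
  n <- length(site1)
  w <- rep(model$base_weight, n)
  patterns <- character(0)
  bonuses <- numeric(0)
  if (!is.null(model$pair_bonuses)) {
    patterns <- model$pair_bonuses$pattern
    bonuses <- model$pair_bonuses$bonus
  }
  if (model$site2_only_bonus > 1) {
    site2_pat <- paste0(strrep("N", design$site1_len + nchar(design$gap)),
                        "GTAAACA")
    patterns <- c(patterns, site2_pat)
    bonuses <- c(bonuses, model$site2_only_bonus)
  }
  if (length(patterns) == 0L) return(w)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    sw <- .shifted_window_bits(site1[lo:hi],
                               if (is.null(site2)) NULL else site2[lo:hi],
                               design, model$shifts)
    for (p in seq_along(patterns)) {
      hit <- .match_windows(patterns[p], sw$bits)
      per_mol <- rowSums(matrix(hit, nrow = sw$n)) > 0L
      w[lo:hi] <- w[lo:hi] * ifelse(per_mol, bonuses[p], 1)
    }
  }
  w
}

#' Simulate an oligo pull-down sequencing experiment
#'
#' Input reads carry uniformly random variable regions. Pull-down reads are
#' sampled with replacement from a finite candidate pool (`pool_factor` x
#' `n_pd` distinct molecules, mimicking library bottlenecking) with
#' probability proportional to each molecule's binding-model weight. All
#' reads are full-length oligos with uniform Phred-30 qualities.
#'
#' @param design a [library_design()].
#' @param model a [binding_model()].
#' @param n_input,n_pd numbers of input and pull-down reads.
#' @param seed master seed; substreams derive from it.
#' @param pool_factor candidate-pool size as a multiple of `n_pd`.
#' @param out_dir optional directory; when given, writes input.fastq,
#'   pd.fastq and truth.json there.
#' @return list with `input` and `pd` read vectors, `qual` (quality string
#'   template), and `truth` (planted model, seeds, pool size).
#' @export
simulate_oligo_pdseq <- function(design, model, n_input = 1e5, n_pd = 2e5,
                                 seed = 1L, pool_factor = 10L, out_dir = NULL) {
  stopifnot(n_input > 0, n_pd > 0)
  if (inherits(model, "binding_model") && is.null(model$pair_bonuses) &&
      model$site2_only_bonus == 1) {
    warning("binding model has no bonuses: pull-down degenerates to uniform")
  }
  seeds <- .substream_seeds(seed, 3L)
  var_s2 <- is.na(design$site2)

  set.seed(seeds[1L])                     # substream: input library
  in_s1 <- .random_dna(n_input, design$site1_len)
  in_s2 <- if (var_s2) .random_dna(n_input, design$site2_len) else NULL
  input_reads <- assemble_oligo(design, in_s1, in_s2)

  set.seed(seeds[2L])                     # substream: pull-down pool + draw
  n_pool <- as.integer(pool_factor * n_pd)
  pool_s1 <- .random_dna(n_pool, design$site1_len)
  pool_s2 <- if (var_s2) .random_dna(n_pool, design$site2_len) else NULL
  wts <- .model_weights(pool_s1, pool_s2, design, model)
  draw <- sample.int(n_pool, n_pd, replace = TRUE, prob = wts)
  pd_reads <- assemble_oligo(design, pool_s1[draw],
                             if (var_s2) pool_s2[draw] else NULL)

  truth <- list(
    seed = seed, substream_seeds = seeds, n_input = n_input, n_pd = n_pd,
    pool_size = n_pool,
    pair_bonuses = model$pair_bonuses,
    site2_only_bonus = model$site2_only_bonus,
    shifts = model$shifts
  )
  out <- list(input = input_reads, pd = pd_reads,
              qual = strrep("?", design$total_len), truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(out$input, file.path(out_dir, "input.fastq"))
    write_fastq(out$pd, file.path(out_dir, "pd.fastq"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(out))
  }
  out
}

#' Configuration for the synthetic genome bundle
#'
#' Defaults define the standard study conditions: 500 foreground peaks with
#' one head-to-head pair planted at the preferred 4-nt spacing, 2,000
#' background peaks with the same pair planted at gaps uniform over 1-10,
#' TnG repeat tracts in a short/long length mixture with half of the
#' tracts receiving an aligned abutting H-H neighbor, occupancy signal
#' boosts per element class, and a differential-expression table whose
#' significant genes sit preferentially within 2 kb of planted elements.
#'
#' @param n_chrom,chrom_len,gc genome shape and composition.
#' @param n_fg_peaks,fg_peak_width,fg_plant_rate,fg_gap foreground peaks and
#'   the planted-pair rate and spacing.
#' @param n_bg_peaks,bg_peak_width,bg_plant_rate,bg_gaps background peaks;
#'   gaps drawn uniformly from `bg_gaps`.
#' @param pair_motif_a,pair_motif_b,pair_orientation the planted pair.
#' @param n_repeats,repeat_units,short_len,long_len,long_fraction repeat
#'   tract parameters (lengths in bp; tract length drawn uniformly within
#'   the class range).
#' @param adjacency_fraction share of repeat tracts given an aligned,
#'   abutting (0-gap) H-H neighbor.
#' @param signal_baseline,boost_long,boost_short_hh,boost_short base
#'   coverage and per-class boosts over a 200-bp window at the tract
#'   center.
#' @param n_genes,gene_width,frac_sig,p_near gene count/size; significant
#'   genes are placed within 2 kb of a planted element with probability
#'   `p_near`.
#' @param n_blacklist,blacklist_width blacklist decoys, placed clear of
#'   peaks.
#' @param seed master seed.
#' @return a `genome_config` list.
#' @export
genome_config <- function(n_chrom = 4L, chrom_len = 400000L, gc = 0.42,
                          n_fg_peaks = 500L, fg_peak_width = 300L,
                          fg_plant_rate = 0.8, fg_gap = 4L,
                          n_bg_peaks = 2000L, bg_peak_width = 300L,
                          bg_plant_rate = 0.5, bg_gaps = 1:10,
                          pair_motif_a = "TGTTTAC", pair_motif_b = "TGTTTAC",
                          pair_orientation = "HH",
                          n_repeats = 240L, repeat_units = c("TTG", "TTTG", "TTTTG"),
                          short_len = c(12L, 20L), long_len = c(40L, 80L),
                          long_fraction = 0.4,
                          adjacency_fraction = 0.5,
                          signal_baseline = 1, boost_long = 8,
                          boost_short_hh = 8, boost_short = 2,
                          n_genes = 300L, gene_width = 2000L,
                          frac_sig = 0.35, p_near = 0.9,
                          n_blacklist = 4L, blacklist_width = 1000L,
                          seed = 7L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fg_plant_rate >= 0, cfg$fg_plant_rate <= 1,
            cfg$bg_plant_rate >= 0, cfg$bg_plant_rate <= 1,
            cfg$adjacency_fraction >= 0, cfg$adjacency_fraction <= 1)
  class(cfg) <- "genome_config"
  cfg
}

# Lay out non-overlapping slots of the given widths at the assigned
# chromosomes, in random order along each chromosome, with at least min_gap
# between slots. Returns data.frame chrom/start/end (1-based closed) in the
# original element order.
.place_slots <- function(widths, chrom_assign, chrom_len, min_gap = 50L) {
  n <- length(widths)
  out <- data.frame(chrom = chrom_assign, start = integer(n), end = integer(n),
                    stringsAsFactors = FALSE)
  for (ch in unique(chrom_assign)) {
    ix <- which(chrom_assign == ch)
    ix <- ix[sample.int(length(ix))]      # random order along the chromosome
    need <- sum(widths[ix]) + (length(ix) + 1L) * min_gap
    slack <- chrom_len - need
    if (slack < 0L) stop("chromosome too short for requested elements",
                         call. = FALSE)
    # random split of the slack into inter-element gaps
    cuts <- sort(sample.int(slack + 1L, length(ix), replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts)) + min_gap
    pos <- 0L
    for (j in seq_along(ix)) {
      pos <- pos + gaps[j]
      out$start[ix[j]] <- pos + 1L
      out$end[ix[j]] <- pos + widths[ix[j]]
      pos <- pos + widths[ix[j]]
    }
  }
  out
}

# overwrite genome[chrom][start..] with insert (1-based)
.write_seq <- function(genome, chrom, start, insert) {
  substr(genome[[chrom]], start, start + nchar(insert) - 1L) <- insert
  genome
}

#' Simulate a genome bundle with planted ground truth
#'
#' Generates a random genome and plants, at recorded coordinates: motif-pair
#' occurrences in foreground peaks (fixed preferred gap) and background
#' peaks (uniform gaps), TnG repeat tracts with a short/long length mixture,
#' aligned abutting H-H neighbors for a fraction of short tracts, a
#' piecewise-constant occupancy track with per-class boosts, genes, and a
#' differential-expression table tied to element proximity. Identical seeds
#' give byte-identical bundles.
#'
#' @param config a [genome_config()].
#' @param out_dir optional directory; when given, writes genome.fa, fg.bed,
#'   bg.bed, blacklist.bed, signal.bedGraph, genes.bed, de.tsv, truth.json.
#' @return list with `genome` (named character), `fg`, `bg`, `blacklist`,
#'   `genes` (GRanges), `signal` (GRanges track), `de` (data.frame) and
#'   `truth` (list of planted-element tables).
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  cfg <- config
  seeds <- .substream_seeds(cfg$seed, 4L)
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))

  set.seed(seeds[1L])                      # substream: genome + elements
  genome <- stats::setNames(
    vapply(chrom_names, function(x) .random_chrom(cfg$chrom_len, cfg$gc),
           character(1L)),
    chrom_names)

  # --- element layout -------------------------------------------------
  n_rep <- cfg$n_repeats
  rep_long <- seq_len(n_rep) <= round(cfg$long_fraction * n_rep)
  rep_len <- ifelse(rep_long,
                    sample(cfg$long_len[1L]:cfg$long_len[2L], n_rep, TRUE),
                    sample(cfg$short_len[1L]:cfg$short_len[2L], n_rep, TRUE))
  # slot widths: peaks, repeat tracts (plus room for an H-H neighbor),
  # blacklist decoys
  hh_len <- 18L
  widths <- c(rep(cfg$fg_peak_width, cfg$n_fg_peaks),
              rep(cfg$bg_peak_width, cfg$n_bg_peaks),
              rep_len + hh_len + 2L,
              rep(cfg$blacklist_width, cfg$n_blacklist))
  kind <- rep(c("fg", "bg", "rep", "bl"),
              c(cfg$n_fg_peaks, cfg$n_bg_peaks, n_rep, cfg$n_blacklist))
  # foreground peaks avoid the last chromosome, which therefore carries
  # background/OCR peaks far (by chromosome) from any bound region
  fg_chroms <- if (cfg$n_chrom > 1L) chrom_names[-cfg$n_chrom] else chrom_names
  chrom_assign <- character(length(widths))
  chrom_assign[kind == "fg"] <-
    sample(rep_len(fg_chroms, cfg$n_fg_peaks))
  chrom_assign[kind != "fg"] <-
    sample(rep_len(chrom_names, sum(kind != "fg")))
  slots <- .place_slots(widths, chrom_assign, cfg$chrom_len)

  fg <- slots[kind == "fg", ]
  bg <- slots[kind == "bg", ]
  repx <- slots[kind == "rep", ]
  bl <- slots[kind == "bl", ]

  # --- plant pairs in peaks -------------------------------------------
  plant_pair <- function(peaks, gaps, rate) {
    n <- nrow(peaks)
    planted <- stats::runif(n) < rate
    gap <- gaps[sample.int(length(gaps), n, replace = TRUE)]
    rec <- NULL
    for (i in which(planted)) {
      a <- .instantiate_pattern(cfg$pair_motif_a)
      b <- .instantiate_pattern(cfg$pair_motif_b)
      ins <- pair_pattern(a, b, cfg$pair_orientation,
                          gap = .random_dna(1L, gap[i], gc = 0.5))
      off <- sample.int(peaks$end[i] - peaks$start[i] + 1L - nchar(ins), 1L)
      start <- peaks$start[i] + off - 1L
      genome <<- .write_seq(genome, peaks$chrom[i], start, ins)
      rec <- rbind(rec, data.frame(
        chrom = peaks$chrom[i], start = start,
        end = start + nchar(ins) - 1L, gap = gap[i],
        orientation = cfg$pair_orientation, peak = i,
        stringsAsFactors = FALSE))
    }
    if (is.null(rec)) {
      rec <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), gap = integer(0),
                        orientation = character(0), peak = integer(0))
    }
    rec
  }
  fg_plants <- plant_pair(fg, cfg$fg_gap, cfg$fg_plant_rate)
  bg_plants <- plant_pair(bg, cfg$bg_gaps, cfg$bg_plant_rate)

  # --- plant repeat tracts and adjacent H-H sites ---------------------
  rep_strand <- sample(c("+", "-"), n_rep, TRUE)
  has_hh <- stats::runif(n_rep) < cfg$adjacency_fraction
  rep_rec <- NULL
  hh_rec <- NULL
  for (i in seq_len(n_rep)) {
    unit <- sample(cfg$repeat_units, 1L)
    tract <- substr(strrep(unit, ceiling(rep_len[i] / nchar(unit)) + 1L),
                    1L, rep_len[i])
    if (rep_strand[i] == "-") tract <- reverse_complement(tract)
    # repeat occupies the start of its slot; an aligned H-H neighbor abuts:
    # TnG(+): H-H downstream; CAn(-): H-H upstream
    if (has_hh[i] && rep_strand[i] == "-") {
      rep_start <- repx$start[i] + hh_len
    } else {
      rep_start <- repx$start[i]
    }
    genome <- .write_seq(genome, repx$chrom[i], rep_start, tract)
    if (has_hh[i]) {
      a <- .instantiate_pattern(cfg$pair_motif_a)
      b <- .instantiate_pattern(cfg$pair_motif_b)
      hh_ins <- pair_pattern(a, b, "HH", gap = .random_dna(1L, 4L))
      hh_start <- if (rep_strand[i] == "-") repx$start[i] else
        rep_start + rep_len[i]
      genome <- .write_seq(genome, repx$chrom[i], hh_start, hh_ins)
      hh_rec <- rbind(hh_rec, data.frame(
        chrom = repx$chrom[i], start = hh_start,
        end = hh_start + nchar(hh_ins) - 1L, repeat_id = i,
        stringsAsFactors = FALSE))
    }
    rep_rec <- rbind(rep_rec, data.frame(
      chrom = repx$chrom[i], start = rep_start,
      end = rep_start + rep_len[i] - 1L, strand = rep_strand[i],
      unit = unit, length = rep_len[i],
      class = if (rep_long[i]) "long" else "short",
      has_hh = has_hh[i], stringsAsFactors = FALSE))
  }
  if (is.null(hh_rec)) {
    hh_rec <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), repeat_id = integer(0))
  }
  if (is.null(rep_rec)) {
    rep_rec <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          unit = character(0), length = integer(0),
                          class = character(0), has_hh = logical(0))
  }

  # --- occupancy signal ------------------------------------------------
  set.seed(seeds[2L])                      # substream: signal
  boost <- ifelse(rep_rec$class == "long", cfg$boost_long,
                  ifelse(rep_rec$has_hh, cfg$boost_short_hh, cfg$boost_short))
  center <- (rep_rec$start + rep_rec$end) %/% 2L
  boost_gr <- GenomicRanges::GRanges(
    rep_rec$chrom,
    IRanges::IRanges(pmax(center - 100L, 1L),
                     pmin(center + 99L, cfg$chrom_len)))
  S4Vectors::mcols(boost_gr)$score <- boost
  # fg peaks also get occupancy so the signal-free-background rule bites
  fg_gr0 <- GenomicRanges::GRanges(fg$chrom, IRanges::IRanges(fg$start, fg$end))
  S4Vectors::mcols(fg_gr0)$score <- cfg$boost_short
  base_gr <- GenomicRanges::GRanges(chrom_names,
                                    IRanges::IRanges(1L, cfg$chrom_len))
  S4Vectors::mcols(base_gr)$score <- cfg$signal_baseline
  all_sig <- c(base_gr, boost_gr, fg_gr0)
  cov <- GenomicRanges::coverage(all_sig, weight = "score")
  sig_df <- do.call(rbind, lapply(chrom_names, function(ch) {
    r <- cov[[ch]]
    rl <- S4Vectors::runLength(r)
    data.frame(chrom = ch,
               start = cumsum(c(1L, rl))[seq_along(rl)],
               width = rl, score = S4Vectors::runValue(r))
  }))
  sig_df <- sig_df[sig_df$score != 0, , drop = FALSE]
  signal <- GenomicRanges::GRanges(
    sig_df$chrom,
    IRanges::IRanges(start = sig_df$start, width = sig_df$width))
  S4Vectors::mcols(signal)$score <- sig_df$score

  # --- genes and differential expression -------------------------------
  set.seed(seeds[3L])                      # substream: genes + DE
  element_anchor <- rbind(
    fg_plants[c("chrom", "start", "end")],
    data.frame(chrom = rep_rec$chrom, start = rep_rec$start,
               end = rep_rec$end))
  n_sig <- round(cfg$frac_sig * cfg$n_genes)
  gene_chrom <- character(cfg$n_genes)
  gene_start <- integer(cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    near <- g <= n_sig && stats::runif(1) < cfg$p_near &&
      nrow(element_anchor) > 0L
    if (near) {
      a <- element_anchor[sample.int(nrow(element_anchor), 1L), ]
      side <- sample(c(-1L, 1L), 1L)
      offs <- sample.int(1500L, 1L)
      gene_chrom[g] <- a$chrom
      gene_start[g] <- if (side > 0L) a$end + offs else
        pmax(a$start - offs - cfg$gene_width, 1L)
    } else {
      gene_chrom[g] <- sample(chrom_names, 1L)
      gene_start[g] <- sample.int(cfg$chrom_len - cfg$gene_width, 1L)
    }
  }
  gene_start <- pmax(pmin(gene_start, cfg$chrom_len - cfg$gene_width + 1L), 1L)
  gene_end <- gene_start + cfg$gene_width - 1L
  gene_strand <- sample(c("+", "-"), cfg$n_genes, TRUE)
  gene_name <- sprintf("gene%04d", seq_len(cfg$n_genes))
  is_sig <- seq_len(cfg$n_genes) <= n_sig
  padj <- ifelse(is_sig,
                 10^stats::runif(cfg$n_genes, -8, log10(0.049)),
                 stats::runif(cfg$n_genes, 0.06, 1))
  log2fc <- ifelse(is_sig,
                   abs(stats::rnorm(cfg$n_genes, 1.2, 0.5)) *
                     sample(c(1, 1, 1, -1), cfg$n_genes, TRUE),
                   stats::rnorm(cfg$n_genes, 0, 0.3))
  de <- data.frame(gene = gene_name, log2fc = round(log2fc, 4),
                   padj = signif(padj, 4), stringsAsFactors = FALSE)

  to_gr <- function(df, strand = NULL) {
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    if (!is.null(strand)) BiocGenerics::strand(gr) <- strand
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  fg_gr <- to_gr(fg)
  bg_gr <- to_gr(bg)
  bl_gr <- to_gr(bl)
  genes_gr <- GenomicRanges::GRanges(gene_chrom,
                                     IRanges::IRanges(gene_start, gene_end),
                                     strand = gene_strand)
  S4Vectors::mcols(genes_gr)$name <- gene_name
  ord_g <- GenomicRanges::order(genes_gr)
  genes_gr <- genes_gr[ord_g]

  truth <- list(seed = cfg$seed, substream_seeds = seeds,
                fg_plants = fg_plants, bg_plants = bg_plants,
                repeats = rep_rec, hh_neighbors = hh_rec,
                pair = list(motif_a = cfg$pair_motif_a,
                            motif_b = cfg$pair_motif_b,
                            orientation = cfg$pair_orientation,
                            fg_gap = cfg$fg_gap),
                significant_genes = gene_name[is_sig])
  bundle <- list(genome = genome, fg = fg_gr, bg = bg_gr, blacklist = bl_gr,
                 signal = signal, genes = genes_gr, de = de, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_intervals(fg_gr, file.path(out_dir, "fg.bed"))
    write_intervals(bg_gr, file.path(out_dir, "bg.bed"))
    write_intervals(bl_gr, file.path(out_dir, "blacklist.bed"))
    write_signal(signal, file.path(out_dir, "signal.bedGraph"))
    write_intervals(genes_gr, file.path(out_dir, "genes.bed"), six = TRUE)
    utils::write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(bundle))
  }
  bundle
}
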