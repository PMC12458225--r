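---
title: "Methods: paired-motif orientation and repeat-adjacency analysis"
author: "pairdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-motif orientation and repeat-adjacency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairdimer)
```

## The problem

FoxP3, the lineage-defining transcription factor of regulatory T cells,
does not bind isolated forkhead motifs (FKHM, consensus `TGTTTAC`) well.
It engages DNA in two composite modes: as a head-to-head (H-H) dimer on
inverted-repeat arrangements of forkhead-like half-sites separated by a
short gap (optimally 4 nt), and as a multimer on TnG-repeat
microsatellites (tandem TTG/TTTG/TTTTG tracts, read as CAn on the
opposite strand). `pairdimer` implements the computational side of
characterising these modes: enrichment analysis of degenerate-oligo
pull-down sequencing (PD-seq), orientation-resolved motif-pair scanning,
genomic enrichment statistics against background peak sets, tandem-repeat
detection with exact PWM p-values, and the geometry of dimer sites
adjacent to repeats. A synthetic-data generator produces every input with
planted ground truth, so the full pipeline is testable without external
downloads.

## Oligo library designs and read parsing

A library oligo is `NBS1 (27 nt) + site1 (7 nt) + TCGA + site2 + NBS2
(35 nt)`. In the *random-rcFKHM* design site 2 is fixed to the
reverse-complement forkhead motif `GTAAACA`, so an FKHM-like site 1
recreates an inverted repeat with a 4-nt gap. In the *random-random*
design both sites are variable. The exact flank sequences are
configurable; the defaults shipped here are arbitrary GC-balanced
non-binding sequences, chosen once and fixed. Flank identity only enters
the analysis through structure anchoring and the baseline probabilities,
both of which are computed from whatever design object is supplied.

`parse_library_reads()` locates the template by exact matching of all
fixed regions (zero mismatches — the extraction is an exact structure
match by design) and rejects, with a reason code rather than an error,
reads with a structure mismatch, a non-ACGT base in a variable region,
or (when qualities are supplied) a variable-region Phred minimum below
20. The quality rule deliberately ignores flank positions.

## Per-sequence enrichment and 2N-motif discovery

Counts are tabulated densely over all 4^7 = 16,384 site-1 sequences and
normalized to reads per million (RPM). Fold enrichment is
`(rpm_pd + eps) / (rpm_input + eps)` with `eps = 0.5` RPM: the additive
smoothing constant is our choice for zero-count handling and is
configurable.

2N motifs are 7-mers with exactly two positions replaced by `N` — each
concrete 7-mer generates C(7,2) = 21 of them, and deduplication over all
sequences leaves 21 x 4^5 = 21,504 distinct patterns. Each pattern's
aggregate count is the sum over its 16 concrete instantiations, a
conservation identity the tests assert exhaustively. The "coverage rank"
statistic answers how many top-ranked 2N motifs are needed before every
sequence in the top-q fraction (by per-sequence enrichment, counting
sequences, not enrichment mass) is an instantiation of at least one
selected motif; motifs are taken greedily in descending enrichment
order. Both the count-based reading of "top 10%" and the greedy
selection rule are design decisions made here, since only the outcome of
such a computation, not its rule, is normally reported.

## Orientation analysis and baseline normalization

From 10 half-site motifs the dictionary holds all 100 ordered pairs in
four orientations — on the positive strand, with `rc` the reverse
complement and a fixed spacer g: `HH = a + g + rc(b)`, `HT = a + g + b`,
`TH = rc(a) + g + rc(b)`, `TT = rc(a) + g + b` — 400 patterns of 18 nt.
These satisfy `rc(HT(a,b)) = TH(b,a)` and `rc(HH(a,b)) = HH(b,a)`,
which is why strand choice only permutes, never changes, the results;
the tests assert these identities over the whole dictionary. The default
motif set ships the textually attested forkhead-like (G1) and GCAT-core
(G2) patterns plus representative placeholders and is a configuration
input: substitute your own discovery output for real analyses.

Because the binder's register is not fixed in the random-random design,
each read contributes five windows (shifts 0, ±1, ±2 around the spacer),
and a read supports a pair if *any* window matches — once per read, never
once per shift. Fixed gap and flank bases bias these counts, so raw
counts are divided by the baseline probability that a uniformly random
variable region matches at at least one shift. Per shift this probability
is a product over window positions (1 for a compatible fixed base, 0 for
an incompatible one, |allowed|/4 for a variable position); shifts are
combined with the independence approximation `1 - prod(1 - p_s)`. The
exact union probability over 4^14 joint states is not computable at desk
scale and the combination rule is not otherwise pinned down; a
Monte-Carlo oracle in the test suite confirms the approximation is
within sampling error (3 SE at 1.5-2 x 10^5 draws) for representative
patterns. Pairs whose pattern conflicts with the fixed bases at every
shift have baseline 0 and are flagged unobservable rather than divided.
Display scaling maps a matrix (or a pair of matrices jointly, e.g. two
proteins on one color scale) to [0, 100] by its maximum.

## Genomic paired-motif enrichment

Peak sequences are scanned on the positive strand only (the symmetry
identities above make the negative strand redundant). Within one
pattern, matches are non-overlapping: the scan resumes past each match,
preventing inflated counts on sliding repeats; different patterns may
overlap freely. In genomic scans the spacer is matched as `N^g`: the
TCGA spacer of the oligo libraries is a library construction artifact,
not a binding requirement.

Counts are normalized per Mb of total peak length in foreground
(ChIP-like) and background (open-chromatin) sets. Significance per pair
uses a one-sided exact binomial test: the background per-bp rate
parameterizes `X ~ Binomial(fg_total_bp, p̂)` and the p-value is
`P[X >= fg_count]`. Treating base pairs as trials (rather than possible
match positions) is one of two defensible parameterizations; it is
isolated in a single function. A zero background count floors `p̂` at
`1/bg_total_bp` and adds 0.5 to both counts for the fold change only.
Following the source methodology, the default significance call is raw
`p < 0.05`; a Benjamini-Hochberg option exists but is off by default.
Peaks overlapping a blacklist interval by >= 1 bp are removed whole.
Overlapping peaks within a set are not merged before length computation
(the reader keeps records as-is); this matters only for pathological
inputs and is documented rather than hidden.

The gap-size profile rebuilds each pair with spacers over a gap range
(default 1-10 nt) and reports per-Mb frequencies and the
foreground/background ratio per gap; the argmax gap per pair is the
recovered spacing preference.

## Repeat detection with exact PWM p-values

The repeat stage reimplements a FIMO-style scan. Log2-odds scores
against the background model are discretized (default 1,000 bins across
the largest per-position range) and the exact distribution of the total
discretized score under the background is obtained by convolving the
per-position distributions (positional dynamic programming). Scanning
uses the same discretization, so the p-value of every reported match is
exact for the discretized score; tests verify equality with exhaustive
enumeration up to width 6 and monotonicity over the whole score range.
Matches below p = 8e-5 are reported; the minus strand is scanned via the
reverse-complemented matrix and reported in plus coordinates with strand
`-` (TnG face `+`, CAn face `-`).

The shipped default TnG matrix is built by equal-weight stacking of
TTG/TTTG/TTTTG register shifts (width 12, pseudocount 0.01, uniform
background). It is a documented synthetic stand-in with the right width
and composition bias — the original query matrix from earlier work is
not reproduced here — and it is a configuration input. No correctness
property depends on it: all oracle tests use small synthetic matrices.

Matches containing degenerate runs — (TG)6, (AC)6, (TA)6, (TC)6, (AG)6,
(CG)6 as 12-nt dinucleotide runs, or 12-nt homopolymers — are removed,
reflecting the binder's TnG (n = 2-5) specificity; note this filter is
also what guarantees that poly-A/poly-T sequence, which any T-rich
matrix scores on one strand, contributes no repeat calls. Overlapping
matches (>= 1 bp) merge transitively into regions; region strand comes
from the best-scoring constituent, ties toward `+`.

## Adjacency geometry

H-H occurrences merged into unique sites are related to repeat regions
by border-to-border distance: 0 when the intervals overlap *or abut*
(the two cases are one adjacency class here — "0 nt gap" — since a
border gap of zero is indistinguishable from touching), positive when
the repeat is downstream, negative when upstream. Orientation is
*aligned* when a plus-strand repeat lies upstream or a minus-strand
repeat lies downstream — the configurations in which the proximal
half-site of the dimer reads seamlessly into the repeat — and
*divergent* otherwise. For distance-0 records the side is taken from
the repeat midpoint relative to the site midpoint; equal-distance ties
prefer the downstream repeat. Both tie-break rules are our choices where
no rule is otherwise specified; reflecting the chromosome flips signs
and preserves alignment calls, a property the tests assert.

Occupancy is summarized as AUC: the sum of per-base coverage of a
piecewise-constant track over a 200-bp window (±100 bp) around a
feature center, with no interpolation. Signal-free background regions
are open-chromatin peaks at least 10 kb from any foreground peak and
with window AUC below the minimum observed over foreground peaks. The
stratified comparison groups repeats as short (<= 20 bp) or long
(>= 40 bp) and as adjacent (distance 0, aligned) or far (>= 1 kb from
any H-H site); repeats between 20 and 40 bp, or near-but-not-abutting a
site, belong to no group. Group summaries use `log2(AUC + 1)` — the +1
keeps zero-coverage windows finite and is monotone, so orderings are
unaffected.

## Gene proximity

Feature density around a gene is feature base pairs (clipped to the
window) per Mb of the expanded interval — a bp-based density, adopted
because "density" with bp/Mb units is most naturally mass-based; windows
expand from the gene body borders, not the TSS. The 2-kb analysis
reports, per adjusted-p bin and optionally per fold-change direction,
the fraction of genes whose expanded body overlaps at least one feature;
empty bins report NA, not 0. Differential-expression fitting is out of
scope: the table of gene, log2 fold change and adjusted p is an input.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested.

**Oligo stage.** Input reads carry uniform variable regions. Pull-down
reads are drawn with replacement from a finite pool of distinct
molecules (default 10 x the read count; configurable) with probability
proportional to a multiplicative binding weight — the finite pool gives
duplicate-read statistics a real library bottleneck would produce, which
matters when judging enrichment noise. The FoxP3-like model attaches a
head-to-head bonus (default 50) to every ordered pair of the degenerate
forkhead-like half-sites; attaching it to fully concrete 14-bp patterns
would plant essentially nothing in a finite pool (expected << 1
eligible molecule), so degeneracy here is what makes the planted signal
realistic rather than a convenience. The FoxP1-like model rewards an
rcFKHM-bearing site 2 alone (default 20), with no site-1 dependence.
Because a site-2-only binder still satisfies the rc(b) half of some H-H
patterns, its orientation profile is near-uniform but not exactly so;
the tests therefore assert consistency-with-uniform and the
FoxP3-vs-FoxP1 contrast rather than a hard flatness band.

**Genome stage.** Background sequence is i.i.d. with configurable GC
(default 0.42). Elements — foreground peaks (500 x 300 bp), background
peaks (2,000 x 300 bp), repeat tracts (240, short 12-20 bp and long
40-80 bp, 40% long), blacklist decoys — are laid out without overlaps;
foreground peaks avoid the last chromosome so that a genuinely
far-from-bound background exists for the signal-free-OCR definition.
Foreground peaks plant one H-H pair at the preferred 4-nt gap (rate
0.8); background peaks plant the same pair with gaps uniform on 1-10
(rate 0.5). Half the repeat tracts receive an aligned, abutting H-H
neighbor. Coverage is baseline 1 plus boosts over ±100 bp of each tract
center: +8 for long tracts, +8 for short tracts with an H-H neighbor,
+2 for short tracts alone — the ordering whose recovery the adjacency
stage tests. Significant genes (padj < 0.05, mostly positive log2 fold
change, i.e. up on factor loss) are placed within 2 kb of planted
elements with probability 0.9. All randomness flows from one master
seed through named substreams; identical seeds give byte-identical
bundles.

**What the generator does not emulate.** Real genomes are not i.i.d.:
repeat families, CpG structure and chromatin-driven peak width
variation are absent, and planted elements are spaced apart, so
overlapping-motif ambiguity is rarer than in vivo. Sequencing error is
off by default (uniform Phred 30). Passing tests therefore demonstrate
that the statistics recover known structure under clean conditions and
that every formula is implemented exactly; they do not certify
performance on real ChIP/ATAC data.

## Problem sizes and numerical choices

The test and analysis runs use desk-scale sizes chosen as this package's
standard conditions: oligo libraries of 1-4 x 10^5 reads (pool factor 4
for the deeper runs), a 4 x 400 kb genome with 500/2,000 peaks for
enrichment and gap recovery, and sparser multi-Mb variants where gene
proximity needs room. At these depths each 2N pattern pools roughly 100
reads, so per-pattern log-enrichment noise is ~0.15; flatness tests are
written against that analytic floor rather than against constants that
only hold at production sequencing depth. Binomial p-values come from
`pbinom` (exact); PWM p-values are exact for the discretized score; the
only deliberate approximation in the package is the shift-union baseline
described above.

## Known limitations

Structure anchoring tolerates zero mismatches in fixed regions; reads
with flank sequencing errors are dropped rather than rescued. The
binomial test treats base pairs as trials. The default TnG matrix and
the default 10-motif dictionary are documented stand-ins, configurable
by the user. Heatmap rendering, peak calling, read alignment and
differential-expression fitting are out of scope.
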