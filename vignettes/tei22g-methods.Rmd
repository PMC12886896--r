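---
title: "Methods: from H3K4me3 ChIP enrichment to 22G-RNA deregulation"
author: "tei22g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from H3K4me3 ChIP enrichment to 22G-RNA deregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tei22g` implements the computational core of a common experimental design
in *C. elegans* chromatin/small-RNA biology: a mutant in a germline
chromatin factor is compared with wild type by (i) H3K4me3 ChIP-seq, (ii)
22G small-RNA sequencing, and optionally (iii) mRNA-seq, and the question
is which genes gain the chromatin mark at their transcription start site
(TSS) and whether those same genes lose or gain secondary 22G-RNAs.  The
package operationalizes that question as a pipeline of small, individually
testable stages, plus a synthetic-data generator that plants known effects
so every stage can be validated by parameter recovery rather than by
eyeballing browser tracks.

All coordinates are 0-based half-open internally; GFF3 (1-based closed) is
converted on read and write.  A single convention end to end removes the
classic off-by-one drift between BED/bedGraph and GFF3.  The gene TSS is
defined as the 5' end of the annotated gene on its strand; transcript-level
TSS selection is deliberately out of scope because gene-level scoring is
what the downstream classifier consumes.

# ChIP enrichment tracks

Aligned ChIP reads (BED of 5' positions with strand) are extended to
`fragment_length` (default 200 bp, matching the usual MACS-style extension)
and counted into fixed 10 bp bins: a fragment increments every bin it
overlaps.  Counting fragments per bin rather than averaging per-base depth
is a deliberate choice: it is monotone, cheap, and the downstream
±500 bp window score averages over ~100 bins anyway, so the two
conventions differ only by a bounded smoothing factor.

Per library, bins are CPM-normalized (`1e6 / library_size`); replicates are
averaged bin-wise *after* normalization; and enrichment is
`log2((IP + c) / (input + c))` with a pseudocount `c = 1` CPM.  The
pseudocount bounds the ratio and pins bins with no coverage in either
library at exactly 0 rather than NaN.  The mutant-vs-wild-type comparison
track is the difference of the two enrichment tracks (a log2 fold-change
of input-normalized enrichments).  The order — normalize each replicate,
average, then ratio — mirrors standard practice (per-sample CPM bigwigs
combined by a mean, then compared).

# TSS scoring and the cumulative-80% classifier

Each gene's H3K4me3 level is the arithmetic mean of enrichment-track bins
intersecting TSS ± 500 bp (windows truncated at chromosome edges are
scored on what remains rather than dropped, so edge genes stay in the
table).  Scores are computed on the log2 enrichment scale — the scale on
which the tracks are defined — not on linear ratios.

Genes are then classified as *H3K4me3-enriched* by a cumulative-
contribution rule: genes with positive `delta = score_mut − score_wt` are
ranked by delta (descending; ties broken by gene id for determinism), and
the selection is the shortest prefix whose cumulative delta reaches 80% of
the total *positive* delta.  Using the positive total (the "total
increased enrichment") rather than the signed total is the only reading
under which the rule is monotone and well defined when some deltas are
negative.  A fixed `1e-9` relative tolerance on the cumulative comparison
keeps exact ties from being broken by binary floating point.  An optional
`min_wt_score` filter restricts the candidate set to genes already marked
in the wild type; it is off by default because the un-filtered rule is the
more conservative (larger) denominator.

One property of this rule is worth stating explicitly: when all planted
effects have equal size and noise is small, the selection converges to
exactly 80% of the affected genes — the rule by construction trades recall
for concentration of signal.  Recovery tests therefore use the Jaccard
index against planted truth with a 0.8 threshold, which the rule meets
from above as noise shrinks.

The across-genes wild-type vs mutant comparison uses a two-sided unpaired
Welch *t*-test on the two score columns (unequal variances assumed
throughout; legends in this literature alternate between plain and
Welch-corrected *t*-tests, and Welch is the safe superset).  The statistic
is wild-type minus mutant, so strong mutant gains give large negative *t*.

# Sliding-window differential binding

Independently of the TSS classifier, the genome is tiled with 200 bp
windows at 10 bp shift and fragments are counted per window exactly as for
bins (no deduplication across overlapping windows — each window is its own
unit of occupancy).  The window count matrix then goes through the same
negative-binomial machinery as every other count table in the package.
Neighbouring windows share fragments and are strongly correlated;
window-level BH q-values are reported for ranking, but calibration claims
are made only about raw p-values under exchangeable groups.

# The moderated NB Wald test

All three count assays (windows, 22G genes, mRNA genes) share one testing
stack:

1. **Size factors** by median-of-ratios: per feature the geometric mean
   across samples, per sample the median of count/geomean over features
   with all-positive counts.  Note the factors are defined relative to the
   geometric-mean reference; rescaling one library rescales *all* factors
   by a common constant, and only factor ratios are invariant.
2. **Dispersion** per feature by method of moments on normalized counts,
   `alpha = (s² − m) / m²`, estimated *within* condition groups
   (df-weighted), so genuine group differences do not masquerade as
   biological variance.  With the few replicates typical of these designs
   (2–4 per genotype) the per-feature estimate is extremely noisy, so it
   is shrunk toward the across-feature median with a prior weight of
   `prior_df = 12` — the empirical-Bayes moderation idea that underlies
   limma/DESeq2-class methods, in its simplest form.  `prior_df = 0`
   recovers the raw estimator.  We chose 12 (about twice the residual df
   of a 4-vs-4 design) as a fixed, conservative prior rather than
   estimating it from the data; simulations below show it calibrates well
   across the regimes the pipeline meets.
3. **Wald test**: group means of normalized counts with a 0.5 pseudocount,
   `log2fc = log2(m2/m1)`, delta-method standard error from the NB
   variance `mu + alpha mu²`, and a two-sided p-value from a *t* reference
   with `prior_df + residual_df` degrees of freedom.  The *t* reference
   (rather than a plain normal) accounts for the residual uncertainty in
   the moderated dispersion; with the normal reference the small-replicate
   null is measurably anti-conservative (~7% at nominal 5% in our
   simulations), while the moderated *t* sits at ~5%.
4. **BH step-up** FDR adjustment, and threshold calls: up/down means
   `q ≤ 0.05` and linear fold change > 2 for 22G-RNAs, `q ≤ 0.01` with any
   fold change for mRNA — the conventional thresholds for these assays.
   Fold-change thresholds apply to the raw (unshrunken) log2fc.

This is deliberately *not* a DESeq2 re-implementation: no GLM, no trended
dispersion, no LFC shrinkage, no independent filtering.  The claim the
package makes — and tests — is calibration and recovery at the stated
thresholds on data of this structure, not numerical equality with any
external tool.  Simulated at the design point used throughout (2000
features, 4 vs 4, dispersion 0.1, base mean 100): null fraction of
p < 0.05 ≈ 0.05, realized FDR at BH 5% with 10% planted 4-fold effects
≈ 0.03, sensitivity ≈ 1.0.  These are the quantities the test suite and
the acceptance script recompute.

# 22G-RNA extraction, mapping and counting

The 22G class is purely operational: reads of 21–23 nt whose first base is
`G` (uppercase; `N` fails).  The filter reports per-reason rejection
counts and is idempotent.

Mapping is exact and end-to-end: each read is matched mismatch-free
against the forward strand and as reverse complement of every chromosome
(Biostrings `PDict`/`matchPDict`, one dictionary per read length).  Reads
hitting 1–100 loci get exactly one alignment, drawn uniformly with an RNG
seeded from `(seed, read_id)` — so the multimapper lottery is reproducible
read by read and independent of processing order, emulating a
random-multimapper aligner configuration with a single reported hit.
Reads with more than 100 loci are discarded.  An exact-match mapper is the
right tool here because the class definition already constrains reads to
21–23 nt and the reference is a toy genome; mismatch-tolerant alignment of
real libraries is explicitly out of scope.

Counting assigns an alignment to a gene when it overlaps any exon by ≥1 bp,
strand-agnostic (the cited counting convention for this assay does not set
a strandedness flag, even though real 22Gs are antisense to their
targets); alignments touching exons of more than one gene are dropped as
ambiguous rather than fractionally assigned.

# Integration

The enriched gene set is intersected with the 22G and mRNA call sets into
a crosstab (how many enriched genes have 22G changes, up/down, mRNA
changes, up/down) and pairwise overlaps.  The hypergeometric upper-tail
p-value attached to overlaps is an explicit extension — proportional-Venn
counting tools report no significance — and the universe is all annotated
protein-coding genes in the run.  External reference lists (e.g. WAGO or
Mutator pathway targets, germline-expressed genes) are consumed as plain
text id lists; none are bundled.

# The synthetic scenario

`make_demo()` writes a complete, seeded scenario: a 2 × 0.5 Mb uniform
random genome; 300 evenly spaced single-exon genes of 500 bp with random
strands; ChIP libraries (2 replicates × {IP, input} × {wild type,
mutant}); 22G FASTQ libraries (4 replicates per genotype); and an mRNA
count matrix.  Planted truth: 30 genes with a 3× mutant gain in IP peak
height at the TSS; 20 genes each with 22G log2FC of +2/−2 in the mutant
(10 of each inside the enriched set, mirroring the real observation that
chromatin-gain genes are enriched for 22G deregulation); 6 mRNA-up and 2
mRNA-down genes.  Everything is recorded in a truth table.

Generator shape choices, made once:

* **IP read placement** is Gaussian around the TSS (sd `peak_width` =
  150 bp) via the fragment *center*, so coverage peaks at the TSS for both
  read strands.  Published metagenes for this mark are TSS-peaked but give
  no shape model; a Gaussian is the simplest unimodal stand-in.
* **Expected library composition**: `background_rate × genome_length`
  (background) and per-gene peak heights act as relative weights rescaled
  so each library's expected size equals `depth`.  Fixing the expected
  depth reproduces the composition effect of CPM normalization — a
  genome-wide gain in the mutant slightly depresses all other loci —
  which real fixed-depth sequencing shows and which a naive additive
  simulation would hide.  Component counts are Poisson; reads falling
  off-chromosome are clipped, keeping the recorded library size exact.
* **Depth**: 1e6 reads per ChIP library and 5e4 per 22G library.  On a
  1 Mb genome this gives per-bin input counts of a few hundred — the
  regime where the ±500 bp window score has small enough noise (sd ≈ 0.06
  on the log2 scale) that the cumulative-80% selection is stable run to
  run.  These sizes keep the full demo within a few minutes on one CPU
  while staying in a realistic coverage-per-bp regime.
* **22G reads** are drawn antisense to exons with per-gene abundances
  log-normal (sdlog 0.6) and the planted multipliers applied in the
  mutant.  Template positions are chosen so the antisense read starts
  with G naturally where the exon sequence allows; otherwise the 5' base
  is overwritten and the read id flagged.  Invalid reads (the
  `1 − frac_valid` remainder) violate the class by length (18–20 or
  24–26 nt) or by a forced non-G start, so the class filter's decision is
  exact by construction and the generator's per-gene valid counts are
  ground truth, not an approximation.

What the generator does *not* emulate: sequencing errors, adapters,
quality scores, PCR duplicates, mappability structure, isoforms,
peak-shape heterogeneity, and real linkage between chromatin state and
small-RNA biogenesis.  Passing recovery tests therefore demonstrates that
the pipeline's inference is correct *given its own model of the data*; it
does not certify performance on real libraries, where upstream artefacts
dominate.

# Numerical and reproducibility choices

* Every stochastic stage derives its seed from the global seed plus stage
  and sample tags through a 31-bit rolling hash, so stages can be rerun
  independently and reruns are byte-identical (`manifest.tsv` hashes are
  the regression surface).
* Text outputs serialize floats at 6 significant digits — a presentation
  choice for hash stability; internal computation is full precision.
* Degenerate inputs have defined behaviour: empty read sets give zero
  tracks; no positive deltas give an empty selection; a constant feature
  floors its dispersion at 1e-8; both score columns constant and equal
  give t = 0, p = 1, and constant-but-different columns report the
  smallest representable p with a degeneracy flag.

# Known limitations

* The NB test supports exactly two groups with ≥2 replicates; no covariates.
* Window q-values inherit neighbour correlation; treat them as ranks.
* The exact-match mapper is for toy genomes; it has no mismatch tolerance
  and no splicing.
* The cumulative-80% rule is scale-free but threshold-sensitive near ties;
  its output should be read jointly with the per-gene score table.
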