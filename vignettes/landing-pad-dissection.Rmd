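---
title: "Models and methods: landing-pad sort-seq dissection of enhancer activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: landing-pad sort-seq dissection of enhancer activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpdissect)
```

# The experiment this package models

A landing-pad screen replaces a genomic enhancer with one payload from a
barcoded library of mutant elements, then reads target-gene expression per
cell by ratiometric RNA FISH: the target mRNA in one fluorescence channel
(AF647) over a housekeeping control (AF488). Cells are sorted into K
expression bins on that ratio, the 8-nt element barcodes are PCR-amplified
and sequenced per bin, and every downstream statement about a mutant rests
on how its barcodes distribute across bins. `lpdissect` implements that
chain — library design, barcode quantification, activity scoring, and the
effect models on top — together with a synthetic generator that produces
every input with known ground truth.

# The synthetic sort-seq generator

`sim_config()` + `simulate_population()` model one sorted population:

* Each element has a true expression on the log10 scale relative to a
  wild-type reference at 0. A cell carrying a barcode of element *e* has
  fluorescence ratio `10^x_e * epsilon`, with `epsilon` lognormal with mean
  1 and coefficient of variation `noise_cv`. All biological and technical
  noise is placed on the ratio; the control channel is held constant at
  `control_channel_mean`, because every downstream quantity consumes only
  the ratio.
* Bins are the K quantile intervals of the pooled ratio distribution
  (octiles for the default K = 8), emulating a sorter that gates a fixed
  fraction of cells per bin; explicit boundaries can be supplied instead.
  The sorted fraction per bin of a real two-round four-way sort is not
  publicly specified, so equal-quantile gating is the assumption, and it is
  also what makes the sorted-cell fractions `s_k = 1/K` exact.
* `emit_fastq()` sequences each bin to the same expected total depth
  (`depth * n_barcodes / K` reads), allocating reads to barcodes by a
  multinomial draw proportional to the bin's cell counts. This mirrors
  library preparation, where every bin is amplified and sequenced to a
  similar depth regardless of how many cells it received — precisely the
  distortion the scoring formula's `c_bk / N_k` term undoes. The unsorted
  background sample is the pooled pre-sort population, not a separate
  simulation. Reads are a 22-nt constant prefix, the barcode at read
  positions 23–30 (1-based), and a constant suffix, with Phred+33
  qualities.
* Each operation consumes a single RNG stream derived from an explicit
  seed and restores the caller's RNG state, so runs are reproducible and
  composable.

What the generator does **not** emulate: background fluorescence in either
channel, autofluorescence spill-over, sorter impurity, PCR jackpotting and
duplicates (no UMIs), cell-cycle heterogeneity, and barcode synthesis
errors. The most consequential omission is background fluorescence — see
*Limitations* below.

Default study conditions (used by the acceptance script and the deeper
tests): 80 elements spanning four orders of magnitude of expression
(uniform on [−4, 0] log10), 4 barcodes per element, 8 bins, 1,000 cells and
an expected 200 reads per barcode, ratio CV 30%. These are the scales of
the screen the package models; the unit tests use smaller populations
(hundreds of cells, 2–4 bins) chosen so the whole suite runs in well under
a minute.

# Activity scoring

`bin_fractions()` computes `f_bk = (c_bk / N_k) * s_k`, renormalized per
barcode; `activity_score()` returns `S_b = sum_k f_bk R_k` with
`R_k = mean AF647_k / mean AF488_k`. Choices worth recording:

* The exact weighting used by published screens of this type is not always
  reported; the depth-normalized, sorted-fraction-weighted form above is
  the natural estimator of a barcode's cell distribution across bins, and
  it is isolated in one function so an alternative weighting can be swapped
  in. When `s_k` is unavailable, `1/K` is used — exact under quantile
  gating.
* No pseudocounts by default. Zero-count bins contribute zero; a barcode
  with zero reads everywhere is dropped with a warning rather than scored.
  An optional +0.5 pseudocount is deliberately *not* applied silently
  because it pulls saturated barcodes off the extreme bin ratios.
* Element summaries use the median of barcode scores pooled over
  replicates (each barcode contributes one score per replicate), matching
  how such screens are plotted and making the summary robust to a single
  misbehaving barcode. Replicate scores are pooled rather than averaged
  per barcode first; with balanced replicates the median is the same, and
  pooling keeps elements scoreable when a barcode drops out of one
  replicate.
* Scores are bounded by the extreme bin ratios, so expression below the
  lowest bin's center saturates at `min R_k`: the screen's dynamic range
  is the bin-ratio range, and `dynamic_range()` exposes it.

# Barcode quantification

Reads are quality-masked (Phred < 20 → N) before the barcode is read from
positions 23–30; short reads are skipped and tallied, and the QC report
asserts `assigned + unassigned + skipped = total` per file. Association is
exact-match only — masking to N already prevents miscounting a damaged
base, and a Hamming-1 rescue exists behind a flag but is off by default.
Background coverage for the `< 50 reads in any replicate` exclusion rule is
counted post-masking and pre-association, i.e. raw extracted barcode
occurrences, since the rule protects against unreliable *representation*,
not against association ambiguity.

Barcode assignment at design time draws uniform random 8-mers with pairwise
Hamming distance ≥ 2. The separation is a design-side safety margin so a
single sequencing error cannot silently convert one library barcode into
another; it does not change the exact-match association.

# Library design

* Motif scanning scores log2-odds against a uniform background, linearly
  rescaled per motif so the worst possible match is 0 and the best 1000
  (the JASPAR relative-score convention); the default acceptance threshold
  is 800 and is configurable, since published screens report scores but
  rarely thresholds.
* "Most conserved" motif positions are the columns with the highest
  maximum base frequency after pseudocount normalization, ties to the
  lower index. Information content is the plausible alternative; maximum
  frequency was chosen because the mutagenesis targets the consensus bases
  a transversion disrupts most directly, and the two metrics rarely
  disagree on the top two columns of a sharp motif.
* The transversion map A↔C, T↔G is an involution and commutes with
  complementation, so motif-strand edits can be applied directly on the
  element strand; the minus-strand bookkeeping is tested against a
  brute-force reverse-complement oracle.
* Edits landing inside another curated occurrence warn rather than error:
  overlap interference is sometimes unavoidable in dense motif clusters,
  and the warning leaves the decision with the designer.
* Coordinates are 0-based half-open internally (BED convention); 1-based
  inclusive appears only at I/O boundaries that require it (e.g. the
  read-position arguments of `extract_barcodes()`, which follow read
  trimming conventions).

# Effect models

* **Calibration** regresses log10(expression) on score — expression is the
  quantity being predicted, and the intercept absorbs the background
  fluorescence that keeps the score–expression line from passing through
  the origin. `pseudo_expression()` applies `10^(a s + b)`.
* **Epistasis**: the multiplicative null says a double mutant's fold
  change is the product of its singles'; the statistic is the log2
  deviation `d`. Records whose double-mutant pseudo-expression sits at or
  below the dynamic-range floor — the 2.5th percentile of an
  enhancer-null control's pseudo-expressions — are flagged rather than
  tested, because a saturated score cannot distinguish multiplicative from
  sub-multiplicative behavior.
* **Buffering**: intrinsic activity A is baseline-subtracted (the
  facilitator-only level is the zero of intrinsic activity), elements at
  or below baseline are excluded with a flag, and the gain G is fit as
  `log10 G ~ log10 A`. A negative slope is the buffering signature: weak
  elements are boosted more than strong ones.
* **Recombinant-fraction correction** inverts the explicit mixing model
  `measured = f * corrected + (1 − f) * baseline`; the assumption that
  non-recombinant cells express at the no-payload baseline is stated
  rather than implicit, and the inversion is unit-tested as an exact
  inverse.

# qPCR, ChIP and nascent transcription

The ΔΔCt method uses base 2 by default even when a measured efficiency is
available (the standard reporting convention); a Pfaffl-style
efficiency-corrected variant sits behind the `efficiency` argument.
Technical replicates are averaged on the Ct scale; an optional outlier rule
(drop a replicate > 0.5 cycles from the median) is off by default because
the aggregation used by any given lab is rarely reported.

The pausing index uses pause = [TSS, TSS + 250) and body =
[TSS + 500, TES − 500) in the direction of transcription, mirrored in
genomic coordinates on the minus strand; the right edge of "TSS to
TSS+250 bp" is ambiguous, and the half-open 250-bp reading keeps the region
lengths exact. The index is scale-invariant, so whether tracks are
normalized first is immaterial (and tested).

Consensus peaks use the reciprocal ≥ 50% overlap rule; concordance is
symmetric and monotone in the threshold. Scaling factors re-implement
median-of-ratios normalization (geometric-mean reference over rows with no
zero, per-sample median of ratios) and are cross-checked in the tests
against both a brute-force oracle and an independent reference
implementation.

# Acceptance computations and their interpretation

`scripts/acceptance.R` recomputes three quantities from scratch under the
default study conditions: the per-barcode score correlation between two
independently simulated replicates (expected to be very high — the same
library measured twice through the full FASTQ round trip), the correlation
between element median scores and true log10 expression for 12 elements
spaced across the central dynamic range (the log10 bin-mean ratios of
0-based octile bins 2 and 7, taken from the replicate-1 reference screen;
0-based indices match the truth table's bin indexing), and the
percent-input identity at equal Cts.

# Limitations

* Scores live on the fluorescence-ratio scale. In this generator the ratio
  is exactly proportional to expression, so over a wide expression range
  the *linear* correlation between scores and *log* expression is
  intrinsically limited — an exact exponential relation caps Pearson r
  well below 1 even when the rank correlation is perfect. Real FlowFISH
  data are compressed by background fluorescence in both channels, which
  makes empirical score–log-expression relations more linear than this
  generator produces. Passing tests therefore demonstrate correct
  recovery of the simulated quantities, not that a real instrument's
  score–expression relation is linear.
* Quantile binning assumes the sorter gates exact population fractions;
  real gates drift, and bins at the tails are noisier than the generator
  suggests.
* The generator draws reads multinomially per bin; overdispersion from PCR
  amplification is not modeled, so real replicate concordance will be
  lower than simulated concordance at equal depth.
* The motif-curation step takes the expressed-TF set as an input; deriving
  it from an RNA-seq quantification (e.g. a TPM > 1 rule) is the caller's
  responsibility.
* Mutant checking against genome-wide motif databases for de novo site
  creation is out of scope, as are alignment, peak calling and
  duplicate/UMI handling.
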