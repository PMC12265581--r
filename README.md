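# lpdissect

Dissection of enhancer activity from landing-pad sort-seq screens.

`lpdissect` implements the computational chain of a recombinase-mediated
enhancer-dissection experiment: a barcoded library of enhancer mutants is
integrated at a genomic landing pad, target-gene expression is read out per
cell by ratiometric RNA FISH (target channel AF647 over a housekeeping
control AF488), cells are sorted into K expression bins, and the element
barcodes are sequenced per bin. The package covers the design of the mutant
library, the read processing, the activity scoring, the downstream effect
models, and a synthetic sort-seq generator with known ground truth that
exercises the whole pipeline end to end. It is aimed at groups running
FlowFISH / sort-seq reporter screens who want a tested, reusable
implementation of this analysis rather than one-off scripts.

## What it computes

**Activity scores (weighted-average method).** For barcode *b* with read
count *c<sub>bk</sub>* in bin *k* (bin total *N<sub>k</sub>*, sorted-cell
fraction *s<sub>k</sub>*, bin fluorescence ratio
*R<sub>k</sub> = AF647<sub>k</sub> / AF488<sub>k</sub>*):

    f_bk = (c_bk / N_k) * s_k,  renormalized so that sum_k f_bk = 1
    S_b  = sum_k f_bk * R_k

Dividing by *N<sub>k</sub>* removes per-bin sequencing depth,
*s<sub>k</sub>* restores each bin's share of the sorted population, and the
score is the occupancy-weighted average of the bin ratios, so
min *R<sub>k</sub>* ≤ *S<sub>b</sub>* ≤ max *R<sub>k</sub>*. Element scores
are medians over barcode scores pooled across replicates.

**Library design.** JASPAR-style PFM scanning with log-odds scores rescaled
to the 0–1000 relative-score range, curation against ChIP-seq peaks and an
expressed-TF list, transversion mutagenesis (A↔C, T↔G) of the two most
conserved motif positions, ~100-bp tiling deletions, mix-and-match
enumeration of e1/e2 single and double mutants, and random 8-nt barcode
assignment with pairwise Hamming distance ≥ 2.

**Barcode quantification.** Quality masking (Phred < 20 → N), extraction of
read positions 23–30, exact-match association against the manifest, and the
background filter that excludes any barcode with < 50 raw background reads
in at least one replicate.

**Effect models.** Calibration of scores to log10 expression
(`calibrate()` / `pseudo_expression()`), the multiplicative (log-additive)
null for double mutants (*d* = log2FC<sub>double</sub> −
log2FC<sub>e1</sub> − log2FC<sub>e2</sub>), the facilitator power-law
buffering fit (OLS of log10 gain on log10 intrinsic activity), and the
recombinant-fraction correction `corrected = baseline + (measured − baseline)/f`
with `f = (p_payload − p_control)/p_payload`.

**qPCR / ChIP / nascent transcription.** 2^−ΔΔCt relative expression,
standard-curve efficiency `E = 10^(−1/slope)`, ChIP percent input
`100% × E^(Ct_input − Ct_ChIP) × input_fraction`, pausing index
(pause-region density over gene-body density), reciprocal-overlap consensus
peaks, and median-of-ratios scaling factors.

## Worked example

Simulate two replicate screens of a 12-element library spanning three orders
of magnitude of expression, quantify the emitted FASTQ files back into
counts, and score:

```r
library(lpdissect)

cfg1 <- sim_config(n_elements = 12,
                   true_log10_expression = seq(-3, 0, length.out = 12),
                   barcodes_per_element = 4, n_bins = 8,
                   cells_per_barcode = 1000, reads_per_barcode_expected = 200,
                   noise_cv = 0.3, seed = 1)
rep1 <- run_screen(cfg1, replicate_id = "rep1")
cfg2 <- cfg1; cfg2$seed <- 2L
rep2 <- run_screen(cfg2, manifest = rep1$truth$manifest, replicate_id = "rep2")

rep1$counts
#> bin count matrix [rep1]: 48 barcodes x 8 bins, 9600 assigned reads
#>   unassigned 0, skipped 0, background sample present

replicate_concordance(rep1$scores, rep2$scores)
#> [1] 0.9994384

tab <- summarize_elements(list(rep1$scores, rep2$scores), rep1$truth$manifest)
head(tab$element_scores, 4)
#>    element_id       score n_scores
#> 1 element_001 0.001173617        8
#> 2 element_002 0.002078334        8
#> 3 element_003 0.003642868        8
#> 4 element_004 0.007126229        8

merged <- merge(tab$element_scores, rep1$truth$truth, by = "element_id")
cor(log10(merged$score), merged$true_log10_expression)
#> [1] 0.9996097
```

The replicate concordance (Pearson r = 0.9994 over 48 shared barcodes) shows
the scoring chain is reproducible across independent sorts; the element
scores recover the simulated expressions over the full range (r = 0.9996 on
the log scale — scores are ratio-scaled, so the log of the score tracks the
log10 expression).

The qPCR and ChIP formulas work on plain tables:

```r
ct <- simulate_qpcr(true_expression_ratio = 0.05, efficiency = 2, ct_sd = 0)
ddct_expression(ct, "target", "reference", "calibrator")
#> calibrator     sample
#>       1.00       0.05

percent_input(ct_input = 24.7, ct_chip = 24.7, efficiency = 1.9)
#> [1] 2
```

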