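#' Run a full synthetic screen replicate end to end
#'
#' Simulates a sorted population from the config, emits per-bin and background
#' FASTQ files, quantifies barcodes back out of the FASTQ, and computes
#' weighted-average activity scores against the population's bin fluorescence
#' summaries. This is the round trip the real screen performs: the scores are
#' derived entirely from the emitted reads, not from the simulation's internal
#' counts.
#'
#' @param config A [sim_config()].
#' @param manifest Optional `library_manifest` (auto-generated otherwise, see
#'   [simulate_population()]).
#' @param replicate_id Replicate label.
#' @param dir Directory for the FASTQ files (a tempdir by default; files are
#'   removed afterwards unless `keep_fastq = TRUE`).
#' @param keep_fastq Keep the emitted FASTQ files.
#' @return A list: `truth` (`sortseq_truth`), `counts` (`bin_count_matrix`),
#'   `fluor` (bin fluorescence table), `scores` ([score_barcodes()] table).
#' @export
run_screen <- function(config, manifest = NULL, replicate_id = "rep1",
                       dir = tempfile("screen_"), keep_fastq = FALSE) {
  truth <- simulate_population(config, manifest = manifest)
  emission <- emit_fastq(truth, truth$manifest,
                         depth = config$reads_per_barcode_expected,
                         seed = config$seed + 1L, dir = dir)
  if (!keep_fastq) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  K <- config$n_bins
  counts <- count_screen(emission$files[seq_len(K)],
                         background_fastq = emission$files[["background"]],
                         manifest = truth$manifest,
                         replicate_id = replicate_id)
  fluor <- bin_fluorescence(truth)
  scores <- score_barcodes(counts, fluor,
                           sorted_fraction = fluor$sorted_fraction)
  list(truth = truth, counts = counts, emission = emission, fluor = fluor,
       scores = scores)
}

#' Central dynamic range of a simulated screen
#'
#' The log10 mean fluorescence ratios of two reference bins of a screen's
#' sorted population, bracketing the expression interval over which bin
#' sorting can resolve differences (scores saturate at the extreme bins).
#'
#' @param truth A `sortseq_truth` (typically from a reference screen spanning
#'   the full assay range).
#' @param bins Length-2 vector of 0-based bin indices bracketing the central
#'   range (default bins 2 and 7 of an 8-bin sort).
#' @return Numeric length-2: log10 of the two bins' mean AF647/AF488 ratios.
#' @export
dynamic_range <- function(truth, bins = c(2L, 7L)) {
  stopifnot(inherits(truth, "sortseq_truth"))
  bs <- truth$bin_stats
  if (!all(bins %in% bs$bin)) stop("reference bins out of range", call. = FALSE)
  idx <- match(bins, bs$bin)
  log10(bs$mean_af647[idx] / bs$mean_af488[idx])
}
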