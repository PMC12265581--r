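#' Simulation configuration for a synthetic sort-seq screen
#'
#' Bundles and validates the parameters of the synthetic FlowFISH sort-seq
#' generator: a barcoded element library whose target-gene expression spans a
#' known range, per-cell ratiometric fluorescence with lognormal noise, K-way
#' bin sorting on the target/control fluorescence ratio, and bin-wise barcode
#' sequencing at configurable depth.
#'
#' @param n_elements Number of library elements.
#' @param true_log10_expression Numeric vector of length `n_elements`: each
#'   element's true target-gene expression on the log10 scale, relative to a
#'   wild-type reference at 0.
#' @param barcodes_per_element Barcodes tagging each element (default 4).
#' @param n_bins Number of sorting bins K (default 8, i.e. octile sorting;
#'   must be >= 2).
#' @param cells_per_barcode Sorted cells carrying each barcode.
#' @param reads_per_barcode_expected Expected sequencing reads per barcode.
#' @param noise_cv Coefficient of variation of the lognormal per-cell
#'   fluorescence-ratio noise (>= 0).
#' @param control_channel_mean Mean control-channel (AF488) intensity per cell;
#'   the generator keeps the control channel constant and places all noise on
#'   the target/control ratio.
#' @param seed Integer seed; all randomness downstream derives from it.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_population()], [read_sim_config()]
#' @export
#' @examples
#' cfg <- sim_config(n_elements = 4, true_log10_expression = c(-3, -2, -1, 0),
#'                   cells_per_barcode = 100, reads_per_barcode_expected = 50,
#'                   noise_cv = 0.3, seed = 1)
sim_config <- function(n_elements,
                       true_log10_expression,
                       barcodes_per_element = 4,
                       n_bins = 8,
                       cells_per_barcode = 1000,
                       reads_per_barcode_expected = 200,
                       noise_cv = 0.3,
                       control_channel_mean = 1,
                       seed = 1) {
  n_elements <- check_count(n_elements, "n_elements")
  barcodes_per_element <- check_count(barcodes_per_element, "barcodes_per_element")
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  cells_per_barcode <- check_count(cells_per_barcode, "cells_per_barcode")
  reads_per_barcode_expected <- check_count(reads_per_barcode_expected,
                                            "reads_per_barcode_expected")
  noise_cv <- check_number(noise_cv, "noise_cv", min = 0)
  control_channel_mean <- check_number(control_channel_mean,
                                       "control_channel_mean", min = 0)
  if (!is.numeric(true_log10_expression) ||
      length(true_log10_expression) != n_elements ||
      any(!is.finite(true_log10_expression))) {
    stop("`true_log10_expression` must be a finite numeric vector of length `n_elements`",
         call. = FALSE)
  }
  structure(
    list(n_elements = n_elements,
         true_log10_expression = as.numeric(true_log10_expression),
         barcodes_per_element = barcodes_per_element,
         n_bins = n_bins,
         cells_per_barcode = cells_per_barcode,
         reads_per_barcode_expected = reads_per_barcode_expected,
         noise_cv = noise_cv,
         control_channel_mean = control_channel_mean,
         seed = check_count(seed, "seed", min = 0L)),
    class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()].
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sort-seq simulation config: %d elements x %d barcodes, K = %d bins\n",
              x$n_elements, x$barcodes_per_element, x$n_bins))
  cat(sprintf("  cells/barcode %d, expected reads/barcode %d, ratio CV %.2f, seed %d\n",
              x$cells_per_barcode, x$reads_per_barcode_expected, x$noise_cv, x$seed))
  cat(sprintf("  true log10 expression in [%.2f, %.2f]\n",
              min(x$true_log10_expression), max(x$true_log10_expression)))
  invisible(x)
}

#' Simulate a sorted cell population with known ground truth
#'
#' Draws per-cell target/control fluorescence ratios for every barcode of every
#' element and sorts the pooled population into K bins. Each cell's ratio is
#' `10^true_log10_expression * lognormal(mean = 1, cv = noise_cv)`. Unless
#' explicit boundaries are supplied, bins are the K quantile intervals of the
#' pooled ratio distribution (octiles for K = 8), emulating a sorter gating a
#' fixed fraction of cells per bin.
#'
#' @param config A [sim_config()].
#' @param manifest Optional [assign_barcodes()] manifest mapping barcodes to
#'   element ids; when `NULL` a manifest with `barcodes_per_element` random
#'   8-mers per element (`element_001`, ...) is generated from the config seed.
#' @param bin_boundaries Optional increasing numeric vector of K - 1 explicit
#'   ratio thresholds overriding quantile binning.
#'
#' @return An object of class `sortseq_truth` with components
#'   `cells` (data frame: `element_id`, `barcode`, `ratio`, `bin` with 0-based
#'   bin index), `bin_boundaries`, `bin_stats` (per-bin cell count and mean
#'   AF647/AF488 intensities computed only from cells in that bin),
#'   `truth` (per-element true log10 expression), `manifest`, and `config`.
#' @export
simulate_population <- function(config, manifest = NULL, bin_boundaries = NULL) {
  stopifnot(inherits(config, "sim_config"))
  element_ids <- sprintf("element_%03d", seq_len(config$n_elements))
  if (is.null(manifest)) {
    dummies <- lapply(element_ids, function(id) {
      element_variant(id, parent = "ACGT", category = "control")
    })
    manifest <- assign_barcodes(dummies,
                                n_per_variant = config$barcodes_per_element,
                                seed = config$seed + 90000L)
  }
  validate_manifest(manifest)
  bc_map <- manifest$barcode_map
  bc_map <- bc_map[bc_map$element_id %in% element_ids, , drop = FALSE]
  if (!all(element_ids %in% bc_map$element_id)) {
    stop("manifest does not cover every simulated element", call. = FALSE)
  }

  K <- config$n_bins
  expr <- setNames(config$true_log10_expression, element_ids)
  cells <- with_seed(config$seed, {
    n_bc <- nrow(bc_map)
    element_id <- rep(bc_map$element_id, each = config$cells_per_barcode)
    barcode <- rep(bc_map$barcode, each = config$cells_per_barcode)
    n_cells <- length(barcode)
    # lognormal multiplicative noise with mean 1 and the requested CV
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      noise <- rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      noise <- rep(1, n_cells)
    }
    data.frame(element_id = element_id, barcode = barcode,
               ratio = 10^expr[element_id] * noise,
               stringsAsFactors = FALSE, row.names = NULL)
  })

  if (length(unique(cells$ratio)) < K) {
    stop("degenerate population: fewer distinct ratios than bins", call. = FALSE)
  }
  if (is.null(bin_boundaries)) {
    bin_boundaries <- unname(quantile(cells$ratio, probs = seq_len(K - 1) / K,
                                      names = FALSE))
  }
  if (length(bin_boundaries) != K - 1 || is.unsorted(bin_boundaries, strictly = TRUE)) {
    stop("`bin_boundaries` must be ", K - 1, " strictly increasing thresholds",
         call. = FALSE)
  }
  cells$bin <- findInterval(cells$ratio, bin_boundaries)  # 0-based bin index

  af488 <- config$control_channel_mean
  bin_stats <- do.call(rbind, lapply(seq_len(K) - 1L, function(k) {
    r <- cells$ratio[cells$bin == k]
    data.frame(bin = k, n_cells = length(r),
               mean_af647 = if (length(r)) mean(r * af488) else NA_real_,
               mean_af488 = af488)
  }))

  structure(
    list(cells = cells, bin_boundaries = bin_boundaries, bin_stats = bin_stats,
         truth = data.frame(element_id = element_ids, true_log10_expression = unname(expr),
                            stringsAsFactors = FALSE),
         manifest = manifest, config = config),
    class = "sortseq_truth")
}

#' @export
print.sortseq_truth <- function(x, ...) {
  cat(sprintf("sort-seq truth: %d cells, %d elements, %d barcodes, %d bins\n",
              nrow(x$cells), nrow(x$truth),
              length(unique(x$cells$barcode)), nrow(x$bin_stats)))
  invisible(x)
}

#' Per-bin fluorescence summaries of a simulated population
#'
#' Collapses a [simulate_population()] truth object into the bin fluorescence
#' table consumed by the scoring module: per-bin mean target (AF647) and
#' control (AF488) intensities plus the sorted-cell fraction.
#'
#' @param truth A `sortseq_truth`.
#' @return A data frame with columns `bin`, `mean_af647`, `mean_af488`,
#'   `sorted_fraction`.
#' @export
bin_fluorescence <- function(truth) {
  stopifnot(inherits(truth, "sortseq_truth"))
  bs <- truth$bin_stats
  data.frame(bin = bs$bin, mean_af647 = bs$mean_af647, mean_af488 = bs$mean_af488,
             sorted_fraction = bs$n_cells / sum(bs$n_cells))
}

# fixed read layout: 22-nt constant prefix, 8-nt barcode, constant suffix,
# so the barcode occupies read positions 23-30 (1-based inclusive)
FASTQ_PREFIX <- "TCGACTGATCGGAAGAGCACAC"  # 22 nt
FASTQ_SUFFIX <- "GTCAGATCGG"              # 10 nt

#' Emit per-bin FASTQ files from a simulated sorted population
#'
#' Writes one FASTQ per sorting bin plus an unsorted background FASTQ pooling
#' the pre-sort population. Every read is a 22-nt constant prefix, the 8-nt
#' element barcode (read positions 23-30, 1-based), and a constant suffix,
#' with Phred+33 qualities. Each bin receives the same expected total depth
#' (`depth * n_barcodes / K` reads) allocated across barcodes by a multinomial
#' draw proportional to the bin's cell counts; the background sample receives
#' `depth * n_barcodes` reads proportional to total (pre-sort) cell counts.
#'
#' @param truth A [simulate_population()] result.
#' @param manifest Library manifest; every barcode present in `truth` must
#'   appear in it.
#' @param depth Expected reads per barcode. `depth = 0` writes empty files
#'   with a warning.
#' @param seed Integer seed for the read-sampling RNG stream.
#' @param dir Output directory (created if needed).
#' @param base_quality Single Phred quality character applied to all bases
#'   (default `"I"`, Q40).
#'
#' @return Invisibly, a list with `files` (named character vector:
#'   `bin1..binK`, `background`), `counts` (barcode x bin matrix of emitted
#'   reads), `background_counts`, and `seed`.
#' @export
emit_fastq <- function(truth, manifest = truth$manifest, depth, seed,
                       dir = tempfile("sortseq_"), base_quality = "I") {
  stopifnot(inherits(truth, "sortseq_truth"))
  validate_manifest(manifest)
  depth <- check_count(depth, "depth", min = 0L)
  barcodes <- sort(unique(truth$cells$barcode))
  if (!all(barcodes %in% manifest$barcode_map$barcode)) {
    stop("truth contains barcodes absent from the manifest", call. = FALSE)
  }
  K <- nrow(truth$bin_stats)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cell_counts <- table(factor(truth$cells$barcode, levels = barcodes),
                       factor(truth$cells$bin, levels = seq_len(K) - 1L))
  cell_counts <- matrix(as.integer(cell_counts), nrow = length(barcodes),
                        dimnames = list(barcodes, paste0("bin", seq_len(K))))

  n_bc <- length(barcodes)
  counts <- matrix(0L, n_bc, K, dimnames = dimnames(cell_counts))
  bg_counts <- setNames(integer(n_bc), barcodes)
  if (depth > 0) {
    with_seed(seed, {
      per_bin_total <- round(depth * n_bc / K)
      for (k in seq_len(K)) {
        if (sum(cell_counts[, k]) == 0) next
        counts[, k] <- as.integer(rmultinom(1, per_bin_total, cell_counts[, k]))
      }
      bg_counts[] <- as.integer(rmultinom(1, depth * n_bc, rowSums(cell_counts)))
    })
  } else {
    warning("depth = 0: emitting empty FASTQ files", call. = FALSE)
  }

  write_reads <- function(path, bc_counts, tag) {
    n <- sum(bc_counts)
    if (n == 0) {
      file.create(path)
      return(invisible(NULL))
    }
    bcs <- rep(names(bc_counts), bc_counts)
    seqs <- Biostrings::DNAStringSet(paste0(FASTQ_PREFIX, bcs, FASTQ_SUFFIX))
    names(seqs) <- sprintf("sim:%s:%06d", tag, seq_len(n))
    qual <- Biostrings::PhredQuality(strrep(base_quality, Biostrings::width(seqs)))
    reads <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    Biostrings::writeQualityScaledXStringSet(reads, path)
    invisible(NULL)
  }

  files <- c(setNames(file.path(dir, sprintf("bin%d.fastq", seq_len(K))),
                      paste0("bin", seq_len(K))),
             background = file.path(dir, "background.fastq"))
  for (k in seq_len(K)) write_reads(files[[k]], counts[, k], paste0("bin", k))
  write_reads(files[["background"]], bg_counts, "background")

  invisible(list(files = files, counts = counts, background_counts = bg_counts,
                 seed = as.integer(seed)))
}

#' Simulate a qPCR Ct table for a known expression ratio
#'
#' Generates target- and reference-gene Ct values for a sample and a calibrator
#' such that, in expectation, `E^(-ddCt)` equals the requested true expression
#' ratio. Used to exercise the ddCt quantification chain with known truth.
#'
#' @param true_expression_ratio Target expression of the sample relative to the
#'   calibrator (> 0).
#' @param efficiency Amplification efficiency E in (1, 2].
#' @param replicates Technical replicates per well (default 3).
#' @param ct_sd Gaussian noise SD added to each Ct (cycles).
#' @param seed Integer seed.
#' @param base_ct Baseline Ct values, a named numeric with entries `target`
#'   and `reference` for the calibrator sample.
#'
#' @return A data frame (`sample`, `gene`, `replicate`, `ct`) with samples
#'   `"sample"` and `"calibrator"` and genes `"target"` and `"reference"`.
#' @export
simulate_qpcr <- function(true_expression_ratio, efficiency = 2, replicates = 3,
                          ct_sd = 0, seed = 1,
                          base_ct = c(target = 25, reference = 15)) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 1 || efficiency > 2) {
    stop("`efficiency` must be in (1, 2]", call. = FALSE)
  }
  true_expression_ratio <- check_number(true_expression_ratio,
                                        "true_expression_ratio")
  if (true_expression_ratio <= 0) {
    stop("`true_expression_ratio` must be > 0", call. = FALSE)
  }
  replicates <- check_count(replicates, "replicates")
  ct_sd <- check_number(ct_sd, "ct_sd", min = 0)

  ddct <- -log(true_expression_ratio) / log(efficiency)
  grid <- expand.grid(sample = c("sample", "calibrator"),
                      gene = c("target", "reference"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  mean_ct <- ifelse(grid$gene == "reference", base_ct[["reference"]],
                    base_ct[["target"]] +
                      ifelse(grid$sample == "sample", ddct, 0))
  grid$ct <- with_seed(seed, mean_ct + rnorm(nrow(grid), sd = ct_sd))
  grid
}

#' Define a gene model for pausing-index computations
#'
#' Coordinates are 0-based half-open. The promoter-proximal pause region is the
#' first 250 bp downstream of the TSS and the gene body runs from TSS + 500 to
#' TES - 500, both measured in the direction of transcription; minus-strand
#' genes have these offsets mirrored in genomic coordinates.
#'
#' @param contig Contig name.
#' @param start,end 0-based half-open genomic span of the transcription unit.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_model` with `pause` and `body` intervals.
#' @export
gene_model <- function(contig, start, end, strand = "+") {
  start <- check_number(start, "start", min = 0)
  end <- check_number(end, "end")
  if (!strand %in% c("+", "-")) stop("`strand` must be '+' or '-'", call. = FALSE)
  if (end - start <= 1250) {
    stop("gene span must exceed 1250 bp so pause and body regions are disjoint",
         call. = FALSE)
  }
  pause <- if (strand == "+") c(start, start + 250) else c(end - 250, end)
  body <- c(start + 500, end - 500)
  if (pause[2] > body[1] && pause[1] < body[2]) {
    stop("overlapping pause/body definition", call. = FALSE)
  }
  structure(list(contig = contig, start = start, end = end, strand = strand,
                 pause = pause, body = body),
            class = "gene_model")
}

#' Simulate a read 3'-end signal track over a gene model
#'
#' Places read 3' ends uniformly across the gene body and at
#' `pause_enrichment`-fold density in the promoter-proximal pause region, on
#' the transcribed strand. Positions outside the two regions receive no signal.
#'
#' @param gene A [gene_model()].
#' @param pause_enrichment Density of the pause region relative to the gene
#'   body (> 0). 1 gives uniform coverage and an expected pausing index of 1.
#' @param depth Total number of read ends to place. `depth = 0` yields an
#'   empty track (the pausing index is then undefined and flagged).
#' @param seed Integer seed.
#' @return A `signal_track`: data frame (`contig`, `pos`, `strand`, `count`)
#'   of 0-based per-base read-end counts, with the selected end recorded in
#'   attribute `which_end`.
#' @export
simulate_signal_track <- function(gene, pause_enrichment, depth, seed = 1) {
  stopifnot(inherits(gene, "gene_model"))
  pause_enrichment <- check_number(pause_enrichment, "pause_enrichment")
  if (pause_enrichment <= 0) stop("`pause_enrichment` must be > 0", call. = FALSE)
  depth <- check_count(depth, "depth", min = 0L)

  pause_len <- gene$pause[2] - gene$pause[1]
  body_len <- gene$body[2] - gene$body[1]
  p_pause <- pause_enrichment * pause_len /
    (pause_enrichment * pause_len + body_len)
  pos <- with_seed(seed, {
    in_pause <- runif(depth) < p_pause
    ifelse(in_pause,
           gene$pause[1] + floor(runif(depth) * pause_len),
           gene$body[1] + floor(runif(depth) * body_len))
  })
  tab <- table(pos)
  track <- data.frame(contig = rep(gene$contig, length(tab)),
                      pos = as.integer(names(tab)),
                      strand = rep(gene$strand, length(tab)),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
  signal_track(track, which_end = "3p")
}
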