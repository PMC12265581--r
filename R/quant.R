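#' Extract element barcodes from a FASTQ file
#'
#' Reproduces the screen's read-processing chain: bases with Phred quality
#' below `qmin` are masked to `N`, then the barcode is taken as the bases at
#' 1-based inclusive read positions `[start, end]` (defaults 23-30, the 8-bp
#' barcode slot of the library's read layout). Reads shorter than `end` are
#' skipped and tallied, never silently dropped.
#'
#' @param fastq Path to a FASTQ file (Phred+33).
#' @param start,end 1-based inclusive barcode coordinates on read 1.
#' @param qmin Minimum Phred quality; lower-quality bases become `N`.
#' @return A list: `barcodes` (character vector, one per usable read, possibly
#'   containing `N`), `n_total`, `n_skipped` (short reads).
#' @export
extract_barcodes <- function(fastq, start = 23, end = 30, qmin = 20) {
  start <- check_count(start, "start")
  end <- check_count(end, "end", min = start)
  # Biostrings warns about dropping its own internal mcols here; harmless
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  suppressWarnings(S4Vectors::mcols(reads) <- NULL)
  n_total <- length(reads)
  if (n_total == 0L) {
    return(list(barcodes = character(0), n_total = 0L, n_skipped = 0L))
  }
  keep <- Biostrings::width(reads) >= end
  n_skipped <- sum(!keep)
  reads <- reads[keep]
  if (!length(reads)) {
    return(list(barcodes = character(0), n_total = n_total,
                n_skipped = n_skipped))
  }
  bc <- as.character(Biostrings::subseq(reads, start, end))
  qual <- Biostrings::subseq(Biostrings::quality(reads), start, end)
  qint <- as(qual, "matrix")  # fixed width, so a clean reads x L matrix
  bc_mat <- matrix(unlist(strsplit(bc, ""), use.names = FALSE),
                   ncol = end - start + 1L, byrow = TRUE)
  bc_mat[qint < qmin] <- "N"
  list(barcodes = apply(bc_mat, 1, paste, collapse = ""),
       n_total = n_total, n_skipped = n_skipped)
}

#' Count extracted barcodes and associate them with library elements
#'
#' Exact-match association only: a read's barcode must equal a manifest
#' barcode verbatim; barcodes containing `N` or absent from the manifest
#' accumulate in the per-bin unassigned tally. Optionally, barcodes at Hamming
#' distance 1 from a unique manifest barcode can be rescued (off by default).
#'
#' @param barcodes_by_bin Named list of character vectors of extracted
#'   barcodes, one entry per sorting bin (in bin order); may include a
#'   `background` entry which is split out.
#' @param manifest A `library_manifest`.
#' @param skipped_by_bin Optional integer vector of short-read tallies from
#'   [extract_barcodes()], same order as `barcodes_by_bin`.
#' @param replicate_id Replicate label stored in the matrix.
#' @param rescue_hamming1 If `TRUE`, reads whose barcode is within Hamming
#'   distance 1 of exactly one manifest barcode are assigned to it.
#' @return An object of class `bin_count_matrix`: `counts` (barcode x bin
#'   integer matrix over all manifest barcodes), `background_counts`,
#'   `bin_totals` (column sums of `counts`), `unassigned` and `skipped`
#'   per bin, and `replicate_id`.
#' @export
count_and_associate <- function(barcodes_by_bin, manifest,
                                skipped_by_bin = NULL,
                                replicate_id = "rep1",
                                rescue_hamming1 = FALSE) {
  validate_manifest(manifest)
  lib <- manifest$barcode_map$barcode
  bg <- barcodes_by_bin[["background"]]
  bins <- barcodes_by_bin[setdiff(names(barcodes_by_bin), "background")]
  if (is.null(names(bins)) || !length(bins)) {
    names(bins) <- paste0("bin", seq_along(bins))
  }

  assign_one <- function(bcs) {
    if (rescue_hamming1 && length(bcs)) {
      unknown <- !(bcs %in% lib)
      if (any(unknown)) {
        rescue <- vapply(unique(bcs[unknown]), function(b) {
          d <- vapply(lib, hamming, 0L, a = b)
          if (sum(d == 1L) == 1L) lib[d == 1L] else NA_character_
        }, "")
        repl <- rescue[bcs[unknown]]
        bcs[unknown][!is.na(repl)] <- repl[!is.na(repl)]
      }
    }
    counts <- table(factor(bcs, levels = lib))
    list(counts = as.integer(counts),
         unassigned = length(bcs) - sum(counts))
  }

  per_bin <- lapply(bins, assign_one)
  counts <- vapply(per_bin, `[[`, integer(length(lib)), "counts")
  counts <- matrix(counts, nrow = length(lib),
                   dimnames = list(lib, names(bins)))
  bg_assigned <- if (!is.null(bg)) assign_one(bg) else NULL
  skipped <- if (is.null(skipped_by_bin)) rep(0L, length(bins)) else
    as.integer(skipped_by_bin)

  structure(
    list(counts = counts,
         background_counts = if (is.null(bg_assigned)) NULL else
           setNames(bg_assigned$counts, lib),
         bin_totals = colSums(counts),
         unassigned = setNames(vapply(per_bin, `[[`, 0L, "unassigned"),
                               names(bins)),
         background_unassigned = if (is.null(bg_assigned)) NA_integer_ else
           bg_assigned$unassigned,
         skipped = setNames(skipped, names(bins)),
         replicate_id = replicate_id),
    class = "bin_count_matrix")
}

#' @export
print.bin_count_matrix <- function(x, ...) {
  cat(sprintf("bin count matrix [%s]: %d barcodes x %d bins, %d assigned reads\n",
              x$replicate_id, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  cat(sprintf("  unassigned %d, skipped %d, background sample %s\n",
              sum(x$unassigned), sum(x$skipped),
              if (is.null(x$background_counts)) "absent" else "present"))
  invisible(x)
}

#' Quantify a full sorted-bin screen from FASTQ files
#'
#' Convenience wrapper running [extract_barcodes()] on every per-bin FASTQ and
#' the unsorted background FASTQ, then [count_and_associate()].
#'
#' @param bin_fastqs Character vector of per-bin FASTQ paths, in bin order.
#' @param background_fastq Path to the unsorted background FASTQ (or `NULL`).
#' @param manifest A `library_manifest`.
#' @param replicate_id Replicate label.
#' @param ... Passed to [extract_barcodes()] (`start`, `end`, `qmin`) and
#'   `rescue_hamming1` to [count_and_associate()].
#' @param rescue_hamming1 See [count_and_associate()].
#' @return A `bin_count_matrix`.
#' @export
count_screen <- function(bin_fastqs, background_fastq = NULL, manifest,
                         replicate_id = "rep1", rescue_hamming1 = FALSE, ...) {
  ext <- lapply(bin_fastqs, extract_barcodes, ...)
  bcs <- lapply(ext, `[[`, "barcodes")
  names(bcs) <- paste0("bin", seq_along(bcs))
  if (!is.null(background_fastq)) {
    bcs$background <- extract_barcodes(background_fastq, ...)$barcodes
  }
  count_and_associate(bcs, manifest,
                      skipped_by_bin = vapply(ext, `[[`, 0L, "n_skipped"),
                      replicate_id = replicate_id,
                      rescue_hamming1 = rescue_hamming1)
}

#' Filter barcodes by background coverage across replicates
#'
#' A barcode is excluded iff its raw read count in the unsorted background
#' sample is strictly below `min_background` in at least one biological
#' replicate. Returns the retained set together with a mandatory exclusion
#' report listing each excluded barcode with its per-replicate counts.
#'
#' @param matrices A `bin_count_matrix` or a list of them (one per replicate),
#'   each carrying background counts.
#' @param min_background Exclusion threshold (default 50; strict `<`).
#' @return A list: `retained` (character vector), `excluded` (data frame
#'   `barcode` plus one count column per replicate), `min_background`.
#' @export
filter_low_coverage <- function(matrices, min_background = 50) {
  if (inherits(matrices, "bin_count_matrix")) matrices <- list(matrices)
  bgs <- lapply(matrices, function(m) {
    if (!inherits(m, "bin_count_matrix") || is.null(m$background_counts)) {
      stop("missing background sample for a replicate", call. = FALSE)
    }
    m$background_counts
  })
  barcodes <- names(bgs[[1]])
  if (!all(vapply(bgs, function(b) identical(names(b), barcodes), TRUE))) {
    stop("replicates disagree on the barcode universe", call. = FALSE)
  }
  bg_mat <- do.call(cbind, bgs)
  colnames(bg_mat) <- vapply(matrices, `[[`, "", "replicate_id")
  low <- rowSums(bg_mat < min_background) > 0
  excluded <- data.frame(barcode = barcodes[low], bg_mat[low, , drop = FALSE],
                         row.names = NULL, stringsAsFactors = FALSE)
  list(retained = barcodes[!low], excluded = excluded,
       min_background = min_background)
}

#' Write a quantification QC report as JSON
#'
#' Records the read-conservation bookkeeping of a screen: assigned,
#' unassigned and skipped reads per bin plus background tallies.
#'
#' @param matrix A `bin_count_matrix`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(matrix, path) {
  stopifnot(inherits(matrix, "bin_count_matrix"))
  report <- list(
    replicate_id = matrix$replicate_id,
    assigned_per_bin = as.list(colSums(matrix$counts)),
    unassigned_per_bin = as.list(matrix$unassigned),
    skipped_per_bin = as.list(matrix$skipped),
    background_assigned = if (is.null(matrix$background_counts)) NULL else
      sum(matrix$background_counts),
    background_unassigned = matrix$background_unassigned)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
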