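#' Per-barcode bin occupancy fractions
#'
#' Converts raw per-bin barcode counts into occupancy fractions
#' `f[b,k] = (c[b,k] / N[k]) * s[k]`, renormalized so each barcode's fractions
#' sum to 1. The division by the bin total `N[k]` removes sequencing-depth
#' differences between bins (bins are sequenced to similar depth regardless of
#' how many cells they hold); the sorted-cell fraction `s[k]` re-weights each
#' bin back to its share of the sorted population (`1/K` when not supplied).
#'
#' @param matrix A `bin_count_matrix`, or a plain barcode x bin count matrix.
#' @param sorted_fraction Optional numeric vector of per-bin sorted-cell
#'   fractions summing to 1; defaults to equal weights.
#' @param retained Optional character vector restricting to retained barcodes
#'   (e.g. from [filter_low_coverage()]).
#' @return A barcode x bin matrix of fractions with unit row sums. Barcodes
#'   with zero reads in every bin are dropped with a warning; bins with zero
#'   total reads contribute 0, with a warning.
#' @export
bin_fractions <- function(matrix, sorted_fraction = NULL, retained = NULL) {
  counts <- if (inherits(matrix, "bin_count_matrix")) matrix$counts else
    as.matrix(matrix)
  if (!is.null(retained)) counts <- counts[rownames(counts) %in% retained, ,
                                           drop = FALSE]
  K <- ncol(counts)
  if (is.null(sorted_fraction)) sorted_fraction <- rep(1 / K, K)
  if (length(sorted_fraction) != K ||
      abs(sum(sorted_fraction) - 1) > 1e-9 || any(sorted_fraction < 0)) {
    stop("`sorted_fraction` must be ", K, " nonnegative values summing to 1",
         call. = FALSE)
  }
  N <- colSums(counts)
  if (any(N == 0)) {
    warning("bin(s) with zero total reads contribute 0: ",
            paste(colnames(counts)[N == 0], collapse = ", "), call. = FALSE)
  }
  w <- ifelse(N > 0, sorted_fraction / N, 0)
  f <- sweep(counts, 2, w, "*")
  rs <- rowSums(f)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " barcode(s) with zero reads in all bins dropped",
            call. = FALSE)
    f <- f[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  sweep(f, 1, rs, "/")
}

#' Weighted-average activity score
#'
#' The activity score of a barcode is the weighted average of the per-bin
#' normalized fluorescence ratios, weighted by the barcode's bin occupancy:
#' `S_b = sum_k f[b,k] * R[k]` with `R[k] = mean_AF647[k] / mean_AF488[k]`.
#' Scores are therefore bounded by the extreme bin ratios.
#'
#' @param fractions A barcode x bin fraction matrix from [bin_fractions()]
#'   (or a single barcode's fraction vector).
#' @param fluor Bin fluorescence table with columns `mean_af647`,
#'   `mean_af488` (one row per bin, in bin order), e.g. from
#'   [bin_fluorescence()] or [read_bin_fluorescence()].
#' @return Named numeric vector of per-barcode scores, in units of the
#'   normalized fluorescence ratio.
#' @export
activity_score <- function(fractions, fluor) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  R <- fluor$mean_af647 / fluor$mean_af488
  if (length(R) != ncol(fractions)) {
    stop("fluorescence table and fraction matrix disagree on bin count",
         call. = FALSE)
  }
  if (any(!is.finite(R)) || any(fluor$mean_af647 <= 0) ||
      any(fluor$mean_af488 <= 0)) {
    stop("bin intensities must be positive", call. = FALSE)
  }
  drop(fractions %*% R)
}

#' Score every barcode of a screen
#'
#' Runs [bin_fractions()] then [activity_score()] and returns a tidy
#' per-barcode score table.
#'
#' @inheritParams bin_fractions
#' @inheritParams activity_score
#' @return Data frame (`barcode`, `score`, `replicate_id`).
#' @export
score_barcodes <- function(matrix, fluor, sorted_fraction = fluor$sorted_fraction,
                           retained = NULL) {
  f <- bin_fractions(matrix, sorted_fraction = sorted_fraction,
                     retained = retained)
  s <- activity_score(f, fluor)
  data.frame(barcode = rownames(f), score = unname(s),
             replicate_id = if (inherits(matrix, "bin_count_matrix"))
               matrix$replicate_id else NA_character_,
             stringsAsFactors = FALSE)
}

#' Summarize barcode scores to element level
#'
#' The element score is the median over its retained barcode scores pooled
#' across replicates (each barcode contributes one score per replicate, as in
#' a screen's per-replicate dot plot). Control elements are summarized
#' separately; elements that lost all barcodes to filtering are flagged, not
#' scored.
#'
#' @param scores A [score_barcodes()] data frame or a list of them (one per
#'   replicate), pooled by concatenation.
#' @param manifest A `library_manifest` mapping barcodes to elements.
#' @param controls Character vector of control element ids.
#' @return An object of class `activity_table`: `barcode_scores` (pooled
#'   input with an `element_id` column), `element_scores` (`element_id`,
#'   `score`, `n_scores`), `control_scores`, and `flagged` (elements with no
#'   retained barcode).
#' @export
summarize_elements <- function(scores, manifest, controls = character()) {
  if (is.data.frame(scores)) scores <- list(scores)
  pooled <- do.call(rbind, scores)
  validate_manifest(manifest)
  pooled$element_id <- manifest$barcode_map$element_id[
    match(pooled$barcode, manifest$barcode_map$barcode)]
  if (anyNA(pooled$element_id)) {
    stop("scores contain barcodes absent from the manifest", call. = FALSE)
  }
  med <- vapply(split(pooled$score, pooled$element_id), median, numeric(1))
  n <- vapply(split(pooled$score, pooled$element_id), length, integer(1))
  element_scores <- data.frame(element_id = names(med), score = unname(med),
                               n_scores = unname(n), stringsAsFactors = FALSE)
  all_ids <- unique(manifest$barcode_map$element_id)
  flagged <- setdiff(all_ids, element_scores$element_id)
  structure(
    list(barcode_scores = pooled,
         element_scores = element_scores[!(element_scores$element_id %in%
                                             controls), , drop = FALSE],
         control_scores = element_scores[element_scores$element_id %in%
                                           controls, , drop = FALSE],
         flagged = flagged),
    class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity table: %d elements (%d controls) from %d barcode scores\n",
              nrow(x$element_scores), nrow(x$control_scores),
              nrow(x$barcode_scores)))
  if (length(x$flagged)) {
    cat("  flagged (no retained barcode):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Replicate concordance of barcode activity scores
#'
#' Pearson correlation of per-barcode scores over the barcodes shared by two
#' replicate score tables.
#'
#' @param scores_a,scores_b [score_barcodes()] data frames.
#' @return Pearson r. At least 3 shared barcodes are required; zero variance
#'   in either replicate yields `NA` with a warning.
#' @export
replicate_concordance <- function(scores_a, scores_b) {
  shared <- merge(scores_a[, c("barcode", "score")],
                  scores_b[, c("barcode", "score")], by = "barcode")
  if (nrow(shared) < 3) stop("fewer than 3 shared barcodes", call. = FALSE)
  if (sd(shared$score.x) == 0 || sd(shared$score.y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(shared$score.x, shared$score.y)
}

#' Read / write bin fluorescence summaries as TSV
#'
#' @param fluor Data frame with columns `bin`, `mean_af647`, `mean_af488` and
#'   optionally `sorted_fraction`.
#' @param path TSV path.
#' @return `read_bin_fluorescence()` returns the validated data frame;
#'   `write_bin_fluorescence()` returns `path` invisibly.
#' @export
read_bin_fluorescence <- function(path) {
  fluor <- read.delim(path)
  if (!all(c("bin", "mean_af647", "mean_af488") %in% names(fluor))) {
    stop("fluorescence TSV needs columns bin, mean_af647, mean_af488",
         call. = FALSE)
  }
  if (any(fluor$mean_af647 <= 0) || any(fluor$mean_af488 <= 0)) {
    stop("bin intensities must be positive", call. = FALSE)
  }
  if (!is.null(fluor$sorted_fraction) &&
      abs(sum(fluor$sorted_fraction) - 1) > 1e-9) {
    stop("sorted fractions must sum to 1", call. = FALSE)
  }
  fluor[order(fluor$bin), , drop = FALSE]
}

#' @rdname read_bin_fluorescence
#' @export
write_bin_fluorescence <- function(fluor, path) {
  write.table(fluor, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
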