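#' Strand-aware per-base read-end signal track
#'
#' @param track Data frame with columns `contig`, `pos` (0-based), `strand`,
#'   `count` (>= 0).
#' @param which_end Which biological read end the counts represent
#'   (`"5p"` or `"3p"`).
#' @return An object of class `signal_track` (a data frame).
#' @export
signal_track <- function(track, which_end = c("3p", "5p")) {
  which_end <- match.arg(which_end)
  if (!all(c("contig", "pos", "strand", "count") %in% names(track))) {
    stop("track needs columns contig, pos, strand, count", call. = FALSE)
  }
  if (any(track$count < 0) || any(track$pos < 0)) {
    stop("track counts and positions must be nonnegative", call. = FALSE)
  }
  structure(as.data.frame(track), class = c("signal_track", "data.frame"),
            which_end = which_end)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal track (%s ends): %d positions, %g total counts\n",
              attr(x, "which_end"), nrow(x), sum(x$count)))
  invisible(x)
}

#' Multiply a signal track by a scaling factor
#'
#' @param track A `signal_track`.
#' @param factor Positive scaling factor, e.g. from [scaling_factors()].
#' @return The rescaled track.
#' @export
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "signal_track"))
  if (factor <= 0) stop("`factor` must be > 0", call. = FALSE)
  track$count <- track$count * factor
  track
}

#' Pol II pausing index
#'
#' The pausing index is the ratio of read-end densities between the
#' promoter-proximal pause region and the gene body:
#' `PI = (pause reads / pause length) / (body reads / body length)`.
#' It is invariant to global depth scaling of the track. Zero body reads make
#' the index undefined: `NA` is returned with a warning.
#'
#' @param track A `signal_track` of 3' read ends.
#' @param gene A [gene_model()] defining the pause and body intervals.
#' @return The pausing index (possibly `NA`).
#' @export
pausing_index <- function(track, gene) {
  stopifnot(inherits(track, "signal_track"), inherits(gene, "gene_model"))
  on_gene <- track$contig == gene$contig & track$strand == gene$strand
  region_sum <- function(iv) {
    sum(track$count[on_gene & track$pos >= iv[1] & track$pos < iv[2]])
  }
  pause_len <- gene$pause[2] - gene$pause[1]
  body_len <- gene$body[2] - gene$body[1]
  body_reads <- region_sum(gene$body)
  if (body_reads == 0) {
    warning("no gene-body reads: pausing index undefined", call. = FALSE)
    return(NA_real_)
  }
  (region_sum(gene$pause) / pause_len) / (body_reads / body_len)
}

peaks_to_iranges <- function(peaks) {
  if (!all(c("start", "end") %in% names(peaks))) {
    stop("peaks need columns start, end (0-based half-open)", call. = FALSE)
  }
  if (any(peaks$start >= peaks$end)) {
    stop("peaks must satisfy start < end", call. = FALSE)
  }
  contig <- if ("contig" %in% names(peaks)) peaks$contig else "chr"
  # BED-style 0-based half-open -> IRanges 1-based closed
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

granges_to_peaks <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Consensus peaks by reciprocal overlap
#'
#' A peak pair is concordant iff their overlap covers at least
#' `min_reciprocal` of the length of *both* peaks (the reciprocal-overlap rule
#' of `bedtools intersect -f 0.50 -r`). The consensus keeps the intervals of
#' `set_a` that have at least one concordant partner in `set_b`; concordance
#' is symmetric, and raising `min_reciprocal` can only shrink the consensus.
#'
#' @param set_a,set_b Peak sets: data frames with `contig` (optional),
#'   `start`, `end` in 0-based half-open coordinates.
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.50).
#' @return The concordant subset of `set_a` (same representation).
#' @export
consensus_peaks <- function(set_a, set_b, min_reciprocal = 0.50) {
  a <- peaks_to_iranges(set_a)
  b <- peaks_to_iranges(set_b)
  hits <- GenomicRanges::findOverlaps(a, b)
  if (!length(hits)) return(set_a[0, , drop = FALSE])
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    a[S4Vectors::queryHits(hits)], b[S4Vectors::subjectHits(hits)]))
  wa <- GenomicRanges::width(a[S4Vectors::queryHits(hits)])
  wb <- GenomicRanges::width(b[S4Vectors::subjectHits(hits)])
  concordant <- ov >= min_reciprocal * wa & ov >= min_reciprocal * wb
  keep <- sort(unique(S4Vectors::queryHits(hits)[concordant]))
  set_a[keep, , drop = FALSE]
}

#' Union of consensus peak sets
#'
#' Concatenates the given peak sets and merges overlapping intervals per
#' contig into a single union peak set.
#'
#' @param ... Peak sets (data frames with `contig` optional, `start`, `end`),
#'   or a single list of them.
#' @return A merged peak set, sorted per contig.
#' @export
union_peaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  gr <- do.call(c, lapply(sets, peaks_to_iranges))
  granges_to_peaks(GenomicRanges::reduce(gr))
}

#' Median-of-ratios scaling factors for a count matrix
#'
#' The reads-under-peaks normalization: for each row (peak or transcript) the
#' reference is its geometric mean across samples, computed over rows with no
#' zero count; each sample's factor is the median across rows of its
#' count-to-reference ratio. Factors are returned both raw and rescaled to
#' geometric mean 1.
#'
#' @param counts Numeric matrix, rows = peaks/transcripts, columns = samples
#'   (>= 2 samples; at least one row positive in every sample).
#' @return A list: `factors` (raw medians of ratios) and `factors_scaled`
#'   (rescaled to geometric mean 1), both named by sample.
#' @export
scaling_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    stop("no rows positive in all samples", call. = FALSE)
  }
  m <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  factors <- apply(m / ref, 2, median)
  if (is.null(names(factors))) {
    names(factors) <- paste0("sample", seq_along(factors))
  }
  list(factors = factors,
       factors_scaled = factors / exp(mean(log(factors))))
}

#' Strand-aware read-end coverage
#'
#' Collapses stranded read intervals into a per-base signal track of the
#' selected biological end: the 5' end of a plus-strand read is its leftmost
#' base and of a minus-strand read its rightmost base (and vice versa for 3').
#' Each read contributes exactly one count.
#'
#' @param reads Data frame of read intervals: `contig` (optional), `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`; anything else is an
#'   error).
#' @param which_end `"5p"` or `"3p"`.
#' @return A [signal_track()] of per-base counts split by contig and strand.
#' @export
end_coverage <- function(reads, which_end = c("5p", "3p")) {
  which_end <- match.arg(which_end)
  if (!all(c("start", "end", "strand") %in% names(reads))) {
    stop("reads need columns start, end, strand", call. = FALSE)
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    stop("unstranded read: strand must be '+' or '-'", call. = FALSE)
  }
  contig <- if ("contig" %in% names(reads)) reads$contig else
    rep("chr", nrow(reads))
  left <- reads$strand == "+"
  pos <- if (which_end == "5p") {
    ifelse(left, reads$start, reads$end - 1L)
  } else {
    ifelse(left, reads$end - 1L, reads$start)
  }
  key <- paste(contig, pos, reads$strand, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[`, "", 1),
                    pos = as.integer(vapply(parts, `[`, "", 2)),
                    strand = vapply(parts, `[`, "", 3),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  signal_track(out, which_end = which_end)
}

#' Write a signal track as bedGraph
#'
#' One bedGraph per strand is conventional; this writes the given track as
#' 0-based half-open single-base intervals, optionally restricted to a strand.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @param strand Optional strand filter (`"+"` or `"-"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = NULL) {
  stopifnot(inherits(track, "signal_track"))
  if (!is.null(strand)) track <- track[track$strand == strand, , drop = FALSE]
  out <- data.frame(track$contig, track$pos, track$pos + 1L, track$count)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
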