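#' Position frequency matrix
#'
#' A light container for a JASPAR-style position frequency matrix: a 4 x L
#' matrix of nonnegative base counts or frequencies with rows A, C, G, T.
#'
#' @param matrix A 4 x L numeric matrix (rows A, C, G, T; L >= 4) of
#'   nonnegative counts or frequencies with positive column sums.
#' @param tf_name Transcription-factor label.
#' @param pseudocount Total pseudocount spread uniformly over the four bases
#'   during frequency normalization (default 0.8, i.e. 0.2 per base).
#' @return An object of class `pfm`.
#' @export
pfm <- function(matrix, tf_name, pseudocount = 0.8) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L || ncol(m) < 4L) {
    stop("PFM must be a 4 x L matrix with L >= 4", call. = FALSE)
  }
  if (any(m < 0) || any(colSums(m) <= 0)) {
    stop("PFM entries must be nonnegative with positive column sums", call. = FALSE)
  }
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(tf_name = as.character(tf_name), matrix = m,
                 pseudocount = check_number(pseudocount, "pseudocount", min = 0)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%d positions)\n", x$tf_name, ncol(x$matrix)))
  print(round(x$matrix, 2))
  invisible(x)
}

#' @export
length.pfm <- function(x) ncol(x$matrix)

#' Read JASPAR plain-text PFM files
#'
#' Parses the JASPAR flat format: a `>ID NAME` header followed by four rows
#' `A [ n n ... ]` etc. Multiple matrices per file are supported.
#'
#' @param path Path to a JASPAR-format text file.
#' @param pseudocount Passed to [pfm()].
#' @return A named list of `pfm` objects (names are TF names).
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path, call. = FALSE)
  out <- lapply(starts, function(i) {
    header <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    name <- if (length(header) >= 2) header[2] else header[1]
    rows <- lapply(lines[i + 1:4], function(r) {
      s <- sub("^\\s*[ACGTacgt]", "", r)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("malformed JASPAR record: ragged matrix rows", call. = FALSE)
    }
    pfm(do.call(rbind, rows), tf_name = name, pseudocount = pseudocount)
  })
  setNames(out, vapply(out, `[[`, "", "tf_name"))
}

# column frequency matrix after uniform pseudocount normalization
pfm_frequencies <- function(x) {
  stopifnot(inherits(x, "pfm"))
  m <- sweep(x$matrix + x$pseudocount / 4, 2,
             colSums(x$matrix) + x$pseudocount, "/")
  m
}

#' Most conserved motif positions
#'
#' Ranks motif columns by their maximum base frequency (after pseudocount
#' normalization) and returns the `k` most conserved ones -- the positions
#' whose transversion disrupts the consensus most. Ties are broken in favor of
#' the lower column index.
#'
#' @param x A [pfm()].
#' @param k Number of positions to select (default 2; `k <= length(x)`).
#' @return Integer vector of 1-based column indices, in increasing order.
#' @export
most_conserved_positions <- function(x, k = 2) {
  stopifnot(inherits(x, "pfm"))
  k <- check_count(k, "k")
  L <- ncol(x$matrix)
  if (k > L) stop("`k` exceeds motif length", call. = FALSE)
  conservation <- apply(pfm_frequencies(x), 2, max)
  sort(order(-conservation, seq_len(L))[seq_len(k)])
}

# log2-odds score matrix against a uniform background
pfm_logodds <- function(x) log2(pfm_frequencies(x) / 0.25)

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Scan one strand of a sequence, returning raw log-odds scores per offset.
scan_strand <- function(seq_chars, lo) {
  L <- ncol(lo)
  n <- length(seq_chars) - L + 1L
  if (n < 1L) return(numeric(0))
  idx <- BASE_IDX[seq_chars]
  if (anyNA(idx)) {
    stop("element sequence contains characters outside A/C/G/T", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    sum(lo[cbind(idx[i:(i + L - 1L)], seq_len(L))])
  }, numeric(1))
}

#' Scan an element sequence with a PFM
#'
#' Scores every offset on both strands with a log2-odds model against a
#' uniform background and rescales scores linearly to the JASPAR-style
#' relative-score range: the motif's minimum possible score maps to 0 and its
#' maximum to 1000.
#'
#' @param x A [pfm()].
#' @param element_seq Element sequence (character or
#'   [Biostrings::DNAString]).
#' @param threshold Minimum relative score to report (default 800).
#' @return A data frame of motif occurrences (`tf_name`, `start`, `end`
#'   0-based half-open, `strand`, `match_score`).
#' @export
scan_pfm <- function(x, element_seq, threshold = 800) {
  stopifnot(inherits(x, "pfm"))
  seq_chars <- strsplit(toupper(as.character(element_seq)), "")[[1]]
  lo <- pfm_logodds(x)
  L <- ncol(lo)
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  rescale <- function(s) 1000 * (s - smin) / (smax - smin)

  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[seq_chars])
  fwd <- rescale(scan_strand(seq_chars, lo))
  rev_ <- rescale(scan_strand(rc, lo))
  n <- length(fwd)
  strand_hits <- function(scores, strand, to_start) {
    idx <- which(scores >= threshold)
    data.frame(start = to_start(idx), strand = rep(strand, length(idx)),
               match_score = scores[idx])
  }
  hits <- rbind(
    strand_hits(fwd, "+", function(i) i - 1L),
    strand_hits(rev_, "-", function(i) n - i)
  )
  if (!nrow(hits)) {
    return(data.frame(tf_name = character(), start = integer(), end = integer(),
                      strand = character(), match_score = numeric()))
  }
  out <- data.frame(tf_name = x$tf_name, start = hits$start,
                    end = hits$start + L, strand = hits$strand,
                    match_score = hits$match_score, stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}
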