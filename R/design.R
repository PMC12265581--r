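#' Curate TF motif occurrences on an element
#'
#' Implements the motif-curation rule of the mutagenesis design: scan the
#' element with every PFM, keep occurrences scoring at least `threshold`
#' (JASPAR-style relative score), retain only TFs in the expressed set, require
#' each occurrence to overlap at least one ChIP-seq peak of the same TF, and
#' merge occurrences of different TFs that sit at the identical interval
#' (paralogous families binding the same site) under a joint `"/"`-separated
#' label.
#'
#' @param pfms A list of [pfm()] objects.
#' @param element_seq Element sequence (A/C/G/T only).
#' @param chip_peaks Data frame of peaks (`tf_name`, `start`, `end`), 0-based
#'   half-open, in the element coordinate frame.
#' @param expressed_tfs Character vector of TFs considered expressed.
#' @param threshold Relative-score acceptance threshold (default 800).
#' @return A data frame of curated occurrences (`tf_name`, `start`, `end`,
#'   `strand`, `match_score`), with merged occurrences carrying the joint
#'   label and the maximum score of the group.
#' @export
curate_motifs <- function(pfms, element_seq, chip_peaks, expressed_tfs,
                          threshold = 800) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  stopifnot(all(vapply(pfms, inherits, TRUE, "pfm")))
  if (!all(c("tf_name", "start", "end") %in% names(chip_peaks))) {
    stop("`chip_peaks` needs columns tf_name, start, end", call. = FALSE)
  }
  hits <- do.call(rbind, lapply(pfms, scan_pfm, element_seq = element_seq,
                                threshold = threshold))
  hits <- hits[hits$tf_name %in% expressed_tfs, , drop = FALSE]
  if (nrow(hits)) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      p <- chip_peaks[chip_peaks$tf_name == hits$tf_name[i], , drop = FALSE]
      any(p$start < hits$end[i] & p$end > hits$start[i])
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  if (!nrow(hits)) return(hits)

  # merge identical intervals across TFs under a joint label
  key <- paste(hits$start, hits$end, sep = ":")
  merged <- do.call(rbind, lapply(split(hits, key), function(g) {
    data.frame(tf_name = paste(sort(unique(g$tf_name)), collapse = "/"),
               start = g$start[1], end = g$end[1],
               strand = g$strand[which.max(g$match_score)],
               match_score = max(g$match_score),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$start, merged$tf_name), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# fixed purine<->pyrimidine transversion map; an involution that commutes with
# complementation, so it can be applied directly on the element strand
TRANSVERSION <- c(A = "C", C = "A", T = "G", G = "T")

#' Construct an element variant
#'
#' @param element_id Variant identifier.
#' @param parent Parent (wild-type) sequence.
#' @param edits Data frame of point edits (`offset` 0-based, `ref`, `alt`),
#'   or `NULL`.
#' @param deletion Length-2 vector: 0-based half-open interval deleted from
#'   the parent, or `NULL`.
#' @param category One of `"motif_mutant_e1"`, `"motif_mutant_e2"`,
#'   `"motif_mutant_both"`, `"tiling_deletion"`, `"control"`.
#' @param tf Optional TF label (used by [mix_and_match()]).
#' @param warnings Character vector of design warnings attached to the variant.
#' @return An object of class `element_variant`; its `sequence` field is the
#'   parent with edits/deletion applied.
#' @export
element_variant <- function(element_id, parent, edits = NULL, deletion = NULL,
                            category = "control", tf = NA_character_,
                            warnings = character()) {
  category <- match.arg(category, c("motif_mutant_e1", "motif_mutant_e2",
                                    "motif_mutant_both", "tiling_deletion",
                                    "control"))
  parent <- toupper(as.character(parent))
  if (!is.null(edits) && nrow(edits)) {
    if (anyDuplicated(edits$offset)) {
      stop("overlapping edits at the same offset", call. = FALSE)
    }
    if (any(edits$offset < 0 | edits$offset >= nchar(parent))) {
      stop("edit offset outside parent sequence", call. = FALSE)
    }
    ref <- substring(parent, edits$offset + 1, edits$offset + 1)
    if (!all(ref == edits$ref)) {
      stop("stale coordinates: ref base does not match parent", call. = FALSE)
    }
  }
  if (!is.null(deletion)) {
    if (length(deletion) != 2 || deletion[1] >= deletion[2] ||
        deletion[1] < 0 || deletion[2] > nchar(parent)) {
      stop("deletion interval must be a nonempty 0-based half-open interval within the parent",
           call. = FALSE)
    }
  }
  structure(list(element_id = as.character(element_id), parent = parent,
                 edits = edits, deletion = deletion, category = category,
                 tf = tf, warnings = warnings,
                 sequence = apply_variant(parent, edits, deletion)),
            class = "element_variant")
}

#' Apply a variant's edits and deletion to a parent sequence
#'
#' @param parent Parent sequence.
#' @param edits Point-edit data frame as in [element_variant()].
#' @param deletion Deletion interval as in [element_variant()].
#' @return The mutated sequence.
#' @export
apply_variant <- function(parent, edits = NULL, deletion = NULL) {
  chars <- strsplit(parent, "")[[1]]
  if (!is.null(edits) && nrow(edits)) {
    chars[edits$offset + 1] <- edits$alt
  }
  if (!is.null(deletion)) {
    keep <- setdiff(seq_along(chars), seq(deletion[1] + 1, deletion[2]))
    chars <- chars[keep]
  }
  paste(chars, collapse = "")
}

#' @export
print.element_variant <- function(x, ...) {
  n_ed <- if (is.null(x$edits)) 0L else nrow(x$edits)
  cat(sprintf("element variant %s [%s]: %d nt, %d edit(s)%s\n",
              x$element_id, x$category, nchar(x$sequence), n_ed,
              if (is.null(x$deletion)) "" else
                sprintf(", deletion [%d,%d)", x$deletion[1], x$deletion[2])))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Transversion-mutate the most conserved bases of a motif occurrence
#'
#' Replaces the targeted motif positions with their purine<->pyrimidine
#' transversions (A<->C, T<->G), mapping motif columns to element offsets in a
#' strand-aware way. If an edit falls inside another curated occurrence, a
#' warning is attached to the variant (overlap interference is tolerated, not
#' forbidden).
#'
#' @param element_seq Parent element sequence.
#' @param occurrence One-row data frame as returned by [curate_motifs()]
#'   (`start`, `end` 0-based half-open, `strand`).
#' @param positions 1-based motif column indices to mutate (e.g. from
#'   [most_conserved_positions()]). Empty positions yield an edit-free variant.
#' @param element_id Identifier for the variant (default derived from the TF).
#' @param other_occurrences Optional data frame of the remaining curated
#'   occurrences, used to flag overlap interference.
#' @param category Variant category label.
#' @return An [element_variant()].
#' @export
transversion_mutate <- function(element_seq, occurrence, positions,
                                element_id = NULL, other_occurrences = NULL,
                                category = "motif_mutant_e1") {
  occurrence <- as.list(occurrence[1, , drop = FALSE])
  if (is.null(element_id)) {
    element_id <- paste0("m", occurrence$tf_name)
  }
  L <- occurrence$end - occurrence$start
  positions <- as.integer(positions)
  if (length(positions) && (any(positions < 1) || any(positions > L))) {
    stop("`positions` must be 1-based motif columns within the occurrence",
         call. = FALSE)
  }
  offsets <- if (occurrence$strand == "+") {
    occurrence$start + positions - 1L
  } else {
    occurrence$end - positions
  }
  seq_up <- toupper(as.character(element_seq))
  edits <- NULL
  if (length(offsets)) {
    ref <- substring(seq_up, offsets + 1, offsets + 1)
    edits <- data.frame(offset = offsets, ref = ref,
                        alt = unname(TRANSVERSION[ref]),
                        stringsAsFactors = FALSE)
    edits <- edits[order(edits$offset), , drop = FALSE]
  }
  warnings <- character()
  if (!is.null(edits) && !is.null(other_occurrences) && nrow(other_occurrences)) {
    for (i in seq_len(nrow(edits))) {
      inside <- other_occurrences$start <= edits$offset[i] &
        other_occurrences$end > edits$offset[i]
      if (any(inside)) {
        warnings <- c(warnings, sprintf(
          "edit at offset %d falls inside occurrence(s): %s", edits$offset[i],
          paste(unique(other_occurrences$tf_name[inside]), collapse = ", ")))
      }
    }
  }
  element_variant(element_id, parent = seq_up, edits = edits,
                  category = category, tf = occurrence$tf_name,
                  warnings = warnings)
}

#' Tiling deletion variants across an element
#'
#' One deletion variant per requested segment; segments may overlap (finer
#' tiles refining earlier ones are allowed) and a full-element segment yields
#' an empty-sequence deletion control.
#'
#' @param element_seq Parent element sequence.
#' @param segment_table Data frame (`name`, `start`, `end`), 0-based half-open,
#'   with unique names; zero-length or out-of-bounds segments are errors.
#' @return A list of [element_variant()]s of category `"tiling_deletion"`.
#' @export
tile_deletions <- function(element_seq, segment_table) {
  if (!all(c("name", "start", "end") %in% names(segment_table))) {
    stop("`segment_table` needs columns name, start, end", call. = FALSE)
  }
  if (anyDuplicated(segment_table$name)) {
    stop("segment names must be unique", call. = FALSE)
  }
  seq_up <- toupper(as.character(element_seq))
  lapply(seq_len(nrow(segment_table)), function(i) {
    s <- segment_table[i, ]
    element_variant(paste0("del_", s$name), parent = seq_up,
                    deletion = c(s$start, s$end), category = "tiling_deletion")
  })
}

#' Mix-and-match enumeration of single and double mutants
#'
#' Pairs every mutated first sub-element (e1) with the wild-type second
#' sub-element (e2) and vice versa, and adds the e1-mut + e2-mut double for
#' TFs mutated in both sub-elements; concatenation order is e1 then e2. TFs
#' present on only one side yield only the single-sided variant. A wild-type
#' e1+e2 reference variant is included.
#'
#' @param e1_variants,e2_variants Lists of [element_variant()]s carrying a
#'   `tf` label, with parents equal to the wild-type e1 and e2 sequences.
#' @param e1_wt,e2_wt Wild-type sub-element sequences; default to the parents
#'   of the first variants.
#' @return A list of [element_variant()]s over the concatenated e1+e2 parent,
#'   with categories `motif_mutant_e1`, `motif_mutant_e2`,
#'   `motif_mutant_both`, plus a `control` WT reference named `"WT"`.
#' @export
mix_and_match <- function(e1_variants, e2_variants,
                          e1_wt = if (length(e1_variants)) e1_variants[[1]]$parent,
                          e2_wt = if (length(e2_variants)) e2_variants[[1]]$parent) {
  tf_of <- function(vs) vapply(vs, `[[`, "", "tf")
  e1_tfs <- tf_of(e1_variants)
  e2_tfs <- tf_of(e2_variants)
  if (anyNA(c(e1_tfs, e2_tfs))) {
    stop("all variants must carry a `tf` label", call. = FALSE)
  }
  parent <- paste0(e1_wt, e2_wt)
  shift_edits <- function(edits, by) {
    if (is.null(edits) || !nrow(edits)) return(NULL)
    transform(edits, offset = offset + by)
  }
  out <- list(element_variant("WT", parent, category = "control"))
  for (tf in union(e1_tfs, e2_tfs)) {
    v1 <- e1_variants[e1_tfs == tf]
    v2 <- e2_variants[e2_tfs == tf]
    e1_edits <- if (length(v1)) v1[[1]]$edits else NULL
    e2_edits <- if (length(v2)) shift_edits(v2[[1]]$edits, nchar(e1_wt)) else NULL
    if (length(v1)) {
      out <- c(out, list(element_variant(paste0("e1_m", tf), parent,
                                         edits = e1_edits,
                                         category = "motif_mutant_e1", tf = tf)))
    }
    if (length(v2)) {
      out <- c(out, list(element_variant(paste0("e2_m", tf), parent,
                                         edits = e2_edits,
                                         category = "motif_mutant_e2", tf = tf)))
    }
    if (length(v1) && length(v2)) {
      out <- c(out, list(element_variant(paste0("e1e2_m", tf), parent,
                                         edits = rbind(e1_edits, e2_edits),
                                         category = "motif_mutant_both", tf = tf)))
    }
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Assign random barcodes to library variants
#'
#' Draws uniform random ACGT barcodes for each variant, enforcing global
#' uniqueness and a pairwise Hamming distance of at least 2 so that a single
#' sequencing error cannot silently convert one library barcode into another
#' (association downstream remains exact-match).
#'
#' @param variants List of [element_variant()]s.
#' @param n_per_variant Barcodes per variant: a single count or a vector, one
#'   per variant (default 4; must be >= 1).
#' @param length Barcode length (default 8).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_tries Rejection-sampling attempts before declaring the barcode
#'   space exhausted.
#' @return An object of class `library_manifest` with components `variants`
#'   and `barcode_map` (data frame `barcode`, `element_id`).
#' @export
assign_barcodes <- function(variants, n_per_variant = 4, length = 8, seed = 1,
                            max_tries = NULL) {
  stopifnot(all(vapply(variants, inherits, TRUE, "element_variant")))
  length <- check_count(length, "length")
  if (base::length(n_per_variant) == 1L) {
    n_per_variant <- rep(n_per_variant, base::length(variants))
  }
  if (base::length(n_per_variant) != base::length(variants) ||
      any(n_per_variant < 1)) {
    stop("`n_per_variant` must be >= 1 for every variant", call. = FALSE)
  }
  n_total <- sum(n_per_variant)
  if (4^length < n_total) {
    stop("barcode space exhausted: 4^length < barcodes needed", call. = FALSE)
  }
  if (is.null(max_tries)) max_tries <- 1000L * n_total

  barcodes <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (base::length(barcodes) < n_total) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("barcode space exhausted: could not satisfy Hamming >= 2 constraint",
             call. = FALSE)
      }
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      ok <- !base::length(barcodes) ||
        all(vapply(barcodes, hamming, 0L, b = cand) >= 2L)
      if (ok) barcodes <- c(barcodes, cand)
    }
  })
  ids <- vapply(variants, `[[`, "", "element_id")
  if (anyDuplicated(ids)) stop("variant element ids must be unique", call. = FALSE)
  manifest <- structure(
    list(variants = variants,
         barcode_map = data.frame(barcode = barcodes,
                                  element_id = rep(ids, n_per_variant),
                                  stringsAsFactors = FALSE)),
    class = "library_manifest")
  validate_manifest(manifest)
}

#' Validate a library manifest
#'
#' Enforced on creation and on load: barcodes are unique, exactly 8 nt of
#' uppercase A/C/G/T (or the manifest's recorded length), and every element
#' carries at least one barcode.
#'
#' @param manifest A `library_manifest`.
#' @param barcode_length Required barcode length (default 8).
#' @return The manifest, invisibly, if valid; otherwise an error.
#' @export
validate_manifest <- function(manifest, barcode_length = 8) {
  if (!inherits(manifest, "library_manifest")) {
    stop("not a library_manifest", call. = FALSE)
  }
  bm <- manifest$barcode_map
  if (!all(c("barcode", "element_id") %in% names(bm))) {
    stop("manifest barcode_map needs columns barcode, element_id", call. = FALSE)
  }
  if (anyDuplicated(bm$barcode)) stop("barcodes must be unique", call. = FALSE)
  if (!all(nchar(bm$barcode) == barcode_length)) {
    stop("barcodes must be exactly ", barcode_length, " nt", call. = FALSE)
  }
  if (!all(grepl("^[ACGT]+$", bm$barcode))) {
    stop("barcodes must be uppercase A/C/G/T", call. = FALSE)
  }
  if (length(manifest$variants)) {
    ids <- vapply(manifest$variants, `[[`, "", "element_id")
    if (!all(ids %in% bm$element_id)) {
      stop("every variant needs at least one barcode", call. = FALSE)
    }
  }
  invisible(manifest)
}

#' @export
print.library_manifest <- function(x, ...) {
  n_el <- length(unique(x$barcode_map$element_id))
  cat(sprintf("library manifest: %d elements, %d barcodes (mean %.2f per element)\n",
              n_el, nrow(x$barcode_map), nrow(x$barcode_map) / n_el))
  invisible(x)
}

#' Write / read a library manifest as TSV
#'
#' The TSV holds one row per barcode (`barcode`, `element_id`, `category`,
#' `edits`), with edits serialized as `offset:ref>alt` separated by `;` and
#' deletions as `del:start-end`. [read_manifest()] re-validates barcode
#' uniqueness and length on load. Variant sequences can be written alongside
#' with [write_variant_fasta()].
#'
#' @param manifest A `library_manifest`.
#' @param path Output / input TSV path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a validated `library_manifest` (without parent sequences).
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  vs <- manifest$variants
  meta <- if (length(vs)) {
    data.frame(
      element_id = vapply(vs, `[[`, "", "element_id"),
      category = vapply(vs, `[[`, "", "category"),
      edits = vapply(vs, function(v) {
        parts <- character()
        if (!is.null(v$edits) && nrow(v$edits)) {
          parts <- sprintf("%d:%s>%s", v$edits$offset, v$edits$ref, v$edits$alt)
        }
        if (!is.null(v$deletion)) {
          parts <- c(parts, sprintf("del:%d-%d", v$deletion[1], v$deletion[2]))
        }
        paste(parts, collapse = ";")
      }, ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(element_id = unique(manifest$barcode_map$element_id),
               category = "control", edits = "", stringsAsFactors = FALSE)
  }
  out <- merge(manifest$barcode_map, meta, by = "element_id", sort = FALSE)
  out <- out[, c("barcode", "element_id", "category", "edits")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  manifest <- structure(
    list(variants = list(),
         barcode_map = data.frame(barcode = tab$barcode,
                                  element_id = tab$element_id,
                                  stringsAsFactors = FALSE),
         metadata = unique(tab[, intersect(c("element_id", "category", "edits"),
                                           names(tab))])),
    class = "library_manifest")
  validate_manifest(manifest)
  manifest
}

#' Write variant sequences as FASTA
#'
#' @param variants List of [element_variant()]s (or a `library_manifest`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_variant_fasta <- function(variants, path) {
  if (inherits(variants, "library_manifest")) variants <- variants$variants
  seqs <- Biostrings::DNAStringSet(vapply(variants, `[[`, "", "sequence"))
  names(seqs) <- vapply(variants, `[[`, "", "element_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
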