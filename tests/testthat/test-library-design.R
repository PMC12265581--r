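test_that("most conserved positions follow frequency ranking with index tie-breaks", {
  m <- cbind(c(1, 0, 0, 0), c(.5, .5, 0, 0), c(1, 0, 0, 0), c(.25, .25, .25, .25))
  p <- pfm(m, "TOY", pseudocount = 0)
  expect_equal(most_conserved_positions(p, 2), c(1L, 3L))
  expect_equal(most_conserved_positions(p, 4), 1:4)
  expect_error(most_conserved_positions(p, 5), "length")

  uni <- pfm(matrix(0.25, 4, 6), "UNIF", pseudocount = 0)
  expect_equal(most_conserved_positions(uni, 2), c(1L, 2L))
})

test_that("conservation ranking is unchanged by permuting non-selected columns", {
  set.seed(1)
  for (i in 1:10) {
    m <- matrix(rexp(4 * 8), 4, 8)
    p <- pfm(m, "R", pseudocount = 0.8)
    sel <- most_conserved_positions(p, 2)
    others <- setdiff(1:8, sel)
    perm <- sample(others)
    m2 <- m
    m2[, others] <- m[, perm]
    freq <- apply(pfm_frequencies(p), 2, max)
    sel2 <- most_conserved_positions(pfm(m2, "R", pseudocount = 0.8), 2)
    expect_equal(sort(freq[sel]),
                 sort(apply(pfm_frequencies(pfm(m2, "R", 0.8)), 2, max)[sel2]))
  }
})

test_that("PFM scanning finds exact matches and curation applies peak/expression filters", {
  # PFM matching TTTT
  m <- rbind(A = c(0, 0, 0, 0), C = c(0, 0, 0, 0),
             G = c(0, 0, 0, 0), T = c(10, 10, 10, 10))
  p <- pfm(m, "TBX", pseudocount = 0.4)
  seq <- "AATTTTAA"
  peak <- data.frame(tf_name = "TBX", start = 0, end = 8)
  occ <- curate_motifs(list(p), seq, peak, expressed_tfs = "TBX")
  occ_plus <- occ[occ$strand == "+", ]
  expect_equal(nrow(occ_plus), 1L)
  expect_equal(occ_plus$start, 2L)
  expect_equal(occ_plus$end, 6L)
  expect_equal(occ_plus$match_score, 1000)

  # no covering peak -> empty; TF not expressed -> empty
  no_peak <- data.frame(tf_name = "TBX", start = 6, end = 8)
  expect_equal(nrow(curate_motifs(list(p), seq, no_peak, "TBX")), 0L)
  expect_equal(nrow(curate_motifs(list(p), seq, peak, "OTHER")), 0L)
  expect_error(scan_pfm(p, "AANTTT"), "outside")
})

test_that("identical-interval occurrences of grouped TFs merge under a joint label", {
  m <- rbind(A = c(10, 0, 0, 10), C = c(0, 10, 0, 0),
             G = c(0, 0, 10, 0), T = c(0, 0, 0, 0))
  p1 <- pfm(m, "AP1", pseudocount = 0.4)
  p2 <- pfm(m, "NFE2", pseudocount = 0.4)
  seq <- "GGACGAGG"
  peaks <- data.frame(tf_name = c("AP1", "NFE2"), start = 0, end = 8)
  occ <- curate_motifs(list(p1, p2), seq, peaks, c("AP1", "NFE2"))
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$tf_name, "AP1/NFE2")
})

test_that("JASPAR flat files round-trip through the reader", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TOYTF",
    "A  [ 10  0  5  2 ]",
    "C  [  0 10  5  2 ]",
    "G  [  0  0  0  2 ]",
    "T  [  0  0  0  4 ]",
    ">MA0002.1 OTHER",
    "A 1 2 3 4",
    "C 1 2 3 4",
    "G 1 2 3 4",
    "T 1 2 3 4"), path)
  pfms <- read_jaspar(path)
  expect_named(pfms, c("TOYTF", "OTHER"))
  expect_equal(unname(pfms$TOYTF$matrix["A", ]), c(10, 0, 5, 2))
  expect_equal(ncol(pfms$OTHER$matrix), 4L)
})

test_that("transversion mutagenesis applies the fixed purine-pyrimidine map", {
  seq <- "GGGGGGGGGGATCGGGG"
  occ <- data.frame(tf_name = "X", start = 10L, end = 14L, strand = "+",
                    match_score = 1000)
  v <- transversion_mutate(seq, occ, positions = 1:4)
  # ATCG -> CGAT under A->C, T->G, C->A, G->T
  expect_equal(substr(v$sequence, 11, 14), "CGAT")
  expect_equal(v$edits$ref, c("A", "T", "C", "G"))
  expect_equal(v$edits$alt, c("C", "G", "A", "T"))

  # empty positions: identical to parent, zero edits
  v0 <- transversion_mutate(seq, occ, positions = integer(0))
  expect_identical(v0$sequence, toupper(seq))
  expect_null(v0$edits)
})

test_that("minus-strand motif columns map to element offsets by reverse complement", {
  set.seed(2)
  for (i in 1:10) {
    el <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    start <- sample(0:24, 1)
    L <- 6L
    occ <- data.frame(tf_name = "X", start = start, end = start + L,
                      strand = "-", match_score = 1000)
    positions <- sort(sample(seq_len(L), 2))
    v <- transversion_mutate(el, occ, positions)

    # oracle: mutate the motif-strand sequence directly, then reconstruct
    motif_seq <- revcomp(substr(el, start + 1, start + L))
    chars <- strsplit(motif_seq, "")[[1]]
    tv <- c(A = "C", C = "A", T = "G", G = "T")
    chars[positions] <- tv[chars[positions]]
    expected <- paste0(substr(el, 1, start), revcomp(paste(chars, collapse = "")),
                       substr(el, start + L + 1, nchar(el)))
    expect_identical(v$sequence, expected)
  }
})

test_that("transversion map is an involution and edits round-trip", {
  set.seed(3)
  for (i in 1:10) {
    el <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    occ <- data.frame(tf_name = "X", start = 5L, end = 15L,
                      strand = sample(c("+", "-"), 1), match_score = 1000)
    pos <- sample(1:10, 3)
    v <- transversion_mutate(el, occ, pos)
    # round-trip: stored sequence equals edits applied to the parent
    expect_identical(v$sequence, apply_variant(v$parent, v$edits))
    # involution: mutating the mutant at the same positions restores the parent
    v2 <- transversion_mutate(v$sequence, occ, pos)
    expect_identical(v2$sequence, el)
  }
})

test_that("stale coordinates and overlap interference are handled", {
  occ <- data.frame(tf_name = "X", start = 0L, end = 4L, strand = "+",
                    match_score = 1000)
  v <- transversion_mutate("ACGT", occ, 1:2)
  expect_error(element_variant("bad", "ACGT",
                               edits = data.frame(offset = 0, ref = "G", alt = "T")),
               "stale")
  other <- data.frame(tf_name = "Y", start = 1L, end = 3L, strand = "+",
                      match_score = 900)
  v_warn <- transversion_mutate("ACGT", occ, 2, other_occurrences = other)
  expect_match(v_warn$warnings, "inside occurrence")
})

test_that("tiling deletions remove the requested segments", {
  el <- strrep("ACGT", 239)  # 956 nt, the screen's element size
  segs <- data.frame(name = c("e1.1", "e1.all"),
                     start = c(0, 0), end = c(100, 956))
  vars <- tile_deletions(el, segs)
  expect_equal(nchar(vars[[1]]$sequence), 856L)
  expect_identical(vars[[1]]$sequence, substr(el, 101, 956))
  expect_equal(nchar(vars[[2]]$sequence), 0L)  # full-element deletion control
  expect_error(tile_deletions(el, data.frame(name = "z", start = 5, end = 5)),
               "interval")
  expect_error(tile_deletions(el, data.frame(name = "z", start = 0, end = 1000)),
               "interval")
})

test_that("mix-and-match enumerates single and double mutants per TF", {
  e1 <- "AAAACCCC"
  e2 <- "GGGGTTTT"
  mk <- function(parent, off, tf) {
    ref <- substr(parent, off + 1, off + 1)
    tv <- c(A = "C", C = "A", T = "G", G = "T")
    element_variant(paste0("m", tf), parent,
                    edits = data.frame(offset = off, ref = ref,
                                       alt = unname(tv[ref])),
                    category = "motif_mutant_e1", tf = tf)
  }
  # GATA mutated in both sub-elements, KLF only in e1
  e1v <- list(mk(e1, 0, "GATA"), mk(e1, 4, "KLF"))
  e2v <- list(mk(e2, 1, "GATA"))
  out <- mix_and_match(e1v, e2v)
  cats <- vapply(out, `[[`, "", "category")
  expect_equal(sum(cats == "control"), 1L)            # WT reference
  expect_equal(sum(cats == "motif_mutant_e1"), 2L)
  expect_equal(sum(cats == "motif_mutant_e2"), 1L)
  expect_equal(sum(cats == "motif_mutant_both"), 1L)  # GATA only
  # double carries both edits at shifted e2 offsets
  dbl <- out[[which(cats == "motif_mutant_both")]]
  expect_equal(dbl$edits$offset, c(0L, nchar(e1) + 1L))
  expect_identical(dbl$sequence, apply_variant(dbl$parent, dbl$edits))
})

test_that("mix-and-match counts match a brute-force enumeration over random TF sets", {
  set.seed(4)
  tv <- c(A = "C", C = "A", T = "G", G = "T")
  mk <- function(parent, tf) {
    element_variant(paste0("m", tf), parent,
                    edits = data.frame(offset = 0,
                                       ref = substr(parent, 1, 1),
                                       alt = unname(tv[substr(parent, 1, 1)])),
                    tf = tf)
  }
  for (i in 1:5) {
    tfs1 <- sample(LETTERS, sample(3:8, 1))
    tfs2 <- sample(LETTERS, sample(3:8, 1))
    out <- mix_and_match(lapply(tfs1, mk, parent = "ACGTACGT"),
                         lapply(tfs2, mk, parent = "TTTTAAAA"))
    # oracle: per TF, one variant per mutated side plus one double when shared
    expected <- 1L + length(tfs1) + length(tfs2) +
      length(intersect(tfs1, tfs2))
    expect_length(out, expected)
  }
})

test_that("barcode assignment is unique, Hamming-separated and seed-deterministic", {
  vars <- lapply(sprintf("el%02d", 1:83), function(id) element_variant(id, "ACGT"))
  man <- assign_barcodes(vars, n_per_variant = 4, seed = 17)
  bcs <- man$barcode_map$barcode
  expect_equal(length(bcs), 332L)
  expect_false(anyDuplicated(bcs) > 0)
  expect_true(all(nchar(bcs) == 8))
  # pairwise Hamming >= 2 on a sample of pairs
  idx <- t(combn(sample(length(bcs), 25), 2))
  d <- apply(idx, 1, function(p) {
    sum(strsplit(bcs[p[1]], "")[[1]] != strsplit(bcs[p[2]], "")[[1]])
  })
  expect_true(all(d >= 2))

  man2 <- assign_barcodes(vars, n_per_variant = 4, seed = 17)
  expect_identical(man$barcode_map, man2$barcode_map)

  expect_error(assign_barcodes(vars, n_per_variant = 0), ">= 1")
  expect_error(assign_barcodes(vars, n_per_variant = 4, length = 2),
               "exhausted")
})

test_that("manifests validate on creation and on load", {
  man <- toy_manifest()
  path <- tempfile(fileext = ".tsv")
  write_manifest(man, path)
  man2 <- read_manifest(path)
  expect_identical(man2$barcode_map[order(man2$barcode_map$barcode), ],
                   man$barcode_map[order(man$barcode_map$barcode), ])

  # corrupt the file: duplicate barcode
  tab <- read.delim(path, colClasses = "character")
  tab$barcode[2] <- tab$barcode[1]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(path), "unique")

  # corrupt the file: wrong length
  tab$barcode[2] <- "ACGT"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(path), "8 nt")
})
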