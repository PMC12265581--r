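# shared in-code fixtures for the suite; everything is generated at test time

toy_manifest <- function(n_elements = 3, n_per_variant = 2, seed = 42) {
  ids <- sprintf("element_%03d", seq_len(n_elements))
  vars <- lapply(ids, function(id) element_variant(id, parent = "ACGT"))
  assign_barcodes(vars, n_per_variant = n_per_variant, seed = seed)
}

# write a FASTQ with explicit sequences and per-read quality strings
write_test_fastq <- function(path, seqs, quals = strrep("I", nchar(seqs))) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, sprintf("@read%03d", i), seqs[i], "+", quals[i])
  }
  writeLines(lines, path)
  path
}

# a read whose bases 23-30 are `barcode`, with the package's layout
layout_read <- function(barcode) {
  paste0(strrep("T", 22), barcode, strrep("A", 10))
}

# brute-force reconstruction used as an oracle for strand-aware motif edits
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# a small screen run under fixed conditions, reused across scoring tests
small_screen <- function(expr = c(-3, -2, -1, 0), cv = 0.3,
                         cells = 400, reads = 100, seed = 7) {
  cfg <- sim_config(length(expr), expr, barcodes_per_element = 2, n_bins = 4,
                    cells_per_barcode = cells,
                    reads_per_barcode_expected = reads,
                    noise_cv = cv, seed = seed)
  run_screen(cfg)
}
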