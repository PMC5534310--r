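# Independent oracles and small fixture builders shared across test files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Brute-force affine-gap local alignment (Gotoh) in plain R, score only.
# Deliberately independent of the package's C++ implementation: dense
# matrices, no banding, no traceback. Gap of length k costs go + k * ge.
oracle_local_score <- function(q, t, match = 1, mismatch = 1, go = 1, ge = 1) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  m <- length(qs); n <- length(ts)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      s <- if (qs[i - 1] == ts[j - 1] && qs[i - 1] != "N") match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  as.integer(best)
}

# Small FASTA/GFF3 writers for loader tests (text built by hand on purpose,
# so the package's own writers are not in the loop).
write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

make_records <- function(seqs, ids = sprintf("rec%02d", seq_along(seqs)),
                         species = NA_character_) {
  data.frame(record_id = ids, seq = seqs, length = nchar(seqs),
             species = species)
}

table1_bc01F <- "GGTGCTGAAGAAAGTTGTCGGTGTCTTTGTGTTAACCTAGAGTTTGATCMTGGCTCAG"
table1_bc01R <- "GGTGCTGAAGAAAGTTGTCGGTGTCTTTGTGTTAACCTACCGCCCCAGTHAAACT"
table1_bc08F <- "GGTGCTGTTCAGGGAACAAACCAAGTTACGTTTAACCTAGAGTTTGATCMTGGCTCAG"
table1_bc08R <- "GGTGCTGTTCAGGGAACAAACCAAGTTACGTTTAACCTACCGCCCCAGTHAAACT"

package_specs <- function() {
  read_barcode_specs(system.file("extdata", "barcodes_minion.tsv",
                                 package = "rrnprofile", mustWork = TRUE))
}
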