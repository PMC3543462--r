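# In-code fixtures shared across test files.

# A tiny conflict-free reference set: two clades of Acantharia plus an
# outgroup, 40 bp each.
tiny_reference_set <- function() {
  reference_set(
    ids = c("refA1", "refA2", "refC3", "refC4", "hapto1"),
    sequences = c(
      refA1 = "ACGTACGTACGTACGTACGTTTTTACGTACGTACGTACGT",
      refA2 = "ACGTACGTACGTACGTACGTTTTAACGTACGTACGTACGT",
      refC3 = "TTGCATGCATGCATGCATGCAAAATTGCATGCATGCATGC",
      refC4 = "TTGCATGCATGCATGCATGCAAATTTGCATGCATGCATGC",
      hapto1 = "GGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCC"
    ),
    lineages = list(
      c("Acantharea", "Holacanthida", "CladeA"),
      c("Acantharea", "Holacanthida", "CladeA"),
      c("Acantharea", "Chaunacanthida", "CladeC", "C3"),
      c("Acantharea", "Chaunacanthida", "CladeC", "C4"),
      c("Haptophyta", "Prymnesiophyceae")
    ),
    name = "tiny"
  )
}

# Write a reference set to temp FASTA/TSV; returns the two paths.
tiny_reference_files <- function(set = tiny_reference_set()) {
  fa <- tempfile(fileext = ".fasta")
  tx <- tempfile(fileext = ".tsv")
  write_reference_set(set, fa, tx)
  c(fasta = fa, taxonomy = tx)
}

# A read-set tibble built from explicit sequences with uniform quality q.
make_reads <- function(sequences, q = 40L, ids = NULL) {
  ids <- ids %||% sprintf("r%03d", seq_along(sequences))
  tibble::tibble(
    id = ids,
    sequence = sequences,
    qualities = lapply(nchar(sequences), function(n) rep(as.integer(q), n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap an insert in the default (instantiated) primers so it passes the
# default qc_config() primer rule.
with_primers <- function(insert, cfg = qc_config()) {
  # instantiate degenerate positions to their first compatible base, as the
  # read simulator does, then reverse-complement the 3' primer
  inst <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(vapply(chars, function(c) {
      substr(Biostrings::IUPAC_CODE_MAP[[c]], 1L, 1L)
    }, character(1)), collapse = "")
  }
  rev3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(inst(cfg$rev_primer))))
  paste0(inst(cfg$fwd_primer), insert, rev3)
}
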