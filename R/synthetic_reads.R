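# Seeded simulators for clade-structured reference databases and
# error-bearing, quality-scored amplicon reads with machine-readable truth.

#' Configuration for the amplicon simulator
#'
#' Defaults emulate a V9 18S rRNA amplicon survey of Acantharia: short
#' (~130 bp) hypervariable inserts flanked by the general-eukaryote V9
#' primers 1389F/1510R, a handful of well-separated molecular clades, and a
#' substitution-only sequencing error model in which miscalled bases carry a
#' low Phred score.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_clades number of clades.
#' @param refs_per_clade reference sequences per clade.
#' @param ref_length reference (insert) length in bp.
#' @param between_clade_divergence substitution fraction separating each clade
#'   ancestor from the shared root sequence.
#' @param within_clade_divergence substitution fraction separating each
#'   reference from its clade ancestor; must be below
#'   `between_clade_divergence`.
#' @param read_error_rate per-base substitution probability of simulated reads.
#' @param quality_model named numeric vector `c(correct = , error = )` giving
#'   the Phred score emitted for correctly read and miscalled bases.
#' @param fwd_primer,rev_primer primer sequences (IUPAC codes allowed); reads
#'   are built as `fwd_primer + insert + reverse_complement(rev_primer)`.
#' @param indel_rate optional per-base indel probability (default 0, i.e. a
#'   substitution-only error model).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_clades = 4L,
                              refs_per_clade = 5L,
                              ref_length = 130L,
                              between_clade_divergence = 0.2,
                              within_clade_divergence = 0.02,
                              read_error_rate = 0.01,
                              quality_model = c(correct = 40L, error = 20L),
                              fwd_primer = "TTGTACACACCGCCC",
                              rev_primer = "CCTTCYGCAGGTTCACCTAC",
                              indel_rate = 0) {
  if (between_clade_divergence < 0 || between_clade_divergence >= 1 ||
      within_clade_divergence < 0 || within_clade_divergence >= 1) {
    stopf("divergences must lie in [0, 1)")
  }
  if (within_clade_divergence >= between_clade_divergence &&
      between_clade_divergence > 0) {
    stopf("within_clade_divergence must be below between_clade_divergence")
  }
  if (read_error_rate < 0 || read_error_rate >= 1) {
    stopf("read_error_rate must lie in [0, 1)")
  }
  stopifnot(n_clades >= 1, refs_per_clade >= 1, ref_length >= 1,
            all(c("correct", "error") %in% names(quality_model)))
  structure(list(seed = as.integer(seed), n_clades = as.integer(n_clades),
                 refs_per_clade = as.integer(refs_per_clade),
                 ref_length = as.integer(ref_length),
                 between_clade_divergence = between_clade_divergence,
                 within_clade_divergence = within_clade_divergence,
                 read_error_rate = read_error_rate,
                 quality_model = quality_model,
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 indel_rate = indel_rate),
            class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

random_sequence <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability `rate`, always to one of
# the three other bases. Returns list(sequence, mutated = logical per base).
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(BASES, b), 1L)
    }, character(1))
  }
  list(sequence = paste(chars, collapse = ""), mutated = hit)
}

# Replace degenerate IUPAC positions by their alphabetically first compatible
# base, so simulated reads are concrete and deterministic while remaining an
# exact IUPAC match to the degenerate primer.
instantiate_primer <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) {
    substr(Biostrings::IUPAC_CODE_MAP[[c]], 1L, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a clade-structured reference database
#'
#' Draws a random root sequence, derives one ancestor per clade by mutating
#' the root at `between_clade_divergence`, and then derives each reference by
#' mutating its clade ancestor at `within_clade_divergence`. Lineages are
#' two-rank: `Acantharea;Clade<letter>`.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `refs` (a [reference_set()]) and `clade_map`
#'   (tibble `id`, `clade`).
#' @export
generate_reference_set <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  root <- random_sequence(cfg$ref_length)
  ids <- character(0); seqs <- character(0); lineages <- list()
  clade_labels <- paste0("Clade", LETTERS[seq_len(cfg$n_clades)])
  for (k in seq_len(cfg$n_clades)) {
    ancestor <- mutate_sequence(root, cfg$between_clade_divergence)$sequence
    for (r in seq_len(cfg$refs_per_clade)) {
      id <- sprintf("%s_ref%d", clade_labels[k], r)
      ids <- c(ids, id)
      seqs <- c(seqs, mutate_sequence(ancestor,
                                      cfg$within_clade_divergence)$sequence)
      lineages <- c(lineages, list(c("Acantharea", clade_labels[k])))
    }
  }
  refs <- reference_set(ids, seqs, lineages, name = "simulated-acantharia-v9")
  clade_map <- tibble::tibble(
    id = ids,
    clade = rep(clade_labels, each = cfg$refs_per_clade)
  )
  list(refs = refs, clade_map = clade_map)
}

#' Simulate quality-scored reads with known truth
#'
#' Each read is `fwd_primer + mutated reference + reverse_complement(rev_primer)`
#' (degenerate primer positions instantiated to their first compatible base).
#' Bases altered by the error model receive the `error` Phred score of the
#' quality model, all others the `correct` score; primer bases are error-free.
#'
#' @param refs a [reference_set()] to draw source sequences from.
#' @param n_reads number of reads.
#' @param cfg a [simulation_config()].
#' @return A list with `reads` (read-set tibble, see [read_fastq()]) and
#'   `truth` (tibble `read_id`, `source_ref`, `lineage`).
#' @export
simulate_reads <- function(refs, n_reads, cfg) {
  stopifnot(inherits(refs, "reference_set"), inherits(cfg, "simulation_config"))
  if (n_reads <= 0L) stopf("n_reads must be positive")
  # independent stream from the reference draw so refs+reads can share a cfg
  set.seed(cfg$seed + 1L)
  fwd <- instantiate_primer(cfg$fwd_primer)
  rev3 <- revcomp(instantiate_primer(cfg$rev_primer))
  q_ok <- as.integer(cfg$quality_model[["correct"]])
  q_err <- as.integer(cfg$quality_model[["error"]])
  src <- sample(refs$ids, n_reads, replace = TRUE)
  ids <- sprintf("read%05d", seq_len(n_reads))
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    mut <- mutate_sequence(refs$sequences[[src[i]]], cfg$read_error_rate)
    insert_q <- ifelse(mut$mutated, q_err, q_ok)
    seqs[i] <- paste0(fwd, mut$sequence, rev3)
    quals[[i]] <- as.integer(c(rep(q_ok, nchar(fwd)), insert_q,
                               rep(q_ok, nchar(rev3))))
  }
  reads <- tibble::tibble(id = ids, sequence = seqs, qualities = quals)
  truth <- tibble::tibble(
    read_id = ids,
    source_ref = src,
    lineage = vapply(refs$lineages[src], paste, character(1), collapse = ";")
  )
  list(reads = reads, truth = truth)
}

#' Write simulated reads and their truth sidecar
#'
#' @param sim result of [simulate_reads()].
#' @param fastq_path,truth_path output paths (FASTQ and TSV).
#' @return Invisibly, the two paths.
#' @export
write_simulated_reads <- function(sim, fastq_path, truth_path) {
  write_fastq(sim$reads, fastq_path)
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fastq = fastq_path, truth = truth_path))
}
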