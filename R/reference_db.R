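#' Build a clade-annotated reference set
#'
#' A reference set binds nucleotide sequences (typically V9 18S rRNA
#' fragments) to ranked taxonomic lineages. Sequences are upper-cased and RNA
#' `U` is normalised to `T` on construction, since rRNA references mix both
#' conventions.
#'
#' @param ids character vector of unique record identifiers.
#' @param sequences character vector of nucleotide sequences (IUPAC codes
#'   allowed), same length as `ids`.
#' @param lineages list of character vectors, each a root-first lineage such
#'   as `c("Acantharea", "Holacanthida", "CladeB", "B1")`. Labels must not
#'   contain the `";"` delimiter.
#' @param name optional name for the set.
#' @return An object of class `reference_set`: a list with elements `name`,
#'   `ids`, `sequences` (named by id) and `lineages` (named list).
#' @seealso [load_reference_set()], [lca()]
#' @export
reference_set <- function(ids, sequences, lineages, name = "reference_set") {
  if (length(ids) < 1L) stopf("a reference set needs at least one record")
  if (anyDuplicated(ids)) {
    stopf("duplicate reference id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(sequences) != length(ids) || length(lineages) != length(ids)) {
    stopf("ids, sequences and lineages must have equal length")
  }
  sequences <- chartr("u", "t", sequences)
  sequences <- toupper(sequences)
  sequences <- chartr("U", "T", sequences)
  if (any(nchar(sequences) < 1L)) stopf("empty reference sequence")
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", sequences)
  if (any(bad)) {
    stopf("non-nucleotide characters in sequence(s): %s",
          paste(ids[bad], collapse = ", "))
  }
  lineages <- lapply(lineages, validate_lineage)
  names(sequences) <- ids
  names(lineages) <- ids
  structure(list(name = name, ids = ids, sequences = sequences,
                 lineages = lineages),
            class = "reference_set")
}

validate_lineage <- function(ranks) {
  ranks <- as.character(ranks)
  if (length(ranks) < 1L || any(!nzchar(ranks))) {
    stopf("lineage must be a non-empty vector of non-empty labels")
  }
  if (any(grepl(";", ranks, fixed = TRUE))) {
    stopf("lineage labels must not contain ';'")
  }
  ranks
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set '%s': %d records, %d distinct lineages>\n",
              x$name, length(x$ids), length(unique(lineage_strings(x)))))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$ids)

lineage_strings <- function(set) {
  vapply(set$lineages, paste, character(1), collapse = ";")
}

parse_lineage <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]

#' Load a reference set from FASTA plus taxonomy TSV
#'
#' The taxonomy file is a headerless two-column TSV, `id<TAB>lineage`, with
#' the lineage a semicolon-delimited root-first rank string (the de-facto
#' amplicon-reference convention). Every FASTA id must appear exactly once in
#' the taxonomy file.
#'
#' @param fasta_path path to the reference FASTA.
#' @param taxonomy_path path to the taxonomy TSV.
#' @param name name for the resulting set (default: FASTA file name).
#' @return A [reference_set()].
#' @export
load_reference_set <- function(fasta_path, taxonomy_path,
                               name = basename(fasta_path)) {
  if (!file.exists(fasta_path)) stopf("FASTA not found: %s", fasta_path)
  if (!file.exists(taxonomy_path)) stopf("taxonomy not found: %s", taxonomy_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stopf("empty FASTA: %s", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, header = FALSE, sep = "\t",
                    col.names = c("id", "lineage"),
                    colClasses = "character", quote = "")
  if (nrow(tax) == 0L) stopf("empty taxonomy file: %s", taxonomy_path)
  if (anyDuplicated(tax$id)) {
    stopf("duplicate taxonomy id(s): %s",
          paste(unique(tax$id[duplicated(tax$id)]), collapse = ", "))
  }
  missing <- setdiff(ids, tax$id)
  if (length(missing)) {
    stopf("FASTA id(s) absent from taxonomy: %s",
          paste(missing, collapse = ", "))
  }
  lineages <- lapply(tax$lineage[match(ids, tax$id)], parse_lineage)
  reference_set(ids, as.character(seqs), lineages, name = name)
}

#' Write a reference set to FASTA plus taxonomy TSV
#'
#' @param set a [reference_set()].
#' @param fasta_path,taxonomy_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_set <- function(set, fasta_path, taxonomy_path) {
  stopifnot(inherits(set, "reference_set"))
  dna <- Biostrings::DNAStringSet(set$sequences)
  names(dna) <- set$ids
  Biostrings::writeXStringSet(dna, fasta_path)
  write.table(data.frame(id = set$ids, lineage = lineage_strings(set)),
              taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta_path, taxonomy = taxonomy_path))
}

#' Last common ancestor of taxonomic lineages
#'
#' Returns the longest root-first common prefix of the given lineages; this is
#' the lineage given to a read whose nearest reference neighbours tie at equal
#' identity. If the lineages share no rank at all the designated root lineage
#' `"Unassigned-root"` is returned.
#'
#' @param lineages a list of character vectors (root-first lineages); a single
#'   character vector is treated as one lineage.
#' @return A character vector, the common-prefix lineage.
#' @examples
#' lca(list(c("Acantharea", "Chaunacanthida", "CladeC", "C3"),
#'          c("Acantharea", "Chaunacanthida", "CladeC", "C4")))
#' @export
lca <- function(lineages) {
  if (is.character(lineages)) lineages <- list(lineages)
  if (length(lineages) == 0L) stopf("lca needs at least one lineage")
  lineages <- lapply(lineages, validate_lineage)
  prefix <- lineages[[1]]
  for (ln in lineages[-1]) {
    k <- 0L
    upto <- min(length(prefix), length(ln))
    while (k < upto && prefix[k + 1L] == ln[k + 1L]) k <- k + 1L
    prefix <- prefix[seq_len(k)]
    if (k == 0L) break
  }
  if (length(prefix) == 0L) "Unassigned-root" else prefix
}

#' Validate the taxonomy of a reference set
#'
#' Report-only check of a loaded reference set: lineage depth distribution,
#' per-clade record counts at a given rank, and rank-label conflicts (the same
#' label appearing under different parents, which would make clade-level
#' summaries ambiguous).
#'
#' @param set a [reference_set()].
#' @param clade_rank lineage rank (1-based) at which clades are counted
#'   (default 2, i.e. the level below the class label).
#' @return A list with elements `n_records`, `depth_distribution`,
#'   `clade_counts` and `conflicts` (data frame of label/parent pairs; zero
#'   rows when the taxonomy is consistent).
#' @export
validate_taxonomy <- function(set, clade_rank = 2L) {
  stopifnot(inherits(set, "reference_set"))
  depths <- lengths(set$lineages)
  clades <- vapply(set$lineages, function(l) {
    if (length(l) >= clade_rank) l[clade_rank] else NA_character_
  }, character(1))
  pairs <- do.call(rbind, lapply(set$lineages, function(l) {
    if (length(l) < 2L) return(NULL)
    data.frame(label = l[-1], parent = l[-length(l)])
  }))
  conflicts <- data.frame(label = character(0), parents = character(0))
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    dup <- pairs$label[duplicated(pairs$label)]
    if (length(dup)) {
      conflicts <- do.call(rbind, lapply(unique(dup), function(lb) {
        data.frame(label = lb,
                   parents = paste(sort(pairs$parent[pairs$label == lb]),
                                   collapse = ","))
      }))
    }
  }
  list(n_records = length(set$ids),
       depth_distribution = table(depths),
       clade_counts = table(clades[!is.na(clades)]),
       conflicts = conflicts)
}
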