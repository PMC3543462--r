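# FASTQ (Phred+33) I/O. A read set is a tibble with columns
#   id        character
#   sequence  character
#   qualities list of integer vectors, one Phred score per base

#' Read a Phred+33 FASTQ file into a read-set tibble
#'
#' @param path FASTQ path.
#' @return A tibble with columns `id`, `sequence` and `qualities` (list
#'   column of integer Phred scores, one per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- S4Vectors::mcols(x)$qualities
  qlist <- as(Biostrings::PhredQuality(quals), "IntegerList")
  tibble::tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    qualities = as.list(qlist)
  )
}

#' Write a read-set tibble to a Phred+33 FASTQ file
#'
#' @param reads read-set tibble (see [read_fastq()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  check_read_set(reads)
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  qual <- Biostrings::PhredQuality(
    vapply(reads$qualities, function(q) {
      rawToChar(as.raw(as.integer(q) + 33L))
    }, character(1))
  )
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

check_read_set <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "qualities") %in% names(reads)))
  len_ok <- mapply(function(s, q) nchar(s) == length(q),
                   reads$sequence, reads$qualities)
  if (length(len_ok) && !all(len_ok)) {
    stopf("sequence/quality length mismatch in read(s): %s",
          paste(reads$id[!len_ok], collapse = ", "))
  }
  invisible(reads)
}
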