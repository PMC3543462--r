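# Read-retention rules for V9 amplicon reads: exact primer matching/trimming
# and the sliding 50-bp expected-error window filter.

#' Quality-control configuration
#'
#' @param fwd_primer,rev_primer primer sequences, IUPAC degeneracy allowed
#'   (defaults: the general-eukaryote V9 primers 1389F/1510R). The forward
#'   primer must match at the 5' end of the read and the reverse complement of
#'   the reverse primer at the 3' end, exactly.
#' @param window_length length in bp of the sliding quality window.
#' @param max_window_error maximum tolerated mean per-base error probability
#'   in any window; a read fails when any window mean is strictly greater.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(fwd_primer = "TTGTACACACCGCCC",
                      rev_primer = "CCTTCYGCAGGTTCACCTAC",
                      window_length = 50L,
                      max_window_error = 0.01) {
  stopifnot(window_length >= 1L,
            max_window_error > 0, max_window_error < 1)
  structure(list(fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 window_length = as.integer(window_length),
                 max_window_error = max_window_error),
            class = "qc_config")
}

#' Match and trim primers from a read
#'
#' Requires an exact forward-primer match at position 1 and an exact match of
#' the reverse complement of the reverse primer at the 3' end. IUPAC
#' degeneracy is honoured in the primer only: an `N` (or other ambiguity
#' code) in the read matches nothing. On success both primer spans and their
#' quality scores are removed.
#'
#' @param read one-row read-set tibble, or a list with `id`, `sequence`,
#'   `qualities`.
#' @param cfg a [qc_config()].
#' @return A list: `ok` (logical), and either the trimmed `read` or a
#'   rejection `reason` (`"too-short"`, `"no-fwd-primer"`, `"no-rev-primer"`).
#' @export
primer_match_and_trim <- function(read, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  seq <- read$sequence[[1]]
  qual <- read$qualities[[1]]
  n <- nchar(seq)
  fwd <- strsplit(cfg$fwd_primer, "", fixed = TRUE)[[1]]
  rev3 <- strsplit(revcomp(cfg$rev_primer), "", fixed = TRUE)[[1]]
  if (n < length(fwd) + length(rev3) + 1L) {
    return(list(ok = FALSE, reason = "too-short"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!iupac_match_at(chars, fwd, 1L)) {
    return(list(ok = FALSE, reason = "no-fwd-primer"))
  }
  if (!iupac_match_at(chars, rev3, n - length(rev3) + 1L)) {
    return(list(ok = FALSE, reason = "no-rev-primer"))
  }
  keep <- (length(fwd) + 1L):(n - length(rev3))
  list(ok = TRUE,
       read = list(id = read$id[[1]],
                   sequence = paste(chars[keep], collapse = ""),
                   qualities = as.integer(qual[keep])))
}

#' Sliding-window expected-error filter
#'
#' Converts each Phred score to an error probability `p = 10^(-Q/10)` and
#' computes the mean probability over every window of `window_length`
#' consecutive bases (step 1). The read fails when any window mean is
#' strictly greater than `max_window_error`; a window mean exactly at the
#' limit passes. Reads shorter than the window length are evaluated as a
#' single full-length window.
#'
#' @param read list or one-row tibble with `qualities`.
#' @param cfg a [qc_config()].
#' @return A list: `ok` (logical), `worst_window_error` (numeric), and
#'   `reason` (`"window"` or `"empty"`) when failing.
#' @export
window_error_filter <- function(read, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  qual <- as.numeric(read$qualities[[1]])
  if (length(qual) == 0L) {
    return(list(ok = FALSE, reason = "empty", worst_window_error = NA_real_))
  }
  p <- 10^(-qual / 10)
  w <- min(cfg$window_length, length(p))
  cs <- c(0, cumsum(p))
  starts <- seq_len(length(p) - w + 1L)
  means <- (cs[starts + w] - cs[starts]) / w
  worst <- max(means)
  # 1e-12 guard keeps a window sitting exactly at the limit (e.g. every base
  # at p = 0.01) on the passing side despite floating-point summation
  ok <- !(worst - cfg$max_window_error > 1e-12)
  if (ok) list(ok = TRUE, worst_window_error = worst)
  else list(ok = FALSE, reason = "window", worst_window_error = worst)
}

#' Run the full quality-control stage over a read set
#'
#' Applies the primer rule, then the window rule; the chimera check is an
#' explicit no-op hook (`chimera_filter`) so the stage structure mirrors a
#' complete amplicon pipeline. Rejection counts partition the input exactly.
#'
#' @param reads read-set tibble (see [read_fastq()]).
#' @param cfg a [qc_config()].
#' @param chimera_filter optional function `(reads) -> logical vector` marking
#'   reads to keep; the default keeps everything (chimera detection is out of
#'   scope for this package).
#' @return A list with `retained` (trimmed read-set tibble) and `counts`
#'   (named integer vector: `retained`, `too-short`, `no-fwd-primer`,
#'   `no-rev-primer`, `window`, `empty`, `chimera`).
#' @export
run_qc <- function(reads, cfg = qc_config(), chimera_filter = NULL) {
  check_read_set(reads)
  reasons <- c("too-short", "no-fwd-primer", "no-rev-primer",
               "window", "empty", "chimera")
  counts <- setNames(integer(length(reasons) + 1L), c("retained", reasons))
  kept <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    row <- list(id = reads$id[i], sequence = reads$sequence[i],
                qualities = reads$qualities[i])
    pm <- primer_match_and_trim(row, cfg)
    if (!pm$ok) {
      counts[pm$reason] <- counts[pm$reason] + 1L
      next
    }
    wf <- window_error_filter(list(qualities = list(pm$read$qualities)), cfg)
    if (!wf$ok) {
      counts[wf$reason] <- counts[wf$reason] + 1L
      next
    }
    kept[[i]] <- pm$read
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  retained <- tibble::tibble(
    id = vapply(kept, `[[`, character(1), "id"),
    sequence = vapply(kept, `[[`, character(1), "sequence"),
    qualities = lapply(kept, `[[`, "qualities")
  )
  if (!is.null(chimera_filter) && nrow(retained) > 0) {
    keep <- chimera_filter(retained)
    counts["chimera"] <- sum(!keep)
    retained <- retained[keep, , drop = FALSE]
  }
  counts["retained"] <- nrow(retained)
  list(retained = retained, counts = counts)
}
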