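# Taxonomic assignment by optimal global pairwise alignment: every retained
# read is aligned end-to-end against every reference sequence; the read takes
# the lineage of its nearest neighbour by percent identity, or the last common
# ancestor of all tied nearest neighbours.

#' Affine-gap scoring scheme for global DNA alignment
#'
#' A gap of length L costs `gap_open + L * gap_extend`. The defaults
#' (+5 / -4 / -12 / -2) are common DNA global-search parameters; all four are
#' configurable.
#'
#' @param match match score (> mismatch).
#' @param mismatch mismatch score.
#' @param gap_open,gap_extend gap penalties (<= 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4,
                           gap_open = -12, gap_extend = -2) {
  if (match <= mismatch) stopf("match score must exceed mismatch score")
  if (gap_open > 0 || gap_extend > 0) stopf("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch / Gotoh alignment: end-to-end, terminal gaps penalized,
#' affine gap costs. Ties in score are resolved deterministically: among
#' co-optimal alignments the one with the most matching columns (then the
#' fewest columns, then diagonal over up over left) is returned, so the
#' reported identity is unique, symmetric in the two sequences, and
#' reproducible byte for byte. A column counts as a match only when both
#' symbols are the same unambiguous A/C/G/T; `N` and gap columns never match
#' but always count as columns.
#'
#' @param query,ref nucleotide strings over A/C/G/T/N (non-empty).
#' @param scoring a [scoring_scheme()].
#' @return A list of class `pairwise_alignment`: `aligned_query`,
#'   `aligned_ref`, `score`, `n_matches`, `n_columns`, `identity`
#'   (= n_matches / n_columns).
#' @export
global_align <- function(query, ref, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  if (!nzchar(query) || !nzchar(ref)) stopf("sequences must be non-empty")
  res <- .nw_align_cpp(toupper(query), toupper(ref),
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  res$identity <- res$n_matches / res$n_columns
  class(res) <- "pairwise_alignment"
  res
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<global alignment: score %g, identity %d/%d = %.4f>\n",
              x$score, x$n_matches, x$n_columns, x$identity))
  cat(x$aligned_query, "\n")
  cat(x$aligned_ref, "\n")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' `n_matches / n_columns` over all alignment columns, counting a column as a
#' match only when both symbols are the same unambiguous nucleotide; columns
#' containing `N` or a gap enter the denominator only.
#'
#' @param aln a [global_align()] result.
#' @return The identity as a fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$n_columns == 0) stopf("alignment has zero columns")
  aln$n_matches / aln$n_columns
}

# Align one query against all references; returns the batch stats matrix.
align_to_refs <- function(sequence, refs, scoring) {
  .nw_batch_cpp(toupper(sequence), unname(refs$sequences),
                scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_extend)
}

#' Assign one read to the reference database
#'
#' Aligns the read to every reference, ranks references by percent identity
#' (compared as exact rationals, so ties are detected without floating-point
#' artifacts), and assigns the lineage of the single nearest neighbour or the
#' last common ancestor of all tied nearest neighbours. Reads whose best
#' identity is not strictly greater than the threshold are
#' `unassigned-below-threshold` ("more than 85% identity" is required).
#'
#' @param sequence read sequence (primer-trimmed).
#' @param refs a [reference_set()].
#' @param scoring a [scoring_scheme()].
#' @param threshold identity threshold (default 0.85, strict "more than").
#' @return A list: `best_identity`, `n_matches`, `n_columns`,
#'   `tied_ref_ids`, `lineage` (character vector), `status`.
#' @export
assign_read <- function(sequence, refs, scoring = scoring_scheme(),
                        threshold = 0.85) {
  stopifnot(inherits(refs, "reference_set"))
  stats <- align_to_refs(sequence, refs, scoring)
  m <- unname(stats[, "n_matches"])
  cl <- unname(stats[, "n_columns"])
  best <- 1L
  for (i in seq_along(m)[-1]) {
    if (m[i] * cl[best] > m[best] * cl[i]) best <- i
  }
  tied <- which(vapply(seq_along(m), function(i) {
    frac_equal(m[i], cl[i], m[best], cl[best])
  }, logical(1)))
  tied_ids <- refs$ids[tied]
  lineage <- if (length(tied) == 1L) {
    refs$lineages[[tied]]
  } else {
    lca(refs$lineages[tied])
  }
  assigned <- frac_gt_threshold(m[best], cl[best], threshold)
  list(best_identity = m[best] / cl[best],
       n_matches = as.integer(m[best]),
       n_columns = as.integer(cl[best]),
       tied_ref_ids = tied_ids,
       lineage = lineage,
       status = if (assigned) "assigned" else "unassigned-below-threshold")
}

#' Assign a whole read set
#'
#' @param reads read-set tibble (see [read_fastq()]), typically the retained
#'   output of [run_qc()].
#' @param refs a [reference_set()].
#' @param scoring a [scoring_scheme()].
#' @param threshold identity threshold (strict "more than").
#' @return A tibble with one row per read: `read_id`, `best_identity`,
#'   `n_matches`, `n_columns`, `tied_ref_ids` (comma-separated), `lineage`
#'   (semicolon-joined), `status`.
#' @export
assign_reads <- function(reads, refs, scoring = scoring_scheme(),
                         threshold = 0.85) {
  check_read_set(reads)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    a <- assign_read(reads$sequence[i], refs, scoring, threshold)
    tibble::tibble(read_id = reads$id[i],
                   best_identity = a$best_identity,
                   n_matches = a$n_matches,
                   n_columns = a$n_columns,
                   tied_ref_ids = paste(a$tied_ref_ids, collapse = ","),
                   lineage = paste(a$lineage, collapse = ";"),
                   status = a$status)
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(read_id = character(), best_identity = numeric(),
                          n_matches = integer(), n_columns = integer(),
                          tied_ref_ids = character(), lineage = character(),
                          status = character()))
  }
  dplyr::bind_rows(rows)
}

#' Screen reads for similarity to cyst reference sequences
#'
#' Retains reads whose identity to at least one named cyst reference is
#' strictly greater than the threshold (default 0.97), and counts retained
#' reads per cyst reference. A read above threshold for several cyst
#' references is counted for each, and retained once.
#'
#' @param reads read-set tibble.
#' @param refs a [reference_set()] containing the cyst references.
#' @param cyst_ref_ids ids of cyst reference sequences within `refs`.
#' @param scoring a [scoring_scheme()].
#' @param threshold identity threshold (default 0.97, strict).
#' @return A list with `retained` (tibble `read_id`, `best_cyst_ref`,
#'   `best_identity`) and `counts` (named integer vector per cyst id).
#' @export
filter_by_similarity <- function(reads, refs, cyst_ref_ids,
                                 scoring = scoring_scheme(),
                                 threshold = 0.97) {
  check_read_set(reads)
  stopifnot(inherits(refs, "reference_set"))
  unknown <- setdiff(cyst_ref_ids, refs$ids)
  if (length(unknown)) {
    stopf("unknown cyst reference id(s): %s", paste(unknown, collapse = ", "))
  }
  cyst_refs <- reference_set(cyst_ref_ids,
                             refs$sequences[cyst_ref_ids],
                             refs$lineages[cyst_ref_ids])
  counts <- setNames(integer(length(cyst_ref_ids)), cyst_ref_ids)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    stats <- align_to_refs(reads$sequence[i], cyst_refs, scoring)
    idty <- stats[, "n_matches"] / stats[, "n_columns"]
    hit <- vapply(seq_along(idty), function(j) {
      frac_gt_threshold(stats[j, "n_matches"], stats[j, "n_columns"],
                        threshold)
    }, logical(1))
    if (any(hit)) {
      counts[hit] <- counts[hit] + 1L
      bi <- which.max(idty)
      out[[i]] <- tibble::tibble(read_id = reads$id[i],
                                 best_cyst_ref = cyst_ref_ids[bi],
                                 best_identity = idty[bi])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  retained <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(read_id = character(), best_cyst_ref = character(),
                   best_identity = numeric())
  list(retained = retained, counts = counts)
}
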