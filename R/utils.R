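# Internal helpers shared across modules.

# Identity values are exact rationals n_matches/n_columns with small integer
# parts, so cross-multiplication compares them without floating-point ties.
# `frac_gt_threshold` compares such a rational against an arbitrary decimal
# threshold: near-equality (within 1e-9) is treated as equal, which implements
# the strict "more than" rule robustly because distinct read identities differ
# by at least 1/n_columns^2 >> 1e-9.
frac_gt_threshold <- function(num, den, threshold) {
  (num / den) - threshold > 1e-9
}

frac_equal <- function(num1, den1, num2, den2) {
  # exact for counts < 2^26, far beyond any alignment length used here
  num1 * den2 == num2 * den1
}

# Truncation toward zero at `digits` decimals, used only by the reporting
# layer to mirror printed tables. A 1e-9 guard absorbs representation error in
# products such as 0.23 * 0.120 so that values sitting on a decimal boundary
# truncate by their exact rational value, not by their binary neighbour.
truncate_decimals <- function(x, digits) {
  scaled <- x * 10^digits
  trunc(scaled + sign(scaled) * 1e-9) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Reverse complement for possibly IUPAC-degenerate nucleotide strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# TRUE when the (possibly degenerate) IUPAC code `code` covers the concrete
# read base `base`. Read-side N or other ambiguity codes match nothing.
iupac_base_match <- function(code, base) {
  allowed <- Biostrings::IUPAC_CODE_MAP[code]
  if (is.na(allowed) || is.na(base)) return(FALSE)
  base %in% c("A", "C", "G", "T") && grepl(base, allowed, fixed = TRUE)
}

# Vectorised: does `seq` match the degenerate `primer` at offset `start`?
iupac_match_at <- function(seq_chars, primer_chars, start) {
  idx <- seq_along(primer_chars) + start - 1L
  if (max(idx) > length(seq_chars)) return(FALSE)
  all(mapply(function(code, base) iupac_base_match(code, base),
             primer_chars, seq_chars[idx]))
}
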