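# Independent brute-force oracle for global alignment: enumerates every
# global alignment of two short sequences as a path of column operations and
# returns the maximum affine-gap score. No dynamic programming, no memoisation
# - exponential, usable only for sequences of length <= ~7.
brute_force_best_score <- function(a, b, sc = scoring_scheme()) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) sc$match else sc$mismatch
      rec(i + 1L, j + 1L, "M", acc + s)
    }
    if (i <= n) { # gap in b, consumes a
      open <- if (!identical(prev, "U")) sc$gap_open else 0
      rec(i + 1L, j, "U", acc + open + sc$gap_extend)
    }
    if (j <= m) { # gap in a, consumes b
      open <- if (!identical(prev, "L")) sc$gap_open else 0
      rec(i, j + 1L, "L", acc + open + sc$gap_extend)
    }
    invisible()
  }
  rec(1L, 1L, "S", 0)
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
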