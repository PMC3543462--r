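test_that("global alignment reproduces known scores and alignments", {
  sc <- scoring_scheme()
  a <- global_align("ACGTACGT", "ACGTACGT", sc)
  expect_equal(a$score, 40)
  expect_equal(a$n_matches, 8L)
  expect_equal(a$n_columns, 8L)
  expect_equal(percent_identity(a), 1)

  # single substitution beats any gapped alternative under the defaults
  b <- global_align("ACGT", "AGGT", sc)
  expect_equal(b$score, 3 * 5 - 4)
  expect_equal(b$n_matches / b$n_columns, 3 / 4)
  expect_equal(brute_force_best_score("ACGT", "AGGT", sc), b$score)

  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment score equals the brute-force optimum on short pairs", {
  sc <- scoring_scheme()
  set.seed(13)
  for (i in 1:60) {
    x <- random_dna(sample(1:6, 1))
    y <- random_dna(sample(1:6, 1))
    expect_equal(global_align(x, y, sc)$score, brute_force_best_score(x, y, sc),
                 info = paste(x, y))
  }
  # also under an alternative scoring scheme
  sc2 <- scoring_scheme(match = 2, mismatch = -3, gap_open = -5,
                        gap_extend = -1)
  for (i in 1:20) {
    x <- random_dna(sample(1:6, 1))
    y <- random_dna(sample(1:6, 1))
    expect_equal(global_align(x, y, sc2)$score,
                 brute_force_best_score(x, y, sc2), info = paste(x, y))
  }
})

test_that("alignment score matches an independent affine-gap implementation", {
  # Biostrings uses the same gap convention (open + L * extend)
  mat <- matrix(-4, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat) <- 5
  mat["N", "N"] <- -4 # N never matches
  set.seed(29)
  for (i in 1:25) {
    x <- random_dna(sample(20:80, 1))
    y <- random_dna(sample(20:80, 1))
    s_ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, type = "global", substitutionMatrix = mat,
      gapOpening = 12, gapExtension = 2))
    expect_equal(global_align(x, y)$score, s_ref, info = paste(x, y))
  }
})

test_that("identity counts matches over all columns, N and gaps excluded", {
  # forced gap: query shorter than ref
  aln <- global_align("ACGT", "ACAGT")
  expect_equal(aln$n_columns, 5L)
  expect_equal(aln$n_matches, 4L)
  expect_equal(percent_identity(aln), 0.8)
  expect_equal(nchar(aln$aligned_query), nchar(aln$aligned_ref))
  # no gap-vs-gap column
  qg <- strsplit(aln$aligned_query, "")[[1]] == "-"
  rg <- strsplit(aln$aligned_ref, "")[[1]] == "-"
  expect_false(any(qg & rg))

  # one N column among ten otherwise matching columns counts in the
  # denominator only
  alnN <- global_align("ACGTNACGTA", "ACGTTACGTA")
  expect_equal(alnN$n_columns, 10L)
  expect_equal(alnN$n_matches, 9L)

  # symmetry of identity under the symmetric default scoring
  set.seed(31)
  for (i in 1:15) {
    x <- random_dna(30); y <- random_dna(30)
    expect_equal(global_align(x, y)$identity, global_align(y, x)$identity)
  }
})

test_that("reads take their nearest neighbour's lineage, LCA on ties", {
  refs <- tiny_reference_set()
  # a reference sequence assigns to itself with identity 1 and no tie
  for (id in refs$ids) {
    a <- assign_read(refs$sequences[[id]], refs)
    expect_equal(a$best_identity, 1)
    expect_equal(a$tied_ref_ids, id)
    expect_equal(a$lineage, refs$lineages[[id]])
    expect_equal(a$status, "assigned")
  }

  # refC3 and refC4 differ only at position 24 (A vs T); a read carrying G
  # there is exactly equidistant -> LCA "...;CladeC"
  tie_read <- refs$sequences[["refC3"]]
  substr(tie_read, 24, 24) <- "G"
  i3 <- global_align(tie_read, refs$sequences[["refC3"]])
  i4 <- global_align(tie_read, refs$sequences[["refC4"]])
  expect_identical(c(i3$n_matches, i3$n_columns),
                   c(i4$n_matches, i4$n_columns))
  a <- assign_read(tie_read, refs)
  expect_setequal(a$tied_ref_ids, c("refC3", "refC4"))
  expect_equal(a$lineage, c("Acantharea", "Chaunacanthida", "CladeC"))
})

test_that("the 85% identity rule is strictly greater-than", {
  # 20-bp references, ungapped alignments: 17/20 = 0.85 exactly
  ref <- reference_set("r1", "ACGTACGTACGTACGTACGT",
                       list(c("Acantharea", "CladeA")))
  q17 <- "ACGTACGTACGTACGTATTG" # 3 mismatches at the tail
  a17 <- assign_read(q17, ref)
  expect_equal(a17$best_identity, 17 / 20)
  expect_equal(a17$status, "unassigned-below-threshold")
  q18 <- "ACGTACGTACGTACGTACTG" # 2 mismatches
  expect_equal(assign_read(q18, ref)$status, "assigned")

  # threshold monotonicity: raising the threshold never assigns more reads
  refs <- tiny_reference_set()
  set.seed(17)
  reads <- vapply(1:12, function(i) {
    s <- refs$sequences[[sample(length(refs$ids), 1)]]
    chars <- strsplit(s, "")[[1]]
    k <- sample(0:12, 1)
    if (k > 0) {
      pos <- sample(length(chars), k)
      chars[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1))
  n_assigned <- function(thr) {
    sum(vapply(reads, function(s) {
      assign_read(s, refs, threshold = thr)$status == "assigned"
    }, logical(1)))
  }
  counts <- vapply(c(0.5, 0.7, 0.85, 0.95, 0.99), n_assigned, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the cyst similarity screen keeps reads strictly above 97%", {
  # 100-bp cyst reference; plant 1, 2, 3 and 5 mismatches
  cyst <- strrep("ACGTTGCAGT", 10)
  refs <- reference_set(c("cyst6", "other"),
                        c(cyst, strrep("GATTACAGGG", 10)),
                        list(c("Acantharea", "CladeB", "B1"),
                             c("Acantharea", "CladeD")))
  mutate_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- if (substr(s, p, p) == "A") "C" else "A"
    s
  }
  reads <- make_reads(c(cyst,                      # 1.00 retained
                        mutate_at(cyst, 5),        # 0.99 retained
                        mutate_at(cyst, c(5, 50)), # 0.98 retained
                        mutate_at(cyst, c(5, 50, 95)),        # 0.97 excluded
                        mutate_at(cyst, c(5, 30, 50, 70, 95)) # 0.95 excluded
  ))
  res <- filter_by_similarity(reads, refs, "cyst6")
  expect_equal(nrow(res$retained), 3L)
  expect_equal(unname(res$counts["cyst6"]), 3L)
  expect_setequal(res$retained$read_id, c("r001", "r002", "r003"))

  expect_error(filter_by_similarity(reads, refs, "nope"), "unknown cyst")
})
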