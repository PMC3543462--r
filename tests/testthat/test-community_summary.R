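test_that("depth zones use half-open bins with a closed 3000 m top", {
  expect_equal(as.character(bin_by_depth_zone(50)), "0-100 m")
  expect_equal(as.character(bin_by_depth_zone(100)), "100-1000 m")
  expect_equal(as.character(bin_by_depth_zone(999.9)), "100-1000 m")
  expect_equal(as.character(bin_by_depth_zone(1000)), "1000-3000 m")
  expect_equal(as.character(bin_by_depth_zone(3000)), "1000-3000 m")
  expect_equal(as.character(bin_by_depth_zone(3000.1)), "below-3000 m")
  expect_error(bin_by_depth_zone(-1), "non-negative")
  # monotone non-decreasing in depth with respect to zone order
  depths <- sort(runif(50, 0, 5000))
  zones <- as.integer(bin_by_depth_zone(depths))
  expect_true(all(diff(zones) >= 0))
})

make_assignments <- function(clades, sample_id = "s1",
                             status = "assigned") {
  tibble::tibble(
    read_id = sprintf("%s_r%03d", sample_id, seq_along(clades)),
    best_identity = 1, n_matches = 10L, n_columns = 10L,
    tied_ref_ids = "x",
    lineage = ifelse(is.na(clades), "Acantharea",
                     paste("Acantharea", clades, sep = ";")),
    status = rep_len(status, length(clades)),
    sample_id = sample_id
  )
}

metadata_fixture <- tibble::tibble(
  sample_id = c("s1", "s2"),
  station = c("st1", "st2"),
  depth_m = c(5, 800),
  size_fraction = c("0.8-5um", "20-2000um"),
  zone = bin_by_depth_zone(c(5, 800))
)

test_that("composition fractions normalise per sample and mask by floor", {
  asn <- make_assignments(c(rep("CladeA", 50), rep("CladeB", 30),
                            rep("CladeE", 20)))
  tab <- tabulate_composition(asn, metadata_fixture)
  expect_equal(sort(tab$fraction, decreasing = TRUE), c(0.5, 0.3, 0.2))
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  expect_true(all(tab$display))

  # a clade at 0.5% stays in the data but is masked for display
  asn2 <- make_assignments(c(rep("CladeA", 199), "CladeF"))
  tab2 <- tabulate_composition(asn2, metadata_fixture)
  row_f <- tab2[tab2$clade == "CladeF", ]
  expect_equal(row_f$count, 1L)
  expect_equal(row_f$fraction, 0.005)
  expect_false(row_f$display)

  # unassigned reads are excluded from denominators, reported separately
  asn3 <- rbind(make_assignments(rep("CladeA", 8)),
                make_assignments(rep("CladeB", 2),
                                 status = "unassigned-below-threshold"))
  tab3 <- tabulate_composition(asn3, metadata_fixture)
  expect_equal(tab3$fraction, 1)
  expect_equal(attr(tab3, "n_unassigned"), 2L)

  # LCA-truncated lineages too shallow for the clade rank stay in the
  # denominator as "unresolved"
  asn4 <- make_assignments(c("CladeA", "CladeA", NA, "CladeB"))
  tab4 <- tabulate_composition(asn4, metadata_fixture)
  expect_equal(sum(tab4$fraction), 1, tolerance = 1e-12)
  expect_true("unresolved" %in% tab4$clade)

  expect_error(tabulate_composition(make_assignments("CladeA", "sX"),
                                    metadata_fixture), "absent")
})

test_that("planted clade proportions are recovered within multinomial error", {
  p <- c(CladeA = 0.6, CladeB = 0.3, CladeC = 0.1)
  n <- 2000
  set.seed(22)
  draw <- sample(names(p), n, replace = TRUE, prob = p)
  asn <- make_assignments(draw)
  tab <- tabulate_composition(asn, metadata_fixture)
  # 99% multinomial CI per clade
  for (cl in names(p)) {
    f <- tab$fraction[tab$clade == cl]
    half <- 2.58 * sqrt(p[[cl]] * (1 - p[[cl]]) / n)
    expect_lt(abs(f - p[[cl]]), half)
  }
})

test_that("zone pivot pools samples and keeps per-row normalisation", {
  asn <- rbind(make_assignments(c(rep("CladeA", 6), rep("CladeB", 4)), "s1"),
               make_assignments(c(rep("CladeI", 9), rep("CladeB", 1)), "s2"))
  tab <- tabulate_composition(asn, metadata_fixture)
  wide <- pivot_by_zone(tab)
  expect_equal(nrow(wide), 2L)
  frac_cols <- setdiff(names(wide), c("zone", "size_fraction"))
  expect_equal(unname(rowSums(wide[, frac_cols])), c(1, 1),
               tolerance = 1e-12)
  meso <- wide[wide$zone == "100-1000 m", ]
  expect_equal(meso$CladeI, 0.9)
})

test_that("fraction_of_group is plain percentage arithmetic with guards", {
  expect_equal(fraction_of_group(44, 1000), 4.4)
  expect_equal(fraction_of_group(0, 10), 0)
  expect_equal(fraction_of_group(755538, 755538 * 10), 10)
  expect_error(fraction_of_group(1, 0), "positive")
  expect_error(fraction_of_group(5, 4), "group_counts")
  # scale invariance
  expect_equal(fraction_of_group(3, 12), fraction_of_group(300, 1200))
})
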