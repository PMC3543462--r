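# Community composition summaries: clade fractions per sample, depth-zone
# binning, and the acantharian fraction of total protist reads.

ZONE_LEVELS <- c("0-100 m", "100-1000 m", "1000-3000 m", "below-3000 m")

#' Bin a sampling depth into a depth zone
#'
#' Half-open bins `[0, 100)`, `[100, 1000)`, `[1000, 3000]` (closed top) and
#' `below-3000 m` for anything deeper, matching the zones commonly used to
#' summarise vertical distributions of plankton sequences.
#'
#' @param depth_m depth in meters (vectorised, non-negative).
#' @return Factor with levels `0-100 m`, `100-1000 m`, `1000-3000 m`,
#'   `below-3000 m`.
#' @export
bin_by_depth_zone <- function(depth_m) {
  if (any(is.na(depth_m)) || any(depth_m < 0)) {
    stopf("depth_m must be non-negative")
  }
  zone <- ifelse(depth_m < 100, ZONE_LEVELS[1],
          ifelse(depth_m < 1000, ZONE_LEVELS[2],
          ifelse(depth_m <= 3000, ZONE_LEVELS[3], ZONE_LEVELS[4])))
  factor(zone, levels = ZONE_LEVELS)
}

#' Load sample metadata
#'
#' @param path CSV with columns `sample_id`, `station`, `depth_m`,
#'   `size_fraction`.
#' @return A tibble with a derived `zone` column.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata CSV not found: %s", path)
  md <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("sample_id", "station", "depth_m", "size_fraction")
  missing <- setdiff(req, names(md))
  if (length(missing)) {
    stopf("metadata lacks column(s): %s", paste(missing, collapse = ", "))
  }
  md$zone <- bin_by_depth_zone(md$depth_m)
  md
}

#' Tabulate clade composition per sample
#'
#' Counts assigned reads per (sample, clade label) where the clade label is
#' the lineage element at `clade_rank`; lineages too shallow to reach that
#' rank (e.g. LCA-assigned reads resolved only to a higher level) are grouped
#' as `"unresolved"` so per-sample fractions still sum to one. Clades whose
#' fraction falls below the display floor are masked in display output
#' (`display` column) but retained in the data. Unassigned reads are excluded
#' from the denominators and reported in the `n_unassigned` attribute.
#'
#' @param assignments tibble from [assign_reads()] with an added `sample_id`
#'   column.
#' @param metadata tibble from [read_sample_metadata()] (or equivalent).
#' @param clade_rank lineage rank holding the clade label (default 2).
#' @param display_floor fraction below which a clade is masked in display
#'   output (default 0.01).
#' @return A tibble `sample_id`, `zone`, `size_fraction`, `clade`, `count`,
#'   `fraction`, `display`.
#' @export
tabulate_composition <- function(assignments, metadata, clade_rank = 2L,
                                 display_floor = 0.01) {
  stopifnot("sample_id" %in% names(assignments))
  unknown <- setdiff(unique(assignments$sample_id), metadata$sample_id)
  if (length(unknown)) {
    stopf("sample id(s) absent from metadata: %s",
          paste(unknown, collapse = ", "))
  }
  assigned <- dplyr::filter(assignments, .data$status == "assigned")
  n_unassigned <- nrow(assignments) - nrow(assigned)
  clade_of <- function(lineage) {
    ranks <- parse_lineage(lineage)
    if (length(ranks) >= clade_rank) ranks[clade_rank] else "unresolved"
  }
  assigned$clade <- vapply(assigned$lineage, clade_of, character(1),
                           USE.NAMES = FALSE)
  out <- assigned |>
    dplyr::count(.data$sample_id, .data$clade, name = "count") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(display = .data$fraction >= display_floor) |>
    dplyr::left_join(
      dplyr::select(metadata, "sample_id", "zone", "size_fraction"),
      by = "sample_id") |>
    dplyr::select("sample_id", "zone", "size_fraction", "clade",
                  "count", "fraction", "display")
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Pivot a composition table by depth zone
#'
#' Pools counts over samples within each (zone, size fraction) and returns a
#' wide clade-by-zone table of fractions, the shape used to compare photic
#' and mesopelagic communities.
#'
#' @param composition output of [tabulate_composition()].
#' @return A wide tibble, one row per (zone, size_fraction), one column per
#'   clade.
#' @export
pivot_by_zone <- function(composition) {
  composition |>
    dplyr::group_by(.data$zone, .data$size_fraction, .data$clade) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$zone, .data$size_fraction) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select(-"count") |>
    tidyr::pivot_wider(names_from = "clade", values_from = "fraction",
                       values_fill = 0)
}

#' Percentage of a group within a total
#'
#' Used for, e.g., the acantharian share of total protist reads in a sample.
#'
#' @param group_counts reads in the group (vectorised).
#' @param total_counts total reads; must be positive and at least
#'   `group_counts`.
#' @return Percentage `100 * group / total`.
#' @export
fraction_of_group <- function(group_counts, total_counts) {
  if (any(total_counts <= 0)) stopf("total_counts must be positive")
  if (any(group_counts < 0) || any(group_counts > total_counts)) {
    stopf("group_counts must lie in [0, total_counts]")
  }
  100 * group_counts / total_counts
}
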