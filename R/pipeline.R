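# End-to-end orchestration: QC -> assignment -> community summary, plus the
# independent sediment-trap Sr flux stage, with a manifest recording input
# hashes, the effective configuration and per-stage counts.

#' Pipeline configuration
#'
#' Bundles input paths and stage parameters. Paths may be `NULL` where a
#' stage is not wanted: `metadata_csv` enables the community summary,
#' `trap_csv` the strontium flux stage.
#'
#' @param reads_fastq FASTQ of raw reads (Phred+33).
#' @param ref_fasta,taxonomy_tsv reference database files
#'   (see [load_reference_set()]).
#' @param out_dir output directory (created if absent).
#' @param metadata_csv optional sample metadata CSV
#'   (see [read_sample_metadata()]).
#' @param sample_id sample id attached to all reads in `reads_fastq` when a
#'   metadata table is supplied (single-sample FASTQ convention).
#' @param trap_csv optional trap bottle CSV (see [read_trap_series()]).
#' @param poc_csv optional CSV `bottle_id,total_poc_flux`.
#' @param qc a [qc_config()].
#' @param scoring a [scoring_scheme()].
#' @param assign_threshold identity threshold for assignment (strict).
#' @param cyst_ref_ids optional ids for the cyst-similarity screen.
#' @param cyst_threshold identity threshold of that screen (strict).
#' @param background_cutoff Sr background cutoff, ug/mL.
#' @param ratio a [c_sr_ratio()].
#' @param collection_area trap collection area, m2.
#' @param seed integer seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed matters when simulators generate the inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads_fastq, ref_fasta, taxonomy_tsv, out_dir,
                            metadata_csv = NULL, sample_id = "sample1",
                            trap_csv = NULL, poc_csv = NULL,
                            qc = qc_config(), scoring = scoring_scheme(),
                            assign_threshold = 0.85,
                            cyst_ref_ids = NULL, cyst_threshold = 0.97,
                            background_cutoff = 9, ratio = c_sr_ratio(),
                            collection_area = 0.66, seed = 1L) {
  structure(list(reads_fastq = reads_fastq, ref_fasta = ref_fasta,
                 taxonomy_tsv = taxonomy_tsv, out_dir = out_dir,
                 metadata_csv = metadata_csv, sample_id = sample_id,
                 trap_csv = trap_csv, poc_csv = poc_csv,
                 qc = qc, scoring = scoring,
                 assign_threshold = assign_threshold,
                 cyst_ref_ids = cyst_ref_ids,
                 cyst_threshold = cyst_threshold,
                 background_cutoff = background_cutoff, ratio = ratio,
                 collection_area = collection_area,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  must_exist <- c(reads = cfg$reads_fastq, references = cfg$ref_fasta,
                  taxonomy = cfg$taxonomy_tsv)
  opt <- c(metadata = cfg$metadata_csv, trap = cfg$trap_csv,
           poc = cfg$poc_csv)
  for (nm in names(must_exist)) {
    if (is.null(must_exist[[nm]]) || !file.exists(must_exist[[nm]])) {
      stopf("pipeline input '%s' missing: %s", nm,
            must_exist[[nm]] %||% "<NULL>")
    }
  }
  for (nm in names(opt)) {
    if (!is.null(opt[[nm]]) && !file.exists(opt[[nm]])) {
      stopf("pipeline input '%s' missing: %s", nm, opt[[nm]])
    }
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes QC, taxonomic assignment, the optional community summary and the
#' optional (independent) strontium flux stage, writing every stage output
#' plus a `manifest.json` with input MD5 hashes, the effective configuration
#' and per-stage record counts. Identical inputs and configuration give
#' byte-identical outputs; no timestamps are written.
#'
#' @param cfg a [pipeline_config()].
#' @param dry_run when `TRUE`, validate the configuration and return the
#'   manifest skeleton without reading data or writing outputs.
#' @return The manifest, invisibly; outputs land in `cfg$out_dir`
#'   (`qc_retained.fastq`, `qc_counts.json`, `assignments.tsv`,
#'   `composition_long.csv`, `composition_zone_pivot.csv`,
#'   `cyst_similarity.tsv`, `sr_flux.csv`, `manifest.json` as applicable).
#' @export
run_pipeline <- function(cfg, dry_run = FALSE) {
  validate_pipeline_config(cfg)
  if (dry_run) {
    return(invisible(list(config = echo_config(cfg), dry_run = TRUE)))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- load_reference_set(cfg$ref_fasta, cfg$taxonomy_tsv)
  reads <- read_fastq(cfg$reads_fastq)

  qc_res <- run_qc(reads, cfg$qc)
  write_fastq(qc_res$retained, file.path(cfg$out_dir, "qc_retained.fastq"))
  jsonlite::write_json(as.list(qc_res$counts),
                       file.path(cfg$out_dir, "qc_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  assignments <- assign_reads(qc_res$retained, refs, cfg$scoring,
                              cfg$assign_threshold)
  write.table(assignments, file.path(cfg$out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  status_counts <- table(factor(assignments$status,
                                levels = c("assigned",
                                           "unassigned-below-threshold")))

  counts <- list(
    input_reads = nrow(reads),
    qc = as.list(qc_res$counts),
    assignment = as.list(status_counts)
  )

  if (!is.null(cfg$cyst_ref_ids)) {
    cyst <- filter_by_similarity(qc_res$retained, refs, cfg$cyst_ref_ids,
                                 cfg$scoring, cfg$cyst_threshold)
    write.table(cyst$retained,
                file.path(cfg$out_dir, "cyst_similarity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$cyst_similarity <- as.list(cyst$counts)
  }

  if (!is.null(cfg$metadata_csv)) {
    metadata <- read_sample_metadata(cfg$metadata_csv)
    assignments$sample_id <- cfg$sample_id
    composition <- tabulate_composition(assignments, metadata)
    utils::write.csv(composition,
                     file.path(cfg$out_dir, "composition_long.csv"),
                     row.names = FALSE)
    utils::write.csv(pivot_by_zone(composition),
                     file.path(cfg$out_dir, "composition_zone_pivot.csv"),
                     row.names = FALSE)
    counts$composition_rows <- nrow(composition)
  }

  if (!is.null(cfg$trap_csv)) {
    poc <- if (!is.null(cfg$poc_csv)) {
      utils::read.csv(cfg$poc_csv, stringsAsFactors = FALSE)
    }
    series_list <- read_trap_series(cfg$trap_csv, cfg$collection_area)
    flux <- dplyr::bind_rows(lapply(series_list, analyze_trap_series,
                                    cutoff = cfg$background_cutoff,
                                    ratio = cfg$ratio, poc_table = poc))
    utils::write.csv(flux, file.path(cfg$out_dir, "sr_flux.csv"),
                     row.names = FALSE)
    counts$flux_bottles <- nrow(flux)
    counts$flux_significant <- sum(flux$significant)
  }

  inputs <- c(reads = cfg$reads_fastq, references = cfg$ref_fasta,
              taxonomy = cfg$taxonomy_tsv, metadata = cfg$metadata_csv,
              trap = cfg$trap_csv, poc = cfg$poc_csv)
  manifest <- list(
    inputs = as.list(unname(Map(function(nm, p) {
      list(role = nm, path = p, md5 = unname(tools::md5sum(p)))
    }, names(inputs), inputs))),
    config = echo_config(cfg),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

echo_config <- function(cfg) {
  list(seed = cfg$seed,
       qc = unclass(cfg$qc),
       scoring = unclass(cfg$scoring),
       assign_threshold = cfg$assign_threshold,
       cyst_threshold = cfg$cyst_threshold,
       background_cutoff = cfg$background_cutoff,
       c_sr_ratio = unclass(cfg$ratio),
       collection_area = cfg$collection_area,
       sample_id = cfg$sample_id)
}
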