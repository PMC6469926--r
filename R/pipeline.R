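## Pipeline stage runners: thin file-in / file-out wrappers over the
## package functions, shared by the command-line interface.

write_stage_log <- function(path, stage, config, counts) {
  jsonlite::write_json(
    list(stage = stage,
         package = "mitolineage",
         version = as.character(utils::packageVersion("mitolineage")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config),
         counts = counts),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run bulk variant calling on a pileup file
#'
#' Reads a pileup TSV, runs the candidate caller and the full filter
#' cascade, screens for contamination, and writes the variant table
#' (`<out_prefix>_variants.tsv` plus a minimal VCF), the contamination
#' report (`_contamination.json`) and a machine-readable stage log
#' (`_log.json`).
#'
#' @param pileup_file Path to a pileup TSV.
#' @param out_prefix Output path prefix.
#' @param config A [mito_config()].
#' @param common_variants_file Optional VCF/TSV of common population
#'   variants for the contamination screen.
#' @return The classified variant-call tibble, invisibly.
#' @export
run_call_bulk <- function(pileup_file, out_prefix, config = mito_config(),
                          common_variants_file = NULL) {
  p <- read_pileup(pileup_file, genome_length = config$genome_length)
  calls <- call_heteroplasmies(
    p, min_vaf = config$min_vaf, min_alt_reads = config$min_alt_reads,
    match = config$blacklist_match,
    min_per_strand = config$min_per_strand,
    low = config$strand_low, high = config$strand_high,
    homoplasmic_cut = config$homoplasmic_cut,
    report_cut = config$report_cut)
  common <- if (!is.null(common_variants_file)) {
    read_common_variants(common_variants_file)
  }
  report <- withCallingHandlers(
    screen_contamination(calls, common,
                         max_het = config$contamination_max_het,
                         max_overlap_frac = config$contamination_max_overlap),
    warning = function(w) invokeRestart("muffleWarning"))
  write_variants(calls, paste0(out_prefix, "_variants.tsv"), vcf = TRUE)
  jsonlite::write_json(report, paste0(out_prefix, "_contamination.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_stage_log(paste0(out_prefix, "_log.json"), "call-bulk", config,
                  list(n_sites = nrow(p), n_candidates = nrow(calls),
                       n_heteroplasmic =
                         sum(calls$classification == "heteroplasmic"),
                       n_homoplasmic =
                         sum(calls$classification == "homoplasmic"),
                       n_filtered = sum(calls$classification == "filtered"),
                       contamination_flagged = report$flagged))
  invisible(calls)
}

read_cell_dir <- function(cells_dir, genome_length) {
  files <- sort(list.files(cells_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_validation("no cell pileup TSVs found in '%s'", cells_dir)
  }
  pileups <- lapply(files, read_pileup, genome_length = genome_length)
  names(pileups) <- sub("\\.tsv$", "", basename(files))
  pileups
}

#' Genotype single cells against a bulk variant table
#'
#' Reads per-cell pileup TSVs from a directory and a bulk variant table,
#' re-counts the passing heteroplasmic variants in every cell, binarizes,
#' classifies wild-type cells, and computes the depth-binned detection-rate
#' table. Writes the long genotype table (`_genotypes.tsv`), support and
#' depth matrices (`_support.tsv`, `_depth.tsv`), WT labels
#' (`_wt_labels.tsv`), the detection-rate table (`_detection_rate.tsv`)
#' and a stage log.
#'
#' @param cells_dir Directory of per-cell pileup TSVs (one file per cell).
#' @param variants_file Variant table written by [run_call_bulk()].
#' @param out_prefix Output path prefix.
#' @param config A [mito_config()].
#' @return The binarized genotype tibble, invisibly.
#' @export
run_genotype_cells <- function(cells_dir, variants_file, out_prefix,
                               config = mito_config()) {
  pileups <- read_cell_dir(cells_dir, config$genome_length)
  calls <- read_variants(variants_file)
  het <- passing_variants(calls)
  if (nrow(het) == 0L) {
    stop_validation("no passing heteroplasmic variants in '%s'", variants_file)
  }
  genotypes <- genotype_cells(pileups, het) |>
    binarize_genotypes(min_support = config$min_support)
  coverage <- cell_coverage(pileups, genome_length = config$genome_length)
  wt <- classify_wt_cells(genotypes, unique(genotypes$variant_id), coverage,
                          min_genome_coverage = config$wt_coverage)
  rates <- detection_rate_by_depth(genotypes, bin_width = config$bin_width)
  readr::write_tsv(genotypes, paste0(out_prefix, "_genotypes.tsv"))
  support <- genotype_matrix(genotypes, "support")
  depth <- genotype_matrix(genotypes, "site_depth")
  readr::write_tsv(tibble::as_tibble(support, rownames = "cell_id"),
                   paste0(out_prefix, "_support.tsv"))
  readr::write_tsv(tibble::as_tibble(depth, rownames = "cell_id"),
                   paste0(out_prefix, "_depth.tsv"))
  readr::write_tsv(wt, paste0(out_prefix, "_wt_labels.tsv"))
  readr::write_tsv(rates, paste0(out_prefix, "_detection_rate.tsv"))
  write_stage_log(paste0(out_prefix, "_log.json"), "genotype-cells", config,
                  list(n_cells = length(pileups), n_variants = nrow(het),
                       n_wt = sum(wt$label == "WT"),
                       n_carrier = sum(wt$label == "carrier"),
                       n_insufficient = sum(wt$label == "insufficient")))
  invisible(genotypes)
}

read_genotypes <- function(file) {
  x <- readr::read_tsv(file, col_types = readr::cols(
    cell_id = readr::col_character(), variant_id = readr::col_character(),
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), support = readr::col_integer(),
    site_depth = readr::col_integer(),
    .default = readr::col_guess()))
  tibble::as_tibble(x)
}

#' Infer clone sets and assign cells
#'
#' Reads a long genotype table (from [run_genotype_cells()]), groups
#' co-detected variants into clone sets, assigns every cell (clone /
#' doublet / WT / unassigned), and, when several per-population variant
#' tables are supplied, builds the shared-versus-specific population
#' lineage table. Writes the clone model as JSON (`_clones.json`), the
#' cell labels (`_assignments.tsv`), optionally the population table
#' (`_populations.tsv`), and a stage log.
#'
#' @param genotypes_file Long genotype TSV.
#' @param out_prefix Output path prefix.
#' @param config A [mito_config()].
#' @param wt_labels_file Optional WT-label TSV from [run_genotype_cells()].
#' @param population_variant_files Optional named character vector of >= 2
#'   variant-table paths, one per sorted population.
#' @return The `mito_clones` object, invisibly.
#' @export
run_infer_clones <- function(genotypes_file, out_prefix,
                             config = mito_config(),
                             wt_labels_file = NULL,
                             population_variant_files = NULL) {
  genotypes <- read_genotypes(genotypes_file)
  if (!"detected" %in% names(genotypes)) {
    genotypes <- binarize_genotypes(genotypes,
                                    min_support = config$min_support)
  }
  sets <- infer_clone_sets(genotypes, min_cells = config$min_cells,
                           exceedance_quantile = config$exceedance_quantile,
                           depth_normalize = config$depth_normalize,
                           min_support = config$min_support)
  wt <- if (!is.null(wt_labels_file)) {
    readr::read_tsv(wt_labels_file, col_types = readr::cols(
      cell_id = readr::col_character(), label = readr::col_character()))
  }
  model <- assign_clones(genotypes, sets, wt_labels = wt)
  jsonlite::write_json(
    list(clone_sets = model$clone_sets,
         ungrouped = as.list(attr(sets, "ungrouped") %||% character()),
         assignments = model$assignments[c("cell_id", "label", "n_sets_hit")],
         evidence = setNames(model$assignments$evidence,
                             model$assignments$cell_id),
         summary = glance(model)),
    paste0(out_prefix, "_clones.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  readr::write_tsv(model$assignments[c("cell_id", "label", "n_sets_hit")],
                   paste0(out_prefix, "_assignments.tsv"))
  if (!is.null(population_variant_files)) {
    tables <- lapply(population_variant_files, read_variants)
    pops <- population_hierarchy(tables, report_cut = config$report_cut)
    readr::write_tsv(pops, paste0(out_prefix, "_populations.tsv"))
  }
  write_stage_log(paste0(out_prefix, "_log.json"), "infer-clones", config,
                  as.list(glance(model)))
  invisible(model)
}

#' Simulate a dataset to disk
#'
#' @param sim_cfg A [sim_config()] (or path handled by the CLI).
#' @param out_dir Output directory.
#' @param bulk_depth If non-`NULL`, also writes a bulk pileup
#'   (`bulk.tsv`) simulated at this total depth.
#' @return The `mito_sim` object, invisibly.
#' @export
run_simulate <- function(sim_cfg, out_dir, bulk_depth = NULL) {
  sim <- simulate_cells(sim_cfg)
  write_simulation(sim, out_dir)
  if (!is.null(bulk_depth)) {
    write_pileup(simulate_bulk(sim_cfg, bulk_depth),
                 file.path(out_dir, "bulk.tsv"))
  }
  write_stage_log(file.path(out_dir, "log.json"), "simulate",
                  structure(list(seed = sim_cfg$seed), class = "mito_config"),
                  list(n_cells = sim_cfg$n_cells,
                       n_variants = nrow(sim_cfg$clone_variants),
                       n_doublets = sum(sim$truth$cells$is_doublet)))
  invisible(sim)
}

#' Recompute a detection-rate table from a genotype table
#'
#' @param genotypes_file Long genotype TSV.
#' @param out_file Output TSV path.
#' @param config A [mito_config()].
#' @return The detection-rate tibble, invisibly.
#' @export
run_detection_rate <- function(genotypes_file, out_file,
                               config = mito_config()) {
  genotypes <- read_genotypes(genotypes_file)
  if (!"detected" %in% names(genotypes)) {
    genotypes <- binarize_genotypes(genotypes,
                                    min_support = config$min_support)
  }
  rates <- detection_rate_by_depth(genotypes, bin_width = config$bin_width)
  readr::write_tsv(rates, out_file)
  invisible(rates)
}
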