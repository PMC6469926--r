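#' Pipeline run configuration
#'
#' Collects every tunable threshold of the workflow with its default. All
#' defaults are the values used for bulk ATAC-seq mtDNA calling and
#' single-cell genotyping: candidate VAF floor 0.1%, strand rule (>2 reads
#' per strand, balance in (0.3, 0.7)), homoplasmic cut 0.9, bulk reporting
#' threshold 1%, any-read single-cell positivity, 40X wild-type coverage
#' rule, depth bins of 10, and a minimum of 3 carrier cells per clone set.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated named list of class `mito_config`.
#' @export
#' @examples
#' mito_config(report_cut = 0.02)
mito_config <- function(...) {
  defaults <- list(
    min_vaf = 0.001,
    min_alt_reads = 1L,
    blacklist_match = "site",
    min_per_strand = 2L,
    strand_low = 0.3,
    strand_high = 0.7,
    homoplasmic_cut = 0.9,
    report_cut = 0.01,
    contamination_max_het = 30L,
    contamination_max_overlap = 0.5,
    min_support = 1L,
    wt_coverage = 40,
    bin_width = 10L,
    min_cells = 3L,
    exceedance_quantile = 0.99,
    depth_normalize = TRUE,
    genome_length = MT_GENOME_LENGTH,
    seed = 1L)
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop_validation("unknown configuration key(s): %s",
                    paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides)
  check_proportion(cfg$min_vaf, "min_vaf", allow_zero = FALSE)
  check_count(cfg$min_alt_reads, "min_alt_reads", min = 1)
  if (!cfg$blacklist_match %in% c("site", "position")) {
    stop_validation("blacklist_match must be 'site' or 'position'")
  }
  check_count(cfg$min_per_strand, "min_per_strand")
  check_proportion(c(cfg$strand_low, cfg$strand_high), "strand_low/high")
  if (cfg$strand_low >= cfg$strand_high) {
    stop_validation("strand_low must be < strand_high")
  }
  check_proportion(cfg$homoplasmic_cut, "homoplasmic_cut", allow_zero = FALSE)
  check_proportion(cfg$report_cut, "report_cut", allow_zero = FALSE,
                   allow_one = FALSE)
  if (cfg$report_cut >= cfg$homoplasmic_cut) {
    stop_validation("report_cut must be < homoplasmic_cut")
  }
  check_count(cfg$contamination_max_het, "contamination_max_het", min = 1)
  check_proportion(cfg$contamination_max_overlap, "contamination_max_overlap")
  check_count(cfg$min_support, "min_support", min = 1)
  if (cfg$wt_coverage <= 0) stop_validation("wt_coverage must be > 0")
  check_count(cfg$bin_width, "bin_width", min = 1)
  check_count(cfg$min_cells, "min_cells", min = 1)
  check_proportion(cfg$exceedance_quantile, "exceedance_quantile")
  check_count(cfg$genome_length, "genome_length", min = 1)
  structure(cfg, class = "mito_config")
}

#' Read a run configuration from a YAML file
#'
#' @param file Path to a YAML file whose keys are [mito_config()]
#'   arguments.
#' @param ... Further overrides applied on top of the file.
#' @return A `mito_config` list.
#' @export
read_config <- function(file, ...) {
  vals <- yaml::read_yaml(file) %||% list()
  mito_config(modifyList(vals, list(...)))
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds [sim_config()] arguments; `clone_variants` is given as a
#' list of records with fields `clone`, `pos`, `ref`, `alt`, `vaf_mean`,
#' `vaf_concentration`.
#'
#' @param file Path to the YAML file.
#' @param ... Overrides applied on top of the file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(file, ...) {
  vals <- yaml::read_yaml(file) %||% list()
  vals <- modifyList(vals, list(...))
  if (!is.null(vals$clone_variants) && !is.data.frame(vals$clone_variants)) {
    vals$clone_variants <- dplyr::bind_rows(vals$clone_variants)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop_validation("unknown simulation key(s): %s",
                    paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}
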