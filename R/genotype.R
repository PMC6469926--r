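#' Re-count candidate variants in single cells
#'
#' For every cell and every candidate variant (typically heteroplasmies
#' called from bulk or merged single-cell data), counts the reads in that
#' cell supporting the candidate's alternate allele at its position
#' (`support`) and the total depth there (`site_depth`). Only reads matching
#' the candidate allele count as support: a different non-reference allele
#' at the same position contributes to depth but not to support. A position
#' absent from a cell's pileup yields support 0 and depth 0.
#'
#' @param cell_pileups A named list of pileup tibbles, one per cell; names
#'   are cell identifiers.
#' @param candidates A variant-call tibble (e.g. [passing_variants()]
#'   output); must be non-empty.
#' @return A long genotype tibble: `cell_id`, `variant_id`, `pos`, `ref`,
#'   `alt`, `support`, `site_depth`.
#' @export
genotype_cells <- function(cell_pileups, candidates) {
  if (nrow(candidates) == 0L) {
    stop_validation("`candidates` must contain at least one variant")
  }
  if (length(cell_pileups) == 0L) {
    stop_validation("`cell_pileups` must contain at least one cell")
  }
  if (is.null(names(cell_pileups)) || anyDuplicated(names(cell_pileups))) {
    stop_validation("`cell_pileups` must be a uniquely named list")
  }
  cand <- tibble::tibble(variant_id = candidates$variant_id,
                         pos = candidates$pos, ref = candidates$ref,
                         alt = candidates$alt)
  if (anyDuplicated(cand$variant_id) > 0L) {
    stop_validation("duplicate candidate variant ids")
  }
  alt_fwd_j <- match(paste0(tolower(cand$alt), "_fwd"), COUNT_COLS)
  alt_rev_j <- match(paste0(tolower(cand$alt), "_rev"), COUNT_COLS)
  n_cand <- nrow(cand)
  cells <- names(cell_pileups)
  support <- matrix(0L, n_cand, length(cells))
  depth <- matrix(0L, n_cand, length(cells))
  for (ci in seq_along(cells)) {
    p <- cell_pileups[[ci]]
    idx <- match(cand$pos, p$pos)
    found <- which(!is.na(idx))
    if (length(found) > 0L) {
      cm <- matrix(unlist(p[idx[found], COUNT_COLS], use.names = FALSE),
                   nrow = length(found))
      k <- seq_along(found)
      support[found, ci] <- cm[cbind(k, alt_fwd_j[found])] +
        cm[cbind(k, alt_rev_j[found])]
      depth[found, ci] <- rowSums(cm)
    }
  }
  tibble::tibble(cell_id = rep(cells, each = n_cand),
                 variant_id = rep(cand$variant_id, length(cells)),
                 pos = rep(cand$pos, length(cells)),
                 ref = rep(cand$ref, length(cells)),
                 alt = rep(cand$alt, length(cells)),
                 support = as.integer(support),
                 site_depth = as.integer(depth))
}

#' Binarize a genotype table
#'
#' A cell is scored positive for a variant when it is supported by at least
#' `min_support` reads; the default of 1 follows the any-read positivity
#' rule used for sparse single-cell libraries.
#'
#' @param genotypes A long genotype tibble from [genotype_cells()].
#' @param min_support Reads required to call a variant detected
#'   (default 1).
#' @return `genotypes` with a logical `detected` column.
#' @export
binarize_genotypes <- function(genotypes, min_support = 1) {
  check_count(min_support, "min_support", min = 1)
  genotypes$detected <- genotypes$support >= min_support
  genotypes
}

#' Cells-by-variants matrix view of a genotype table
#'
#' @param genotypes A long genotype tibble.
#' @param value Which quantity to spread: `"support"`, `"site_depth"`, or
#'   `"detected"` (requires [binarize_genotypes()] first).
#' @return A numeric matrix, cells in rows, variants in columns.
#' @export
genotype_matrix <- function(genotypes,
                            value = c("support", "site_depth", "detected")) {
  value <- match.arg(value)
  if (value == "detected" && !"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() before value = \"detected\"")
  }
  wide <- tidyr::pivot_wider(
    genotypes[c("cell_id", "variant_id", value)],
    names_from = "variant_id", values_from = dplyr::all_of(value),
    values_fill = 0)
  m <- as.matrix(wide[-1]) * 1
  rownames(m) <- wide$cell_id
  m
}

#' Per-cell mean mitochondrial coverage
#'
#' Mean depth over unmasked genome positions (absent positions count as
#' zero), per cell.
#'
#' @param cell_pileups A named list of pileup tibbles.
#' @param mask Coverage mask (see [coverage_summary()]).
#' @param genome_length Genome length; defaults to each pileup's attribute.
#' @return A tibble: `cell_id`, `mean_depth`.
#' @export
cell_coverage <- function(cell_pileups, mask = default_coverage_mask(),
                          genome_length = NULL) {
  purrr::imap_dfr(cell_pileups, function(p, cell) {
    cs <- coverage_summary(p, mask = mask, genome_length = genome_length)
    tibble::tibble(cell_id = cell, mean_depth = cs$mean_depth)
  })
}

#' Classify cells as variant carriers, wild-type, or insufficient
#'
#' A cell carrying any clone-defining variant is a `carrier` regardless of
#' coverage (a detected variant is positive evidence). A cell with no
#' detected clone variant is called `WT` only when its mean mitochondrial
#' coverage exceeds `min_genome_coverage` (default 40X) -- below that,
#' absence of evidence is uninformative and the cell is `insufficient`.
#'
#' @param genotypes A binarized genotype tibble ([binarize_genotypes()]).
#' @param clone_variants Clone-defining variants: a character vector of
#'   variant ids, or a list of such vectors (the union is used).
#' @param coverage A tibble `cell_id`, `mean_depth` from [cell_coverage()].
#' @param min_genome_coverage Coverage required (exclusive) to call WT
#'   (default 40).
#' @return A tibble: `cell_id`, `label` in `{carrier, WT, insufficient}`.
#' @export
classify_wt_cells <- function(genotypes, clone_variants, coverage,
                              min_genome_coverage = 40) {
  if (min_genome_coverage <= 0) {
    stop_validation("`min_genome_coverage` must be > 0")
  }
  if (!"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() first")
  }
  vars <- unique(unlist(clone_variants, use.names = FALSE))
  per_cell <- genotypes |>
    dplyr::filter(.data$variant_id %in% vars) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(any_detected = any(.data$detected), .groups = "drop")
  out <- dplyr::left_join(
    tibble::tibble(cell_id = unique(genotypes$cell_id)),
    per_cell, by = "cell_id")
  out <- dplyr::left_join(out, coverage, by = "cell_id")
  out$any_detected[is.na(out$any_detected)] <- FALSE
  out$label <- dplyr::case_when(
    out$any_detected ~ "carrier",
    !is.na(out$mean_depth) & out$mean_depth > min_genome_coverage ~ "WT",
    .default = "insufficient")
  out[c("cell_id", "label")]
}

#' Empirical detection rate as a function of site depth
#'
#' For each variant, cells are partitioned into half-open depth bins
#' `[0,w), [w,2w), ...` by their total sequencing depth at the variant
#' position, and the detection rate is the fraction of cells in the bin in
#' which the variant is detected. Empty intermediate bins are reported with
#' `n_cells = 0` and an undefined (`NA`) rate.
#'
#' @param genotypes A binarized genotype tibble.
#' @param bin_width Depth bin width (default 10).
#' @return A tibble of class `mito_detection_rates`: `variant_id`,
#'   `depth_lo`, `depth_hi`, `n_cells`, `n_detected`, `rate`.
#' @export
detection_rate_by_depth <- function(genotypes, bin_width = 10) {
  check_count(bin_width, "bin_width", min = 1)
  if (!"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() first")
  }
  g <- genotypes
  g$bin <- g$site_depth %/% bin_width
  tab <- g |>
    dplyr::group_by(.data$variant_id, .data$bin) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_detected = sum(.data$detected), .groups = "drop")
  tab <- tab |>
    dplyr::group_by(.data$variant_id) |>
    tidyr::complete(bin = seq(0L, max(.data$bin)),
                    fill = list(n_cells = 0L, n_detected = 0L)) |>
    dplyr::ungroup()
  tab$depth_lo <- tab$bin * bin_width
  tab$depth_hi <- (tab$bin + 1L) * bin_width
  tab$rate <- ifelse(tab$n_cells > 0, tab$n_detected / tab$n_cells, NA_real_)
  out <- tab[c("variant_id", "depth_lo", "depth_hi",
               "n_cells", "n_detected", "rate")]
  class(out) <- c("mito_detection_rates", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Combined detection rate over linked variants
#'
#' When several variants are co-inherited markers of the same clone,
#' detecting any one of them identifies the lineage, so per-variant
#' detection rates combine as `1 - prod(1 - R_i)`.
#'
#' @param rates Numeric vector of per-variant detection rates in `[0, 1]`.
#' @return The combined rate.
#' @export
#' @examples
#' combined_detection_rate(c(0.5, 0.5, 0.5, 0.5)) # 0.9375
combined_detection_rate <- function(rates) {
  if (length(rates) < 1L) stop_validation("`rates` must be non-empty")
  check_proportion(rates, "rates")
  1 - prod(1 - rates)
}

#' Closed-form detection probability under binomial read sampling
#'
#' Probability that a variant at cellular allele frequency `f`, sequenced
#' to depth `d` at its site, is supported by at least `min_support` reads:
#' `P(Binomial(d, f) >= min_support)`. For `min_support = 1` this is
#' `1 - (1 - f)^d`. Used as the analytic reference for empirical
#' detection-rate curves and for depth-normalizing expected co-occurrence.
#'
#' @param f Cellular variant allele frequency in `[0, 1]` (vectorized).
#' @param d Site depth, non-negative integer (vectorized).
#' @param min_support Reads required for a positive call (default 1).
#' @return Detection probability, vectorized over `f` and `d`.
#' @export
#' @examples
#' detection_probability(0.2, 20) # 1 - 0.8^20
detection_probability <- function(f, d, min_support = 1) {
  check_proportion(f, "f")
  check_count(d, "d")
  check_count(min_support, "min_support", min = 1)
  pbinom(min_support - 1, size = d, prob = f, lower.tail = FALSE)
}
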