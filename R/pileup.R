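#' Validate a stranded mitochondrial pileup table
#'
#' A pileup table holds, per mtDNA position, the reference allele and eight
#' stranded allele counts (`a_fwd`, `a_rev`, ..., `t_fwd`, `t_rev`) after any
#' upstream base- and mapping-quality filtering. Positions are 1-based rCRS
#' coordinates; missing positions imply zero depth (sparse representation).
#'
#' @param x A data frame with columns `pos`, `ref` and the eight count
#'   columns.
#' @param genome_length Length of the mitochondrial reference
#'   (default 16569, rCRS).
#' @param sample_id Optional sample label stored as an attribute.
#' @return A validated tibble sorted by position, with attributes
#'   `genome_length` and `sample_id`.
#' @export
#' @examples
#' as_pileup(data.frame(pos = 3010, ref = "G",
#'   a_fwd = 0, a_rev = 0, c_fwd = 0, c_rev = 0,
#'   g_fwd = 12, g_rev = 10, t_fwd = 0, t_rev = 0))
as_pileup <- function(x, genome_length = MT_GENOME_LENGTH, sample_id = NULL) {
  check_count(genome_length, "genome_length", min = 1)
  x <- tibble::as_tibble(x)
  needed <- c("pos", "ref", COUNT_COLS)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop_validation("pileup is missing columns: %s",
                    paste(missing_cols, collapse = ", "))
  }
  x <- x[needed]
  if (nrow(x) > 0L) {
    if (anyNA(x$pos) || any(x$pos < 1L) || any(x$pos > genome_length) ||
        any(x$pos != floor(x$pos))) {
      stop_validation("pileup positions must be integers in [1, %d]",
                      genome_length)
    }
    if (anyDuplicated(x$pos) > 0L) {
      stop_validation("duplicate pileup position: %d",
                      x$pos[anyDuplicated(x$pos)])
    }
    if (!all(x$ref %in% c(ALLELES, "N"))) {
      stop_validation("ref allele must be one of A, C, G, T, N")
    }
    counts <- as.matrix(x[COUNT_COLS])
    if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
      stop_validation("allele counts must be non-negative integers")
    }
  }
  x$pos <- as.integer(x$pos)
  x[COUNT_COLS] <- lapply(x[COUNT_COLS], as.integer)
  x <- dplyr::arrange(x, .data$pos)
  attr(x, "genome_length") <- as.integer(genome_length)
  attr(x, "sample_id") <- sample_id
  x
}

pileup_genome_length <- function(p, genome_length = NULL) {
  as.integer(genome_length %||% attr(p, "genome_length") %||% MT_GENOME_LENGTH)
}

#' Read a pileup TSV
#'
#' Expects a header line and tab-separated columns
#' `pos ref a_fwd a_rev c_fwd c_rev g_fwd g_rev t_fwd t_rev`.
#'
#' @param file Path to the TSV file.
#' @inheritParams as_pileup
#' @return A validated pileup tibble (see [as_pileup()]).
#' @export
read_pileup <- function(file, genome_length = MT_GENOME_LENGTH,
                        sample_id = NULL) {
  x <- tryCatch(
    suppressWarnings(readr::read_tsv(file, col_types = readr::cols(
      pos = readr::col_integer(), ref = readr::col_character(),
      .default = readr::col_integer()))),
    error = function(e) stop_parse("failed to parse pileup '%s': %s",
                                   file, conditionMessage(e)))
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    stop_parse("malformed pileup row in '%s' at line %d", file, probs$row[1] + 1L)
  }
  as_pileup(x, genome_length = genome_length,
            sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(file)))
}

#' Write a pileup TSV
#'
#' @param p A pileup tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pileup <- function(p, file) {
  readr::write_tsv(p[c("pos", "ref", COUNT_COLS)], file)
  invisible(file)
}

#' Per-site total depth
#'
#' Adds a `depth` column: the sum of the eight stranded allele counts.
#'
#' @param p A pileup tibble.
#' @return `p` with a `depth` column.
#' @export
pileup_depth <- function(p) {
  p$depth <- as.integer(rowSums(as.matrix(p[COUNT_COLS])))
  p
}

#' Default coverage mask around the rCRS position-3107 artifact
#'
#' The rCRS carries an 'N' placeholder at position 3107 which produces a
#' strong artificial depletion of aligned reads nearby; coverage summaries
#' exclude a small window around it by default.
#'
#' @param pad Positions to include on either side of 3107 (default 2,
#'   giving the interval 3105-3110 that spans the ACNTT context).
#' @return A tibble with columns `start`, `end`.
#' @export
default_coverage_mask <- function(pad = 2L) {
  tibble::tibble(start = 3107L - pad, end = 3108L + pad)
}

#' Summarize mitochondrial genome coverage
#'
#' Computes the per-position depth vector over the whole genome (absent
#' positions count as zero depth) and the mean depth over unmasked
#' positions.
#'
#' @param p A pileup tibble.
#' @param mask Intervals to exclude from the mean, as a data frame with
#'   `start`/`end` columns (1-based, inclusive). Defaults to the window
#'   around the rCRS 3107 'N'. Use `NULL` for no mask.
#' @param genome_length Genome length; defaults to the pileup attribute.
#' @return An object of class `mito_coverage`; use [glance()] for the
#'   one-row summary and [tidy()] for the per-position depth table.
#' @export
coverage_summary <- function(p, mask = default_coverage_mask(),
                             genome_length = NULL) {
  genome_length <- pileup_genome_length(p, genome_length)
  mask <- normalize_mask(mask, genome_length)
  p <- pileup_depth(p)
  depth <- integer(genome_length)
  depth[p$pos] <- p$depth
  masked <- mask_positions(mask, genome_length)
  keep <- setdiff(seq_len(genome_length), masked)
  structure(
    list(mean_depth = mean(depth[keep]),
         per_position_depth = depth,
         masked_intervals = mask,
         genome_length = genome_length,
         sample_id = attr(p, "sample_id")),
    class = "mito_coverage")
}

#' @export
print.mito_coverage <- function(x, ...) {
  cat(sprintf("<mito_coverage> %s\n", x$sample_id %||% ""))
  cat(sprintf("  genome length : %d\n", x$genome_length))
  cat(sprintf("  mean depth    : %.2f (over unmasked positions)\n",
              x$mean_depth))
  cat(sprintf("  masked        : %d interval(s)\n", nrow(x$masked_intervals)))
  invisible(x)
}

#' @rdname coverage_summary
#' @param x A `mito_coverage` object.
#' @param ... Unused.
#' @method tidy mito_coverage
#' @export
tidy.mito_coverage <- function(x, ...) {
  masked <- mask_positions(x$masked_intervals, x$genome_length)
  tibble::tibble(pos = seq_len(x$genome_length),
                 depth = x$per_position_depth,
                 masked = seq_len(x$genome_length) %in% masked)
}

#' @rdname coverage_summary
#' @method glance mito_coverage
#' @export
glance.mito_coverage <- function(x, ...) {
  tibble::tibble(mean_depth = x$mean_depth,
                 genome_length = x$genome_length,
                 n_masked_positions =
                   length(mask_positions(x$masked_intervals, x$genome_length)),
                 n_covered_positions = sum(x$per_position_depth > 0))
}

#' Fraction of reads mapping to the mitochondrial genome
#'
#' The mtDNA enrichment of a library: mitochondrial reads divided by total
#' (mitochondrial plus nuclear) reads, after quality filtering and duplicate
#' removal upstream.
#'
#' @param mito_reads,nuclear_reads Non-negative read counts; not both zero.
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' mito_read_fraction(17, 83)
mito_read_fraction <- function(mito_reads, nuclear_reads) {
  check_count(mito_reads, "mito_reads")
  check_count(nuclear_reads, "nuclear_reads")
  if (any(mito_reads + nuclear_reads == 0)) {
    stop_validation("mito_reads and nuclear_reads must not both be zero")
  }
  mito_reads / (mito_reads + nuclear_reads)
}
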