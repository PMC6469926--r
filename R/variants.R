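#' Default blacklist of recurrent mitochondrial false-positive substitutions
#'
#' Thirteen substitutions recurrently miscalled in mtDNA sequencing data:
#' misalignment around two homopolymer tracts (rCRS 302-315 and 513-525) and
#' around the 'N' placeholder at rCRS 3107. Candidates matching a blacklist
#' entry on both position and alternate allele are filtered by
#' [filter_blacklist()].
#'
#' @return A tibble with columns `pos`, `ref`, `alt`, `variant_id`,
#'   `provenance` (13 rows).
#' @export
#' @examples
#' default_blacklist()
default_blacklist <- function() {
  entries <- c("A302C", "C309T", "C311T", "C312T", "C313T", "G316C",
               "C514A", "A515G", "A523C", "C524G",
               "C3106A", "T3109C", "C3110A")
  prov <- c(rep("homopolymer_302_315", 6L),
            rep("homopolymer_513_525", 4L),
            rep("reference_N_3107", 3L))
  m <- regmatches(entries, regexec("^([ACGT])(\\d+)([ACGT])$", entries))
  tibble::tibble(
    pos = as.integer(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 2L),
    alt = vapply(m, `[`, "", 4L),
    variant_id = entries,
    provenance = prov)
}

new_variant_calls <- function(pos, ref, alt, vaf, depth, fwd_alt, rev_alt) {
  tibble::tibble(
    pos = as.integer(pos), ref = ref, alt = alt,
    variant_id = variant_id(pos, ref, alt),
    vaf = vaf, depth = as.integer(depth),
    fwd_alt = as.integer(fwd_alt), rev_alt = as.integer(rev_alt),
    classification = rep("heteroplasmic", length(pos)),
    filter_reasons = rep(list(character()), length(pos)))
}

## classification = "filtered" iff filter_reasons non-empty; otherwise keep
## the VAF-based class assigned so far.
add_filter_reason <- function(calls, hit, reason) {
  calls$filter_reasons[hit] <- purrr::map(calls$filter_reasons[hit],
                                          ~ union(.x, reason))
  calls$classification[lengths(calls$filter_reasons) > 0L] <- "filtered"
  calls
}

#' Call candidate mitochondrial variants from a pileup
#'
#' Emits one candidate per (position, non-reference allele) whose variant
#' allele frequency (VAF) and supporting-read count clear the candidate
#' floor. The default floor of 0.1% matches permissive frequency-based
#' somatic calling on deeply covered mtDNA; it is deliberately lower than
#' the bulk reporting threshold applied later by [classify_vaf()].
#' Multi-allelic sites yield multiple candidates.
#'
#' @param p A pileup tibble (see [as_pileup()]).
#' @param min_vaf Candidate VAF floor in `(0, 1]` (default 0.001).
#' @param min_alt_reads Minimum variant-supporting reads (default 1).
#' @return A variant-call tibble with columns `pos`, `ref`, `alt`,
#'   `variant_id`, `vaf`, `depth`, `fwd_alt`, `rev_alt`, `classification`,
#'   `filter_reasons` (list column). Fresh candidates start as
#'   `heteroplasmic` with no filter reasons; run the filter cascade
#'   ([filter_blacklist()], [filter_strand()], [classify_vaf()]) to finish
#'   classification.
#' @export
call_variants <- function(p, min_vaf = 0.001, min_alt_reads = 1) {
  check_proportion(min_vaf, "min_vaf", allow_zero = FALSE)
  check_count(min_alt_reads, "min_alt_reads", min = 1)
  p <- pileup_depth(p)
  p <- p[p$depth > 0L & p$ref %in% ALLELES, , drop = FALSE]
  long <- purrr::map_dfr(ALLELES, function(allele) {
    rows <- p[p$ref != allele, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    fwd <- rows[[paste0(tolower(allele), "_fwd")]]
    rev <- rows[[paste0(tolower(allele), "_rev")]]
    tibble::tibble(pos = rows$pos, ref = rows$ref, alt = allele,
                   fwd_alt = fwd, rev_alt = rev, depth = rows$depth)
  })
  if (nrow(long) == 0L) {
    return(new_variant_calls(integer(), character(), character(),
                             double(), integer(), integer(), integer()))
  }
  long$alt_reads <- long$fwd_alt + long$rev_alt
  long <- long[long$alt_reads >= min_alt_reads, , drop = FALSE]
  long$vaf <- long$alt_reads / long$depth
  long <- long[long$vaf >= min_vaf, , drop = FALSE]
  long <- dplyr::arrange(long, .data$pos, .data$alt)
  new_variant_calls(long$pos, long$ref, long$alt, long$vaf, long$depth,
                    long$fwd_alt, long$rev_alt)
}

#' Remove blacklisted substitutions
#'
#' Marks calls matching a blacklist entry as `filtered` with reason
#' `"blacklist"`. By default matching is on (position, alternate allele)
#' pairs, exactly the 13 printed substitutions; `match = "position"` widens
#' removal to any alternate allele at a blacklisted position, reflecting the
#' positional nature of the underlying misalignment.
#'
#' @param calls A variant-call tibble.
#' @param blacklist A blacklist tibble (default [default_blacklist()]).
#' @param match `"site"` (position + alt, default) or `"position"`.
#' @return `calls` with reasons appended; no rows are dropped.
#' @export
filter_blacklist <- function(calls, blacklist = default_blacklist(),
                             match = c("site", "position")) {
  match <- match.arg(match)
  hit <- if (match == "site") {
    paste(calls$pos, calls$alt) %in% paste(blacklist$pos, blacklist$alt)
  } else {
    calls$pos %in% blacklist$pos
  }
  add_filter_reason(calls, hit, "blacklist")
}

#' Strand-support and strand-balance filter
#'
#' Strand imbalance is a signature of sequencing error (including the
#' elevated error rate at A bases on some Illumina instruments and G->T /
#' C->A oxidative DNA damage). A call passes only if strictly more than
#' `min_per_strand` variant reads are seen on each strand and the forward
#' fraction `fwd / (fwd + rev)` lies strictly between `low` and `high`.
#'
#' @param calls A variant-call tibble.
#' @param min_per_strand Reads required (exclusive) per strand (default 2,
#'   i.e. >2 reads on each strand).
#' @param low,high Open strand-balance interval (defaults 0.3 and 0.7).
#' @return `calls` with reasons `"strand_support"` / `"strand_balance"`
#'   appended where the contract fails; no rows are dropped.
#' @export
filter_strand <- function(calls, min_per_strand = 2, low = 0.3, high = 0.7) {
  check_count(min_per_strand, "min_per_strand")
  check_proportion(c(low, high), "low/high")
  if (low >= high) stop_validation("`low` must be < `high`")
  support_fail <- !(calls$fwd_alt > min_per_strand &
                    calls$rev_alt > min_per_strand)
  total <- calls$fwd_alt + calls$rev_alt
  ratio <- ifelse(total > 0, calls$fwd_alt / total, NA_real_)
  balance_fail <- is.na(ratio) | !(ratio > low & ratio < high)
  calls <- add_filter_reason(calls, support_fail, "strand_support")
  add_filter_reason(calls, balance_fail, "strand_balance")
}

#' Classify calls by variant allele frequency
#'
#' Splits unfiltered calls into homoplasmic (VAF above `homoplasmic_cut`;
#' near-fixed variants, typically germline, which distinguish individuals
#' rather than clones) and heteroplasmic. Heteroplasmic calls at or below
#' the reporting threshold are filtered with reason
#' `"below_report_threshold"`. Calls with VAF in `(homoplasmic_cut, 1)` are
#' additionally annotated `suspect_homoplasmic` in `filter_flags`, since
#' not-quite-fixed variants are enriched for reference-bias artifacts; they
#' remain classified homoplasmic.
#'
#' @param calls A variant-call tibble.
#' @param homoplasmic_cut VAF above which a call is homoplasmic
#'   (default 0.9).
#' @param report_cut Heteroplasmic reporting threshold (default 0.01, the
#'   bulk 1% rule).
#' @return `calls` with `classification` updated and a `filter_flags` list
#'   column added.
#' @export
classify_vaf <- function(calls, homoplasmic_cut = 0.9, report_cut = 0.01) {
  check_proportion(homoplasmic_cut, "homoplasmic_cut", allow_zero = FALSE)
  check_proportion(report_cut, "report_cut", allow_zero = FALSE,
                   allow_one = FALSE)
  if (report_cut >= homoplasmic_cut) {
    stop_validation("`report_cut` must be < `homoplasmic_cut`")
  }
  if (!"filter_flags" %in% names(calls)) {
    calls$filter_flags <- rep(list(character()), nrow(calls))
  }
  suspect <- calls$vaf > homoplasmic_cut & calls$vaf < 1
  calls$filter_flags[suspect] <- purrr::map(calls$filter_flags[suspect],
                                            ~ union(.x, "suspect_homoplasmic"))
  calls <- add_filter_reason(calls, calls$vaf <= report_cut,
                             "below_report_threshold")
  clean <- lengths(calls$filter_reasons) == 0L
  calls$classification[clean & calls$vaf > homoplasmic_cut] <- "homoplasmic"
  calls$classification[clean & calls$vaf <= homoplasmic_cut] <- "heteroplasmic"
  calls
}

#' Run the full bulk filter cascade
#'
#' Convenience wrapper: [call_variants()] then [filter_blacklist()],
#' [filter_strand()] and [classify_vaf()]. The final pass/fail set is
#' independent of filter order because each filter only appends reasons.
#'
#' @inheritParams call_variants
#' @inheritParams filter_blacklist
#' @inheritParams filter_strand
#' @inheritParams classify_vaf
#' @return A classified variant-call tibble.
#' @export
call_heteroplasmies <- function(p, min_vaf = 0.001, min_alt_reads = 1,
                                blacklist = default_blacklist(),
                                match = "site",
                                min_per_strand = 2, low = 0.3, high = 0.7,
                                homoplasmic_cut = 0.9, report_cut = 0.01) {
  call_variants(p, min_vaf = min_vaf, min_alt_reads = min_alt_reads) |>
    filter_blacklist(blacklist = blacklist, match = match) |>
    filter_strand(min_per_strand = min_per_strand, low = low, high = high) |>
    classify_vaf(homoplasmic_cut = homoplasmic_cut, report_cut = report_cut)
}

#' Variants that pass all filters
#'
#' @param calls A variant-call tibble.
#' @param classification Classes to keep (default heteroplasmic only, the
#'   calls used for lineage work).
#' @return The passing subset of `calls`.
#' @export
passing_variants <- function(calls,
                             classification = "heteroplasmic") {
  calls[lengths(calls$filter_reasons) == 0L &
          calls$classification %in% classification, , drop = FALSE]
}

#' Screen a sample for cross-individual contamination
#'
#' A contaminating second individual injects that person's homoplasmic
#' variants as apparent low-frequency heteroplasmies, so contaminated
#' samples show (i) an unusually large number of heteroplasmic calls and
#' (ii) heavy overlap with common population variants. Either signal flags
#' the sample.
#'
#' @param calls A classified variant-call tibble.
#' @param common_variants Common population variants as a data frame with
#'   `pos` and `alt` columns (see [read_common_variants()]), or `NULL` to
#'   skip the overlap check (with a warning).
#' @param max_het Heteroplasmy count at or above which the sample is
#'   flagged (default 30).
#' @param max_overlap_frac Fraction of heteroplasmies overlapping common
#'   variants at or above which the sample is flagged (default 0.5).
#' @return A one-row tibble: `n_heteroplasmic`, `n_overlapping_common`,
#'   `overlap_frac`, `flagged`, `threshold_used`, `overlap_threshold_used`.
#' @export
screen_contamination <- function(calls, common_variants = NULL,
                                 max_het = 30, max_overlap_frac = 0.5) {
  check_count(max_het, "max_het", min = 1)
  check_proportion(max_overlap_frac, "max_overlap_frac")
  het <- passing_variants(calls)
  n_het <- nrow(het)
  if (is.null(common_variants) || nrow(common_variants) == 0L) {
    warn("no common-variant list supplied; overlap check skipped")
    n_common <- NA_integer_
    frac <- NA_real_
    flagged <- n_het >= max_het
  } else {
    n_common <- sum(paste(het$pos, het$alt) %in%
                      paste(common_variants$pos, common_variants$alt))
    frac <- if (n_het > 0) n_common / n_het else 0
    flagged <- n_het >= max_het || frac >= max_overlap_frac
  }
  tibble::tibble(n_heteroplasmic = n_het,
                 n_overlapping_common = n_common,
                 overlap_frac = frac,
                 flagged = flagged,
                 threshold_used = as.integer(max_het),
                 overlap_threshold_used = max_overlap_frac)
}

#' Read a common-population-variant list
#'
#' Accepts a VCF (positions and ALT alleles are extracted; multi-allelic
#' records are split) or a two-column TSV with header `pos` and `alt`.
#'
#' @param file Path to a `.vcf` file or a two-column TSV.
#' @return A tibble with columns `pos`, `alt`.
#' @export
read_common_variants <- function(file) {
  if (grepl("\\.vcf(\\.gz)?$", file, ignore.case = TRUE)) {
    if (requireNamespace("vcfR", quietly = TRUE)) {
      v <- vcfR::read.vcfR(file, verbose = FALSE)
      fix <- tibble::as_tibble(vcfR::getFIX(v))
      out <- tidyr::separate_rows(fix[c("POS", "ALT")], "ALT", sep = ",")
      return(tibble::tibble(pos = as.integer(out$POS), alt = out$ALT))
    }
    ## minimal fixed-field fallback when vcfR is unavailable
    lines <- readr::read_lines(file)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble::tibble(pos = as.integer(vapply(fields, `[`, "", 2L)),
                          alt = vapply(fields, `[`, "", 5L))
    return(tidyr::separate_rows(out, "alt", sep = ","))
  }
  x <- readr::read_tsv(file, col_types = readr::cols(
    pos = readr::col_integer(), alt = readr::col_character()))
  tibble::as_tibble(x[c("pos", "alt")])
}

#' Write a variant-call table
#'
#' Writes the tab-separated variant table (`pos ref alt vaf depth fwd_alt
#' rev_alt class filters`). With `vcf = TRUE`, additionally writes a minimal
#' VCF alongside (CHROM `chrM`, INFO carrying VAF and stranded support).
#'
#' @param calls A variant-call tibble.
#' @param file Output TSV path.
#' @param vcf Also write `<file>.vcf`? Default `FALSE`.
#' @return `file`, invisibly.
#' @export
write_variants <- function(calls, file, vcf = FALSE) {
  flat <- tibble::tibble(
    pos = calls$pos, ref = calls$ref, alt = calls$alt,
    vaf = calls$vaf, depth = calls$depth,
    fwd_alt = calls$fwd_alt, rev_alt = calls$rev_alt,
    class = calls$classification,
    filters = vapply(calls$filter_reasons, paste, "", collapse = ";"))
  flat$filters[flat$filters == ""] <- "PASS"
  readr::write_tsv(flat, file)
  if (vcf) {
    vcf_file <- paste0(file, ".vcf")
    header <- c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=chrM>",
      "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
      "##INFO=<ID=SF,Number=1,Type=Integer,Description=\"Forward alt reads\">",
      "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Reverse alt reads\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("chrM\t%d\t%s\t%s\t%s\t.\t%s\tVAF=%g;DP=%d;SF=%d;SR=%d",
                    flat$pos, variant_id(flat$pos, flat$ref, flat$alt),
                    flat$ref, flat$alt,
                    ifelse(flat$filters == "PASS", "PASS",
                           gsub(";", ",", flat$filters)),
                    flat$vaf, flat$depth, flat$fwd_alt, flat$rev_alt)
    readr::write_lines(c(header, body), vcf_file)
  }
  invisible(file)
}

#' Read a variant-call table written by [write_variants()]
#'
#' @param file Path to the TSV.
#' @return A variant-call tibble.
#' @export
read_variants <- function(file) {
  x <- readr::read_tsv(file, col_types = readr::cols(
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), vaf = readr::col_double(),
    depth = readr::col_integer(), fwd_alt = readr::col_integer(),
    rev_alt = readr::col_integer(), class = readr::col_character(),
    filters = readr::col_character()))
  calls <- new_variant_calls(x$pos, x$ref, x$alt, x$vaf, x$depth,
                             x$fwd_alt, x$rev_alt)
  calls$classification <- x$class
  calls$filter_reasons <- purrr::map(x$filters,
                                     ~ if (.x == "PASS") character()
                                       else strsplit(.x, ";")[[1]])
  calls
}
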