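#' Build a stranded pileup table from a BAM file
#'
#' Optional adapter from coordinate-sorted alignments to the pileup TSV
#' dialect consumed by the rest of the package. Restricts to the
#' mitochondrial contig and applies the mapping- and base-quality floors
#' before counting, so downstream tables carry already-filtered counts.
#' Use `min_baseq = 30` for bulk libraries and `min_baseq = 20` (with
#' `min_mapq = 20`) for shallow single-cell libraries.
#'
#' Requires the `Rsamtools` package (and `Biostrings` when `reference` is
#' a FASTA path).
#'
#' @param bam_file Path to an indexed, coordinate-sorted BAM.
#' @param reference The mitochondrial reference sequence: a single string,
#'   a character vector of per-position alleles, or a FASTA path.
#' @param contig Mitochondrial contig name (default `"chrM"`).
#' @param min_mapq Minimum mapping quality (default 30).
#' @param min_baseq Minimum base quality (default 30).
#' @param genome_length Genome length; defaults to the reference length.
#' @return A validated pileup tibble (see [as_pileup()]).
#' @export
pileup_from_bam <- function(bam_file, reference, contig = "chrM",
                            min_mapq = 30, min_baseq = 30,
                            genome_length = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_validation("pileup_from_bam() requires the Rsamtools package")
  }
  ref <- normalize_reference(reference)
  genome_length <- as.integer(genome_length %||% length(ref))
  param <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_mapq = as.integer(min_mapq),
    min_base_quality = as.integer(min_baseq),
    distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  which <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(1L, genome_length))
  sb <- Rsamtools::ScanBamParam(which = which)
  pl <- Rsamtools::pileup(bam_file, scanBamParam = sb, pileupParam = param)
  pl <- pl[pl$nucleotide %in% ALLELES, , drop = FALSE]
  long <- tibble::tibble(
    pos = as.integer(pl$pos),
    col = paste0(tolower(as.character(pl$nucleotide)),
                 ifelse(as.character(pl$strand) == "+", "_fwd", "_rev")),
    count = as.integer(pl$count))
  wide <- tidyr::pivot_wider(long, names_from = "col",
                             values_from = "count", values_fill = 0L,
                             values_fn = sum)
  for (cc in setdiff(COUNT_COLS, names(wide))) wide[[cc]] <- 0L
  wide$ref <- ref[wide$pos]
  as_pileup(wide[c("pos", "ref", COUNT_COLS)],
            genome_length = genome_length,
            sample_id = sub("\\.bam$", "", basename(bam_file)))
}

normalize_reference <- function(reference) {
  if (length(reference) == 1L && file.exists(reference) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop_validation("reading a FASTA reference requires Biostrings")
    }
    seq <- Biostrings::readDNAStringSet(reference)[[1]]
    reference <- as.character(seq)
  }
  if (length(reference) == 1L && nchar(reference) > 1L) {
    reference <- strsplit(toupper(reference), "")[[1]]
  }
  if (!all(reference %in% c(ALLELES, "N"))) {
    stop_validation("reference must consist of A, C, G, T, N")
  }
  reference
}
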