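## internal validation helpers -------------------------------------------

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "mitolineage_validation_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "mitolineage_parse_error")
}

check_proportion <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_validation("`%s` must be numeric and non-missing", name)
  }
  lo <- if (allow_zero) x >= 0 else x > 0
  hi <- if (allow_one) x <= 1 else x < 1
  if (!all(lo & hi)) {
    stop_validation("`%s` must lie in the unit interval", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    stop_validation("`%s` must be an integer >= %s", name, min)
  }
  invisible(x)
}

#' Canonical variant identifier
#'
#' Variants are labelled `<ref><position><alt>` (e.g. `A302C`), the convention
#' used for mitochondrial substitutions throughout the package.
#'
#' @param pos 1-based mtDNA position.
#' @param ref,alt Reference and alternate alleles (`A`, `C`, `G`, `T`).
#' @return Character vector of identifiers.
#' @export
#' @examples
#' variant_id(302, "A", "C")
variant_id <- function(pos, ref, alt) {
  paste0(ref, pos, alt)
}

## Validate a mask given as a two-column data frame (start, end), a length-2
## numeric vector, or NULL. Returns a tibble with columns start, end.
normalize_mask <- function(mask, genome_length) {
  if (is.null(mask)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  if (is.numeric(mask) && length(mask) == 2L) {
    mask <- tibble::tibble(start = mask[1], end = mask[2])
  }
  mask <- tibble::as_tibble(mask)
  if (!all(c("start", "end") %in% names(mask))) {
    stop_validation("mask must have columns `start` and `end`")
  }
  if (any(mask$start > mask$end)) {
    stop_validation("mask interval with start > end")
  }
  ## intervals entirely beyond the genome (e.g. the rCRS 3107 default on a
  ## shorter reference) are irrelevant and dropped
  mask <- mask[mask$start <= genome_length, , drop = FALSE]
  if (any(mask$start < 1) || any(mask$end > genome_length)) {
    stop_validation("mask interval outside [1, %d]", genome_length)
  }
  mask <- dplyr::arrange(mask, .data$start)
  if (nrow(mask) > 1L && any(mask$start[-1] <= mask$end[-nrow(mask)])) {
    stop_validation("mask intervals overlap")
  }
  mask
}

mask_positions <- function(mask, genome_length) {
  if (nrow(mask) == 0L) return(integer())
  unlist(purrr::map2(mask$start, mask$end, seq.int), use.names = FALSE)
}
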