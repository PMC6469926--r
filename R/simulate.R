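#' Describe the variants carried by simulated clones
#'
#' Convenience constructor for the `clone_variants` table of [sim_config()].
#' Each row is one heteroplasmic variant carried by one clone; per-cell
#' realized allele frequencies are drawn from a Beta distribution with the
#' given mean and concentration (`shape1 = mean * conc`,
#' `shape2 = (1 - mean) * conc`), reflecting the cell-to-cell spread of
#' heteroplasmy produced by random mtDNA segregation. `vaf_concentration =
#' Inf` fixes the VAF at its mean.
#'
#' @param clone Integer clone index (1-based).
#' @param pos 1-based mtDNA position.
#' @param ref,alt Reference and alternate alleles.
#' @param vaf_mean Mean cellular VAF in `(0, 1]`.
#' @param vaf_concentration Beta concentration (> 0; default 50, a
#'   moderate spread; `Inf` for a fixed VAF).
#' @return A tibble usable as `clone_variants`.
#' @export
sim_variants <- function(clone, pos, ref, alt, vaf_mean,
                         vaf_concentration = 50) {
  tibble::tibble(clone = as.integer(clone), pos = as.integer(pos),
                 ref = ref, alt = alt, vaf_mean = vaf_mean,
                 vaf_concentration = vaf_concentration)
}

#' Configure a synthetic clonal population
#'
#' Defines the ground truth for [simulate_cells()] / [simulate_bulk()]: the
#' clonal composition of the cell population, the heteroplasmic variants
#' marking each clone, the per-cell per-site sequencing-depth model, the
#' sequencing error rate, strand assignment, and the doublet rate of the
#' single-cell capture.
#'
#' @param n_cells Number of cells (>= 1).
#' @param clone_fractions Clone proportions, summing to 1.
#' @param clone_variants A tibble from [sim_variants()]; clone indices must
#'   reference `clone_fractions`.
#' @param genome_length Genome length (default 16569).
#' @param depth_model `"nbinom"` (default; overdispersed, the shape of
#'   per-site ATAC coverage), `"poisson"`, or `"fixed"`.
#' @param depth_mean Mean per-cell per-site depth (default 50).
#' @param depth_size Negative-binomial size parameter (default 10).
#' @param error_rate Per-base substitution error probability after quality
#'   filtering (default 1e-3; errors are spread uniformly over the three
#'   non-reference alleles).
#' @param strand_prob Probability a read is forward-strand (default 0.5).
#' @param doublet_rate Probability a library is a doublet, i.e. two cells
#'   captured together and their counts summed (default 0).
#' @param covered_positions Positions to simulate; `NULL` (default) covers
#'   the whole genome densely. Restricting to the variant positions makes
#'   large detection-rate experiments cheap.
#' @param seed Integer RNG seed; identical configurations give
#'   bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells, clone_fractions, clone_variants,
                       genome_length = MT_GENOME_LENGTH,
                       depth_model = c("nbinom", "poisson", "fixed"),
                       depth_mean = 50, depth_size = 10,
                       error_rate = 1e-3, strand_prob = 0.5,
                       doublet_rate = 0, covered_positions = NULL,
                       seed = 1L) {
  check_count(n_cells, "n_cells", min = 1)
  check_count(genome_length, "genome_length", min = 1)
  depth_model <- match.arg(depth_model)
  if (abs(sum(clone_fractions) - 1) > 1e-9 || any(clone_fractions < 0)) {
    stop_validation("`clone_fractions` must be non-negative and sum to 1")
  }
  check_proportion(error_rate, "error_rate", allow_one = FALSE)
  check_proportion(strand_prob, "strand_prob")
  check_proportion(doublet_rate, "doublet_rate", allow_one = FALSE)
  if (depth_mean <= 0) stop_validation("`depth_mean` must be > 0")
  if (depth_size <= 0) stop_validation("`depth_size` must be > 0")
  cv <- tibble::as_tibble(clone_variants)
  needed <- c("clone", "pos", "ref", "alt", "vaf_mean", "vaf_concentration")
  if (!all(needed %in% names(cv))) {
    stop_validation("`clone_variants` needs columns: %s",
                    paste(needed, collapse = ", "))
  }
  if (nrow(cv) > 0L) {
    if (any(cv$clone < 1L) || any(cv$clone > length(clone_fractions))) {
      stop_validation("`clone` indices must reference clone_fractions")
    }
    if (any(cv$pos < 1L) || any(cv$pos > genome_length)) {
      stop_validation("variant position outside [1, %d]", genome_length)
    }
    if (!all(cv$ref %in% ALLELES) || !all(cv$alt %in% ALLELES) ||
        any(cv$ref == cv$alt)) {
      stop_validation("variant ref/alt must be distinct A/C/G/T alleles")
    }
    check_proportion(cv$vaf_mean, "vaf_mean", allow_zero = FALSE)
    if (any(cv$vaf_concentration <= 0)) {
      stop_validation("`vaf_concentration` must be > 0 (Beta parameters infeasible)")
    }
    dup_ref <- cv |>
      dplyr::distinct(.data$pos, .data$ref) |>
      dplyr::count(.data$pos)
    if (any(dup_ref$n > 1L)) {
      stop_validation("conflicting reference alleles at position %d",
                      dup_ref$pos[dup_ref$n > 1L][1])
    }
    if (anyDuplicated(cv[c("clone", "pos")]) > 0L) {
      stop_validation("a clone may carry at most one variant per position")
    }
  }
  if (!is.null(covered_positions)) {
    covered_positions <- sort(unique(as.integer(covered_positions)))
    if (any(covered_positions < 1L) || any(covered_positions > genome_length)) {
      stop_validation("covered_positions outside [1, %d]", genome_length)
    }
    if (!all(cv$pos %in% covered_positions)) {
      stop_validation("covered_positions must include all variant positions")
    }
  }
  structure(list(n_cells = as.integer(n_cells),
                 clone_fractions = as.numeric(clone_fractions),
                 clone_variants = cv,
                 genome_length = as.integer(genome_length),
                 depth_model = depth_model,
                 depth_mean = depth_mean, depth_size = depth_size,
                 error_rate = error_rate, strand_prob = strand_prob,
                 doublet_rate = doublet_rate,
                 covered_positions = covered_positions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## deterministic pseudo-reference: allele at pos cycles A,C,G,T, overridden
## by the configured refs at variant positions
sim_reference <- function(cfg, positions) {
  ref <- ALLELES[((positions - 1L) %% 4L) + 1L]
  if (nrow(cfg$clone_variants) > 0L) {
    idx <- match(cfg$clone_variants$pos, positions)
    ref[idx[!is.na(idx)]] <- cfg$clone_variants$ref[!is.na(idx)]
  }
  ref
}

sim_depth <- function(cfg, n) {
  switch(cfg$depth_model,
         fixed = rep(as.integer(round(cfg$depth_mean)), n),
         poisson = rpois(n, cfg$depth_mean),
         nbinom = rnbinom(n, size = cfg$depth_size, mu = cfg$depth_mean))
}

## Stranded count matrix (sites x 8) for one library. True alt reads are
## supplied per site; remaining reads flip to an error allele with
## probability error_rate, split evenly over the three non-reference
## alleles; conservation holds exactly (ref + alt + error reads == depth).
sim_count_matrix <- function(depth, ref, alt_idx, alt_reads, error_rate,
                             strand_prob) {
  n_sites <- length(depth)
  per_allele <- matrix(0L, n_sites, 4L)
  err_total <- rbinom(n_sites, depth - alt_reads, error_rate)
  ## multinomial split of the errors into three equal parts
  x1 <- rbinom(n_sites, err_total, 1 / 3)
  x2 <- rbinom(n_sites, err_total - x1, 1 / 2)
  err <- cbind(x1, x2, err_total - x1 - x2)
  ref_i <- match(ref, ALLELES)
  for (r in 1:4) {
    s <- which(ref_i == r)
    if (length(s) == 0L) next
    per_allele[s, setdiff(1:4, r)] <- err[s, , drop = FALSE]
  }
  has_alt <- which(!is.na(alt_idx))
  if (length(has_alt) > 0L) {
    ij <- cbind(has_alt, alt_idx[has_alt])
    per_allele[ij] <- per_allele[ij] + alt_reads[has_alt]
  }
  per_allele[cbind(seq_len(n_sites), ref_i)] <-
    depth - rowSums(per_allele)
  fwd <- matrix(rbinom(n_sites * 4L, per_allele, strand_prob), n_sites, 4L)
  counts <- matrix(0L, n_sites, 8L, dimnames = list(NULL, COUNT_COLS))
  counts[, seq(1L, 8L, 2L)] <- fwd
  counts[, seq(2L, 8L, 2L)] <- per_allele - fwd
  counts
}

## Per-clone variant lookup, precomputed once so the per-cell loop does no
## data-frame subsetting.
sim_clone_lookup <- function(cfg, positions) {
  cv <- cfg$clone_variants
  lapply(seq_along(cfg$clone_fractions), function(k) {
    v <- cv[cv$clone == k, , drop = FALSE]
    list(idx = match(v$pos, positions),
         alt_i = match(v$alt, ALLELES),
         vaf_mean = v$vaf_mean,
         conc = v$vaf_concentration,
         id = variant_id(v$pos, v$ref, v$alt))
  })
}

## One library (one cell, or one member of a doublet): realized VAFs and
## the stranded count matrix.
sim_one_library <- function(cfg, pre, n_sites, ref) {
  depth <- sim_depth(cfg, n_sites)
  n_var <- length(pre$idx)
  vafs <- numeric(n_var)
  alt_reads <- integer(n_sites)
  alt_idx <- rep(NA_integer_, n_sites)
  if (n_var > 0L) {
    fixed <- !is.finite(pre$conc)
    vafs[fixed] <- pre$vaf_mean[fixed]
    if (any(!fixed)) {
      vafs[!fixed] <- rbeta(sum(!fixed),
                            pre$vaf_mean[!fixed] * pre$conc[!fixed],
                            (1 - pre$vaf_mean[!fixed]) * pre$conc[!fixed])
    }
    alt_reads[pre$idx] <- rbinom(n_var, depth[pre$idx], vafs)
    alt_idx[pre$idx] <- pre$alt_i
  }
  counts <- sim_count_matrix(depth, ref, alt_idx, alt_reads,
                             cfg$error_rate, cfg$strand_prob)
  list(counts = counts, vafs = setNames(vafs, pre$id))
}

## fast constructor for simulator output (inputs known valid and sorted)
new_sim_pileup <- function(positions, ref, counts, genome_length, sample_id) {
  cols <- c(list(pos = positions, ref = ref),
            lapply(seq_len(8L), function(j) counts[, j]))
  names(cols) <- c("pos", "ref", COUNT_COLS)
  out <- tibble::new_tibble(cols, nrow = length(positions))
  attr(out, "genome_length") <- genome_length
  attr(out, "sample_id") <- sample_id
  out
}

#' Simulate single-cell mitochondrial pileups with known clonal truth
#'
#' Each cell draws a clone by `clone_fractions`; for every variant in that
#' clone's set the cell draws a cellular VAF from the configured Beta; at
#' every covered site the cell draws a depth from the depth model,
#' variant-supporting reads from `Binomial(depth, VAF)`, sequencing errors
#' on the remaining reads, and a forward/reverse strand split. Doublet
#' libraries merge the counts of two independently drawn cells.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `mito_sim`: `pileups` (named list of pileup
#'   tibbles), `truth` (list with `cells` -- `cell_id`, `clone`,
#'   `clone_label`, `is_doublet` -- `cell_vafs` and `variants` tibbles),
#'   and `config`.
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  positions <- cfg$covered_positions %||% seq_len(cfg$genome_length)
  ref <- sim_reference(cfg, positions)
  n_clones <- length(cfg$clone_fractions)
  pre_by_clone <- sim_clone_lookup(cfg, positions)
  n_sites <- length(positions)
  withr::with_seed(cfg$seed, {
    cell_ids <- sprintf("cell_%04d", seq_len(cfg$n_cells))
    is_doublet <- stats::runif(cfg$n_cells) < cfg$doublet_rate
    pileups <- vector("list", cfg$n_cells)
    clone1 <- integer(cfg$n_cells)
    clone2 <- rep(NA_integer_, cfg$n_cells)
    vaf_rows <- vector("list", cfg$n_cells)
    for (c_i in seq_len(cfg$n_cells)) {
      clone1[c_i] <- sample.int(n_clones, 1L, prob = cfg$clone_fractions)
      lib <- sim_one_library(cfg, pre_by_clone[[clone1[c_i]]], n_sites, ref)
      counts <- lib$counts
      vafs <- lib$vafs
      if (is_doublet[c_i]) {
        clone2[c_i] <- sample.int(n_clones, 1L, prob = cfg$clone_fractions)
        lib2 <- sim_one_library(cfg, pre_by_clone[[clone2[c_i]]], n_sites, ref)
        counts <- counts + lib2$counts
        vafs <- c(vafs, lib2$vafs)
      }
      pileups[[c_i]] <- new_sim_pileup(positions, ref, counts,
                                       cfg$genome_length, cell_ids[c_i])
      if (length(vafs) > 0L) {
        vaf_rows[[c_i]] <- list(cell_id = cell_ids[c_i],
                                variant_id = names(vafs), vaf = unname(vafs))
      }
    }
    names(pileups) <- cell_ids
    nz <- purrr::compact(vaf_rows)
    cell_vafs <- tibble::tibble(
      cell_id = rep(vapply(nz, `[[`, "", "cell_id"),
                    vapply(nz, function(x) length(x$variant_id), 0L)),
      variant_id = as.character(unlist(lapply(nz, `[[`, "variant_id"))),
      vaf = as.numeric(unlist(lapply(nz, `[[`, "vaf"))))
    cv <- cfg$clone_variants
    truth <- list(
      cells = tibble::tibble(
        cell_id = cell_ids, clone = clone1,
        clone_label = ifelse(is_doublet,
                             paste0("clone_", pmin(clone1, clone2),
                                    "+clone_", pmax(clone1, clone2)),
                             paste0("clone_", clone1)),
        is_doublet = is_doublet),
      cell_vafs = cell_vafs,
      variants = if (nrow(cv) > 0L) {
        tibble::tibble(variant_id = variant_id(cv$pos, cv$ref, cv$alt),
                       clone = cv$clone, pos = cv$pos, ref = cv$ref,
                       alt = cv$alt, vaf_mean = cv$vaf_mean)
      } else {
        tibble::tibble(variant_id = character(), clone = integer(),
                       pos = integer(), ref = character(),
                       alt = character(), vaf_mean = double())
      })
    structure(list(pileups = pileups, truth = truth, config = cfg),
              class = "mito_sim")
  })
}

#' Simulate a bulk mitochondrial pileup
#'
#' The bulk VAF of each variant is its population-weighted mean cellular
#' VAF (clone fraction times mean heteroplasmy); counts at `total_depth`
#' are drawn binomially with the same error and strand models as
#' [simulate_cells()].
#'
#' @param cfg A [sim_config()].
#' @param total_depth Bulk depth per site (> 0).
#' @return A pileup tibble.
#' @export
simulate_bulk <- function(cfg, total_depth) {
  stopifnot(inherits(cfg, "sim_config"))
  check_count(total_depth, "total_depth", min = 1)
  positions <- cfg$covered_positions %||% seq_len(cfg$genome_length)
  ref <- sim_reference(cfg, positions)
  cv <- cfg$clone_variants
  withr::with_seed(cfg$seed + 1L, {
    depth <- sim_depth(modifyList(cfg, list(depth_mean = total_depth)),
                       length(positions))
    alt_reads <- integer(length(positions))
    alt_idx <- rep(NA_integer_, length(positions))
    if (nrow(cv) > 0L) {
      ## expected bulk VAF: clone fraction times mean cellular heteroplasmy
      agg <- tibble::tibble(pos = cv$pos, alt = cv$alt,
                            vaf = cv$vaf_mean * cfg$clone_fractions[cv$clone]) |>
        dplyr::group_by(.data$pos, .data$alt) |>
        dplyr::summarise(vaf = sum(.data$vaf), .groups = "drop")
      if (anyDuplicated(agg$pos) > 0L) {
        stop_validation(
          "simulate_bulk does not support two alternate alleles at one position")
      }
      idx <- match(agg$pos, positions)
      alt_reads[idx] <- rbinom(nrow(agg), depth[idx], pmin(agg$vaf, 1))
      alt_idx[idx] <- match(agg$alt, ALLELES)
    }
    counts <- sim_count_matrix(depth, ref, alt_idx, alt_reads,
                               cfg$error_rate, cfg$strand_prob)
    new_sim_pileup(positions, ref, counts, cfg$genome_length, "bulk")
  })
}

#' Write a simulated dataset to disk
#'
#' Writes one pileup TSV per cell under `dir/cells/`, the ground truth as
#' JSON, and a manifest recording the full configuration.
#'
#' @param sim A `mito_sim` object from [simulate_cells()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mito_sim"))
  cells_dir <- file.path(dir, "cells")
  dir.create(cells_dir, recursive = TRUE, showWarnings = FALSE)
  for (cell in names(sim$pileups)) {
    write_pileup(sim$pileups[[cell]], file.path(cells_dir,
                                                paste0(cell, ".tsv")))
  }
  jsonlite::write_json(
    list(cells = sim$truth$cells, cell_vafs = sim$truth$cell_vafs,
         variants = sim$truth$variants),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  cfg <- sim$config
  cfg$clone_variants <- as.data.frame(cfg$clone_variants)
  yaml::write_yaml(unclass(cfg), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
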