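#' Probability that a given mtDNA site is mutated in one cell
#'
#' With per-base per-generation mutation rate `r` and `n` mtDNA copies per
#' cell, the chance of observing a mutation at a given site in a cell is
#' `n * r` (capped at 1). With `r ~ 1e-7` and `n` between 100 and 10000,
#' this is 1e-5 to 1e-3 -- small enough that recurrent independent origin
#' of the same variant across cells is negligible, the premise of using
#' shared heteroplasmies as lineage marks.
#'
#' @param n_copies mtDNA copies per cell (>= 1).
#' @param rate Per-base mutation rate (> 0, default 1e-7).
#' @return A probability.
#' @export
#' @examples
#' independent_origin_probability(10000) # 1e-3
#' independent_origin_probability(100)   # 1e-5
independent_origin_probability <- function(n_copies, rate = 1e-7) {
  if (!is.numeric(n_copies) || any(n_copies < 1)) {
    stop_validation("`n_copies` must be >= 1")
  }
  if (!is.numeric(rate) || any(rate <= 0)) {
    stop_validation("`rate` must be > 0")
  }
  pmin(n_copies * rate, 1)
}

#' Probability that N cells share a variant by independent origin
#'
#' `p_n ^ n_cells`: the chance that the same site mutated independently in
#' every one of `n_cells` cells. Already for 3 cells at `p_n = 1e-3` this
#' is 1e-9, which is why 3 or more cells sharing a heteroplasmy are taken
#' to descend from a common ancestor.
#'
#' @param p_n Per-cell mutation probability ([independent_origin_probability()]).
#' @param n_cells Number of cells sharing the variant (>= 1).
#' @return A probability.
#' @export
coincidence_probability <- function(p_n, n_cells) {
  check_proportion(p_n, "p_n")
  check_count(n_cells, "n_cells", min = 1)
  p_n^n_cells
}

#' Expected number of cells co-detecting two independent variants
#'
#' Under the null that two variants mark unrelated lineages, the expected
#' number of cells detecting both is `p_v1 * p_v2 * N`. Optionally, per-cell
#' weights normalize for sequencing depth: `sum(p_v1 * p_v2 * w_c)` where
#' `w_c` is the product of the two per-cell detection probabilities given
#' that cell's depth (see [detection_probability()]), rescaled so that
#' uniform full detectability recovers the unweighted formula.
#'
#' @param p_v1,p_v2 Per-variant detection frequencies in `[0, 1]`.
#' @param n_cells Number of cells.
#' @param weights Optional per-cell weights of length `n_cells`.
#' @return Expected co-detection count.
#' @export
expected_cooccurrence <- function(p_v1, p_v2, n_cells, weights = NULL) {
  check_proportion(p_v1, "p_v1")
  check_proportion(p_v2, "p_v2")
  check_count(n_cells, "n_cells", min = 0)
  if (is.null(weights)) {
    return(p_v1 * p_v2 * n_cells)
  }
  if (length(weights) != n_cells) {
    stop_validation("`weights` must have length n_cells (%d)", n_cells)
  }
  sum(p_v1 * p_v2 * weights)
}

#' Group co-detected variants into clone-defining sets
#'
#' Variants inherited from the same ancestral cell are co-detected in the
#' same cells far more often than independence allows. This builds a
#' co-detection graph: an edge joins two variants when their observed
#' co-detection count exceeds the upper Poisson quantile of the expected
#' count under independence ([expected_cooccurrence()], optionally
#' depth-normalized). Connected components supported by at least
#' `min_cells` carrier cells become clone-defining sets; weaker components
#' are left ungrouped.
#'
#' @param genotypes A binarized genotype tibble ([binarize_genotypes()]).
#' @param min_cells Carrier cells required to accept a set (default 3, the
#'   point at which independent recurrence is vanishingly unlikely).
#' @param exceedance_quantile Poisson quantile for the co-detection test
#'   (default 0.99).
#' @param depth_normalize Weight the expected count by per-cell detection
#'   probabilities estimated from carrier VAFs and per-cell site depths
#'   (default `TRUE`).
#' @param min_support Reads for positivity, used by the depth weights
#'   (default 1).
#' @return A list of character vectors of variant ids (clone sets), ordered
#'   by decreasing carrier support, with attribute `ungrouped` holding the
#'   remaining variant ids. Empty (with a warning) when no variant reaches
#'   `min_cells` carriers.
#' @export
infer_clone_sets <- function(genotypes, min_cells = 3,
                             exceedance_quantile = 0.99,
                             depth_normalize = TRUE,
                             min_support = 1) {
  check_count(min_cells, "min_cells", min = 1)
  check_proportion(exceedance_quantile, "exceedance_quantile")
  if (!"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() first")
  }
  det <- genotype_matrix(genotypes, "detected")
  n_cells <- nrow(det)
  vars <- colnames(det)
  carriers <- colSums(det)
  eligible <- vars[carriers >= min_cells]
  if (length(eligible) == 0L) {
    warn(sprintf("no variant detected in >= %d cells; no clone sets inferred",
                 min_cells))
    out <- list()
    attr(out, "ungrouped") <- vars
    return(out)
  }
  p_v <- carriers / n_cells

  ## per-cell detection probability given depth, using the mean carrier VAF
  ## as the variant's cellular allele-frequency estimate
  w <- NULL
  if (depth_normalize) {
    depth <- genotype_matrix(genotypes, "site_depth")[rownames(det), vars,
                                                      drop = FALSE]
    support <- genotype_matrix(genotypes, "support")[rownames(det), vars,
                                                     drop = FALSE]
    f_hat <- vapply(seq_along(vars), function(j) {
      carr <- det[, j] > 0
      if (!any(carr)) return(0)
      mean(support[carr, j] / pmax(depth[carr, j], 1))
    }, numeric(1))
    pdet <- vapply(seq_along(vars), function(j) {
      detection_probability(f_hat[j], depth[, j], min_support = min_support)
    }, numeric(nrow(det)))
    if (is.null(dim(pdet))) pdet <- matrix(pdet, nrow = 1L)
    colnames(pdet) <- vars
  }

  edges <- character(0)
  for (i in seq_along(eligible)) {
    for (j in seq_len(i - 1L)) {
      v1 <- eligible[i]; v2 <- eligible[j]
      observed <- sum(det[, v1] & det[, v2])
      if (depth_normalize) {
        ## rescale joint detectability so fully detectable cells weigh 1
        wts <- pdet[, v1] * pdet[, v2]
        denom <- mean(pdet[, v1]) * mean(pdet[, v2])
        wts <- if (denom > 0) wts / denom else rep(0, n_cells)
        expected <- expected_cooccurrence(p_v[v1], p_v[v2], n_cells,
                                          weights = wts)
      } else {
        expected <- expected_cooccurrence(p_v[v1], p_v[v2], n_cells)
      }
      if (observed > qpois(exceedance_quantile, expected)) {
        edges <- c(edges, v1, v2)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(eligible)
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  keep <- vapply(sets, function(s) {
    sum(rowSums(det[, s, drop = FALSE]) > 0) >= min_cells
  }, logical(1))
  grouped <- unname(sets[keep])
  support_n <- vapply(grouped, function(s) {
    sum(rowSums(det[, s, drop = FALSE]) > 0)
  }, numeric(1))
  grouped <- lapply(grouped[order(-support_n)], sort)
  out <- grouped
  attr(out, "ungrouped") <- setdiff(vars, unlist(grouped))
  out
}

#' Assign cells to clones
#'
#' A cell whose detections fall in exactly one clone-defining set is
#' assigned to that clone; detections spanning two or more sets mark a
#' doublet (two cells captured as one library), which is excluded from
#' downstream clone counts. Cells with no clone-set detection are labelled
#' `WT` when the wild-type rule allows (sufficient coverage, see
#' [classify_wt_cells()]) and `unassigned` otherwise -- including cells
#' whose only detections are in ungrouped variants.
#'
#' @param genotypes A binarized genotype tibble.
#' @param clone_sets A list of disjoint variant-id sets
#'   ([infer_clone_sets()]).
#' @param wt_labels Optional tibble `cell_id`, `label` from
#'   [classify_wt_cells()]; cells labelled `WT` there and detecting no
#'   clone variant become `WT`.
#' @return An object of class `mito_clones`: list with `clone_sets`,
#'   `assignments` (tibble `cell_id`, `label`, `n_sets_hit`, `evidence`
#'   list column of detected variant ids) and `params`. [tidy()] returns
#'   the assignments, [glance()] a one-row summary.
#' @export
assign_clones <- function(genotypes, clone_sets, wt_labels = NULL) {
  if (!"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() first")
  }
  sets <- lapply(clone_sets, as.character)
  if (length(sets) > 1L) {
    all_ids <- unlist(sets)
    if (anyDuplicated(all_ids) > 0L) {
      stop_validation("clone sets must be pairwise disjoint")
    }
  }
  det <- genotype_matrix(genotypes, "detected")
  cells <- rownames(det)
  set_names <- paste0("clone_", seq_along(sets))
  hits <- if (length(sets) == 0L) {
    matrix(FALSE, nrow(det), 0L)
  } else {
    vapply(sets, function(s) {
      s <- intersect(s, colnames(det))
      if (length(s) == 0L) return(rep(FALSE, nrow(det)))
      rowSums(det[, s, drop = FALSE]) > 0
    }, logical(nrow(det)))
  }
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1L)
  n_sets_hit <- rowSums(hits)
  label <- rep("unassigned", length(cells))
  single <- n_sets_hit == 1L
  label[single] <- set_names[apply(hits[single, , drop = FALSE], 1L,
                                   which.max)]
  label[n_sets_hit >= 2L] <- "doublet"
  if (!is.null(wt_labels)) {
    wt_cells <- wt_labels$cell_id[wt_labels$label == "WT"]
    label[n_sets_hit == 0L & cells %in% wt_cells] <- "WT"
  }
  evidence <- lapply(cells, function(cc) {
    colnames(det)[det[cc, ] > 0]
  })
  assignments <- tibble::tibble(cell_id = cells, label = label,
                                n_sets_hit = as.integer(n_sets_hit),
                                evidence = evidence)
  structure(list(clone_sets = setNames(sets, set_names),
                 assignments = assignments,
                 params = list(n_cells = length(cells),
                               wt_rule = !is.null(wt_labels))),
            class = "mito_clones")
}

#' @export
print.mito_clones <- function(x, ...) {
  cat("<mito_clones>\n")
  for (k in names(x$clone_sets)) {
    cat(sprintf("  %s: %s (%d cells)\n", k,
                paste(x$clone_sets[[k]], collapse = ", "),
                sum(x$assignments$label == k)))
  }
  tab <- table(x$assignments$label)
  for (lbl in c("WT", "doublet", "unassigned")) {
    if (lbl %in% names(tab)) cat(sprintf("  %s: %d cells\n", lbl, tab[[lbl]]))
  }
  invisible(x)
}

#' @rdname assign_clones
#' @param x A `mito_clones` object.
#' @param ... Unused.
#' @method tidy mito_clones
#' @export
tidy.mito_clones <- function(x, ...) {
  x$assignments
}

#' @rdname assign_clones
#' @method glance mito_clones
#' @export
glance.mito_clones <- function(x, ...) {
  lbl <- x$assignments$label
  tibble::tibble(
    n_cells = length(lbl),
    n_clones = length(x$clone_sets),
    n_assigned = sum(startsWith(lbl, "clone_")),
    n_wt = sum(lbl == "WT"),
    n_doublet = sum(lbl == "doublet"),
    n_unassigned = sum(lbl == "unassigned"),
    doublet_rate = mean(lbl == "doublet"))
}

#' Shared versus population-specific variants across sorted populations
#'
#' Given per-population variant tables (e.g. pre-leukemic stem cells,
#' leukemic stem cells, blasts), categorizes each heteroplasmic variant as
#' shared across populations (present above the reporting threshold in two
#' or more) or specific to one population. Shared variants place the
#' populations carrying them on a common branch of the lineage hierarchy;
#' population-specific variants mark subsequent private expansion.
#'
#' @param variant_tables A named list (>= 2 entries) of classified
#'   variant-call tibbles, one per population.
#' @param report_cut Presence threshold on VAF (default 0.01).
#' @return A long tibble: `variant_id`, `pos`, `ref`, `alt`, `population`,
#'   `vaf`, `depth`, `n_populations`, `populations`, `category`
#'   (`shared_across_populations` or `population_specific:<name>`),
#'   ordered by decreasing sharing then position. Rows exist only for
#'   populations where the variant is present.
#' @export
population_hierarchy <- function(variant_tables, report_cut = 0.01) {
  if (length(variant_tables) < 2L || is.null(names(variant_tables))) {
    stop_validation("`variant_tables` must be a named list of >= 2 populations")
  }
  check_proportion(report_cut, "report_cut", allow_zero = FALSE,
                   allow_one = FALSE)
  long <- purrr::imap_dfr(variant_tables, function(calls, popn) {
    het <- passing_variants(calls)
    het <- het[het$vaf > report_cut, , drop = FALSE]
    tibble::tibble(variant_id = het$variant_id, pos = het$pos,
                   ref = het$ref, alt = het$alt, population = popn,
                   vaf = het$vaf, depth = het$depth)
  })
  if (nrow(long) == 0L) {
    return(tibble::tibble(variant_id = character(), pos = integer(),
                          ref = character(), alt = character(),
                          population = character(), vaf = double(),
                          depth = integer(), n_populations = integer(),
                          populations = character(), category = character()))
  }
  ref_check <- long |>
    dplyr::distinct(.data$pos, .data$ref) |>
    dplyr::count(.data$pos)
  if (any(ref_check$n > 1L)) {
    stop_validation("inconsistent reference allele at position %d",
                    ref_check$pos[ref_check$n > 1L][1])
  }
  meta <- long |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(n_populations = dplyr::n_distinct(.data$population),
                     populations = paste(sort(unique(.data$population)),
                                         collapse = "+"),
                     .groups = "drop")
  meta$category <- ifelse(meta$n_populations >= 2L,
                          "shared_across_populations",
                          paste0("population_specific:", meta$populations))
  out <- dplyr::left_join(long, meta, by = "variant_id")
  dplyr::arrange(out, dplyr::desc(.data$n_populations), .data$pos,
                 .data$population)
}
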