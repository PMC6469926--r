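test_that("independent-origin probability is copy number times rate", {
  expect_equal(independent_origin_probability(1e4, 1e-7), 1e-3)
  expect_equal(independent_origin_probability(100, 1e-7), 1e-5)
  expect_equal(independent_origin_probability(1e9, 1e-7), 1) # capped
  expect_error(independent_origin_probability(0),
               class = "mitolineage_validation_error")
})

test_that("coincidence probability decays geometrically in cell count", {
  expect_equal(coincidence_probability(1e-3, 3), 1e-9)
  expect_equal(coincidence_probability(1, 50), 1)
  expect_equal(coincidence_probability(1e-5, 2), 1e-10)
  # strictly decreasing in N for 0 < p < 1
  for (p in c(1e-5, 1e-3, 0.5, 0.99)) {
    vals <- coincidence_probability(p, 1:8)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("expected co-occurrence follows the product formula", {
  expect_equal(expected_cooccurrence(0.1, 0.1, 100), 1)
  expect_equal(expected_cooccurrence(0, 0.9, 1000), 0)
  expect_equal(expected_cooccurrence(0.2, 0.5, 10, weights = rep(1, 10)), 1)
  expect_error(expected_cooccurrence(0.2, 0.5, 10, weights = rep(1, 4)),
               class = "mitolineage_validation_error")
})

test_that("observed co-detection of conditionally independent variants sits in the Poisson band", {
  # one clone carries both variants; given fixed depth, detections are
  # independent across variants, so the null expectation applies
  cv <- dplyr::bind_rows(sim_variants(1, 40, "T", "C", 0.08, Inf),
                         sim_variants(1, 80, "T", "G", 0.05, Inf))
  cfg <- sim_config(n_cells = 800, clone_fractions = 1, clone_variants = cv,
                    genome_length = 100, depth_model = "fixed",
                    depth_mean = 20, error_rate = 0,
                    covered_positions = c(40, 80), seed = 19)
  g <- genotype_simulation(simulate_cells(cfg))
  det <- genotype_matrix(g, "detected")
  observed <- sum(det[, "T40C"] & det[, "T80G"])
  expected <- expected_cooccurrence(mean(det[, "T40C"]), mean(det[, "T80G"]),
                                    nrow(det))
  expect_gte(observed, qpois(0.025, expected))
  expect_lte(observed, qpois(0.975, expected))
})

test_that("block-diagonal co-detection recovers the two variant sets", {
  # 40 cells: 20 detect {A,B}, 20 detect {C}; perfect blocks
  cells <- sprintf("c%02d", 1:40)
  g <- tidyr::expand_grid(cell_id = cells,
                          tibble::tibble(variant_id = c("A10G", "A20G", "A30G"),
                                         pos = c(10L, 20L, 30L), ref = "A",
                                         alt = "G"))
  in_block1 <- g$cell_id %in% cells[1:20] & g$variant_id %in% c("A10G", "A20G")
  in_block2 <- g$cell_id %in% cells[21:40] & g$variant_id == "A30G"
  g$support <- ifelse(in_block1 | in_block2, 5L, 0L)
  g$site_depth <- 50L
  g <- binarize_genotypes(g)
  sets <- infer_clone_sets(g, min_cells = 3)
  expect_equal(length(sets), 2L)
  expect_setequal(sets[[1]], c("A10G", "A20G"))
  expect_equal(sets[[2]], "A30G")
  expect_equal(attr(sets, "ungrouped"), character(0))
})

test_that("variants below the carrier floor stay ungrouped", {
  g <- tibble::tibble(cell_id = sprintf("c%02d", 1:10),
                      variant_id = "A10G", pos = 10L, ref = "A", alt = "G",
                      support = c(1L, rep(0L, 9)), site_depth = 30L)
  g <- binarize_genotypes(g)
  expect_warning(sets <- infer_clone_sets(g, min_cells = 3),
                 "no clone sets")
  expect_equal(length(sets), 0L)
  expect_equal(attr(sets, "ungrouped"), "A10G")
})

test_that("simulated two-clone structure is recovered exactly", {
  sim <- simulate_cells(two_clone_config(n_cells = 150, depth_mean = 50,
                                         seed = 101))
  g <- genotype_simulation(sim)
  sets <- infer_clone_sets(g, min_cells = 3)
  expect_equal(length(sets), 2L)
  expect_setequal(sets[[1]], c("A30G", "T60C", "A90C", "T120A"))
  expect_setequal(sets[[2]], c("T180G", "T240C"))
})

test_that("clone sets are disjoint and each variant appears at most once", {
  for (seed in c(7, 55)) {
    sim <- simulate_cells(two_clone_config(n_cells = 100, seed = seed))
    g <- genotype_simulation(sim)
    sets <- infer_clone_sets(g)
    ids <- unlist(sets)
    expect_equal(anyDuplicated(ids), 0L)
    expect_true(all(ids %in% unique(g$variant_id)))
  }
})

test_that("cells are assigned to clones, doublets flagged on mixtures", {
  g <- tidyr::expand_grid(
    cell_id = c("pure1", "mixed", "silent"),
    tibble::tibble(variant_id = c("A10G", "A20G"), pos = c(10L, 20L),
                   ref = "A", alt = "G"))
  g$support <- dplyr::case_when(
    g$cell_id == "pure1" & g$variant_id == "A10G" ~ 4L,
    g$cell_id == "mixed" ~ 2L,
    .default = 0L)
  g$site_depth <- 50L
  g <- binarize_genotypes(g)
  model <- assign_clones(g, list("A10G", "A20G"))
  lbl <- setNames(tidy(model)$label, tidy(model)$cell_id)
  expect_equal(lbl[["pure1"]], "clone_1")
  expect_equal(lbl[["mixed"]], "doublet")
  expect_equal(lbl[["silent"]], "unassigned")
  gl <- glance(model)
  expect_equal(gl$n_doublet, 1L)
  expect_equal(gl$n_clones, 2L)
  expect_error(assign_clones(g, list(c("A10G", "A20G"), "A20G")),
               class = "mitolineage_validation_error")
})

test_that("assignment labels never contradict the evidence", {
  sim <- simulate_cells(two_clone_config(n_cells = 120, doublet_rate = 0.1,
                                         seed = 8))
  g <- genotype_simulation(sim)
  sets <- infer_clone_sets(g)
  model <- assign_clones(g, sets)
  td <- tidy(model)
  for (k in seq_along(sets)) {
    in_k <- td$label == paste0("clone_", k)
    outside <- setdiff(unlist(sets), sets[[k]])
    expect_false(any(purrr::map_lgl(td$evidence[in_k],
                                    ~ any(.x %in% outside))))
  }
  doublet_rows <- td[td$label == "doublet", ]
  expect_true(all(doublet_rows$n_sets_hit >= 2L))
})

test_that("clone recovery agrees with simulated truth (ARI >= 0.95)", {
  skip_if_not_installed("mclust")
  sim <- simulate_cells(two_clone_config(n_cells = 150, depth_mean = 100,
                                         error_rate = 1e-3, seed = 42))
  g <- genotype_simulation(sim)
  sets <- infer_clone_sets(g)
  model <- assign_clones(g, sets)
  td <- dplyr::inner_join(tidy(model), sim$truth$cells, by = "cell_id")
  td <- td[!td$label %in% c("doublet", "WT", "unassigned"), ]
  ari <- mclust::adjustedRandIndex(td$label, td$clone)
  expect_gte(ari, 0.95)
  # accuracy of the label mapping itself
  map <- table(td$label, td$clone)
  expect_gte(sum(apply(map, 1, max)) / sum(map), 0.95)
})

test_that("doublet flagging matches the configured doublet rate", {
  # two clones with fully detectable variant sets: every true mixed-clone
  # doublet shows variants from both sets
  cv <- dplyr::bind_rows(sim_variants(1, 30, "A", "G", 0.6, Inf),
                         sim_variants(2, 60, "T", "C", 0.6, Inf))
  cfg <- sim_config(n_cells = 600, clone_fractions = c(0.5, 0.5),
                    clone_variants = cv, genome_length = 100,
                    depth_model = "fixed", depth_mean = 60, error_rate = 0,
                    doublet_rate = 0.12, covered_positions = c(30, 60),
                    seed = 33)
  sim <- simulate_cells(cfg)
  g <- genotype_simulation(sim)
  model <- assign_clones(g, list("A30G", "T60C"))
  flagged <- mean(tidy(model)$label == "doublet")
  # only mixed-clone doublets are detectable: rate x P(two different clones)
  detectable <- 0.12 * 0.5
  se <- sqrt(detectable * (1 - detectable) / 600)
  expect_lt(abs(flagged - detectable), 3 * se)
  truth_doublet <- sim$truth$cells$is_doublet &
    !is.na(sim$truth$cells$clone_label) &
    grepl("\\+", sim$truth$cells$clone_label) &
    sim$truth$cells$clone_label == "clone_1+clone_2"
  expect_equal(sum(tidy(model)$label == "doublet"), sum(truth_doublet))
})

test_that("population hierarchy separates shared from specific variants", {
  mk_table <- function(spec) call_heteroplasmies(variant_pileup(spec))
  shared <- tibble::tibble(pos = 1000, ref = "A", alt = "G",
                           alt_fwd = 25, alt_rev = 25, depth = 1000)
  lsc_extra <- tibble::tibble(pos = 2000, ref = "C", alt = "T",
                              alt_fwd = 40, alt_rev = 40, depth = 1000)
  phsc_only <- tibble::tibble(pos = 3000, ref = "G", alt = "A",
                              alt_fwd = 20, alt_rev = 20, depth = 1000)
  tables <- list(
    pHSC = mk_table(dplyr::bind_rows(shared, phsc_only)),
    LSC = mk_table(dplyr::bind_rows(shared, lsc_extra)),
    blast = mk_table(dplyr::bind_rows(shared, lsc_extra)))
  ph <- population_hierarchy(tables, report_cut = 0.01)
  cat_of <- function(v) unique(ph$category[ph$variant_id == v])
  expect_equal(cat_of("A1000G"), "shared_across_populations")
  expect_equal(unique(ph$n_populations[ph$variant_id == "A1000G"]), 3L)
  # present in LSC and blast but not pHSC: shared on that subtree
  expect_equal(cat_of("C2000T"), "shared_across_populations")
  expect_equal(unique(ph$populations[ph$variant_id == "C2000T"]),
               "LSC+blast")
  expect_equal(cat_of("G3000A"), "population_specific:pHSC")
  # ordered by breadth of sharing, then position
  expect_equal(ph$variant_id[1], "A1000G")
  expect_error(population_hierarchy(tables["pHSC"]),
               class = "mitolineage_validation_error")
})

test_that("population tables with conflicting reference alleles are rejected", {
  t1 <- call_heteroplasmies(variant_pileup(tibble::tibble(
    pos = 500, ref = "A", alt = "G", alt_fwd = 25, alt_rev = 25,
    depth = 1000)))
  t2 <- call_heteroplasmies(variant_pileup(tibble::tibble(
    pos = 500, ref = "C", alt = "G", alt_fwd = 25, alt_rev = 25,
    depth = 1000)))
  expect_error(population_hierarchy(list(a = t1, b = t2)),
               class = "mitolineage_validation_error")
})
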