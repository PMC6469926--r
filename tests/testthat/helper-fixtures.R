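# Fixture builders shared across test files. Everything is generated in
# code; no data files.

COUNT_COLS_TEST <- function() {
  c("a_fwd", "a_rev", "c_fwd", "c_rev", "g_fwd", "g_rev", "t_fwd", "t_rev")
}

# One pileup row with explicit stranded counts.
fixture_site <- function(pos, ref, a_fwd = 0, a_rev = 0, c_fwd = 0, c_rev = 0,
                         g_fwd = 0, g_rev = 0, t_fwd = 0, t_rev = 0) {
  tibble::tibble(pos = pos, ref = ref, a_fwd = a_fwd, a_rev = a_rev,
                 c_fwd = c_fwd, c_rev = c_rev, g_fwd = g_fwd, g_rev = g_rev,
                 t_fwd = t_fwd, t_rev = t_rev)
}

# Pileup containing the requested variants: per row (pos, ref, alt,
# alt_fwd, alt_rev, depth), the remaining depth is reference reads split
# evenly between strands.
variant_pileup <- function(spec, genome_length = 16569) {
  rows <- purrr::pmap_dfr(spec, function(pos, ref, alt, alt_fwd, alt_rev,
                                         depth) {
    counts <- stats::setNames(rep(0, 8),
                              c("a_fwd", "a_rev", "c_fwd", "c_rev",
                                "g_fwd", "g_rev", "t_fwd", "t_rev"))
    counts[paste0(tolower(alt), "_fwd")] <- alt_fwd
    counts[paste0(tolower(alt), "_rev")] <- alt_rev
    ref_reads <- depth - alt_fwd - alt_rev
    counts[paste0(tolower(ref), "_fwd")] <-
      counts[paste0(tolower(ref), "_fwd")] + floor(ref_reads / 2)
    counts[paste0(tolower(ref), "_rev")] <-
      counts[paste0(tolower(ref), "_rev")] + ceiling(ref_reads / 2)
    dplyr::bind_cols(tibble::tibble(pos = pos, ref = ref),
                     tibble::as_tibble(as.list(counts)))
  })
  as_pileup(rows, genome_length = genome_length)
}

# A random but reproducible sparse pileup for round-trip / property tests.
random_pileup <- function(n_sites = 50, genome_length = 16569, seed = 1) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(genome_length, n_sites))
    counts <- matrix(rpois(n_sites * 8L, 5), n_sites, 8L)
    x <- tibble::tibble(pos = pos,
                        ref = sample(c("A", "C", "G", "T"), n_sites,
                                     replace = TRUE))
    x[c("a_fwd", "a_rev", "c_fwd", "c_rev",
        "g_fwd", "g_rev", "t_fwd", "t_rev")] <- as.data.frame(counts)
    as_pileup(x, genome_length = genome_length)
  })
}

# Default two-clone simulation used by lineage tests: clone 1 carries four
# variants, clone 2 two, VAFs at or above 0.1.
two_clone_config <- function(n_cells = 150, depth_mean = 100,
                             error_rate = 1e-3, doublet_rate = 0,
                             genome_length = 300, seed = 42,
                             depth_model = "nbinom") {
  cv <- dplyr::bind_rows(
    sim_variants(1, c(30, 60, 90, 120), c("A", "T", "A", "T"),
                 c("G", "C", "C", "A"), c(0.35, 0.25, 0.15, 0.10), 80),
    sim_variants(2, c(180, 240), c("T", "T"), c("G", "C"),
                 c(0.30, 0.20), 80))
  sim_config(n_cells = n_cells, clone_fractions = c(0.55, 0.45),
             clone_variants = cv, genome_length = genome_length,
             depth_model = depth_model, depth_mean = depth_mean,
             depth_size = 10, error_rate = error_rate,
             doublet_rate = doublet_rate, seed = seed)
}

# Run the standard genotyping chain on a simulation.
genotype_simulation <- function(sim, min_support = 1) {
  truth_vars <- sim$truth$variants
  cand <- tibble::tibble(variant_id = truth_vars$variant_id,
                         pos = truth_vars$pos, ref = truth_vars$ref,
                         alt = truth_vars$alt)
  binarize_genotypes(genotype_cells(sim$pileups, cand),
                     min_support = min_support)
}
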