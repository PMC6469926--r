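test_that("candidate caller honours the 0.001 VAF floor and alt-read floor", {
  p <- variant_pileup(tibble::tibble(
    pos = c(100, 200, 300), ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    alt_fwd = c(1, 0, 0), alt_rev = c(0, 0, 3), depth = c(1000, 500, 500)))
  calls <- call_variants(p, min_vaf = 0.001, min_alt_reads = 1)
  expect_setequal(calls$variant_id, c("A100G", "G300A"))
  expect_equal(calls$vaf[calls$variant_id == "A100G"], 0.001)
  # zero non-reference reads at 200 -> no call
  expect_false("C200T" %in% calls$variant_id)
})

test_that("multi-allelic sites yield one candidate per alternate allele", {
  site <- fixture_site(50, "A", a_fwd = 40, a_rev = 40, c_fwd = 5, c_rev = 5,
                       g_fwd = 10, g_rev = 0)
  calls <- call_variants(as_pileup(site))
  expect_setequal(calls$variant_id, c("A50C", "A50G"))
  expect_equal(calls$depth, c(100L, 100L))
  expect_equal(calls$vaf, (calls$fwd_alt + calls$rev_alt) / calls$depth)
})

test_that("called VAF matches simulated truth within binomial error", {
  cv <- sim_variants(1, 500, "A", "G", 0.25, Inf)
  cfg <- sim_config(n_cells = 1, clone_fractions = 1, clone_variants = cv,
                    genome_length = 1000, depth_model = "fixed",
                    depth_mean = 100, error_rate = 0, seed = 21)
  bulk <- simulate_bulk(cfg, 10000)
  calls <- call_variants(bulk)
  hit <- calls[calls$variant_id == "A500G", ]
  expect_equal(nrow(hit), 1L)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(hit$vaf - 0.25), 3 * se)
})

test_that("the default blacklist holds exactly the 13 recurrent artifacts", {
  bl <- default_blacklist()
  expect_equal(nrow(bl), 13L)
  expect_setequal(bl$variant_id,
                  c("A302C", "C309T", "C311T", "C312T", "C313T", "G316C",
                    "C514A", "A515G", "A523C", "C524G",
                    "C3106A", "T3109C", "C3110A"))
  expect_equal(bl$ref, substr(bl$variant_id, 1, 1))
})

test_that("blacklist filtering matches on (position, alt) pairs", {
  spec <- tibble::tibble(pos = c(309, 3106, 309),
                         ref = c("C", "C", "C"),
                         alt = c("T", "A", "G"),
                         alt_fwd = c(10, 10, 10), alt_rev = c(10, 10, 10),
                         depth = c(100, 100, 100))
  # site mode: C309G (same position, different alt) survives
  calls <- filter_blacklist(call_variants(variant_pileup(spec[c(1, 2), ])))
  expect_true(all(calls$classification == "filtered"))
  expect_true(all(purrr::map_lgl(calls$filter_reasons, ~ "blacklist" %in% .x)))

  p3 <- variant_pileup(spec[3, ])
  keep <- filter_blacklist(call_variants(p3))
  expect_false("blacklist" %in% unlist(keep$filter_reasons))
  # position mode widens removal to any alt at a blacklisted position
  drop <- filter_blacklist(call_variants(p3), match = "position")
  expect_true("blacklist" %in% unlist(drop$filter_reasons))
})

test_that("strand filter agrees with brute-force evaluation of its contract", {
  grid <- expand.grid(fwd = 0:8, rev = 0:8)
  grid <- grid[grid$fwd + grid$rev > 0, ]
  spec <- tibble::tibble(pos = seq_len(nrow(grid)), ref = "A", alt = "G",
                         alt_fwd = grid$fwd, alt_rev = grid$rev, depth = 100)
  calls <- filter_strand(call_variants(variant_pileup(spec), min_vaf = 1e-4))
  passed <- lengths(calls$filter_reasons) == 0L
  ratio <- grid$fwd / (grid$fwd + grid$rev)
  oracle <- grid$fwd > 2 & grid$rev > 2 & ratio > 0.3 & ratio < 0.7
  expect_equal(passed[order(calls$pos)], oracle)
  # boundary: ratio exactly 0.3 fails the strict inequality
  expect_false(oracle[grid$fwd == 3 & grid$rev == 7])
  # one-sided support fails both conditions
  expect_false(oracle[grid$fwd == 8 & grid$rev == 0])
  # symmetric support passes
  expect_true(oracle[grid$fwd == 5 & grid$rev == 5])
})

test_that("VAF classification separates homoplasmic, heteroplasmic, reported", {
  spec <- tibble::tibble(pos = c(10, 20, 30, 40),
                         ref = "A", alt = "G",
                         alt_fwd = c(475, 120, 2, 500),
                         alt_rev = c(475, 120, 3, 500),
                         depth = c(1000, 1000, 1000, 1000))
  calls <- classify_vaf(call_variants(variant_pileup(spec)))
  byid <- setNames(calls$classification, calls$variant_id)
  expect_equal(byid[["A10G"]], "homoplasmic")   # vaf 0.95
  expect_equal(byid[["A20G"]], "heteroplasmic") # vaf 0.24
  expect_equal(byid[["A30G"]], "filtered")      # vaf 0.005 < 1% report cut
  expect_true("below_report_threshold" %in%
                unlist(calls$filter_reasons[calls$variant_id == "A30G"]))
  # VAF exactly 1 stays homoplasmic and is not flagged suspect
  expect_equal(byid[["A40G"]], "homoplasmic")
  flags <- setNames(calls$filter_flags, calls$variant_id)
  expect_true("suspect_homoplasmic" %in% flags[["A10G"]])
  expect_false("suspect_homoplasmic" %in% flags[["A40G"]])
})

test_that("filter cascade pass/fail set is independent of filter order", {
  withr::with_seed(31, {
    spec <- tibble::tibble(
      pos = sample(c(1:500, 309, 3106), 40),
      ref = "C", alt = sample(c("T", "A", "G"), 40, replace = TRUE),
      alt_fwd = sample(0:30, 40, replace = TRUE),
      alt_rev = sample(0:30, 40, replace = TRUE))
    spec$depth <- spec$alt_fwd + spec$alt_rev + sample(0:2000, 40,
                                                       replace = TRUE)
    spec <- spec[!duplicated(spec$pos), ]
  })
  base <- call_variants(variant_pileup(spec), min_alt_reads = 1)
  filters <- list(filter_blacklist,
                  filter_strand,
                  classify_vaf)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  results <- lapply(perms, function(ord) {
    out <- base
    for (k in ord) out <- filters[[k]](out)
    out
  })
  pass_sets <- lapply(results, function(r) {
    sort(r$variant_id[lengths(r$filter_reasons) == 0L])
  })
  for (i in 2:6) expect_equal(pass_sets[[i]], pass_sets[[1]])
  reason_sets <- lapply(results, function(r) {
    lapply(r$filter_reasons[order(r$variant_id)], sort)
  })
  for (i in 2:6) expect_equal(reason_sets[[i]], reason_sets[[1]])
})

test_that("contamination screen flags heteroplasmy excess and common overlap", {
  mk_calls <- function(n, common_n) {
    spec <- tibble::tibble(pos = seq(100, by = 7, length.out = n),
                           ref = "A", alt = "G",
                           alt_fwd = 25, alt_rev = 25, depth = 1000)
    calls <- classify_vaf(filter_strand(call_variants(variant_pileup(spec))))
    list(calls = calls,
         common = tibble::tibble(pos = spec$pos[seq_len(common_n)],
                                 alt = "G"))
  }
  # the excluded-case pattern: 37 heteroplasmies, most overlapping common SNPs
  x <- mk_calls(37, 30)
  rep1 <- screen_contamination(x$calls, x$common)
  expect_true(rep1$flagged)
  expect_equal(rep1$n_heteroplasmic, 37L)
  expect_equal(rep1$n_overlapping_common, 30L)

  y <- mk_calls(3, 0)
  # a common list with no overlap: not flagged
  expect_false(screen_contamination(
    y$calls, tibble::tibble(pos = 2L, alt = "T"))$flagged)

  z <- mk_calls(10, 8)
  rep3 <- screen_contamination(z$calls, z$common)
  expect_true(rep3$flagged)           # 0.8 >= 0.5 overlap
  expect_equal(rep3$overlap_frac, 0.8)

  expect_warning(rep4 <- screen_contamination(y$calls, NULL),
                 "overlap check skipped")
  expect_false(rep4$flagged)
  expect_true(is.na(rep4$n_overlapping_common))
})

test_that("passing calls never carry a blacklisted site or a strand violation", {
  bulkish <- withr::with_seed(77, {
    spec <- tibble::tibble(
      pos = sample(16569, 60), ref = "A", alt = "G",
      alt_fwd = sample(0:50, 60, replace = TRUE),
      alt_rev = sample(0:50, 60, replace = TRUE))
    spec$depth <- spec$alt_fwd + spec$alt_rev + 500
    variant_pileup(spec)
  })
  calls <- call_heteroplasmies(bulkish)
  pass <- passing_variants(calls, c("heteroplasmic", "homoplasmic"))
  bl <- default_blacklist()
  expect_false(any(paste(pass$pos, pass$alt) %in% paste(bl$pos, bl$alt)))
  ratio <- pass$fwd_alt / (pass$fwd_alt + pass$rev_alt)
  expect_true(all(pass$fwd_alt > 2 & pass$rev_alt > 2 &
                    ratio > 0.3 & ratio < 0.7))
})

test_that("variant table round-trips through TSV and emits valid VCF lines", {
  spec <- tibble::tibble(pos = c(100, 309), ref = "C", alt = "T",
                         alt_fwd = c(20, 20), alt_rev = c(22, 22),
                         depth = c(400, 400))
  calls <- call_heteroplasmies(variant_pileup(spec))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variants(calls, f, vcf = TRUE)
  back <- read_variants(f)
  expect_equal(back$variant_id, calls$variant_id)
  expect_equal(back$classification, calls$classification)
  expect_equal(lapply(back$filter_reasons, sort),
               lapply(calls$filter_reasons, sort))
  vcf <- readLines(paste0(f, ".vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(body), 2L)
  expect_true(all(startsWith(body, "chrM\t")))
  expect_true(any(grepl("blacklist", body)))
})

test_that("common-variant lists load from TSV and VCF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(pos = c(73L, 263L), alt = c("G", "G")), tsv)
  expect_equal(read_common_variants(tsv)$pos, c(73L, 263L))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrM\t73\t.\tA\tG\t.\t.\t.",
               "chrM\t263\t.\tA\tG,C\t.\t.\t."), vcf)
  cv <- read_common_variants(vcf)
  expect_equal(nrow(cv), 3L)
  expect_setequal(cv$alt[cv$pos == 263], c("G", "C"))
})
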