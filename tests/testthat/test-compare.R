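test_that("divergence categories follow the threshold and margin rules", {
  paired <- data.frame(chrom = "c", start = 0, end = 1,
                       score_h1 = c(0.05, 0.05, 0.05, 0.90, 0.5, NA),
                       score_h2 = c(0.90, 0.07, 0.25, 0.04, 0.5, 0.9),
                       overhang = FALSE)
  out <- classify_divergence(paired, threshold = 0.1, margin = 0.3)
  expect_equal(out$category,
               c("h1_specific_lc", "conserved_repetitive", "indeterminate",
                 "h2_specific_lc", "conserved_unique", "indeterminate"))
  expect_equal(out$delta[1], 0.05 - 0.90)
  expect_true(is.na(out$delta[6]))
  expect_error(classify_divergence(paired, margin = -1), "margin")
})

test_that("comparing a profile with itself yields no divergence", {
  set.seed(41)
  sim <- generate_diploid(quick_config(seed = 41, n_chromosomes = 2,
                                       chrom_length = 100000))
  p <- complexity_profile(sim$hap1, window_spec(10000, 5000, 10))
  rec <- compare_profiles(p, p)
  expect_true(all(rec$category %in% c("conserved_repetitive",
                                      "conserved_unique", "indeterminate")))
  expect_true(all(rec$delta[!is.na(rec$delta)] == 0))
  expect_false(any(rec$overhang))
  ds <- summarize_divergence(rec)
  expect_true(all(ds$divergence_score == 0 | is.na(ds$divergence_score)))
})

test_that("swapping inputs mirrors deltas, labels, and asymmetry", {
  bp <- data.frame(chrom = "chr1", haplotype = "hap2", start = 2000,
                   span = 40000, monomer_length = 8,
                   stringsAsFactors = FALSE)
  sim <- generate_diploid(quick_config(seed = 43, n_chromosomes = 2,
                                       chrom_length = 200000,
                                       block_plan = bp))
  spec <- window_spec(10000, 5000, 10)
  p1 <- complexity_profile(sim$hap1, spec)
  p2 <- complexity_profile(sim$hap2, spec)
  fwd <- compare_profiles(p1, p2)
  rev <- compare_profiles(p2, p1)
  expect_equal(rev$delta, -fwd$delta)
  swap <- c(h1_specific_lc = "h2_specific_lc",
            h2_specific_lc = "h1_specific_lc",
            conserved_repetitive = "conserved_repetitive",
            conserved_unique = "conserved_unique",
            indeterminate = "indeterminate")
  expect_equal(rev$category, unname(swap[fwd$category]))
  expect_gt(sum(fwd$category == "h2_specific_lc"), 0)

  params <- segmentation_params(min_span = 30000, k = 10)
  b1 <- call_blocks(p1, params); b2 <- call_blocks(p2, params)
  ds_fwd <- summarize_divergence(fwd, b1, b2)
  ds_rev <- summarize_divergence(rev, b2, b1)
  expect_equal(ds_rev$terminal_asymmetry, -ds_fwd$terminal_asymmetry)
})

test_that("length differences appear as overhang windows", {
  set.seed(47)
  s1 <- c(chrA = random_seq(100000))
  s2 <- c(chrA = paste0(s1[["chrA"]], random_seq(50000)))
  spec <- window_spec(10000, 5000, 10)
  p1 <- complexity_profile(s1, spec)
  p2 <- complexity_profile(s2, spec)
  rec <- compare_profiles(p1, p2)
  # surplus h2 windows: starts 100k..145k on the 5 kb grid
  expect_equal(sum(rec$overhang), 10)
  expect_true(all(rec$category[rec$overhang] == "indeterminate"))
  expect_true(all(is.na(rec$score_h1[rec$overhang])))
})

test_that("profiles with different window settings refuse to compare", {
  set.seed(48)
  s <- c(chrA = random_seq(50000))
  p1 <- complexity_profile(s, window_spec(10000, 5000, 10))
  p2 <- complexity_profile(s, window_spec(10000, 10000, 10))
  expect_error(match_windows(p1, p2), "different window specifications")
  p3 <- complexity_profile(s, window_spec(10000, 5000, 5))
  expect_error(match_windows(p1, p3), "different window specifications")
})

test_that("chromosomes missing from one haplotype are excluded", {
  set.seed(49)
  s1 <- c(chrA = random_seq(50000), chrB = random_seq(50000))
  s2 <- c(chrA = random_seq(50000))
  spec <- window_spec(10000, 5000, 10)
  p1 <- complexity_profile(s1, spec)
  p2 <- complexity_profile(s2, spec)
  expect_message(rec <- compare_profiles(p1, p2), "only one profile")
  expect_equal(unique(rec$chrom), "chrA")
  expect_equal(attr(rec, "unpaired_chroms"), "chrB")
})

test_that("summary counts add up and categories partition windows", {
  set.seed(50)
  sim <- generate_diploid(quick_config(seed = 50, n_chromosomes = 3,
                                       chrom_length = 100000))
  p <- complexity_profile(sim$hap1, window_spec(10000, 5000, 10))
  rec <- compare_profiles(p, p)
  ds <- summarize_divergence(rec)
  cats <- c("conserved_repetitive", "conserved_unique", "h1_specific_lc",
            "h2_specific_lc", "indeterminate")
  expect_equal(rowSums(ds[, cats]), ds$n_windows,
               ignore_attr = TRUE)
  expect_equal(sum(ds$n_windows), nrow(rec))
})
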