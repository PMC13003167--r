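test_that("background generation is deterministic and respects GC", {
  expect_identical(generate_background(10, 0.5, seed = 1),
                   generate_background(10, 0.5, seed = 1))
  gc <- vapply(1:20, function(s) {
    x <- strsplit(generate_background(100000, 0.5, seed = s), "")[[1]]
    mean(x %in% c("G", "C"))
  }, numeric(1))
  # binomial sd is sqrt(0.25/1e5) ~ 0.0016; 0.01 is > 6 sd
  expect_true(all(abs(gc - 0.5) < 0.01))
  x <- strsplit(generate_background(100000, 0.7, seed = 3), "")[[1]]
  expect_lt(abs(mean(x %in% c("G", "C")) - 0.7), 0.01)
  expect_error(generate_background(0, 0.5), "configuration error")
  expect_error(generate_background(10, 1.2), "configuration error")
})

test_that("planted tandem blocks are strictly periodic", {
  set.seed(5)
  s <- random_seq(20000)
  res <- plant_tandem_block(s, start = 3000, span = 7000, monomer_length = 7)
  expect_equal(nchar(res$sequence), 20000)
  block <- substr(res$sequence, 3001, 10000)
  expect_identical(block, substr(strrep(res$monomer, 1000), 1, 7000))
  starts <- seq(1, 7000 - 6, by = 7)
  expect_true(all(substring(block, starts, starts + 6) == res$monomer))
  # flanks untouched
  expect_identical(substr(res$sequence, 1, 3000), substr(s, 1, 3000))
  expect_identical(substring(res$sequence, 10001), substring(s, 10001))
  expect_error(plant_tandem_block(s, 0, 10, 20), "monomer_length")
  expect_error(plant_tandem_block(s, 19000, 5000, 7), "out of bounds")
})

test_that("drawn monomers avoid the telomere motif", {
  set.seed(6)
  for (i in 1:20) {
    res <- plant_tandem_block(random_seq(1000), 0, 500, 7,
                              avoid = "TTTAGGG")
    arr <- strrep(res$monomer, 3)
    expect_false(grepl("TTTAGGG", arr, fixed = TRUE))
    expect_false(grepl("CCCTAAA", arr, fixed = TRUE))
  }
})

test_that("telomere planting writes exact arrays at each end", {
  set.seed(8)
  s <- random_seq(5000)
  left <- plant_telomere(s, "left", "TTTAGGG", 700)
  expect_identical(substr(left, 1, 700), strrep("TTTAGGG", 100))
  expect_identical(substring(left, 701), substring(s, 701))
  right <- plant_telomere(s, "right", "TTTAGGG", 700)
  expect_identical(substring(right, 4301), strrep("CCCTAAA", 100))
  expect_identical(plant_telomere(s, "left", "TTTAGGG", 0), s)
  expect_error(plant_telomere(s, "left", "TTTAGGG", 6000),
               "configuration error")
})

test_that("inversions are involutions and translocations conserve bases", {
  set.seed(9)
  haps <- list(hap1 = c(chrA = random_seq(1000), chrB = random_seq(800)),
               hap2 = c(chrA = random_seq(1000), chrB = random_seq(800)))
  inv <- list(type = "inversion", haplotype = "hap1", chrom = "chrA",
              start = 100, end = 200)
  once <- apply_sv(haps, inv)
  expect_false(identical(once$hap1[["chrA"]], haps$hap1[["chrA"]]))
  expect_identical(apply_sv(once, inv)$hap1, haps$hap1)
  # hap2 untouched
  expect_identical(once$hap2, haps$hap2)

  tr <- list(type = "translocation", haplotype = "hap2", chrom_a = "chrA",
             chrom_b = "chrB", breakpoint_a = 400, breakpoint_b = 600)
  out <- apply_sv(haps, tr)
  expect_equal(nchar(out$hap2[["chrA"]]), 400 + (800 - 600))
  expect_equal(nchar(out$hap2[["chrB"]]), 600 + (1000 - 400))
  expect_equal(sum(nchar(out$hap2)), sum(nchar(haps$hap2)))
  expect_identical(out$hap1, haps$hap1)

  bad <- list(type = "inversion", haplotype = "hap1", chrom = "chrA",
              start = 300, end = 200)
  expect_error(apply_sv(haps, bad), "configuration error")
})

test_that("diploid generation is reproducible and feature-faithful", {
  cfg <- simulation_config(n_chromosomes = 9, chrom_length = 120000,
                           seed = 42)
  sim1 <- generate_diploid(cfg)
  sim2 <- generate_diploid(cfg)
  expect_identical(sim1$hap1, sim2$hap1)
  expect_identical(sim1$hap2, sim2$hap2)
  expect_identical(sim1$truth, sim2$truth)

  # every truth interval extracted from the FASTA matches its definition
  truth <- sim1$truth
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    if (!r$kind %in% c("telomere", "terminal_block", "tandem_block")) next
    seq <- substr(sim1[[r$haplotype]][[r$chrom]], r$start + 1, r$end)
    if (r$kind == "telomere" && r$end_label == "right") {
      arr <- strrep(r$monomer, ceiling(nchar(seq) / nchar(r$monomer)))
      expect_identical(seq, substring(arr, nchar(arr) - nchar(seq) + 1))
    } else {
      expect_identical(seq,
                       substr(strrep(r$monomer,
                                     ceiling(nchar(seq) / nchar(r$monomer))),
                              1, nchar(seq)))
    }
  }
})

test_that("a plan with no features yields identical haplotypes", {
  cfg <- quick_config(seed = 3)
  sim <- generate_diploid(cfg)
  expect_identical(sim$hap1, sim$hap2)
  expect_equal(nrow(sim$truth), 0)
})

test_that("haplotype-specific plans appear in truth exactly once", {
  bp <- data.frame(chrom = "chr2", haplotype = "hap2", start = 50000,
                   span = 30000, monomer_length = 9,
                   stringsAsFactors = FALSE)
  cfg <- quick_config(seed = 4, n_chromosomes = 2, chrom_length = 200000,
                      block_plan = bp)
  sim <- generate_diploid(cfg)
  rec <- sim$truth[sim$truth$kind %in% c("terminal_block", "tandem_block"), ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$haplotype, "hap2")
  expect_equal(rec$chrom, "chr2")
  # hap1 keeps background there, hap2 does not
  expect_false(identical(substr(sim$hap1[["chr2"]], 50001, 80000),
                         substr(sim$hap2[["chr2"]], 50001, 80000)))
  expect_identical(sim$hap1[["chr1"]], sim$hap2[["chr1"]])
})

test_that("SVs relocate planted features with coordinates remapped", {
  bp <- data.frame(chrom = "chr1", haplotype = "both", start = 30000,
                   span = 10000, monomer_length = 7,
                   stringsAsFactors = FALSE)
  sv <- list(list(type = "inversion", haplotype = "hap2", chrom = "chr1",
                  start = 20000, end = 80000))
  cfg <- quick_config(seed = 5, n_chromosomes = 1, chrom_length = 100000,
                      block_plan = bp, sv_plan = sv)
  sim <- generate_diploid(cfg)
  t2 <- sim$truth[sim$truth$haplotype == "hap2" &
                    sim$truth$kind == "tandem_block", ]
  # [30k,40k) mirrored inside [20k,80k) -> [60k,70k)
  expect_equal(t2$start, 60000)
  expect_equal(t2$end, 70000)
  # the relocated interval is a tandem array of the (reverse-complemented)
  # monomer; inversion flips the truncation to the array's left edge, so the
  # check is phase-agnostic
  seg <- substr(sim$hap2[["chr1"]], 60001, 70000)
  expect_true(grepl(seg, strrep(t2$monomer, ceiling(10000 / 7) + 2),
                    fixed = TRUE))
  expect_identical(seg, revcomp(substr(sim$hap1[["chr1"]], 30001, 40000)))

  # a breakpoint splitting a feature is rejected
  sv_bad <- list(list(type = "inversion", haplotype = "hap2", chrom = "chr1",
                      start = 35000, end = 80000))
  cfg_bad <- quick_config(seed = 5, n_chromosomes = 1,
                          chrom_length = 100000, block_plan = bp,
                          sv_plan = sv_bad)
  expect_error(generate_diploid(cfg_bad), "splits planted feature")
})

test_that("telomere motifs are rare in random background", {
  set.seed(12)
  for (i in 1:10) {
    s <- generate_background(10000, 0.5)
    expect_lt(count_motif(s, "TTTAGGG"), 5)
  }
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(simulation_config(n_chromosomes = 0), "configuration error")
  expect_error(simulation_config(gc_content = 0), "configuration error")
  bp <- data.frame(chrom = "chr1", haplotype = "hap1", start = 90000,
                   span = 20000, monomer_length = 5,
                   stringsAsFactors = FALSE)
  expect_error(quick_config(seed = 1, n_chromosomes = 1,
                            chrom_length = 100000, block_plan = bp),
               "out of chromosome bounds")
  # overlapping planted features on one haplotype
  bp2 <- data.frame(chrom = c("chr1", "chr1"), haplotype = "hap1",
                    start = c(10000, 15000), span = c(10000, 10000),
                    monomer_length = 5, stringsAsFactors = FALSE)
  expect_error(quick_config(seed = 1, n_chromosomes = 1,
                            chrom_length = 100000, block_plan = bp2),
               "overlapping")
})

test_that("written FASTA and truth round-trip", {
  cfg <- quick_config(seed = 6, n_chromosomes = 2, chrom_length = 50000,
                      block_plan = data.frame(
                        chrom = "chr1", haplotype = "both", start = 10000,
                        span = 5000, monomer_length = 6,
                        stringsAsFactors = FALSE))
  sim <- generate_diploid(cfg)
  outdir <- tempfile("sim")
  paths <- write_diploid(sim, outdir)
  reread <- read_genome(paths[["hap1"]])
  expect_identical(unname(reread), unname(sim$hap1))
  expect_identical(names(reread), names(sim$hap1))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(sim$truth))
  unlink(outdir, recursive = TRUE)
})
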