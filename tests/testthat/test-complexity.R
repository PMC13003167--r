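test_that("window counts match hand enumeration on analytic cases", {
  expect_equal(unname(count_window_kmers("AAAA", 3)[c("total", "distinct")]),
               c(2, 1))
  expect_equal(unname(count_window_kmers("ACGTACGTACGT", 3)[c("total", "distinct")]),
               c(10, 4))
  # N positions are excluded from numerator and denominator
  expect_equal(unname(count_window_kmers("ACGNACG", 3)[c("total", "distinct")]),
               c(2, 1))
  # k longer than the window yields empty counts
  expect_equal(unname(count_window_kmers("ACG", 5)), c(0, 0, 0))
  # soft-masked bases count like uppercase
  expect_equal(count_window_kmers("acgtACGT", 4),
               count_window_kmers("ACGTACGT", 4))
  expect_error(count_window_kmers("ACGT", 0), "k must be")
})

test_that("counts agree exactly with the naive substring-set oracle", {
  set.seed(101)
  for (i in 1:300) {
    len <- sample(50:2000, 1)
    seq <- random_seq(len, c("A", "C", "G", "T", "N"))
    k <- sample(1:12, 1)
    got <- count_window_kmers(seq, k)
    want <- oracle_kmer_counts(seq, k)
    expect_equal(unname(got), unname(want))
  }
})

test_that("canonical and singleton modes agree with the oracle", {
  set.seed(202)
  for (i in 1:50) {
    seq <- random_seq(sample(50:500, 1), c("A", "C", "G", "T", "N"))
    k <- sample(1:8, 1)
    got <- count_window_kmers(seq, k, canonical = TRUE)
    want <- oracle_kmer_counts(seq, k, canonical = TRUE)
    expect_equal(unname(got), unname(want))
  }
  # singletons: ACGT at k=3 gives two 3-mers, both unique
  expect_equal(unname(count_window_kmers("ACGT", 3)[["singleton"]]), 2)
  expect_equal(unname(count_window_kmers("AAAA", 3)[["singleton"]]), 0)
})

test_that("window grid follows the 0, S, 2S, ... convention with truncation", {
  spec <- window_spec(50000, 25000, c(3, 10))
  g <- window_grid(125000, spec)
  expect_equal(g$start, c(0, 25000, 50000, 75000, 100000))
  expect_equal(g$end[5], 125000)
  # shorter than the largest k: no usable window
  expect_equal(nrow(window_grid(5, window_spec(50, 25, 10))), 0)
  expect_error(window_grid(0, spec), "positive")
  # grid covers the whole chromosome without gaps
  g2 <- window_grid(90001, spec)
  expect_equal(min(g2$start), 0)
  expect_equal(max(g2$end), 90001)
  covered <- rep(FALSE, 90001)
  for (i in seq_len(nrow(g2))) covered[(g2$start[i] + 1):g2$end[i]] <- TRUE
  expect_true(all(covered))
})

test_that("window_spec validates its arguments", {
  expect_error(window_spec(step = 0), "step")
  expect_error(window_spec(1000, 2000), "step")
  expect_error(window_spec(100, 50, k = 200), "k must")
  expect_error(window_spec(k = 35), "not supported")
})

test_that("profile scores respect the pigeonhole and birthday regimes", {
  set.seed(7)
  s <- random_seq(100000)
  p <- complexity_profile(setNames(s, "chrA"), window_spec(50000, 25000, c(3, 10)))
  k3 <- p[p$k == 3, ]
  # at k=3 every long window saturates the 64 possible 3-mers
  expect_true(all(k3$distinct_kmers <= 64))
  expect_true(all(k3$score <= 64 / (k3$end - k3$start - 2)))
  # at k=10 random sequence scores near the birthday expectation
  k10 <- p[p$k == 10 & p$end - p$start == 50000, ]
  m <- 4^10; n <- 49991
  expected <- m * (1 - (1 - 1 / m)^n) / n
  expect_true(all(abs(k10$score - expected) < 0.01))
  # defined scores always lie in (0, min(1, 4^k/total)]
  ok <- !is.na(p$score)
  expect_true(all(p$score[ok] > 0 & p$score[ok] <= 1))
  expect_true(all(p$score[ok] >= 1 / p$total_kmers[ok]))
  expect_true(all(p$score[ok] <= pmin(1, 4^p$k[ok] / p$total_kmers[ok])))
})

test_that("tandem arrays score near zero at k = 10", {
  set.seed(11)
  arr <- strrep("ACGTCGA", ceiling(50000 / 7))
  arr <- substr(arr, 1, 50000)
  counts <- count_window_kmers(arr, 10)
  expect_lte(counts[["distinct"]], 20)
  expect_lte(counts[["distinct"]] / counts[["total"]], 20 / 49991)
})

test_that("profile handles masking, N gaps, and bad inputs", {
  set.seed(21)
  s <- random_seq(2000)
  masked <- paste0(tolower(substr(s, 1, 1000)), substring(s, 1001))
  spec <- window_spec(500, 250, 5)
  expect_equal(complexity_profile(setNames(masked, "c"), spec)$score,
               complexity_profile(setNames(s, "c"), spec)$score)
  # an all-N window has no counted k-mers and an NA score
  gap <- paste0(strrep("N", 600), random_seq(1400))
  pg <- complexity_profile(setNames(gap, "c"), spec)
  expect_true(is.na(pg$score[1]))
  expect_equal(pg$total_kmers[1], 0)
  expect_error(complexity_profile(c(a = "ACGT", a = "ACGT"), spec),
               "duplicate")
  expect_error(complexity_profile(character(0)), "empty|named")
  expect_error(read_genome(tempfile(fileext = ".fa")), "not found")
})

test_that("profile TSV round-trips through write and read", {
  set.seed(31)
  p <- complexity_profile(setNames(random_seq(5000), "chr1"),
                          window_spec(1000, 500, c(3, 10)))
  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  p2 <- read_profile_tsv(path)
  expect_equal(p2$score, p$score, tolerance = 1e-12)
  expect_equal(attr(p2, "spec")$window, attr(p, "spec")$window)
  unlink(c(path, paste0(path, ".provenance.json")))
})
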