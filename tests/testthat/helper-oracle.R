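# Naive substring-set oracle for k-mer window counts, independent of the
# package's compiled counter: enumerate substrings, drop any containing a
# non-ACGT character, tabulate.
oracle_kmer_counts <- function(seq, k, canonical = FALSE) {
  s <- toupper(seq)
  n <- nchar(s)
  if (k > n) return(c(total = 0, distinct = 0, singleton = 0))
  subs <- substring(s, 1:(n - k + 1), k:n)
  subs <- subs[grepl("^[ACGT]+$", subs)]
  if (canonical && length(subs) > 0) {
    rc <- vapply(subs, revcomp, character(1), USE.NAMES = FALSE)
    subs <- pmin(subs, rc)
  }
  counts <- table(subs)
  c(total = length(subs), distinct = length(counts),
    singleton = sum(counts == 1))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Synthetic complexity profile from a vector of window scores, for testing
# segmentation and comparison logic in isolation.
fake_profile <- function(scores, chrom = "chrA", window = 50000,
                         step = 25000, k = 10L) {
  if (is.list(scores)) {
    chroms <- names(scores)
  } else {
    scores <- setNames(list(scores), chrom)
    chroms <- chrom
  }
  out <- do.call(rbind, lapply(chroms, function(ch) {
    sc <- scores[[ch]]
    starts <- (seq_along(sc) - 1) * step
    data.frame(chrom = ch, start = starts, end = starts + window, k = k,
               total_kmers = 1000,
               distinct_kmers = round(ifelse(is.na(sc), 0, sc) * 1000),
               singleton_kmers = 0, score = sc, stringsAsFactors = FALSE)
  }))
  attr(out, "spec") <- list(window = as.integer(window),
                            step = as.integer(step), k = as.integer(k),
                            canonical = FALSE, mode = "distinct")
  class(out) <- c("complexity_profile", class(out))
  out
}

# Minimal simulation configuration used across tests: no dispersed repeats
# or SVs unless a test plants them explicitly.
quick_config <- function(seed, n_chromosomes = 2, chrom_length = 100000,
                         telomere_plan = NULL, block_plan = NULL,
                         sv_plan = list(), te_plan = NULL, ...) {
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (is.null(telomere_plan)) {
    telomere_plan <- data.frame(chrom = chroms, ends = "none",
                                array_bp = 0, stringsAsFactors = FALSE)
  }
  if (is.null(block_plan)) {
    block_plan <- data.frame(chrom = character(0), haplotype = character(0),
                             start = numeric(0), span = numeric(0),
                             monomer_length = integer(0))
  }
  simulation_config(n_chromosomes = n_chromosomes,
                    chrom_length = chrom_length,
                    telomere_plan = telomere_plan, block_plan = block_plan,
                    sv_plan = sv_plan, te_plan = te_plan, seed = seed, ...)
}
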