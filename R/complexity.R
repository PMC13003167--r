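#' Sliding-window specification
#'
#' The default grid — 50 kb windows advanced in 25 kb steps, profiled at
#' k = 3 ("local memory", short-range simple-repeat structure) and k = 10
#' ("distant memory", long-range repeat structure) — is the standard
#' configuration for chromosome-scale low-complexity mapping.
#'
#' @param window window size in bp (default 50000).
#' @param step step between window starts in bp (default 25000); must satisfy
#'   `0 < step <= window`.
#' @param k integer vector of k-mer lengths (default `c(3, 10)`); each k must
#'   satisfy `1 <= k < window` and `k <= 31`.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(window = 50000L, step = 25000L, k = c(3L, 10L)) {
  window <- as.integer(window); step <- as.integer(step); k <- as.integer(k)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("window must be a positive integer", call. = FALSE)
  if (length(step) != 1L || is.na(step) || step < 1L || step > window)
    stop("step must satisfy 0 < step <= window", call. = FALSE)
  if (length(k) < 1L || anyNA(k) || any(k < 1L) || any(k >= window))
    stop("each k must satisfy 1 <= k < window", call. = FALSE)
  if (any(k > 31L))
    stop("k values above 31 are not supported", call. = FALSE)
  structure(list(window = window, step = step, k = sort(unique(k))),
            class = "window_spec")
}

#' Sliding-window grid for one chromosome
#'
#' Windows start at 0, S, 2S, ... for every start strictly below the
#' chromosome length; each window ends at `min(start + W, chrom_length)`, so
#' the final windows may be truncated. Windows shorter than the largest k are
#' dropped (no k-mer fits). Coordinates are 0-based half-open.
#'
#' @param chrom_length chromosome length in bp.
#' @param spec a [window_spec()].
#' @return data frame with columns `start`, `end`.
#' @export
window_grid <- function(chrom_length, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  chrom_length <- as.numeric(chrom_length)
  if (length(chrom_length) != 1L || is.na(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be positive", call. = FALSE)
  starts <- seq(0, chrom_length - 1, by = spec$step)
  ends <- pmin(starts + spec$window, chrom_length)
  keep <- (ends - starts) >= max(spec$k)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Count k-mers in a window
#'
#' Tabulates every length-k substring at positions `0 ... len - k`.
#' Substrings containing any character outside `{A, C, G, T}` (after
#' uppercasing) are excluded from both counts, so N-joined assembly gaps
#' never register as spurious distinct k-mers. Counting is literal-strand by
#' default; with `canonical = TRUE` each k-mer is collapsed onto the
#' lexicographic minimum of itself and its reverse complement.
#'
#' @param sequence single character string.
#' @param k k-mer length (1..31).
#' @param canonical collapse k-mers with their reverse complements?
#' @return named numeric vector `c(total, distinct, singleton)`; all zero
#'   when `k` exceeds the window length. `singleton` counts the k-mers
#'   occurring exactly once, for the alternative singleton diversity mode.
#' @export
count_window_kmers <- function(sequence, k, canonical = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  .kmer_window_counts(sequence, k, isTRUE(canonical))
}

#' Per-window k-mer complexity profile of an assembly
#'
#' The core statistic: for every chromosome, every window on the sliding
#' grid and every k, the complexity score `distinct_kmers / total_kmers` —
#' near 0 for tandem repeats, near 1 for unique sequence at large k.
#' Lowercase (soft-masked) bases count like uppercase; windows whose counted
#' k-mer total is zero (e.g. all-N gaps) get an `NA` score.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector
#'   (see [read_genome()]).
#' @param spec a [window_spec()].
#' @param canonical collapse reverse complements when counting?
#' @param mode `"distinct"` (default) scores distinct/total; `"singleton"`
#'   scores k-mers occurring exactly once / total.
#' @return data frame of class `complexity_profile` with columns
#'   `chrom start end k total_kmers distinct_kmers score` (plus
#'   `singleton_kmers`), ordered by chromosome, k, then start. The window
#'   specification and counting options are kept in the `spec` attribute.
#' @export
complexity_profile <- function(genome, spec = window_spec(),
                               canonical = FALSE,
                               mode = c("distinct", "singleton")) {
  mode <- match.arg(mode)
  seqs <- read_genome(genome)
  out <- vector("list", length(seqs) * length(spec$k))
  idx <- 0L
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    grid <- window_grid(nchar(s), spec)
    if (nrow(grid) == 0L) next
    win_seq <- substring(s, grid$start + 1L, grid$end)
    for (kk in spec$k) {
      counts <- vapply(win_seq, .kmer_window_counts, numeric(3),
                       k = kk, canonical = canonical, USE.NAMES = FALSE)
      total <- counts[1L, ]
      num <- if (mode == "distinct") counts[2L, ] else counts[3L, ]
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        chrom = chrom, start = grid$start, end = grid$end, k = kk,
        total_kmers = total, distinct_kmers = counts[2L, ],
        singleton_kmers = counts[3L, ],
        score = ifelse(total > 0, num / total, NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  profile <- do.call(rbind, out[seq_len(idx)])
  if (is.null(profile)) {
    profile <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), k = integer(0),
                          total_kmers = numeric(0), distinct_kmers = numeric(0),
                          singleton_kmers = numeric(0), score = numeric(0))
  }
  profile <- profile[order(profile$chrom, profile$k, profile$start), ]
  rownames(profile) <- NULL
  attr(profile, "spec") <- list(
    window = spec$window, step = spec$step, k = spec$k,
    canonical = isTRUE(canonical), mode = mode,
    source = if (is.character(genome) && length(genome) == 1L &&
                 is.null(names(genome))) genome else "in-memory"
  )
  class(profile) <- c("complexity_profile", class(profile))
  profile
}

#' @export
print.complexity_profile <- function(x, ...) {
  sp <- attr(x, "spec")
  cat("complexity_profile:", length(unique(x$chrom)), "chromosome(s),",
      nrow(x), "window records\n")
  if (!is.null(sp)) {
    cat(sprintf("  window %d bp, step %d bp, k = {%s}, %s-strand, %s mode\n",
                sp$window, sp$step, paste(sp$k, collapse = ", "),
                if (isTRUE(sp$canonical)) "canonical" else "literal",
                sp$mode))
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

profile_spec_key <- function(profile) {
  sp <- attr(profile, "spec")
  if (is.null(sp)) return(NULL)
  list(window = as.integer(sp$window), step = as.integer(sp$step),
       k = as.integer(sp$k), canonical = isTRUE(sp$canonical),
       mode = as.character(sp$mode))
}

# chromosome lengths implied by a profile's window grid (the grid covers
# [0, L) whenever L >= max(k), so max(end) recovers L)
profile_chrom_lengths <- function(profile) {
  vapply(split(profile$end, profile$chrom), max, numeric(1))
}
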