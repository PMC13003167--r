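#' Telomere scan parameters
#'
#' Defaults: the plant-canonical `TTTAGGG` repeat, a 10 kb scan at each
#' chromosome end, and a minimum of 50 motif occurrences (about 350 bp of
#' repeat) to call an end telomeric. In random background the expected
#' occurrence count of a 7-mer in 10 kb is about `10000 / 4^7` (roughly
#' 0.6), so the threshold separates planted arrays from background by two
#' orders of magnitude.
#'
#' @param motif telomeric repeat unit over A/C/G/T, length >= 3.
#' @param terminal_len bases scanned at each end (default 10000).
#' @param min_count minimum occurrences for a positive call (default 50).
#' @param right_revcomp scan the right end for the reverse complement of the
#'   motif (the standard telomere orientation convention; default `TRUE`).
#' @return object of class `telomere_params`.
#' @export
telomere_params <- function(motif = "TTTAGGG", terminal_len = 10000L,
                            min_count = 50L, right_revcomp = TRUE) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]{3,}$", motif))
    stop("motif must be a string over A/C/G/T of length >= 3", call. = FALSE)
  if (terminal_len < nchar(motif))
    stop("terminal_len must be at least the motif length", call. = FALSE)
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  structure(list(motif = motif, terminal_len = as.integer(terminal_len),
                 min_count = as.integer(min_count),
                 right_revcomp = isTRUE(right_revcomp)),
            class = "telomere_params")
}

#' Count non-overlapping motif occurrences
#'
#' Scans left to right, case-insensitively, consuming each match (greedy
#' non-overlapping counting). Characters outside A/C/G/T (e.g. N) never
#' match.
#'
#' @param sequence character string.
#' @param motif motif to count (non-empty).
#' @return integer count.
#' @export
count_motif <- function(sequence, motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("configuration error: motif must be a non-empty string",
         call. = FALSE)
  hits <- gregexpr(toupper(motif), toupper(sequence), fixed = TRUE)[[1L]]
  if (length(hits) == 1L && hits[1L] == -1L) return(0L)
  # gregexpr with fixed = TRUE already returns non-overlapping matches
  length(hits)
}

#' Scan chromosome termini for telomeric repeat arrays
#'
#' The left end scans `sequence[0, terminal_len)` for the motif; the right
#' end scans the terminal `terminal_len` bases for the reverse complement of
#' the motif (configurable off). Chromosomes shorter than `terminal_len`
#' are scanned whole, with a message. An end is called telomeric when the
#' motif count reaches `min_count`; each chromosome is then classed as
#' `both`, `left_only`, `right_only` or `none`.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param params a [telomere_params()].
#' @return list with `calls` (data frame `chrom end count density present`;
#'   `density = count * motif_len / scanned_len`) and `classes` (data frame
#'   `chrom class`).
#' @export
scan_telomeres <- function(genome, params = telomere_params()) {
  seqs <- read_genome(genome)
  motif_len <- nchar(params$motif)
  right_motif <- if (params$right_revcomp) revcomp(params$motif) else
    params$motif
  calls <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    scan_len <- min(params$terminal_len, L)
    if (scan_len < params$terminal_len)
      message(chrom, " is shorter than terminal_len; scanning whole ",
              "chromosome (", L, " bp)")
    left_seq <- substr(s, 1L, scan_len)
    right_seq <- substring(s, L - scan_len + 1L)
    n_left <- count_motif(left_seq, params$motif)
    n_right <- count_motif(right_seq, right_motif)
    data.frame(
      chrom = chrom, end = c("left", "right"),
      count = c(n_left, n_right),
      density = c(n_left, n_right) * motif_len / scan_len,
      present = c(n_left, n_right) >= params$min_count,
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, calls)
  classes <- do.call(rbind, lapply(split(calls, calls$chrom), function(cc) {
    left <- cc$present[cc$end == "left"]
    right <- cc$present[cc$end == "right"]
    data.frame(chrom = cc$chrom[1L],
               class = if (left && right) "both"
               else if (left) "left_only"
               else if (right) "right_only"
               else "none",
               stringsAsFactors = FALSE)
  }))
  classes <- classes[match(names(seqs), classes$chrom), , drop = FALSE]
  rownames(calls) <- rownames(classes) <- NULL
  list(calls = calls, classes = classes)
}
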