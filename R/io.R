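#' Load a genome as a named set of chromosome sequences
#'
#' Accepts a FASTA path (plain or gzip-compressed), a
#' [Biostrings::DNAStringSet], or a named character vector. Sequence names
#' are truncated at the first whitespace, matching common FASTA header
#' conventions. Soft-masked (lowercase) bases are kept as-is; all counting
#' downstream is case-insensitive.
#'
#' @param x FASTA file path, `DNAStringSet`, or named character vector.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             file.exists(x)) {
    set <- tryCatch(
      Biostrings::readDNAStringSet(x),
      error = function(e) stop("unreadable FASTA file '", x, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    seqs <- as.character(set)
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else if (is.character(x) && length(x) == 1L) {
    stop("input FASTA file not found: '", x, "'", call. = FALSE)
  } else {
    stop("genome must be a FASTA path, DNAStringSet, or named character vector",
         call. = FALSE)
  }
  if (length(seqs) == 0L) {
    stop("empty genome: no sequences found", call. = FALSE)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path; lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param x single character string over the IUPAC alphabet.
#' @return reverse-complemented string (uppercased).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Write a complexity profile as TSV (with a provenance sidecar)
#'
#' Columns: `chrom start end k total_kmers distinct_kmers score`; undefined
#' scores are written as `NA`. The window specification and counting options
#' are written to `<path>.provenance.json` so a reloaded profile can be
#' compared safely.
#'
#' @param profile a `complexity_profile` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  cols <- c("chrom", "start", "end", "k", "total_kmers", "distinct_kmers",
            "score")
  write_tsv_file(profile[, cols], path)
  prov <- attr(profile, "spec")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a complexity profile TSV written by [write_profile_tsv()]
#'
#' @param path TSV path; a `<path>.provenance.json` sidecar is restored into
#'   the `spec` attribute when present.
#' @return a `complexity_profile` data frame.
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop("profile TSV not found: '", path, "'",
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    attr(df, "spec") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(df) <- c("complexity_profile", class(df))
  df
}

#' Write per-k bedGraph tracks of window scores
#'
#' One bedGraph per k value; windows with undefined scores are omitted.
#'
#' @param profile a `complexity_profile`.
#' @param prefix output path prefix; files are `<prefix>.k<k>.bedgraph`.
#' @return character vector of written paths, invisibly.
#' @export
write_profile_bedgraph <- function(profile, prefix) {
  paths <- character(0)
  for (kk in sort(unique(profile$k))) {
    sub <- profile[profile$k == kk & !is.na(profile$score), , drop = FALSE]
    p <- sprintf("%s.k%d.bedgraph", prefix, kk)
    write_tsv_file(sub[, c("chrom", "start", "end", "score")], p,
                   col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write repetitive blocks as BED6
#'
#' BED score column is `round(1000 * (1 - mean_score))`, so darker means more
#' repetitive in genome browsers; the name encodes the block id and called
#' end.
#'
#' @param blocks a block table from [call_blocks()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  if (nrow(blocks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = blocks$chrom,
    start = blocks$start,
    end = blocks$end,
    name = sprintf("block_%03d_%s", seq_len(nrow(blocks)), blocks$which_end),
    score = round(1000 * (1 - blocks$mean_score)),
    strand = ".",
    stringsAsFactors = FALSE
  )
  write_tsv_file(bed, path, col.names = FALSE)
  invisible(path)
}

write_tsv_file <- function(df, path, col.names = TRUE) {
  # genomic coordinates must never be written in scientific notation
  old <- options(scipen = 15)
  on.exit(options(old))
  write.table(df, file = path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}
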