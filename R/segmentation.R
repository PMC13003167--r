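#' Segmentation parameters for repetitive-block calling
#'
#' "Near-zero" complexity is operationalized as `score < score_threshold`;
#' at k = 10 with 50 kb windows, tandem arrays score well below 0.01 while
#' unique background scores above 0.9, so the default 0.1 separates the two
#' regimes with a wide margin. `merge_gap` tolerates isolated
#' higher-complexity windows inside an extensive block (e.g. a dispersed
#' element nested in satellite). `min_span` suppresses short calls: the
#' desk-scale default is 100 kb; at full chromosome scale 5 Mb reproduces
#' the "extensive terminal block" notion. `terminal_fraction` defines the
#' terminal zone of a chromosome for telomeric/subtelomeric classification.
#'
#' @param score_threshold windows with score below this are low-complexity
#'   (default 0.1).
#' @param merge_gap number of consecutive above-threshold (or NA) windows
#'   that may be bridged inside a block (default 1).
#' @param min_span minimum reported block span in bp (default 100000).
#' @param terminal_fraction fraction of chromosome length forming each
#'   terminal zone (default 0.1; must be in (0, 0.5]).
#' @param k which k the segmentation uses (default 10).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(score_threshold = 0.1, merge_gap = 1L,
                                min_span = 100000, terminal_fraction = 0.1,
                                k = 10L) {
  if (!is.numeric(score_threshold) || score_threshold <= 0 ||
      score_threshold >= 1)
    stop("score_threshold must lie strictly between 0 and 1", call. = FALSE)
  merge_gap <- as.integer(merge_gap)
  if (is.na(merge_gap) || merge_gap < 0L)
    stop("merge_gap must be >= 0", call. = FALSE)
  if (!is.numeric(min_span) || min_span < 0)
    stop("min_span must be >= 0", call. = FALSE)
  if (!is.numeric(terminal_fraction) || terminal_fraction <= 0 ||
      terminal_fraction > 0.5)
    stop("terminal_fraction must lie in (0, 0.5]", call. = FALSE)
  structure(list(score_threshold = score_threshold, merge_gap = merge_gap,
                 min_span = min_span, terminal_fraction = terminal_fraction,
                 k = as.integer(k)),
            class = "segmentation_params")
}

#' Call repetitive blocks from a complexity profile
#'
#' Finds maximal runs of windows whose score falls below the threshold; up
#' to `merge_gap` consecutive above-threshold (or NA) windows are bridged
#' provided both flanks are below threshold. A block spans from the start of
#' its first member window to the end of its last; blocks shorter than
#' `min_span` are suppressed, and blocks never bridge across chromosomes.
#' Terminal classification (see [classify_terminal()]) is applied using the
#' chromosome lengths implied by the window grid unless `chrom_lengths` is
#' given.
#'
#' @param profile a `complexity_profile` containing records at `params$k`.
#' @param params a [segmentation_params()].
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data frame with columns `chrom start end n_windows mean_score
#'   is_terminal which_end`; `n_windows` counts all member windows including
#'   bridged ones, and `mean_score` averages their defined scores.
#' @export
call_blocks <- function(profile, params = segmentation_params(),
                        chrom_lengths = NULL) {
  sub <- profile[profile$k == params$k, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("profile contains no records at k = ", params$k, call. = FALSE)
  if (is.null(chrom_lengths)) chrom_lengths <- profile_chrom_lengths(sub)
  blocks <- list()
  for (chrom in unique(sub$chrom)) {
    w <- sub[sub$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    low <- !is.na(w$score) & w$score < params$score_threshold
    lows <- which(low)
    if (length(lows) == 0L) next
    # group low windows whose index gap is within merge_gap
    grp <- cumsum(c(1, diff(lows) > params$merge_gap + 1L))
    for (g in unique(grp)) {
      members <- lows[grp == g]
      first <- members[1L]; last <- members[length(members)]
      span_start <- w$start[first]; span_end <- w$end[last]
      if (span_end - span_start < params$min_span) next
      scores <- w$score[first:last]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = chrom, start = span_start, end = span_end,
        n_windows = last - first + 1L,
        mean_score = mean(scores, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(blocks) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_score = numeric(0), is_terminal = logical(0),
                      which_end = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, blocks)
  classify_terminal(out, chrom_lengths, params$terminal_fraction)
}

#' Classify blocks as terminal (telomeric/subtelomeric zone) or interior
#'
#' A block is terminal when it begins inside the left terminal zone
#' (`start < terminal_fraction * L`) or ends inside the right one
#' (`end > (1 - terminal_fraction) * L`). Blocks touching both zones report
#' the nearer end; ties go left.
#'
#' @param blocks block table (columns `chrom start end` at least).
#' @param chrom_lengths named vector of chromosome lengths covering every
#'   block's chromosome.
#' @param terminal_fraction fraction of chromosome length per terminal zone.
#' @return `blocks` with `is_terminal` and `which_end`
#'   (`left`/`right`/`none`) set.
#' @export
classify_terminal <- function(blocks, chrom_lengths, terminal_fraction = 0.1) {
  unknown <- setdiff(unique(blocks$chrom), names(chrom_lengths))
  if (length(unknown) > 0)
    stop("unknown chromosome(s) in blocks: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(blocks) == 0L) {
    blocks$is_terminal <- logical(0)
    blocks$which_end <- character(0)
    return(blocks)
  }
  L <- unname(chrom_lengths[blocks$chrom])
  left <- blocks$start < terminal_fraction * L
  right <- blocks$end > (1 - terminal_fraction) * L
  blocks$is_terminal <- left | right
  dist_left <- blocks$start
  dist_right <- L - blocks$end
  blocks$which_end <- ifelse(!blocks$is_terminal, "none",
                      ifelse(left & !right, "left",
                      ifelse(right & !left, "right",
                      ifelse(dist_left <= dist_right, "left", "right"))))
  rownames(blocks) <- NULL
  blocks
}

#' Rank chromosomes by repetitive content
#'
#' For each chromosome, the fraction of defined k-windows scoring below the
#' threshold (`fraction_low`) and the mean complexity deficit
#' (`mean_deficit = mean(1 - score)`). Rank 1 is the most repetitive
#' chromosome; ties are broken by `mean_deficit`, then by name. Chromosomes
#' without any defined score at the requested k are excluded with a message.
#'
#' @param profile a `complexity_profile`.
#' @param params a [segmentation_params()] (threshold and k are used).
#' @return data frame `chrom n_windows fraction_low mean_deficit rank`,
#'   ordered by rank.
#' @export
repetitive_content <- function(profile, params = segmentation_params()) {
  sub <- profile[profile$k == params$k, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("profile contains no records at k = ", params$k, call. = FALSE)
  stats <- lapply(split(sub, sub$chrom), function(w) {
    defined <- w$score[!is.na(w$score)]
    data.frame(chrom = w$chrom[1L], n_windows = length(defined),
               fraction_low = if (length(defined))
                 mean(defined < params$score_threshold) else NA_real_,
               mean_deficit = if (length(defined))
                 mean(1 - defined) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  dropped <- out$chrom[out$n_windows == 0L]
  if (length(dropped) > 0) {
    message("excluding chromosome(s) with no defined scores: ",
            paste(dropped, collapse = ", "))
    out <- out[out$n_windows > 0L, , drop = FALSE]
  }
  ord <- order(-out$fraction_low, -out$mean_deficit, out$chrom)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
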