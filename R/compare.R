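#' Pair windows of two haplotype profiles by coordinate
#'
#' Chromosomes are paired by identical name and windows by identical start
#' on the shared grid; no alignment is attempted. Trailing windows present
#' in only one haplotype (chromosome length differences, e.g. after a
#' translocation) are kept with an `overhang` flag and an `NA` score for the
#' missing side. Chromosomes present in only one profile are excluded and
#' listed in the `unpaired_chroms` attribute. Both profiles must have been
#' computed with an identical window specification and counting options.
#'
#' @param profile_h1,profile_h2 `complexity_profile` objects.
#' @param k the k value to compare at (default 10); must be present in both.
#' @return data frame `chrom start end score_h1 score_h2 overhang`.
#' @export
match_windows <- function(profile_h1, profile_h2, k = 10L) {
  s1 <- profile_spec_key(profile_h1)
  s2 <- profile_spec_key(profile_h2)
  if (!is.null(s1) && !is.null(s2) && !identical(s1, s2))
    stop("profiles were computed with different window specifications; ",
         "recompute both with the same settings", call. = FALSE)
  p1 <- profile_h1[profile_h1$k == k, , drop = FALSE]
  p2 <- profile_h2[profile_h2$k == k, , drop = FALSE]
  if (nrow(p1) == 0L || nrow(p2) == 0L)
    stop("both profiles must contain records at k = ", k, call. = FALSE)

  shared <- intersect(unique(p1$chrom), unique(p2$chrom))
  unpaired <- union(setdiff(unique(p1$chrom), shared),
                    setdiff(unique(p2$chrom), shared))
  if (length(unpaired) > 0)
    message("chromosome(s) present in only one profile excluded: ",
            paste(sort(unpaired), collapse = ", "))

  out <- list()
  for (chrom in sort(shared)) {
    w1 <- p1[p1$chrom == chrom, c("start", "end", "score")]
    w2 <- p2[p2$chrom == chrom, c("start", "end", "score")]
    m <- merge(w1, w2, by = "start", all = TRUE, suffixes = c("_h1", "_h2"))
    m <- m[order(m$start), , drop = FALSE]
    out[[chrom]] <- data.frame(
      chrom = chrom, start = m$start,
      end = pmin(m$end_h1, m$end_h2, na.rm = TRUE),
      score_h1 = m$score_h1, score_h2 = m$score_h2,
      overhang = is.na(m$end_h1) | is.na(m$end_h2),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unpaired_chroms") <- sort(unpaired)
  attr(res, "k") <- as.integer(k)
  res
}

#' Classify window-matched score pairs into divergence categories
#'
#' With low-complexity threshold `t` and margin `m`:
#' both scores `< t` is `conserved_repetitive`; both `>= t + m` is
#' `conserved_unique`; one side `< t` with the other `>= t + m` is
#' `h1_specific_lc` / `h2_specific_lc` (the low side names the category);
#' anything else — including windows with an `NA` score or in the margin
#' band `[t, t + m)` — is `indeterminate`, so threshold-straddling noise is
#' never called haplotype-specific.
#'
#' @param paired output of [match_windows()].
#' @param threshold low-complexity threshold `t` (default 0.1).
#' @param margin width `m` of the indeterminate band above `t`
#'   (default 0.3; must be >= 0).
#' @return `paired` with `delta = score_h1 - score_h2` and `category` added.
#' @export
classify_divergence <- function(paired, threshold = 0.1, margin = 0.3) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  t <- threshold; hi <- threshold + margin
  s1 <- paired$score_h1; s2 <- paired$score_h2
  low1 <- !is.na(s1) & s1 < t;  high1 <- !is.na(s1) & s1 >= hi
  low2 <- !is.na(s2) & s2 < t;  high2 <- !is.na(s2) & s2 >= hi
  category <- rep("indeterminate", nrow(paired))
  category[low1 & low2] <- "conserved_repetitive"
  category[high1 & high2] <- "conserved_unique"
  category[low1 & high2] <- "h1_specific_lc"
  category[low2 & high1] <- "h2_specific_lc"
  paired$delta <- s1 - s2
  paired$category <- category
  paired
}

#' Compare two haplotype complexity profiles
#'
#' Convenience wrapper: [match_windows()] then [classify_divergence()].
#'
#' @inheritParams match_windows
#' @inheritParams classify_divergence
#' @return data frame of per-window divergence records
#'   (`chrom start end score_h1 score_h2 overhang delta category`).
#' @export
compare_profiles <- function(profile_h1, profile_h2, k = 10L,
                             threshold = 0.1, margin = 0.3) {
  classify_divergence(match_windows(profile_h1, profile_h2, k = k),
                      threshold = threshold, margin = margin)
}

#' Summarize haplotype divergence per chromosome
#'
#' Counts windows per category, computes the divergence score
#' `(h1_specific + h2_specific) / classified windows` (classified = not
#' indeterminate), and, when block tables are supplied, the signed terminal
#' block-span asymmetry per end (`hap2 span - hap1 span`, restricted to
#' blocks flagged terminal). Positive asymmetry means hap2 carries the
#' larger terminal repetitive block.
#'
#' @param records output of [compare_profiles()] / [classify_divergence()].
#' @param blocks_h1,blocks_h2 optional block tables from [call_blocks()].
#' @return data frame with per-chromosome category counts,
#'   `divergence_score`, `asym_left`, `asym_right` and `terminal_asymmetry`
#'   (their sum), ordered by decreasing divergence score.
#' @export
summarize_divergence <- function(records, blocks_h1 = NULL,
                                 blocks_h2 = NULL) {
  if (nrow(records) == 0L) stop("no divergence records", call. = FALSE)
  cats <- c("conserved_repetitive", "conserved_unique", "h1_specific_lc",
            "h2_specific_lc", "indeterminate")
  term_span <- function(blocks, chrom, end) {
    if (is.null(blocks) || nrow(blocks) == 0L) return(0)
    sel <- blocks$chrom == chrom & blocks$is_terminal &
      blocks$which_end == end
    sum(blocks$end[sel] - blocks$start[sel])
  }
  rows <- lapply(split(records, records$chrom), function(r) {
    counts <- vapply(cats, function(cc) sum(r$category == cc), integer(1))
    classified <- sum(counts[cats != "indeterminate"])
    chrom <- r$chrom[1L]
    asym_left <- term_span(blocks_h2, chrom, "left") -
      term_span(blocks_h1, chrom, "left")
    asym_right <- term_span(blocks_h2, chrom, "right") -
      term_span(blocks_h1, chrom, "right")
    data.frame(chrom = chrom, n_windows = nrow(r),
               t(counts),
               divergence_score = if (classified > 0)
                 (counts[["h1_specific_lc"]] + counts[["h2_specific_lc"]]) /
                 classified else NA_real_,
               asym_left = asym_left, asym_right = asym_right,
               terminal_asymmetry = asym_left + asym_right,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$divergence_score, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Side-by-side complexity map of two haplotypes for one chromosome
#'
#' Two score tracks on a shared x axis, the desk-scale analogue of the
#' per-chromosome haplotype comparison maps. Requires ggplot2.
#'
#' @param records output of [compare_profiles()].
#' @param chrom chromosome to draw.
#' @return a ggplot object.
#' @export
plot_divergence <- function(records, chrom) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_divergence requires the ggplot2 package", call. = FALSE)
  r <- records[records$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records for chromosome ", chrom, call. = FALSE)
  long <- rbind(
    data.frame(pos = (r$start + r$end) / 2, score = r$score_h1,
               haplotype = "hap1"),
    data.frame(pos = (r$start + r$end) / 2, score = r$score_h2,
               haplotype = "hap2")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e6, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~haplotype, ncol = 1) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "complexity score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
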