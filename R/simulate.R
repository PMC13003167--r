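#' Simulation configuration for a synthetic diploid genome
#'
#' Describes a two-haplotype toy genome with planted telomeric arrays,
#' tandem repetitive blocks, dispersed repeat families and haplotype-specific
#' structural variants, together with the random seed that makes the whole
#' construction reproducible. The defaults emulate, at desk scale, the
#' repeat landscape of a haplotype-resolved citrus-like assembly: nine
#' chromosomes, telomeres at both ends on four of them and at one end on the
#' other five, large asymmetric terminal repetitive blocks on chr2/chr8/chr9
#' (the hap2 copy larger on chr8 and chr9, the hap1 copy larger on chr2),
#' chr5 carrying the most repetitive sequence overall, a hap1-only inversion
#' on chr2 and a hap2-only reciprocal translocation between chr5 and chr7.
#'
#' @param n_chromosomes number of chromosomes per haplotype (default 9).
#' @param chrom_length length of each chromosome in bp (default 1e6).
#' @param gc_content background GC fraction in (0, 1) (default 0.5).
#' @param telomere_motif telomeric repeat unit (default plant-canonical
#'   `TTTAGGG`; its reverse complement is used at right ends).
#' @param telomere_plan data frame with columns `chrom`, `ends` (one of
#'   `both`, `left_only`, `right_only`, `none`) and `array_bp`; `NULL` uses
#'   the default plan.
#' @param block_plan data frame of planted tandem blocks with columns
#'   `chrom`, `haplotype` (`hap1`, `hap2` or `both`), `start` (0-based),
#'   `span`, `monomer_length`; `NULL` uses the default plan.
#' @param te_plan list with `n_families`, `element_length`, `copies_per_family`
#'   describing dispersed repeat families planted identically on both
#'   haplotypes; `NULL` disables them, defaults to 3 families of 2 kb
#'   elements, 15 copies each.
#' @param sv_plan list of structural variants; each element is a list with
#'   `type = "inversion"` (`haplotype`, `chrom`, `start`, `end`) or
#'   `type = "translocation"` (`haplotype`, `chrom_a`, `chrom_b`,
#'   `breakpoint_a`, `breakpoint_b`); `NULL` uses the default plan, an empty
#'   `list()` disables SVs.
#' @param seed integer random seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 9L,
                              chrom_length = 1000000L,
                              gc_content = 0.5,
                              telomere_motif = "TTTAGGG",
                              telomere_plan = NULL,
                              block_plan = NULL,
                              te_plan = list(n_families = 3L,
                                             element_length = 2000L,
                                             copies_per_family = 15L),
                              sv_plan = NULL,
                              seed = 1L) {
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length <- as.numeric(chrom_length)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (is.null(telomere_plan)) {
    telomere_plan <- default_telomere_plan(chroms)
  }
  if (is.null(block_plan)) {
    block_plan <- default_block_plan(chroms, chrom_length)
  }
  if (is.null(sv_plan)) {
    sv_plan <- default_sv_plan(chroms, chrom_length)
  }
  cfg <- structure(list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    gc_content = gc_content, telomere_motif = toupper(telomere_motif),
    telomere_plan = telomere_plan, block_plan = block_plan,
    te_plan = te_plan, sv_plan = sv_plan, seed = as.integer(seed),
    chroms = chroms
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

# Default telomere-end pattern: four chromosomes with telomeres at both
# ends, the rest at a single end (recycled for other chromosome counts).
default_telomere_plan <- function(chroms, array_bp = 2000L) {
  pattern <- c("both", "left_only", "both", "both", "left_only",
               "both", "left_only", "right_only", "left_only")
  data.frame(
    chrom = chroms,
    ends = rep_len(pattern, length(chroms)),
    array_bp = array_bp,
    stringsAsFactors = FALSE
  )
}

# Default tandem-block plan: asymmetric terminal blocks on chr2/chr8/chr9
# and two large interior blocks on chr5 shared by both haplotypes.
default_block_plan <- function(chroms, chrom_length, telomere_bp = 2000L) {
  rows <- list()
  add <- function(chrom, hap, start, span, mono = 12L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, haplotype = hap, start = start, span = span,
      monomer_length = mono, stringsAsFactors = FALSE)
  }
  # spans scale with chromosome length: the large asymmetric blocks cover
  # 15% of a chromosome, their small counterparts 5% (at the 1 Mb default:
  # 150 kb and 50 kb)
  L <- chrom_length
  big <- round(0.15 * L); small <- round(0.05 * L)
  if ("chr2" %in% chroms) {
    add("chr2", "hap1", telomere_bp, big)
    add("chr2", "hap2", telomere_bp, small)
  }
  if ("chr5" %in% chroms) {
    add("chr5", "both", round(0.15 * L), big)
    add("chr5", "both", round(0.40 * L), big)
  }
  if ("chr8" %in% chroms) {
    add("chr8", "hap1", L - telomere_bp - small, small)
    add("chr8", "hap2", L - telomere_bp - big, big)
  }
  if ("chr9" %in% chroms) {
    add("chr9", "hap1", telomere_bp, small)
    add("chr9", "hap2", telomere_bp, big)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), haplotype = character(0),
                      start = numeric(0), span = numeric(0),
                      monomer_length = integer(0)))
  }
  do.call(rbind, rows)
}

# Default SV plan: heterozygous inversion on chr2 (hap1) and a heterozygous
# reciprocal translocation between chr5 and chr7 (hap2).
default_sv_plan <- function(chroms, chrom_length) {
  plan <- list()
  L <- chrom_length
  if ("chr2" %in% chroms) {
    plan[[length(plan) + 1L]] <- list(
      type = "inversion", haplotype = "hap1", chrom = "chr2",
      start = round(0.30 * L), end = round(0.50 * L))
  }
  if (all(c("chr5", "chr7") %in% chroms)) {
    plan[[length(plan) + 1L]] <- list(
      type = "translocation", haplotype = "hap2",
      chrom_a = "chr5", chrom_b = "chr7",
      breakpoint_a = round(0.60 * L), breakpoint_b = round(0.70 * L))
  }
  plan
}

validate_simulation_config <- function(cfg) {
  fail <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$n_chromosomes < 1L) fail("n_chromosomes must be >= 1")
  if (is.na(cfg$chrom_length) || cfg$chrom_length <= 0)
    fail("chrom_length must be positive")
  if (!is.finite(cfg$gc_content) || cfg$gc_content <= 0 || cfg$gc_content >= 1)
    fail("gc_content must lie strictly between 0 and 1")
  if (!grepl("^[ACGT]+$", cfg$telomere_motif))
    fail("telomere_motif must be a non-empty string over A/C/G/T")
  L <- cfg$chrom_length

  tp <- cfg$telomere_plan
  if (nrow(tp) > 0) {
    if (!all(tp$chrom %in% cfg$chroms))
      fail("telomere_plan references unknown chromosomes: ",
           paste(setdiff(tp$chrom, cfg$chroms), collapse = ", "))
    if (!all(tp$ends %in% c("both", "left_only", "right_only", "none")))
      fail("telomere_plan$ends must be both/left_only/right_only/none")
    if (any(tp$array_bp < 0) || any(tp$array_bp > L))
      fail("telomere array_bp must lie in [0, chrom_length]")
    if (any(tp$ends == "both" & 2 * tp$array_bp > L))
      fail("telomere arrays at both ends may not overlap")
    if (anyDuplicated(tp$chrom)) fail("duplicate chromosomes in telomere_plan")
  }

  bp <- cfg$block_plan
  if (nrow(bp) > 0) {
    if (!all(bp$chrom %in% cfg$chroms))
      fail("block_plan references unknown chromosomes: ",
           paste(setdiff(bp$chrom, cfg$chroms), collapse = ", "))
    if (!all(bp$haplotype %in% c("hap1", "hap2", "both")))
      fail("block_plan$haplotype must be hap1/hap2/both")
    bad <- bp$start < 0 | bp$span < 1 | bp$start + bp$span > L
    if (any(bad))
      fail("block out of chromosome bounds: ",
           paste(sprintf("%s:%g+%g", bp$chrom[bad], bp$start[bad],
                         bp$span[bad]), collapse = ", "))
    if (any(bp$monomer_length < 1 | bp$monomer_length > bp$span))
      fail("block monomer_length must satisfy 1 <= monomer_length <= span")
  }

  # largest planted feature must fit twice into a chromosome
  spans <- c(bp$span, tp$array_bp,
             if (!is.null(cfg$te_plan)) cfg$te_plan$element_length)
  if (length(spans) > 0 && max(spans) * 2 > L)
    fail("chrom_length must be at least twice the largest planted feature")

  # per-haplotype interval overlap check (telomeres + blocks)
  for (hap in c("hap1", "hap2")) {
    ivs <- planned_intervals(cfg, hap)
    for (chrom in unique(ivs$chrom)) {
      sub <- ivs[ivs$chrom == chrom, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        fail("overlapping planted features on ", hap, " ", chrom)
    }
  }

  for (sv in cfg$sv_plan) validate_sv(sv, cfg)
  # inversions on one haplotype must not overlap each other
  for (hap in c("hap1", "hap2")) {
    invs <- Filter(function(s) s$type == "inversion" && s$haplotype == hap,
                   cfg$sv_plan)
    if (length(invs) > 1) {
      df <- data.frame(chrom = vapply(invs, `[[`, "", "chrom"),
                       start = vapply(invs, `[[`, 0, "start"),
                       end = vapply(invs, `[[`, 0, "end"))
      for (chrom in unique(df$chrom)) {
        sub <- df[df$chrom == chrom, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
          fail("overlapping inversions on ", hap, " ", chrom)
      }
    }
  }
  invisible(cfg)
}

validate_sv <- function(sv, cfg) {
  fail <- function(...) stop("configuration error: ", ..., call. = FALSE)
  L <- cfg$chrom_length
  if (!sv$haplotype %in% c("hap1", "hap2"))
    fail("sv haplotype must be hap1 or hap2")
  if (sv$type == "inversion") {
    if (!sv$chrom %in% cfg$chroms) fail("inversion on unknown chromosome")
    if (sv$start >= sv$end) fail("inversion requires start < end")
    if (sv$start < 0 || sv$end > L) fail("inversion out of bounds")
  } else if (sv$type == "translocation") {
    if (!all(c(sv$chrom_a, sv$chrom_b) %in% cfg$chroms))
      fail("translocation on unknown chromosome")
    if (sv$chrom_a == sv$chrom_b)
      fail("translocation requires two distinct chromosomes")
    if (sv$breakpoint_a <= 0 || sv$breakpoint_a >= L ||
        sv$breakpoint_b <= 0 || sv$breakpoint_b >= L)
      fail("translocation breakpoints must lie strictly inside chromosomes")
  } else {
    fail("unknown sv type '", sv$type, "'")
  }
  invisible(sv)
}

# telomere + block intervals planned for one haplotype (0-based half-open)
planned_intervals <- function(cfg, hap) {
  out <- list()
  tp <- cfg$telomere_plan
  for (i in seq_len(nrow(tp))) {
    if (tp$array_bp[i] <= 0 || tp$ends[i] == "none") next
    if (tp$ends[i] %in% c("both", "left_only"))
      out[[length(out) + 1L]] <- data.frame(chrom = tp$chrom[i], start = 0,
                                            end = tp$array_bp[i])
    if (tp$ends[i] %in% c("both", "right_only"))
      out[[length(out) + 1L]] <- data.frame(chrom = tp$chrom[i],
                                            start = cfg$chrom_length - tp$array_bp[i],
                                            end = cfg$chrom_length)
  }
  bp <- cfg$block_plan
  bp <- bp[bp$haplotype %in% c(hap, "both"), , drop = FALSE]
  for (i in seq_len(nrow(bp))) {
    out[[length(out) + 1L]] <- data.frame(chrom = bp$chrom[i],
                                          start = bp$start[i],
                                          end = bp$start[i] + bp$span[i])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  do.call(rbind, out)
}

#' Random background sequence
#'
#' @param length sequence length in bp (> 0).
#' @param gc_content GC fraction in (0, 1); A/T and C/G are used
#'   symmetrically.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return character string over `{A, C, G, T}` of exactly `length` bases.
#' @export
generate_background <- function(length, gc_content = 0.5, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length <= 0)
    stop("configuration error: length must be positive", call. = FALSE)
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("configuration error: gc_content must lie strictly in (0, 1)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  at <- (1 - gc_content) / 2
  gc <- gc_content / 2
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c(at, gc, gc, at)), collapse = "")
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# builds a tandem array of `monomer` truncated to span bp; `align` controls
# which side keeps a complete copy when the span is not a multiple
tandem_array <- function(monomer, span, align = c("left", "right")) {
  align <- match.arg(align)
  arr <- strrep(monomer, ceiling(span / nchar(monomer)))
  if (align == "left") substr(arr, 1L, span)
  else substring(arr, nchar(arr) - span + 1L)
}

#' Plant a tandem repetitive block into a sequence
#'
#' Replaces `[start, start + span)` (0-based half-open) with tandem copies
#' of a single monomer, the last copy truncated to fit; the sequence length
#' is unchanged. When `monomer` is `NULL` one is drawn uniformly from the
#' current RNG stream and redrawn if the resulting array would contain any
#' of the `avoid` motifs or their reverse complements (so planted satellite
#' never mimics a telomere).
#'
#' @param sequence character string.
#' @param start 0-based start of the interval to replace.
#' @param span interval width in bp.
#' @param monomer_length monomer length in bp (`1 <= monomer_length <= span`).
#' @param monomer optional explicit monomer.
#' @param avoid character vector of motifs the array must not contain.
#' @return list with `sequence` (modified string) and `monomer` (the unit
#'   used).
#' @export
plant_tandem_block <- function(sequence, start, span, monomer_length,
                               monomer = NULL, avoid = character(0)) {
  L <- nchar(sequence)
  if (monomer_length < 1 || monomer_length > span)
    stop("configuration error: monomer_length must satisfy 1 <= monomer_length <= span",
         call. = FALSE)
  if (start < 0 || span < 1 || start + span > L)
    stop("configuration error: block interval [", start, ", ", start + span,
         ") out of bounds for sequence of length ", L, call. = FALSE)
  if (is.null(monomer)) {
    avoid_all <- unique(c(avoid, vapply(avoid, revcomp, character(1),
                                        USE.NAMES = FALSE)))
    for (try in 1:100) {
      monomer <- random_dna(monomer_length)
      arr_test <- strrep(monomer, max(2L, ceiling(max(nchar(avoid_all), 0) /
                                                    monomer_length) + 1L))
      if (length(avoid_all) == 0L ||
          !any(vapply(avoid_all, function(m) grepl(m, arr_test, fixed = TRUE),
                      logical(1))))
        break
      monomer <- NULL
    }
    if (is.null(monomer))
      stop("configuration error: could not draw a monomer avoiding the given motifs",
           call. = FALSE)
  }
  arr <- tandem_array(monomer, span, "left")
  out <- paste0(substr(sequence, 1L, start),
                arr,
                substring(sequence, start + span + 1L))
  list(sequence = out, monomer = monomer)
}

#' Plant a telomeric repeat array at a chromosome end
#'
#' The terminal `array_bp` bases of the chosen end are replaced by tandem
#' copies of the motif (left end) or of its reverse complement (right end),
#' truncated on the interior side so a complete motif copy sits flush with
#' the chromosome terminus.
#'
#' @param sequence character string.
#' @param end `"left"` or `"right"`.
#' @param motif telomeric repeat unit (default `TTTAGGG`).
#' @param array_bp array length in bp; 0 leaves the sequence unchanged.
#' @return modified sequence string.
#' @export
plant_telomere <- function(sequence, end = c("left", "right"),
                           motif = "TTTAGGG", array_bp) {
  end <- match.arg(end)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("configuration error: motif must be non-empty over A/C/G/T",
         call. = FALSE)
  L <- nchar(sequence)
  if (array_bp > L)
    stop("configuration error: telomere array_bp (", array_bp,
         ") exceeds chromosome length (", L, ")", call. = FALSE)
  if (array_bp <= 0) return(sequence)
  if (end == "left") {
    arr <- tandem_array(motif, array_bp, "left")
    paste0(arr, substring(sequence, array_bp + 1L))
  } else {
    arr <- tandem_array(revcomp(motif), array_bp, "right")
    paste0(substr(sequence, 1L, L - array_bp), arr)
  }
}

#' Apply a structural variant to a pair of haplotype genomes
#'
#' Inversions replace the interval by its reverse complement on the
#' specified haplotype only; reciprocal translocations exchange the tails
#' downstream of the two breakpoints on the specified haplotype only. The
#' total base count of the genome is conserved in both cases.
#'
#' @param haps list with named character vectors `hap1` and `hap2`.
#' @param sv an SV record as in [simulation_config()]'s `sv_plan`.
#' @return modified `haps` list.
#' @export
apply_sv <- function(haps, sv) {
  h <- sv$haplotype
  if (sv$type == "inversion") {
    x <- haps[[h]][[sv$chrom]]
    if (sv$start >= sv$end)
      stop("configuration error: inversion requires start < end",
           call. = FALSE)
    if (sv$start < 0 || sv$end > nchar(x))
      stop("configuration error: inversion out of bounds", call. = FALSE)
    seg <- substr(x, sv$start + 1L, sv$end)
    haps[[h]][[sv$chrom]] <- paste0(substr(x, 1L, sv$start),
                                    revcomp(seg),
                                    substring(x, sv$end + 1L))
  } else if (sv$type == "translocation") {
    a <- haps[[h]][[sv$chrom_a]]
    b <- haps[[h]][[sv$chrom_b]]
    b1 <- sv$breakpoint_a; b2 <- sv$breakpoint_b
    if (b1 <= 0 || b1 >= nchar(a) || b2 <= 0 || b2 >= nchar(b))
      stop("configuration error: translocation breakpoints out of bounds",
           call. = FALSE)
    haps[[h]][[sv$chrom_a]] <- paste0(substr(a, 1L, b1), substring(b, b2 + 1L))
    haps[[h]][[sv$chrom_b]] <- paste0(substr(b, 1L, b2), substring(a, b1 + 1L))
  } else {
    stop("configuration error: unknown sv type '", sv$type, "'",
         call. = FALSE)
  }
  haps
}

new_truth_row <- function(haplotype, kind, chrom, start, end,
                          monomer = NA_character_, family = NA_integer_,
                          end_label = NA_character_,
                          partner_chrom = NA_character_,
                          partner_pos = NA_real_) {
  data.frame(haplotype = haplotype, kind = kind, chrom = chrom,
             start = start, end = end, monomer = monomer,
             family = family, end_label = end_label,
             partner_chrom = partner_chrom, partner_pos = partner_pos,
             stringsAsFactors = FALSE)
}

# remap truth coordinates of one haplotype through an applied SV; errors if
# a breakpoint would split a planted feature
remap_truth_sv <- function(truth, sv, chrom_lengths) {
  h <- sv$haplotype
  sel <- truth$haplotype == h & !truth$kind %in% c("inversion", "translocation")
  if (sv$type == "inversion") {
    on <- sel & truth$chrom == sv$chrom
    inside <- on & truth$start >= sv$start & truth$end <= sv$end
    straddle <- on & !inside & truth$end > sv$start & truth$start < sv$end
    if (any(straddle))
      stop("configuration error: inversion boundary splits planted feature(s): ",
           paste(truth$kind[straddle], collapse = ", "), call. = FALSE)
    if (any(inside)) {
      s0 <- truth$start[inside]; e0 <- truth$end[inside]
      truth$start[inside] <- sv$start + sv$end - e0
      truth$end[inside] <- sv$start + sv$end - s0
      has_mono <- inside & !is.na(truth$monomer)
      truth$monomer[has_mono] <- vapply(truth$monomer[has_mono], revcomp,
                                        character(1), USE.NAMES = FALSE)
    }
  } else {
    new_chrom <- rep(NA_character_, nrow(truth))
    shift <- rep(NA_real_, nrow(truth))
    for (side in 1:2) {
      chrom <- if (side == 1) sv$chrom_a else sv$chrom_b
      partner <- if (side == 1) sv$chrom_b else sv$chrom_a
      bk <- if (side == 1) sv$breakpoint_a else sv$breakpoint_b
      bk_partner <- if (side == 1) sv$breakpoint_b else sv$breakpoint_a
      on <- sel & truth$chrom == chrom
      straddle <- on & truth$start < bk & truth$end > bk
      if (any(straddle))
        stop("configuration error: translocation breakpoint splits planted feature(s) on ",
             chrom, call. = FALSE)
      # mark first, relabel after both sides are inspected
      move <- on & truth$start >= bk
      new_chrom[move] <- partner
      shift[move] <- bk_partner - bk
    }
    moved <- !is.na(new_chrom)
    if (any(moved)) {
      truth$chrom[moved] <- new_chrom[moved]
      truth$start[moved] <- truth$start[moved] + shift[moved]
      truth$end[moved] <- truth$end[moved] + shift[moved]
    }
  }
  truth
}

#' Generate a synthetic diploid genome with planted ground truth
#'
#' Builds two haplotype genomes from a shared random background, plants the
#' configured telomeric arrays, tandem blocks and dispersed repeat copies,
#' then applies haplotype-specific structural variants. Feature coordinates
#' in the returned truth table are remapped through the SVs, so every truth
#' interval is valid for — and extractable from — the emitted sequences.
#' hap2 differs from hap1 exactly by the features planted as hap2-specific
#' (plus applied SVs); with an empty plan the two haplotypes are identical.
#' The construction is fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_diploid`: list with `hap1` and `hap2`
#'   (named character vectors of chromosome sequences), `truth` (data frame
#'   of planted features: `haplotype kind chrom start end monomer family
#'   end_label partner_chrom partner_pos`, 0-based half-open coordinates)
#'   and the resolved `config`.
#' @export
generate_diploid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)
  chroms <- config$chroms
  L <- config$chrom_length

  background <- setNames(vapply(chroms, function(ch)
    generate_background(L, config$gc_content), character(1)), chroms)
  haps <- list(hap1 = background, hap2 = background)
  truth <- list()
  add_truth <- function(row) truth[[length(truth) + 1L]] <<- row

  # tandem blocks (monomer drawn once per plan row, shared across haplotypes
  # for rows planted on both)
  bp <- config$block_plan
  for (i in seq_len(nrow(bp))) {
    target <- if (bp$haplotype[i] == "both") c("hap1", "hap2") else bp$haplotype[i]
    monomer <- NULL
    for (h in target) {
      res <- plant_tandem_block(haps[[h]][[bp$chrom[i]]], bp$start[i],
                                bp$span[i], bp$monomer_length[i],
                                monomer = monomer,
                                avoid = config$telomere_motif)
      haps[[h]][[bp$chrom[i]]] <- res$sequence
      monomer <- res$monomer
      kind <- if (bp$start[i] < 0.1 * L || bp$start[i] + bp$span[i] > 0.9 * L)
        "terminal_block" else "tandem_block"
      add_truth(new_truth_row(h, kind, bp$chrom[i], bp$start[i],
                              bp$start[i] + bp$span[i], monomer = monomer))
    }
  }

  # telomeres (identical plan on both haplotypes)
  tp <- config$telomere_plan
  for (i in seq_len(nrow(tp))) {
    if (tp$ends[i] == "none" || tp$array_bp[i] <= 0) next
    for (h in c("hap1", "hap2")) {
      x <- haps[[h]][[tp$chrom[i]]]
      if (tp$ends[i] %in% c("both", "left_only")) {
        x <- plant_telomere(x, "left", config$telomere_motif, tp$array_bp[i])
      }
      if (tp$ends[i] %in% c("both", "right_only")) {
        x <- plant_telomere(x, "right", config$telomere_motif, tp$array_bp[i])
      }
      haps[[h]][[tp$chrom[i]]] <- x
      if (tp$ends[i] %in% c("both", "left_only"))
        add_truth(new_truth_row(h, "telomere", tp$chrom[i], 0, tp$array_bp[i],
                                monomer = config$telomere_motif,
                                end_label = "left"))
      if (tp$ends[i] %in% c("both", "right_only"))
        add_truth(new_truth_row(h, "telomere", tp$chrom[i],
                                L - tp$array_bp[i], L,
                                monomer = revcomp(config$telomere_motif),
                                end_label = "right"))
    }
  }

  # dispersed repeat families, identical positions on both haplotypes
  te <- config$te_plan
  if (!is.null(te) && te$n_families > 0 && te$copies_per_family > 0) {
    occupied <- rbind(planned_intervals(config, "hap1"),
                      planned_intervals(config, "hap2"))
    breaks <- sv_breakpoints(config$sv_plan)
    el <- te$element_length
    for (fam in seq_len(te$n_families)) {
      element <- random_dna(el)
      while (grepl(config$telomere_motif, element, fixed = TRUE) ||
             grepl(revcomp(config$telomere_motif), element, fixed = TRUE)) {
        element <- random_dna(el)
      }
      placed <- 0L
      tries <- 0L
      while (placed < te$copies_per_family && tries < 2000L) {
        tries <- tries + 1L
        chrom <- sample(chroms, 1L)
        start <- floor(runif(1, 0, L - el))
        end <- start + el
        occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
        if (nrow(occ) > 0 && any(occ$start < end & occ$end > start)) next
        bks <- breaks[breaks$chrom == chrom, , drop = FALSE]
        if (nrow(bks) > 0 && any(bks$pos > start & bks$pos < end)) next
        for (h in c("hap1", "hap2")) {
          x <- haps[[h]][[chrom]]
          haps[[h]][[chrom]] <- paste0(substr(x, 1L, start), element,
                                       substring(x, end + 1L))
          add_truth(new_truth_row(h, "te_copy", chrom, start, end,
                                  family = fam))
        }
        occupied <- rbind(occupied,
                          data.frame(chrom = chrom, start = start, end = end))
        placed <- placed + 1L
      }
      if (placed < te$copies_per_family)
        stop("configuration error: could not place all copies of repeat family ",
             fam, " without overlap", call. = FALSE)
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    new_truth_row("x", "x", "x", 0, 0)[0, ]

  # structural variants, applied after all sequence features so they can
  # relocate planted complexity signal; truth is remapped alongside
  for (sv in config$sv_plan) {
    truth <- remap_truth_sv(truth, sv, NULL)
    haps <- apply_sv(haps, sv)
    if (sv$type == "inversion") {
      truth <- rbind(truth, new_truth_row(
        sv$haplotype, "inversion", sv$chrom, sv$start, sv$end))
    } else {
      truth <- rbind(truth, new_truth_row(
        sv$haplotype, "translocation", sv$chrom_a,
        sv$breakpoint_a, sv$breakpoint_a,
        partner_chrom = sv$chrom_b, partner_pos = sv$breakpoint_b))
    }
  }
  truth <- truth[order(truth$haplotype, truth$chrom, truth$start,
                       truth$kind), ]
  rownames(truth) <- NULL

  structure(list(hap1 = haps$hap1, hap2 = haps$hap2, truth = truth,
                 config = config),
            class = "synthetic_diploid")
}

sv_breakpoints <- function(sv_plan) {
  out <- list()
  for (sv in sv_plan) {
    if (sv$type == "inversion") {
      out[[length(out) + 1L]] <- data.frame(
        chrom = sv$chrom, pos = c(sv$start, sv$end))
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = c(sv$chrom_a, sv$chrom_b),
        pos = c(sv$breakpoint_a, sv$breakpoint_b))
    }
  }
  if (length(out) == 0L) return(data.frame(chrom = character(0),
                                           pos = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.synthetic_diploid <- function(x, ...) {
  cat("synthetic_diploid:", length(x$hap1), "chromosomes per haplotype,",
      nrow(x$truth), "truth records (seed", x$config$seed, ")\n")
  print(table(x$truth$haplotype, x$truth$kind))
  invisible(x)
}

#' Write a synthetic diploid genome to disk
#'
#' Emits `hap1.fasta` and `hap2.fasta` (60-column wrapped), the planted
#' truth as `truth.json`, and the resolved configuration as `config.json`.
#'
#' @param sim a `synthetic_diploid` from [generate_diploid()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_diploid <- function(sim, outdir) {
  stopifnot(inherits(sim, "synthetic_diploid"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(hap1 = file.path(outdir, "hap1.fasta"),
             hap2 = file.path(outdir, "hap2.fasta"),
             truth = file.path(outdir, "truth.json"),
             config = file.path(outdir, "config.json"))
  write_genome_fasta(sim$hap1, paths[["hap1"]])
  write_genome_fasta(sim$hap2, paths[["hap2"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, na = "null")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
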