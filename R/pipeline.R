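#' Assemble a pipeline run configuration
#'
#' One declarative object drives the whole pipeline: input mode, stage
#' parameters and seed. Exactly one input mode applies: `simulate` builds a
#' synthetic diploid from `sim_config`; `fasta_pair` profiles and compares
#' two assemblies; `fasta_single` profiles one assembly (the comparison
#' stage is skipped).
#'
#' @param mode `"simulate"`, `"fasta_pair"` or `"fasta_single"`.
#' @param fasta_h1,fasta_h2 FASTA paths for the fasta modes.
#' @param sim_config a [simulation_config()] for simulate mode (default
#'   configuration if `NULL`).
#' @param spec a [window_spec()].
#' @param canonical collapse reverse complements when counting?
#' @param seg a [segmentation_params()].
#' @param compare_threshold,compare_margin divergence classification
#'   parameters (see [classify_divergence()]).
#' @param telo a [telomere_params()].
#' @param seed integer seed; in simulate mode it overrides
#'   `sim_config$seed`.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "fasta_pair", "fasta_single"),
                       fasta_h1 = NULL, fasta_h2 = NULL,
                       sim_config = NULL,
                       spec = window_spec(), canonical = FALSE,
                       seg = segmentation_params(),
                       compare_threshold = 0.1, compare_margin = 0.3,
                       telo = telomere_params(), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(sim_config))
    sim_config <- simulation_config(seed = seed)
  if (mode %in% c("fasta_pair", "fasta_single") && is.null(fasta_h1))
    stop("configuration error: fasta_h1 is required in mode '", mode, "'",
         call. = FALSE)
  if (mode == "fasta_pair" && is.null(fasta_h2))
    stop("configuration error: fasta_h2 is required in mode 'fasta_pair'",
         call. = FALSE)
  for (p in c(fasta_h1, fasta_h2)) {
    if (!is.null(p) && !file.exists(p))
      stop("configuration error: input file not found: '", p, "'",
           call. = FALSE)
  }
  structure(list(mode = mode, fasta_h1 = fasta_h1, fasta_h2 = fasta_h2,
                 sim_config = sim_config, spec = spec,
                 canonical = isTRUE(canonical), seg = seg,
                 compare_threshold = compare_threshold,
                 compare_margin = compare_margin, telo = telo,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Recognized top-level keys: `mode`, `seed`, `fasta_h1`, `fasta_h2`, and
#' the nested sections `simulation` (scalar [simulation_config()] fields),
#' `window` (`window`, `step`, `k`, `canonical`), `segmentation`
#' ([segmentation_params()] fields), `compare` (`threshold`, `margin`) and
#' `telomere` ([telomere_params()] fields). Anything omitted keeps its
#' default.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop("configuration error: config file not found: '", path, "'",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  seed <- as.integer(if (!is.null(seed)) seed else y$seed %||% 1L)
  w <- y$window %||% list()
  spec <- do.call(window_spec, w[names(w) %in% c("window", "step", "k")])
  sg <- y$segmentation %||% list()
  seg <- do.call(segmentation_params,
                 sg[names(sg) %in% c("score_threshold", "merge_gap",
                                     "min_span", "terminal_fraction", "k")])
  tl <- y$telomere %||% list()
  telo <- do.call(telomere_params,
                  tl[names(tl) %in% c("motif", "terminal_len", "min_count",
                                      "right_revcomp")])
  sim <- NULL
  if ((y$mode %||% "simulate") == "simulate") {
    sc <- y$simulation %||% list()
    keep <- c("n_chromosomes", "chrom_length", "gc_content",
              "telomere_motif")
    sim <- do.call(simulation_config, c(sc[names(sc) %in% keep],
                                        list(seed = seed)))
  }
  run_config(mode = y$mode %||% "simulate",
             fasta_h1 = y$fasta_h1, fasta_h2 = y$fasta_h2,
             sim_config = sim, spec = spec,
             canonical = isTRUE((y$window %||% list())$canonical),
             seg = seg,
             compare_threshold = (y$compare %||% list())$threshold %||% 0.1,
             compare_margin = (y$compare %||% list())$margin %||% 0.3,
             telo = telo, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full low-complexity mapping pipeline
#'
#' Executes simulate (or load) -> profile -> blocks -> compare -> telomeres,
#' writing each stage's standard outputs below `outdir` plus a consolidated
#' machine-readable `report.json`. In simulate mode a truth-versus-called
#' evaluation (block recovery precision/recall, telomere class accuracy,
#' divergence ranking of the perturbed chromosomes) is additionally written.
#' Two runs with identical configuration and seed produce identical report
#' content; wall-clock timings go only to `run.log`.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory?
#' @param quiet suppress progress messages?
#' @return the run report (class `run_report`), invisibly.
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !overwrite)
    stop("output directory '", outdir,
         "' is not empty; use overwrite = TRUE", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    if (!quiet) message("[", name, "] running")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    cat(sprintf("%s\t%.2fs\n", name, dt), file = log_path, append = TRUE)
    res
  }

  # resolved config for provenance
  cfg_json <- file.path(outdir, "config.resolved.json")
  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)

  truth <- NULL
  if (config$mode == "simulate") {
    sim <- stage("simulate", {
      sc <- config$sim_config
      sc$seed <- config$seed
      generate_diploid(sc)
    })
    write_diploid(sim, file.path(outdir, "simulate"))
    genomes <- list(hap1 = sim$hap1, hap2 = sim$hap2)
    truth <- sim$truth
  } else if (config$mode == "fasta_pair") {
    genomes <- list(hap1 = read_genome(config$fasta_h1),
                    hap2 = read_genome(config$fasta_h2))
  } else {
    genomes <- list(hap1 = read_genome(config$fasta_h1))
  }

  profile_dir <- file.path(outdir, "profile")
  block_dir <- file.path(outdir, "blocks")
  telo_dir <- file.path(outdir, "telomeres")
  for (d in c(profile_dir, block_dir, telo_dir))
    dir.create(d, showWarnings = FALSE)

  profiles <- list(); blocks <- list(); telomeres <- list()
  chrom_tables <- list()
  for (h in names(genomes)) {
    profiles[[h]] <- stage(paste0("profile:", h), complexity_profile(
      genomes[[h]], spec = config$spec, canonical = config$canonical))
    write_profile_tsv(profiles[[h]],
                      file.path(profile_dir, paste0(h, ".profile.tsv")))
    write_profile_bedgraph(profiles[[h]], file.path(profile_dir, h))

    blocks[[h]] <- stage(paste0("blocks:", h),
                         call_blocks(profiles[[h]], config$seg))
    write_blocks_bed(blocks[[h]],
                     file.path(block_dir, paste0(h, ".blocks.bed")))
    content <- repetitive_content(profiles[[h]], config$seg)
    write_tsv_file(content,
                   file.path(block_dir, paste0(h, ".repetitive_content.tsv")))

    telomeres[[h]] <- stage(paste0("telomeres:", h),
                            scan_telomeres(genomes[[h]], config$telo))
    write_tsv_file(telomeres[[h]]$calls,
                   file.path(telo_dir, paste0(h, ".calls.tsv")))
    write_tsv_file(telomeres[[h]]$classes,
                   file.path(telo_dir, paste0(h, ".classes.tsv")))

    lens <- vapply(genomes[[h]], nchar, numeric(1))
    bl <- blocks[[h]]
    chrom_tables[[h]] <- data.frame(
      chrom = names(lens), length = unname(lens),
      telomere_class = telomeres[[h]]$classes$class[
        match(names(lens), telomeres[[h]]$classes$chrom)],
      fraction_low = content$fraction_low[match(names(lens), content$chrom)],
      repetitive_rank = content$rank[match(names(lens), content$chrom)],
      n_blocks = vapply(names(lens), function(ch)
        sum(bl$chrom == ch), integer(1)),
      largest_terminal_block = vapply(names(lens), function(ch) {
        sel <- bl$chrom == ch & bl$is_terminal
        if (any(sel)) max(bl$end[sel] - bl$start[sel]) else 0
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    rownames(chrom_tables[[h]]) <- NULL
  }

  divergence <- NULL
  if (length(genomes) == 2L) {
    cmp_dir <- file.path(outdir, "compare")
    dir.create(cmp_dir, showWarnings = FALSE)
    records <- stage("compare", compare_profiles(
      profiles$hap1, profiles$hap2, k = config$seg$k,
      threshold = config$compare_threshold,
      margin = config$compare_margin))
    divergence <- summarize_divergence(records, blocks$hap1, blocks$hap2)
    write_tsv_file(records, file.path(cmp_dir, "divergence_windows.tsv"))
    write_tsv_file(divergence, file.path(cmp_dir, "divergence_summary.tsv"))
  }

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- stage("evaluate", evaluate_run(
      truth, blocks, telomeres, divergence, genomes, config))
    jsonlite::write_json(evaluation, file.path(outdir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  report <- structure(list(
    haplotypes = chrom_tables,
    divergence = divergence,
    note = if (length(genomes) == 1L) "single haplotype: compare stage skipped"
    else NULL,
    evaluation = evaluation,
    provenance = list(
      mode = config$mode, seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_json)),
      package_version = as.character(utils::packageVersion("complexmap"))
    )
  ), class = "run_report")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  cat(sprintf("total\t%.2fs\n",
              as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
      file = log_path, append = TRUE)
  if (!quiet) message("pipeline complete: ", outdir)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (mode:", x$provenance$mode, ", seed:",
      x$provenance$seed, ")\n")
  for (h in names(x$haplotypes)) {
    cat("--", h, "--\n")
    print(x$haplotypes[[h]])
  }
  if (!is.null(x$divergence)) {
    cat("-- divergence (top rows) --\n")
    print(utils::head(x$divergence, 3))
  }
  if (!is.null(x$evaluation)) {
    cat("-- truth evaluation --\n")
    utils::str(x$evaluation)
  }
  invisible(x)
}

#' Evaluate pipeline calls against planted truth
#'
#' Computes block recovery recall and precision (planted tandem/terminal
#' blocks of span at least `min_span` + one window must be recovered with
#' both boundaries within one grid step), the maximum observed boundary
#' error in steps, telomere class accuracy across all chromosomes of both
#' haplotypes, and whether the haplotype-perturbed chromosomes occupy the
#' top of the divergence ranking.
#'
#' @param truth truth table from [generate_diploid()].
#' @param blocks named list (`hap1`, `hap2`) of block tables.
#' @param telomeres named list of [scan_telomeres()] results.
#' @param divergence divergence summary (or `NULL`).
#' @param genomes named list of haplotype sequence vectors.
#' @param config the [run_config()] used.
#' @return named list of scalar metrics.
#' @export
evaluate_run <- function(truth, blocks, telomeres, divergence, genomes,
                         config) {
  step <- config$spec$step
  window <- config$spec$window
  min_span <- config$seg$min_span

  block_kinds <- c("terminal_block", "tandem_block")
  lc_truth <- truth[truth$kind %in% c(block_kinds, "telomere"), , drop = FALSE]
  n_recoverable <- 0L; n_recovered <- 0L; max_err <- 0
  n_called <- 0L; n_called_true <- 0L
  for (h in names(blocks)) {
    planted <- truth[truth$haplotype == h & truth$kind %in% block_kinds, ,
                     drop = FALSE]
    planted <- planted[planted$end - planted$start >= min_span + window, ,
                       drop = FALSE]
    called <- blocks[[h]]
    for (i in seq_len(nrow(planted))) {
      n_recoverable <- n_recoverable + 1L
      cand <- called[called$chrom == planted$chrom[i] &
                       called$end > planted$start[i] &
                       called$start < planted$end[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      err <- pmax(abs(cand$start - planted$start[i]),
                  abs(cand$end - planted$end[i]))
      if (min(err) <= step) {
        n_recovered <- n_recovered + 1L
        max_err <- max(max_err, min(err) / step)
      }
    }
    lc_h <- lc_truth[lc_truth$haplotype == h, , drop = FALSE]
    for (j in seq_len(nrow(called))) {
      n_called <- n_called + 1L
      hit <- any(lc_h$chrom == called$chrom[j] &
                   lc_h$end > called$start[j] - step &
                   lc_h$start < called$end[j] + step)
      if (hit) n_called_true <- n_called_true + 1L
    }
  }

  # telomere classes expected from truth records overlapping the scan zones
  terminal_len <- config$telo$terminal_len
  n_chrom <- 0L; n_class_ok <- 0L
  for (h in names(telomeres)) {
    lens <- vapply(genomes[[h]], nchar, numeric(1))
    tel <- truth[truth$haplotype == h & truth$kind == "telomere", ,
                 drop = FALSE]
    for (chrom in names(lens)) {
      L <- lens[[chrom]]
      tt <- tel[tel$chrom == chrom, , drop = FALSE]
      left <- any(tt$start < terminal_len)
      right <- any(tt$end > L - terminal_len)
      expected <- if (left && right) "both" else if (left) "left_only"
      else if (right) "right_only" else "none"
      got <- telomeres[[h]]$classes$class[
        telomeres[[h]]$classes$chrom == chrom]
      n_chrom <- n_chrom + 1L
      if (identical(got, expected)) n_class_ok <- n_class_ok + 1L
    }
  }

  out <- list(
    block_recall = if (n_recoverable > 0) n_recovered / n_recoverable
    else NA_real_,
    block_precision = if (n_called > 0) n_called_true / n_called
    else NA_real_,
    block_max_boundary_error_steps = max_err,
    n_planted_recoverable = n_recoverable,
    n_blocks_called = n_called,
    telomere_class_accuracy = if (n_chrom > 0) n_class_ok / n_chrom
    else NA_real_
  )

  if (!is.null(divergence)) {
    bp <- config$sim_config$block_plan
    perturbed <- sort(unique(bp$chrom[bp$haplotype != "both"]))
    if (length(perturbed) > 0) {
      topn <- divergence$chrom[seq_len(min(length(perturbed),
                                           nrow(divergence)))]
      out$perturbed_chromosomes <- paste(perturbed, collapse = ",")
      out$divergence_topn_overlap <- length(intersect(perturbed, topn)) /
        length(perturbed)
    }
  }
  out
}
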