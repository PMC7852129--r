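# End-to-end pipeline driver: simulate (optional) -> read depth ->
# region calling -> misassembly classification -> features -> model ->
# randomization statistics, with a JSON + TSV report bundle.

#' Run the full misassembly-audit pipeline
#'
#' Drives every stage on a configuration list (or JSON file): either a
#' synthetic-genome specification (`genome` element holding arguments for
#' [genome_spec()]) or paths to an assembly FASTA and placement/coords
#' tables. Emits a report bundle into `out_dir`: per-bin read depth
#' (bedGraph), called regions (BED), category intervals (BED), coverage
#' class x category fractions, a small balanced classifier report and
#' reshuffling z-scores, plus a single `report.json` with the numeric
#' summaries. Every stage's seed and parameters are logged.
#'
#' @param config Named list or path to a JSON config. Recognised elements:
#'   `genome` (arguments to [genome_spec()]); `paths` (alternatively:
#'   `assembly`, `placements`, `coords`, `truth_regions`); `params`
#'   (`bin_size`, `z`, `q_max`, `q0_max`, `low`, `high`, `min_identity`,
#'   `flank_sizes`, `n_perm`, `n_datasets`, `train_model`); `seed`;
#'   `out_dir`.
#' @return The report list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% tempfile("misasm_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params %||% list()
  bin_size <- p$bin_size %||% 100L
  seed <- config$seed %||% 1L
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  log_line("misasm pipeline; seed=", seed, "; bin_size=", bin_size)

  report <- list(seed = seed, parameters = p)

  if (!is.null(config$genome)) {
    ga <- config$genome
    ga <- lapply(ga, function(x) if (is.data.frame(x)) data.table::as.data.table(x) else x)
    if (!is.null(ga$chrom_lengths)) ga$chrom_lengths <- unlist(ga$chrom_lengths)
    ga$seed <- ga$seed %||% seed
    spec <- do.call(genome_spec, ga)
    log_line("stage simulate: seed=", spec$seed)
    truth <- build_truth_genome(spec)
    collapsed <- derive_collapsed_assembly(truth)
    placements <- simulate_reads(collapsed, bin_size = bin_size)
    blocks <- emit_alignment_coords(truth, collapsed)
    seqs <- collapsed$seqs
    truth_regions <- collapsed$labels$coverage_class
    write_fasta(seqs, file.path(out_dir, "assembly.fa"))
    write_placements(placements, file.path(out_dir, "placements.tsv"))
    write_coords(blocks, file.path(out_dir, "alignment.coords"))
  } else {
    paths <- config$paths %||% config
    for (nm in c("assembly", "placements")) {
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
        stop("missing input path: ", nm)
    }
    seqs <- read_fasta(paths$assembly)
    placements <- read_placements(paths$placements)
    blocks <- if (!is.null(paths$coords)) parse_coords(paths$coords) else NULL
    truth_regions <- if (!is.null(paths$truth_regions))
      read_bed(paths$truth_regions) else NULL
    collapsed <- NULL
  }
  chrom_lengths <- Biostrings::width(seqs)
  names(chrom_lengths) <- names(seqs)

  log_line("stage depth: reads=", nrow(placements))
  bins <- compute_rd(placements, bin_size = bin_size, seqs = seqs)
  write_bedgraph(bins, file.path(out_dir, "rd.bedgraph"))
  report$median_rd <- stats::median(bins$rd[bins$n_frac <= 0.5])

  log_line("stage call-regions")
  regions <- call_regions(bins, z = p$z %||% 2, q_max = p$q_max %||% 0.08,
                          q0_max = p$q0_max %||% 0.5,
                          low = p$low %||% 0.72, high = p$high %||% 1.76)
  regions$n_fraction <- region_n_fraction(regions, seqs)
  write_bed(regions, file.path(out_dir, "regions.bed"),
            extra_cols = c("coverage_class", "mean_rd", "q_value", "q0",
                           "n_fraction"))
  report$region_counts <- as.list(table(regions$coverage_class))
  report$class_lengths <- lapply(
    split(regions$end - regions$start, regions$coverage_class), sum)
  report$rd_by_class <- lapply(split(regions$mean_rd, regions$coverage_class),
                               function(x) c(median = stats::median(x)))
  if (!is.null(truth_regions) && "class" %in% names(truth_regions)) {
    sc <- score_region_calls(regions, truth_regions, level = "nucleotide")
    report$region_recovery <- as.data.frame(sc)
  }

  if (!is.null(blocks)) {
    log_line("stage classify: min_identity=", p$min_identity %||% 95)
    fb <- filter_identity(blocks, p$min_identity %||% 95)
    categories <- classify_regions(fb, min_length = p$min_length %||% 100L)
    write_bed(categories[, c("chrom", "start", "end", "category")],
              file.path(out_dir, "categories.bed"), extra_cols = "category")
    iw <- intersect_with_coverage(categories, regions, chrom_lengths)
    data.table::fwrite(iw$class_by_category,
                       file.path(out_dir, "class_by_category.tsv"), sep = "\t")
    data.table::fwrite(iw$category_by_class,
                       file.path(out_dir, "category_by_class.tsv"), sep = "\t")
    report$class_by_category <- as.data.frame(iw$class_by_category)
    report$category_by_class <- as.data.frame(iw$category_by_class)
  }

  log_line("stage features")
  tracks <- list()
  if (!is.null(collapsed)) {
    # project truth annotation tracks onto the derived assembly where the
    # generator provides them
    tracks <- list(ssrs = shift_track(collapsed, truth$tracks$ssrs),
                   genes = shift_track(collapsed, truth$tracks$genes),
                   tes = shift_track(collapsed, truth$tracks$tes),
                   pseudogenes = shift_track(collapsed, truth$tracks$pseudogenes))
    tracks <- Filter(Negate(is.null), tracks)
  }
  feats <- feature_matrix(regions, seqs, tracks,
                          flank_sizes = p$flank_sizes %||% c(500, 2000),
                          kmer_k = p$kmer_k %||% c(1L, 2L))
  data.table::fwrite(cbind(regions[, c("chrom", "start", "end",
                                       "coverage_class")], feats),
                     file.path(out_dir, "features.tsv"), sep = "\t")

  keep <- regions$coverage_class %in% c("HC", "LC", "BG")
  if (isTRUE(p$train_model %||% TRUE) &&
      length(unique(regions$coverage_class[keep])) >= 2 &&
      min(table(regions$coverage_class[keep])) >= 10) {
    log_line("stage train: seed=", seed)
    X <- as.data.frame(feats)[keep, , drop = FALSE]
    X[is.na(X)] <- 0
    grid <- data.frame(max_depth = c(0L, 5L), mtry_frac = NA_real_,
                       num_trees = p$num_trees %||% 100L)
    mdl <- train_region_classifier(
      X, regions$coverage_class[keep],
      n_datasets = p$n_datasets %||% 10L, n_search = 2L, grid = grid,
      folds = min(5L, min(table(regions$coverage_class[keep]))),
      seed = seed)
    report$model <- list(cv_macro_f1 = mdl$cv_macro_f1,
                         test_macro_f1 = mdl$test_macro_f1,
                         test_accuracy = mdl$test_accuracy,
                         best_params = as.list(mdl$best_params))
    data.table::fwrite(data.table::as.data.table(
      as.data.frame(mdl$confusion_test), keep.rownames = "truth"),
      file.path(out_dir, "confusion_test.tsv"), sep = "\t")
  }

  if (length(tracks) && any(regions$coverage_class == "HC")) {
    log_line("stage permtest: n=", p$n_perm %||% 200L)
    tr <- tracks[[1]]
    zs <- reshuffle_zscore(regions, "HC", tr, chrom_lengths,
                           window = p$window %||% 100000L,
                           n = p$n_perm %||% 200L, seed = seed)
    report$reshuffle_hc <- zs[c("observed", "null_mean", "null_sd", "z",
                                "p_value")]
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_line("done")
  invisible(report)
}

# map a truth-coordinate annotation track into derived-assembly coordinates
# through the kept-segment map (intervals split by removed segments)
shift_track <- function(collapsed, track) {
  if (is.null(track) || !nrow(track)) return(NULL)
  segs <- collapsed$segment_map
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    t <- track[track$chrom == s$tchrom & track$start < s$tend &
                 track$end > s$tstart, ]
    if (!nrow(t)) next
    lo <- pmax(t$start, s$tstart); hi <- pmin(t$end, s$tend)
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = s$qchrom,
      start = lo - s$tstart + s$qstart,
      end = hi - s$tstart + s$qstart)
  }
  if (!length(out)) return(NULL)
  data.table::rbindlist(out)
}
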