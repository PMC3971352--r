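#' Pipeline run configuration
#'
#' @param inputs character vector of read files (BAM or strand BED).
#' @param mode one of "strandcall", "sce", "rearrange", "scaffold-map",
#'   "assemble".
#' @param out_dir output directory.
#' @param bin_size bin width in bp (default 200 kb).
#' @param sd_threshold bin-filter SD multiplier (default 0.2).
#' @param min_quality mapping-quality cutoff (default 10).
#' @param min_reads informativeness minimum per state call (default 20).
#' @param similarity_threshold linkage-group clustering threshold (0.85).
#' @param min_libraries,min_concordance scaffold-placement confidence
#'   thresholds (10 libraries, 60 percent).
#' @param chrom_lengths chromosome-length table (named vector or TSV path);
#'   required for BED inputs.
#' @param gap_file optional gap BED for scaffold-map mode.
#' @param scaffolds character vector of scaffold (contig) names to place in
#'   scaffold-map mode.
#' @param haploid haploid chromosome names.
#' @param seed integer seed for the segmentation permutations.
#' @param make_plots write ideogram PNGs (default TRUE).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(inputs, mode = c("sce", "strandcall", "rearrange",
                                        "scaffold-map", "assemble"),
                       out_dir = "strandtools_out", bin_size = 200000L,
                       sd_threshold = 0.2, min_quality = 10L,
                       min_reads = 20L, similarity_threshold = 0.85,
                       min_libraries = 10L, min_concordance = 60,
                       chrom_lengths = NULL, gap_file = NULL,
                       scaffolds = NULL, haploid = character(),
                       seed = 42L, make_plots = TRUE) {
  mode <- match.arg(mode)
  if (bin_size < 1) stop_bad("invalid bin size %s", bin_size)
  if (!length(inputs)) stop_bad("no input files given")
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1 &&
      file.exists(chrom_lengths))
    chrom_lengths <- read_chrom_lengths(chrom_lengths)
  if (mode == "scaffold-map" && is.null(scaffolds))
    stop_bad("scaffold-map mode needs `scaffolds`")
  structure(list(inputs = inputs, mode = mode, out_dir = out_dir,
                 bin_size = as.integer(bin_size),
                 sd_threshold = sd_threshold,
                 min_quality = as.integer(min_quality),
                 min_reads = as.integer(min_reads),
                 similarity_threshold = similarity_threshold,
                 min_libraries = as.integer(min_libraries),
                 min_concordance = min_concordance,
                 chrom_lengths = chrom_lengths, gap_file = gap_file,
                 scaffolds = scaffolds, haploid = haploid,
                 seed = as.integer(seed), make_plots = make_plots),
            class = "RunConfig")
}

process_library <- function(path, config) {
  reads <- load_reads(path, min_quality = config$min_quality,
                      chrom_lengths = config$chrom_lengths)
  counts <- bin_reads(reads, config$bin_size)
  ploidy <- call_ploidy(counts)
  calls <- call_library_states(counts, ploidy, config$min_reads)
  bg <- background_metric(calls)
  events <- if (config$mode %in% c("sce", "rearrange", "scaffold-map"))
    detect_events(reads, counts, config$bin_size, config$sd_threshold,
                  ploidy, seed = config$seed)
  else data.frame(library = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  left_state = character(), right_state = character(),
                  class = character())
  list(reads = reads, counts = counts, ploidy = ploidy, calls = calls,
       background = bg, events = events)
}

#' Run the end-to-end pipeline for a set of libraries
#'
#' Executes the stage graph of the selected mode over all input libraries,
#' writes the mode's outputs under `config$out_dir`, echoes the
#' configuration as JSON and emits a manifest (file, md5) of everything
#' produced.  A failing library is quarantined (listed in the manifest
#' directory) and the run continues; the exit status is nonzero only on
#' hard errors.
#'
#' @param config a [run_config()].
#' @return list: `status` (0 on success), `manifest` data.frame, `results`
#'   per-library list, `failed` character vector, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "run_config.json")
  cfg <- config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       null = "null")
  results <- list()
  failed <- character()
  for (path in config$inputs) {
    res <- tryCatch(process_library(path, config), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("library %s quarantined: %s", path,
                      conditionMessage(res)))
      failed <- c(failed, path)
      next
    }
    results[[res$reads$library]] <- res
  }
  if (!length(results)) stop_bad("every library failed")
  files <- cfg_path
  if (config$mode %in% c("sce", "rearrange", "scaffold-map")) {
    for (lib in names(results)) {
      bed <- file.path(config$out_dir, paste0(lib, "_events.bed"))
      write_event_bed(results[[lib]]$events, bed, paste0(lib, "_SCE"))
      files <- c(files, bed)
      if (config$make_plots) {
        png <- file.path(config$out_dir, paste0(lib, "_ideogram.png"))
        plot_ideogram(results[[lib]]$counts, results[[lib]]$events,
                      results[[lib]]$background, png)
        files <- c(files, png)
      }
    }
  }
  mis <- recur <- NULL
  if (config$mode %in% c("sce", "rearrange")) {
    all_ev <- do.call(rbind, lapply(results, `[[`, "events"))
    if (length(results) >= 2 && nrow(all_ev)) {
      recur <- amalgamate_events(all_ev, n_libraries = length(results))
      lens <- results[[1]]$counts$chrom_lengths
      mis <- call_misorientations(all_ev,
                                  lapply(results, `[[`, "calls"), lens)
    }
  }
  if (length(results) >= 2) {
    sfiles <- write_summary(results, config$out_dir, mis, recur)
    files <- c(files, unname(sfiles))
  }
  if (config$mode == "scaffold-map") {
    gaps <- if (!is.null(config$gap_file)) read_gap_bed(config$gap_file)
    else {
      warning("no gap file given; gap columns left empty")
      NULL
    }
    counts_list <- lapply(results, `[[`, "counts")
    events_list <- lapply(results, `[[`, "events")
    lens <- results[[1]]$counts$chrom_lengths
    lens <- lens[setdiff(names(lens), config$scaffolds)]
    rs <- region_state_matrix(counts_list, events_list, lens,
                              config$haploid, config$min_reads)
    prows <- NULL
    for (sc in config$scaffolds) {
      ss <- call_scaffold_states(counts_list, sc, config$min_reads)
      size <- results[[1]]$counts$chrom_lengths[[sc]]
      pl <- map_scaffold(ss, rs, sc, size, config$min_libraries,
                         config$min_concordance)
      pl <- crossref_gaps(pl, gaps)
      gp <- pl$gaps$primary
      prows <- rbind(prows, data.frame(
        scaffold = sc, size_kb = size / 1000,
        chrom = pl$chrom %||% NA, start = pl$start, end = pl$end,
        orientation = pl$orientation %||% NA,
        concordance = pl$concordance, n_libraries = pl$n_informative,
        confident = pl$confident,
        gaps_unbridged = pl$gaps$n_unbridged %||% NA,
        gaps_bridged = pl$gaps$n_bridged %||% NA,
        primary_gap = if (!is.null(gp))
          sprintf("%s:%d-%d", gp$chrom, gp$start, gp$end) else ""))
    }
    pfile <- file.path(config$out_dir, "scaffold_placements.csv")
    utils::write.csv(prows, pfile, row.names = FALSE)
    files <- c(files, pfile)
  }
  if (config$mode == "assemble") {
    states <- do.call(rbind, lapply(results, `[[`, "calls"))
    names(states)[names(states) == "chrom"] <- "contig"
    sm <- build_state_matrix(states,
                             results[[1]]$counts$chrom_lengths)
    sep <- separate_haploid(sm)
    lg <- cluster_linkage_groups(sep$diploid, config$similarity_threshold)
    lg <- reorient_and_merge(lg, sep$diploid)
    rows <- NULL
    for (g in seq_along(lg$groups)) {
      grp <- lg$groups[[g]]
      ord <- order_contigs(grp, sep$diploid)
      rows <- rbind(rows, data.frame(
        contig = ord$contigs, group = sprintf("LG%02d", g),
        orientation = grp$orientation[match(ord$contigs, grp$contig)],
        position = seq_along(ord$contigs), ordered = ord$ordered))
    }
    gfile <- file.path(config$out_dir, "linkage_groups.csv")
    utils::write.csv(rows, gfile, row.names = FALSE)
    cfile <- file.path(config$out_dir, "group_concordance.tsv")
    utils::write.table(lg$concordance_matrix, cfile, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, gfile, cfile)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mfile <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mfile)
  invisible(list(status = 0L, manifest = manifest, results = results,
                 failed = failed))
}
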