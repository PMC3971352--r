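#' Write localized events as a UCSC-loadable BED track
#'
#' One record per event, 0-based half-open; the name encodes the state
#' transition (e.g. "CC>WC"), the score the number of reads supporting the
#' flanks within the gross interval; a `track` header line is included.
#'
#' @param events [detect_events()] data.frame.
#' @param path output file.
#' @param track_name track name for the header.
#' @return `path`, invisibly.
#' @export
write_event_bed <- function(events, path, track_name = "SCE_events") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    'track name="%s" description="template-strand transitions" visibility=1',
    track_name), con)
  if (nrow(events)) {
    df <- data.frame(chrom = events$chrom,
                     start = format(events$start, scientific = FALSE, trim = TRUE),
                     end = format(events$end, scientific = FALSE, trim = TRUE),
                     name = paste0(events$left_state, ">", events$right_state,
                                   "|", events$class),
                     score = if ("support" %in% names(events)) events$support
                             else 0L,
                     strand = ".")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Re-read an event BED written by [write_event_bed()]
#'
#' @param path BED file.
#' @return data.frame: `chrom`, `start`, `end`, `left_state`,
#'   `right_state`, `class`.
#' @export
read_event_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), left_state = character(),
                      right_state = character(), class = character()))
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character", "character"))
  parts <- strsplit(df$name, "[>|]")
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             left_state = vapply(parts, `[`, "", 1),
             right_state = vapply(parts, `[`, "", 2),
             class = vapply(parts, `[`, "", 3))
}

#' Write the cross-library summary report
#'
#' Emits machine-readable CSVs: per-library background / SCE counts, the
#' per-chromosome segregation summary (WW/WC/CC tallies with Holm-adjusted
#' chi-squared p), an inter-event nearest-neighbour distance histogram,
#' and, when supplied, the misorientation and recurrent-event tables.
#' Every figure in the report is re-derivable from these files.
#'
#' @param libraries list per library: `background` ([background_metric()]),
#'   `events` ([detect_events()]), `calls` ([call_library_states()]).
#' @param dir output directory.
#' @param misorientations,recurrent optional tables.
#' @return named character vector of files written, invisibly.
#' @export
write_summary <- function(libraries, dir, misorientations = NULL,
                          recurrent = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib_rows <- do.call(rbind, lapply(libraries, function(l)
    data.frame(library = l$background$library,
               background_percent = l$background$background,
               background_defined = l$background$defined,
               n_sce = sum(l$events$class == "SCE"),
               n_events = nrow(l$events))))
  files <- c(libraries = file.path(dir, "library_summary.csv"))
  utils::write.csv(lib_rows, files[["libraries"]], row.names = FALSE)
  seg <- segregation_summary(lapply(libraries, `[[`, "calls"))
  files["segregation"] <- file.path(dir, "segregation_summary.csv")
  utils::write.csv(seg$summary, files[["segregation"]], row.names = FALSE)
  ## nearest-neighbour distances between events, pooled per chromosome
  ev <- do.call(rbind, lapply(libraries, `[[`, "events"))
  dist <- as.numeric(unlist(lapply(split(ev, ev$chrom), function(e) {
    p <- sort((e$start + e$end) / 2)
    if (length(p) > 1) diff(p) else numeric()
  })) %||% numeric())
  brk <- c(0, 10^(4:8), Inf)
  hist_df <- data.frame(
    bin = c("<10kb", "10-100kb", "100kb-1Mb", "1-10Mb", "10-100Mb", ">100Mb"),
    count = as.integer(table(cut(dist, brk, right = FALSE))))
  files["event_distances"] <- file.path(dir, "event_distance_histogram.csv")
  utils::write.csv(hist_df, files[["event_distances"]], row.names = FALSE)
  if (!is.null(misorientations)) {
    files["misorientations"] <- file.path(dir, "misorientations.csv")
    utils::write.csv(misorientations, files[["misorientations"]],
                     row.names = FALSE)
  }
  if (!is.null(recurrent)) {
    files["recurrent"] <- file.path(dir, "recurrent_events.csv")
    utils::write.csv(recurrent, files[["recurrent"]], row.names = FALSE)
  }
  invisible(files)
}

#' Plot a library ideogram
#'
#' One panel per chromosome: Watson read density to the left of the
#' ideogram bar (orange), Crick density to the right (blue), detected
#' events marked with arrowheads, the library background percentage
#' printed on the figure.  Output is deterministic for fixed inputs.
#'
#' @param counts a [bin_reads()] object.
#' @param events optional [detect_events()] data.frame.
#' @param background optional [background_metric()] result.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_ideogram <- function(counts, events = NULL, background = NULL,
                          path, width = 900, height = 600) {
  chroms <- names(counts$chrom_lengths)
  chroms <- chroms[vapply(chroms, function(ch)
    length(counts$W[[ch]]) > 0, logical(1))]
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  n <- length(chroms)
  graphics::par(mar = c(2, 4, 3, 1))
  maxlen <- max(unlist(counts$chrom_lengths[chroms]))
  maxd <- max(1, unlist(counts$W[chroms]), unlist(counts$C[chroms]))
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(maxlen, 0),
                 xaxt = "n", xlab = "", ylab = "position (bp)",
                 main = sprintf("%s%s", counts$library %||% "library",
                                if (!is.null(background) &&
                                    isTRUE(background$defined))
                                  sprintf("  (background %.1f%%)",
                                          background$background) else ""))
  graphics::axis(1, at = seq_len(n), labels = chroms, las = 2, cex.axis = 0.7)
  half <- 0.35
  for (k in seq_len(n)) {
    ch <- chroms[k]
    bb <- bin_bounds(counts, ch)
    graphics::rect(k - 0.05, 0, k + 0.05, counts$chrom_lengths[[ch]],
                   col = "grey85", border = "grey60")
    w <- counts$W[[ch]] / maxd * half
    cc <- counts$C[[ch]] / maxd * half
    graphics::rect(k - 0.05 - w, bb$start, k - 0.05, bb$end,
                   col = "darkorange", border = NA)
    graphics::rect(k + 0.05, bb$start, k + 0.05 + cc, bb$end,
                   col = "steelblue", border = NA)
    if (!is.null(events)) {
      e <- events[events$chrom == ch, , drop = FALSE]
      if (nrow(e))
        graphics::points(rep(k - half - 0.05, nrow(e)),
                         (e$start + e$end) / 2, pch = 17, cex = 1.2,
                         col = "red")
    }
  }
  invisible(path)
}
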