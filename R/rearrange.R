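## Single-linkage grouping of half-open intervals by >= min_overlap bp
## overlap (union-find over the IRanges overlap graph).
overlap_groups <- function(start, end, min_overlap = 1L) {
  n <- length(start)
  if (!n) return(integer())
  ir <- IRanges::IRanges(start = start + 1L, end = pmax(end, start + 1L))
  hits <- IRanges::findOverlaps(ir, ir,
                                minoverlap = as.integer(min_overlap))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Amalgamate events across libraries into recurrent-event calls
#'
#' Events whose intervals mutually overlap (single-linkage, >= `min_overlap`
#' bp) are grouped; groups seen in at least two distinct libraries are
#' reported with the intersected interval and the occurrence count.  Genuine
#' SCEs are stochastic, so recurrent intervals flag potential structural
#' rearrangements (or recurrent-SCE regions); the interpretation is left to
#' the user.
#'
#' @param events event data.frame (rbind of [detect_events()] results over
#'   libraries).
#' @param min_overlap minimum overlap in bp to link two events (default 1).
#' @param n_libraries total informative library count for the fraction
#'   column (default: distinct libraries present in `events`).
#' @return data.frame: `chrom`, `start`, `end` (intersection of the
#'   contributing intervals), `count`, `libraries`
#'   (comma-separated), `fraction`.
#' @export
amalgamate_events <- function(events, min_overlap = 1L, n_libraries = NULL) {
  n_libraries <- n_libraries %||% length(unique(events$library))
  out <- NULL
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, , drop = FALSE]
    e <- e[order(e$start, e$end, e$library), , drop = FALSE]
    grp <- overlap_groups(e$start, e$end, min_overlap)
    for (g in unique(grp)) {
      m <- e[grp == g, , drop = FALSE]
      libs <- sort(unique(m$library))
      if (length(libs) < 2) next
      out <- rbind(out, data.frame(
        chrom = ch, start = max(m$start), end = min(m$end),
        count = length(libs),
        libraries = paste(libs, collapse = ","),
        fraction = length(libs) / n_libraries))
    }
  }
  out %||% data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = integer(),
                      libraries = character(), fraction = numeric())
}

## Pair a library's homozygous<->homozygous boundary events on one
## chromosome into flipped regions: consecutive boundaries toggle the
## orientation, an unpaired final boundary extends to the chromosome end.
pair_flip_regions <- function(ev, chrom_length) {
  if (!nrow(ev)) return(NULL)
  ev <- ev[order(ev$start), , drop = FALSE]
  mid <- (ev$start + ev$end) / 2
  k <- seq(1, nrow(ev), by = 2)
  data.frame(start = mid[k],
             end = ifelse(k + 1 <= nrow(ev), mid[k + 1], chrom_length),
             note = paste0(ev$left_state[k], "->", ev$right_state[k]))
}

#' Call reference misorientations from events pooled across libraries
#'
#' A misoriented reference segment flips the template state of every
#' library that is homozygous over it (WW appears as CC and vice versa); in
#' WC libraries both homologues flip and the mix is unchanged, so only
#' homozygous libraries are informative.  Diploid WW<->CC candidate
#' boundaries are paired per library into flipped regions, merged across
#' libraries by overlap, and reported with their concordance (percent of
#' informative libraries showing the flip).  On haploid chromosomes every
#' switch looks like an SCE, so a misoriented segment is called only where
#' paired switch boundaries recur across *all* informative libraries.
#' Regions informative in fewer than two libraries are suppressed.
#'
#' @param events pooled event data.frame ([detect_events()] over libraries).
#' @param calls_list list of per-library state-call data.frames
#'   ([call_library_states()]), used to count informative libraries.
#' @param chrom_lengths named chromosome lengths.
#' @param min_overlap bp overlap to link regions across libraries.
#' @return data.frame: `chrom`, `start`, `end`, `concordance`,
#'   `n_libraries`, `n_informative`, `type`, `note`.
#' @export
call_misorientations <- function(events, calls_list, chrom_lengths,
                                 min_overlap = 1L) {
  all_calls <- do.call(rbind, calls_list)
  informative_n <- function(ch, haploid) {
    st <- all_calls$state[all_calls$chrom == ch]
    if (haploid) sum(st != "unknown") else sum(st %in% c("WW", "CC"))
  }
  out <- NULL
  for (type in c("diploid", "haploid")) {
    cls <- if (type == "diploid") "misorientation-candidate"
           else "haploid-switch"
    ev <- events[events$class == cls, , drop = FALSE]
    if (!nrow(ev)) next
    for (ch in unique(ev$chrom)) {
      n_inf <- informative_n(ch, type == "haploid")
      regions <- do.call(rbind, lapply(
        split(ev[ev$chrom == ch, , drop = FALSE],
              ev$library[ev$chrom == ch]),
        function(e) {
          r <- pair_flip_regions(e, chrom_lengths[[ch]])
          if (!is.null(r)) cbind(library = e$library[1], r)
        }))
      if (is.null(regions)) next
      grp <- overlap_groups(regions$start, regions$end, min_overlap)
      for (g in unique(grp)) {
        m <- regions[grp == g, , drop = FALSE]
        nlib <- length(unique(m$library))
        if (n_inf < 2) {
          message(sprintf(
            "misorientation region on %s informative in < 2 libraries; suppressed",
            ch))
          next
        }
        conc <- 100 * nlib / n_inf
        ## a flip seen in a single library is far more likely a
        ## segmentation artifact than a reference misorientation
        if (type == "diploid" && nlib < 2) next
        if (type == "haploid" && nlib < n_inf) next
        s <- max(m$start); e <- min(m$end)
        if (s >= e) { s <- min(m$start); e <- max(m$end) }
        out <- rbind(out, data.frame(
          chrom = ch, start = s, end = e, concordance = conc,
          n_libraries = nlib, n_informative = n_inf, type = type,
          note = names(sort(table(m$note), decreasing = TRUE))[1]))
      }
    }
  }
  out %||% data.frame(chrom = character(), start = numeric(),
                      end = numeric(), concordance = numeric(),
                      n_libraries = integer(), n_informative = integer(),
                      type = character(), note = character())
}

#' Segment read depth into copy-number segments
#'
#' Segments the per-bin total-depth track of each chromosome (same CBS
#' backend as SCE detection) on depth relative to the library per-bin
#' average; each segment's copy estimate is round(2 x relative depth),
#' halves away from zero.  Segments tile the chromosome.
#'
#' @param counts a [bin_reads()] object.
#' @param mask optional [filter_bins()] mask.
#' @param alpha,nperm,seed CBS parameters.
#' @return data.frame: `chrom`, `start`, `end`, `depth` (relative),
#'   `copy_number`.
#' @export
detect_cnv_segments <- function(counts, mask = NULL, alpha = 0.01,
                                nperm = 1000L, seed = 42L) {
  lens <- counts$chrom_lengths
  widths <- lapply(names(lens), function(ch) {
    bb <- bin_bounds(counts, ch)
    bb$end - bb$start
  })
  names(widths) <- names(lens)
  tot <- lapply(names(lens), function(ch) counts$W[[ch]] + counts$C[[ch]])
  names(tot) <- names(lens)
  lib_rate <- sum(unlist(tot)) / sum(unlist(widths))
  if (lib_rate == 0) stop_bad("zero library depth")
  out <- NULL
  for (ci in seq_along(lens)) {
    ch <- names(lens)[ci]
    keep <- if (!is.null(mask)) !mask[[ch]] else rep(TRUE, length(tot[[ch]]))
    idx <- which(keep)
    if (length(idx) < 2) next
    rel <- (tot[[ch]][idx] / widths[[ch]][idx]) / lib_rate
    bps <- cbs_segment(rel, alpha, nperm, seed + ci)
    edges <- c(0L, bps, length(rel))
    bb <- bin_bounds(counts, ch)
    seg <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(k) {
      sel <- (edges[k] + 1L):edges[k + 1L]
      data.frame(from = idx[sel[1]], to = idx[sel[length(sel)]],
                 depth = mean(rel[sel]))
    }))
    seg$copy_number <- round_half_away(2 * seg$depth)
    merge_k <- c(TRUE, seg$copy_number[-1] != seg$copy_number[-nrow(seg)])
    grp <- cumsum(merge_k)
    seg <- do.call(rbind, lapply(split(seg, grp), function(s)
      data.frame(from = s$from[1], to = s$to[nrow(s)],
                 depth = mean(s$depth), copy_number = s$copy_number[1])))
    ## tile the chromosome: segment boundaries midway handled by extending
    ## each segment to the start of the next retained bin run
    seg$start <- bb$start[seg$from]
    seg$end <- bb$end[seg$to]
    seg$start[1] <- 0
    seg$end[nrow(seg)] <- lens[[ch]]
    if (nrow(seg) > 1)
      seg$end[-nrow(seg)] <- seg$start[-1]
    out <- rbind(out, data.frame(chrom = ch, start = seg$start,
                                 end = seg$end, depth = seg$depth,
                                 copy_number = seg$copy_number))
  }
  out %||% data.frame(chrom = character(), start = numeric(),
                      end = numeric(), depth = numeric(),
                      copy_number = integer())
}
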