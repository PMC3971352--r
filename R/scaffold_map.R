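#' Call an orphan scaffold's template state in every library
#'
#' @param counts_list list of per-library [bin_reads()] objects whose
#'   reference includes the scaffold as a contig.
#' @param scaffold scaffold (contig) name.
#' @param min_reads informativeness minimum per library (default 20).
#' @return list: `states` data.frame (`library`, `state`, `W`, `C`,
#'   `informative`), `haploid_candidate` (TRUE when informative libraries
#'   only ever show one strand, never both -- the sex-chromosome
#'   signature), `n_informative`.
#' @export
call_scaffold_states <- function(counts_list, scaffold, min_reads = 20L) {
  states <- do.call(rbind, lapply(counts_list, function(bc) {
    s <- call_chromosome_state(bc, scaffold, 2L, min_reads)
    s$library <- bc$library %||% "lib"
    s
  }))
  inf <- states$informative
  if (!any(inf))
    warning(sprintf("scaffold %s informative in no library; placement skipped",
                    scaffold))
  hap <- sum(inf) >= 3 && all(states$state[inf] %in% c("WW", "CC"))
  list(states = states, haploid_candidate = hap, n_informative = sum(inf))
}

#' Per-library chromosome region states on a common breakpoint grid
#'
#' Each chromosome is split at every library's detected event positions
#' (interval midpoints); the union of breakpoints over libraries forms a
#' common grid, the finest partition on which concordance is well defined.
#' Each library's state over a grid region is the state of its own
#' (coarser) region containing it, called from the binned counts.
#'
#' @param counts_list list of per-library [bin_reads()] objects.
#' @param events_list list of per-library [detect_events()] data.frames.
#' @param chrom_lengths named chromosome lengths (chromosomes to score;
#'   scaffolds excluded by the caller).
#' @param haploid character vector of haploid chromosome names.
#' @param min_reads informativeness minimum per region and library.
#' @return list per chromosome: `regions` data.frame (`start`, `end`) and
#'   `states` character matrix (regions x libraries; "unknown" when
#'   uninformative), plus `haploid` flag.
#' @export
region_state_matrix <- function(counts_list, events_list, chrom_lengths,
                                haploid = character(), min_reads = 20L) {
  libs <- vapply(counts_list, function(bc) bc$library %||% "lib",
                 character(1))
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    mids <- sort(unique(unlist(lapply(events_list, function(ev) {
      e <- ev[ev$chrom == ch, , drop = FALSE]
      (e$start + e$end) / 2
    }))))
    edges <- c(0, mids, len)
    regions <- data.frame(start = edges[-length(edges)], end = edges[-1])
    is_hap <- ch %in% haploid
    mat <- matrix("unknown", nrow(regions), length(libs),
                  dimnames = list(NULL, libs))
    for (li in seq_along(libs)) {
      bc <- counts_list[[li]]
      if (is.null(bc$W[[ch]])) next
      ev <- events_list[[li]]
      own_mids <- sort((ev$start[ev$chrom == ch] + ev$end[ev$chrom == ch]) / 2)
      own_edges <- c(0, own_mids, len)
      bb <- bin_bounds(counts_list[[li]], ch)
      bmid <- (bb$start + bb$end) / 2
      for (k in seq_len(length(own_edges) - 1L)) {
        sel <- bmid >= own_edges[k] & bmid < own_edges[k + 1L]
        W <- sum(bc$W[[ch]][sel]); C <- sum(bc$C[[ch]][sel])
        st <- if (W + C < min_reads) "unknown"
        else if (is_hap) { if (W >= C) "W" else "C" }
        else c("CC", "WC", "WW")[round_half_away((W - C) / (W + C)) + 2L]
        rmid <- (regions$start + regions$end) / 2
        cover <- rmid >= own_edges[k] & rmid < own_edges[k + 1L]
        mat[cover, li] <- st
      }
    }
    out[[ch]] <- list(regions = regions, states = mat, haploid = is_hap)
  }
  out
}

## match + orientation vote of a scaffold state against a region state
score_pair <- function(sc, rg, haploid) {
  if (haploid) {
    if (sc %in% c("WW", "W")) sc <- "W" else if (sc %in% c("CC", "C")) sc <- "C"
    if (!rg %in% c("W", "C") || !sc %in% c("W", "C"))
      return(c(match = 0, same = 0, reverse = 0))
    if (sc == rg) c(match = 1, same = 1, reverse = 0)
    else c(match = 1, same = 0, reverse = 1)
  } else if (sc == "WC") {
    c(match = as.numeric(rg == "WC"), same = 0, reverse = 0)
  } else if (sc %in% c("WW", "CC")) {
    if (rg == sc) c(match = 1, same = 1, reverse = 0)
    else if (rg %in% c("WW", "CC")) c(match = 1, same = 0, reverse = 1)
    else c(match = 0, same = 0, reverse = 0)
  } else c(match = 0, same = 0, reverse = 0)
}

#' Place an orphan scaffold by cross-library template-state concordance
#'
#' For each chromosome region, the scaffold's per-library state is compared
#' with the region's: a WC scaffold matches WC regions only; a WW scaffold
#' matches WW regions in the same orientation and CC regions in reverse
#' orientation (and symmetrically for CC), and never matches a WC region.
#' Concordance is the percentage of mutually informative libraries that
#' match; the best region wins, its orientation is the majority of
#' same-versus-reverse votes, and the call is confident when more than
#' `min_libraries` libraries were informative and concordance exceeds
#' `min_concordance`.  Haploid-candidate scaffolds are scored against
#' haploid chromosomes only.
#'
#' @param scaffold_states result of [call_scaffold_states()].
#' @param region_states result of [region_state_matrix()].
#' @param scaffold scaffold name.
#' @param scaffold_size scaffold length in bp (reported; used by gap
#'   cross-referencing).
#' @param min_libraries,min_concordance confidence thresholds (defaults
#'   10 libraries, 60 percent, both strict).
#' @return object of class `ScaffoldPlacement`: best region, orientation
#'   ("same"/"reverse"; NA unless confident), concordance, informative
#'   library count, `confident`, `ambiguous` plus the per-region score
#'   table in `$scores`.
#' @export
map_scaffold <- function(scaffold_states, region_states, scaffold = "scaffold",
                         scaffold_size = NA_real_, min_libraries = 10L,
                         min_concordance = 60) {
  st <- scaffold_states$states
  hap_sc <- isTRUE(scaffold_states$haploid_candidate)
  ## a haploid-looking scaffold can only be scored against haploid
  ## chromosomes when the genome has any; otherwise fall back to diploid
  ## scoring (a short diploid scaffold may show no WC by chance)
  if (hap_sc && !any(vapply(region_states, `[[`, logical(1), "haploid")))
    hap_sc <- FALSE
  scores <- NULL
  for (ch in names(region_states)) {
    rs <- region_states[[ch]]
    if (hap_sc && !rs$haploid) next
    if (!hap_sc && rs$haploid) next
    for (k in seq_len(nrow(rs$regions))) {
      match_n <- same_n <- rev_n <- inf_n <- 0
      for (li in seq_len(ncol(rs$states))) {
        lib <- colnames(rs$states)[li]
        si <- match(lib, st$library)
        if (is.na(si) || !st$informative[si]) next
        rg <- rs$states[k, li]
        if (rg == "unknown") next
        inf_n <- inf_n + 1
        v <- score_pair(st$state[si], rg, rs$haploid)
        match_n <- match_n + v[["match"]]
        same_n <- same_n + v[["same"]]
        rev_n <- rev_n + v[["reverse"]]
      }
      if (inf_n == 0) next
      scores <- rbind(scores, data.frame(
        chrom = ch, start = rs$regions$start[k], end = rs$regions$end[k],
        concordance = 100 * match_n / inf_n, n_informative = inf_n,
        same = same_n, reverse = rev_n))
    }
  }
  if (is.null(scores))
    return(structure(list(scaffold = scaffold, size = scaffold_size,
                          chrom = NA, start = NA, end = NA,
                          orientation = NA, concordance = NA,
                          n_informative = 0L, confident = FALSE,
                          ambiguous = FALSE, scores = NULL,
                          gaps = NULL), class = "ScaffoldPlacement"))
  best_c <- max(scores$concordance)
  top <- scores[scores$concordance >= best_c - 1e-9, , drop = FALSE]
  best <- top[which.max(top$n_informative), , drop = FALSE]
  ambiguous <- nrow(top) > 1 && length(unique(top$chrom)) > 1
  confident <- !ambiguous && best$n_informative > min_libraries &&
    best$concordance > min_concordance
  orientation <- if (!confident) NA_character_
  else if (best$same > best$reverse) "same"
  else if (best$reverse > best$same) "reverse"
  else NA_character_
  structure(list(scaffold = scaffold, size = scaffold_size,
                 chrom = best$chrom, start = best$start, end = best$end,
                 orientation = orientation,
                 concordance = best$concordance,
                 n_informative = best$n_informative,
                 confident = confident, ambiguous = ambiguous,
                 candidates = top, scores = scores, gaps = NULL),
            class = "ScaffoldPlacement")
}

#' @export
print.ScaffoldPlacement <- function(x, ...) {
  cat(sprintf("ScaffoldPlacement %s -> %s:%s-%s  %s  conc %.1f%%  n=%d%s%s\n",
              x$scaffold, x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","),
              x$orientation %||% NA, x$concordance, x$n_informative,
              if (isTRUE(x$confident)) "  [confident]" else "",
              if (isTRUE(x$ambiguous)) "  [ambiguous]" else ""))
  invisible(x)
}

#' Read a gap annotation BED (4th column "bridged"/"unbridged")
#'
#' @param path BED file.
#' @return data.frame: `chrom`, `start`, `end`, `type`.
#' @export
read_gap_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "type")
  df
}

#' Cross-reference a scaffold placement against assembly gaps
#'
#' Gaps overlapping the best region qualify as candidate insertion points
#' when they are unbridged (unknown size), or bridged with a length of at
#' least the scaffold's; the primary candidate is the largest qualifying
#' unbridged gap, then the largest qualifying bridged gap, the rest are
#' alternates.  Counts of unbridged (u) and bridged (b) gaps in the region
#' are reported.
#'
#' @param placement a [map_scaffold()] result.
#' @param gaps gap table ([read_gap_bed()]); NULL leaves the placement
#'   unchanged with empty gap fields.
#' @param scaffold_size scaffold length in bp (defaults to
#'   `placement$size`).
#' @return the placement with `$gaps`: `primary`, `alternates` (data.frame),
#'   `n_unbridged`, `n_bridged`.
#' @export
crossref_gaps <- function(placement, gaps = NULL,
                          scaffold_size = placement$size) {
  if (is.null(gaps) || is.na(placement$chrom)) return(placement)
  g <- gaps[gaps$chrom == placement$chrom &
            gaps$end > placement$start & gaps$start < placement$end,
            , drop = FALSE]
  g$length <- g$end - g$start
  qual <- g[g$type == "unbridged" |
            (g$type == "bridged" & g$length >= scaffold_size), , drop = FALSE]
  qual <- qual[order(qual$type != "unbridged", -qual$length), , drop = FALSE]
  placement$gaps <- list(
    primary = if (nrow(qual)) qual[1, , drop = FALSE] else NULL,
    alternates = if (nrow(qual) > 1) qual[-1, , drop = FALSE] else NULL,
    n_unbridged = sum(g$type == "unbridged"),
    n_bridged = sum(g$type == "bridged"))
  placement
}

#' Rewrite a reference: flip misoriented segments, insert placed scaffolds
#'
#' Misoriented intervals are replaced in place by their reverse complement
#' (length preserved; applying the same flip twice restores the original).
#' Each confidently placed scaffold with a primary gap is inserted --
#' reverse-complemented first when its orientation is "reverse" -- into the
#' central portion of the gap, preserving the flanking N runs when the gap
#' exceeds the scaffold; a scaffold longer than an unbridged gap replaces
#' the whole gap (unbridged gaps have unknown true size) with a ledger
#' note.  Edited records are renamed with a version suffix and the placed
#' scaffold records are dropped.  Overlapping edits are an error.
#'
#' @param sequences a [Biostrings::DNAStringSet] holding every touched
#'   chromosome and scaffold.
#' @param misorientations data.frame `chrom`, `start`, `end` (0-based
#'   half-open), or NULL.
#' @param placements list of [crossref_gaps()] results (only confident
#'   placements with a primary gap are applied), or NULL.
#' @param suffix version suffix appended to edited record names.
#' @return list: `sequences` (edited DNAStringSet), `ledger` data.frame of
#'   edits (`record`, `action`, `start`, `end`, `detail`).
#' @export
update_reference <- function(sequences, misorientations = NULL,
                             placements = NULL, suffix = "_v2") {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  edits <- NULL
  if (!is.null(misorientations) && nrow(misorientations))
    edits <- rbind(edits, data.frame(
      chrom = misorientations$chrom, start = misorientations$start,
      end = misorientations$end, action = "flip", scaffold = NA,
      orientation = NA))
  for (p in placements %||% list()) {
    if (!isTRUE(p$confident) || is.null(p$gaps$primary)) next
    gp <- p$gaps$primary
    edits <- rbind(edits, data.frame(
      chrom = gp$chrom, start = gp$start, end = gp$end,
      action = "insert", scaffold = p$scaffold,
      orientation = p$orientation %||% "same"))
  }
  if (is.null(edits))
    return(list(sequences = sequences,
                ledger = data.frame(record = character(),
                                    action = character(), start = numeric(),
                                    end = numeric(), detail = character())))
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop_bad("overlapping edits on %s", ch)
    if (!ch %in% names(sequences))
      stop_bad("no sequence for %s", ch)
  }
  ledger <- NULL
  out <- as.list(sequences)
  touched <- character()
  ## flips are length-preserving; apply them first, then insertions from
  ## the highest coordinate down so earlier gap coordinates stay valid
  edits <- edits[order(edits$action != "flip", -edits$start), , drop = FALSE]
  for (k in seq_len(nrow(edits))) {
    ed <- edits[k, ]
    seq <- out[[ed$chrom]]
    if (ed$action == "flip") {
      piece <- Biostrings::reverseComplement(
        Biostrings::subseq(seq, ed$start + 1L, ed$end))
      out[[ed$chrom]] <- Biostrings::xscat(
        Biostrings::subseq(seq, 1L, ed$start),
        piece,
        Biostrings::subseq(seq, ed$end + 1L, length(seq)))
      ledger <- rbind(ledger, data.frame(
        record = ed$chrom, action = "flip", start = ed$start, end = ed$end,
        detail = "reverse complemented in place"))
    } else {
      if (!ed$scaffold %in% names(out))
        stop_bad("no sequence for scaffold %s", ed$scaffold)
      sc <- out[[ed$scaffold]]
      if (identical(ed$orientation, "reverse"))
        sc <- Biostrings::reverseComplement(sc)
      gap_len <- ed$end - ed$start
      sc_len <- length(sc)
      if (gap_len >= sc_len) {
        left_n <- floor((gap_len - sc_len) / 2)
        right_n <- gap_len - sc_len - left_n
        piece <- Biostrings::xscat(strrep("N", left_n), sc,
                                   strrep("N", right_n))
        detail <- sprintf("inserted into gap centre, %d+%d flanking Ns kept",
                          left_n, right_n)
      } else {
        piece <- sc
        detail <- "scaffold longer than gap; whole gap replaced (unbridged gaps have unknown length)"
      }
      out[[ed$chrom]] <- Biostrings::xscat(
        Biostrings::subseq(seq, 1L, ed$start),
        piece,
        Biostrings::subseq(seq, ed$end + 1L, length(seq)))
      out[[ed$scaffold]] <- NULL
      ledger <- rbind(ledger, data.frame(
        record = ed$chrom, action = "insert", start = ed$start,
        end = ed$end, detail = sprintf("%s (%s): %s", ed$scaffold,
                                       ed$orientation, detail)))
    }
    touched <- union(touched, ed$chrom)
  }
  res <- Biostrings::DNAStringSet(lapply(out, function(s)
    if (methods::is(s, "DNAString")) s else Biostrings::DNAString(s)))
  names(res)[names(res) %in% touched] <-
    paste0(names(res)[names(res) %in% touched], suffix)
  list(sequences = res, ledger = ledger %||% data.frame())
}
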