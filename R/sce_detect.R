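level_to_state <- function(level, copy_number = 2L) {
  if (is.na(level)) return("unknown")
  if (copy_number == 1L) {
    if (level > 0) "W" else if (level < 0) "C" else "unknown"
  } else c("CC", "WC", "WW")[level + 2L]
}

chrom_reads <- function(reads, chrom) {
  r <- reads$reads
  r[r$chrom == chrom, c("start", "strand"), drop = FALSE]
}

## Bin a position/strand data.frame over [lo, hi) at `bin_size` and return a
## ratio track in the format segment_track() expects.
rebin_window <- function(r, lo, hi, bin_size) {
  nb <- max(1L, as.integer(ceiling((hi - lo) / bin_size)))
  sel <- r$start >= lo & r$start < hi
  b <- floor((r$start[sel] - lo) / bin_size) + 1L
  W <- tabulate(b[r$strand[sel] == "W"], nbins = nb)
  C <- tabulate(b[r$strand[sel] == "C"], nbins = nb)
  tot <- W + C
  start <- lo + (seq_len(nb) - 1) * bin_size
  data.frame(bin = seq_len(nb) - 1L, start = start,
             end = pmin(start + bin_size, hi), W = W, C = C,
             ratio = ifelse(tot > 0, (W - C) / tot, NA_real_),
             level = ifelse(tot > 0, round_half_away(
               ifelse(tot > 0, (W - C) / tot, 0)), NA_integer_),
             masked = tot == 0)
}

#' Iteratively refine a changepoint interval by re-binning and re-segmenting
#'
#' Starting from a gross two-bin interval, each iteration (i) pads the
#' current interval by half its length on each side (clipped to the
#' chromosome) to catch events at bin boundaries, (ii) re-bins the reads of
#' the padded window at one fifth of the current interval width on the
#' first iteration (80 kb for the default 400 kb gross interval) and one
#' fifth of the previous bin size thereafter, (iii) re-segments, and (iv)
#' keeps the new two-bin changepoint interval.  Refinement stops when fewer
#' than `min_reads` reads remain inside the current interval or when
#' re-segmentation does not find exactly one changepoint.
#'
#' @param interval numeric `c(lo, hi)` in bp (0-based half-open).
#' @param reads data.frame of the chromosome's reads (`start`, `strand`),
#'   sorted by position, or a [read_set()] plus `chrom`.
#' @param chrom_length chromosome length for clipping.
#' @param chrom chromosome name (when `reads` is a ReadSet).
#' @param min_reads stop threshold (default 50 reads).
#' @param subdivision number of new bins per interval width (default 5).
#' @param alpha,nperm,seed CBS parameters.
#' @return list: `interval` (last accepted), `refined` (FALSE when no
#'   iteration was accepted), `trace` data.frame of per-iteration
#'   `bin_size`, `start`, `end`, `n_reads`.
#' @export
refine_interval <- function(interval, reads, chrom_length, chrom = NULL,
                            min_reads = 50L, subdivision = 5L,
                            alpha = 0.01, nperm = 1000L, seed = 42L) {
  if (inherits(reads, "ReadSet")) reads <- chrom_reads(reads, chrom)
  cur <- as.numeric(interval)
  trace <- data.frame(iteration = integer(), bin_size = numeric(),
                      start = numeric(), end = numeric(),
                      n_reads = integer())
  bsz <- (cur[2] - cur[1]) / subdivision
  iter <- 0L
  repeat {
    n_in <- sum(reads$start >= cur[1] & reads$start < cur[2])
    if (n_in < min_reads) break
    plo <- max(0, cur[1] - (cur[2] - cur[1]) / 2)
    phi <- min(chrom_length, cur[2] + (cur[2] - cur[1]) / 2)
    track <- rebin_window(reads, plo, phi, bsz)
    seg <- segment_track(track, alpha, nperm, seed + iter)
    if (nrow(seg$changepoints) != 1L) break
    iter <- iter + 1L
    cp <- seg$changepoints
    cur <- c(cp$start[1], cp$end[1])
    trace <- rbind(trace, data.frame(iteration = iter, bin_size = bsz,
                                     start = cur[1], end = cur[2],
                                     n_reads = n_in))
    bsz <- bsz / subdivision
  }
  list(interval = cur, refined = iter > 0L, trace = trace)
}

#' Read-level walker refinement of a template-strand transition
#'
#' Scans reads from the homozygous side of a transition and reports the
#' first read on the opposite template, accepting it only if the 10
#' preceding reads (in scan order) all carry the homozygous template strand
#' and at least 4 of the 20 following reads -- the candidate itself counted
#' among them -- carry the opposite strand (at least 20% in the other
#' direction); rejected candidates are skipped and the scan continues.
#' When fewer than 20 reads remain past a candidate the check runs on the
#' reads available with the same count threshold.  The returned interval is
#' the span between the start positions of the last homozygous-template
#' read and the accepted opposite-template read.
#'
#' @param interval gross/refined interval `c(lo, hi)` in bp; candidates are
#'   restricted to this interval padded by half its length per side, while
#'   the preceding/following checks may use reads beyond it.
#' @param reads chromosome read data.frame (`start`, `strand`) sorted by
#'   position, or a [read_set()] plus `chrom`.
#' @param homozygous_side `"left"` or `"right"`: which flank holds the
#'   homozygous state.
#' @param homozygous_strand the template strand of the homozygous flank
#'   ("W" or "C").
#' @param chrom chromosome name when `reads` is a ReadSet.
#' @param n_before,n_following,min_opposite walker rule parameters
#'   (defaults 10, 20, 4).
#' @return list: `interval` `c(lo, hi)`, `refined` (FALSE when no candidate
#'   passed before reads were exhausted).
#' @export
walker_refine <- function(interval, reads, homozygous_side,
                          homozygous_strand, chrom = NULL,
                          n_before = 10L, n_following = 20L,
                          min_opposite = 4L) {
  if (inherits(reads, "ReadSet")) reads <- chrom_reads(reads, chrom)
  lo <- interval[1]; hi <- interval[2]
  pad <- (hi - lo) / 2
  wlo <- lo - pad; whi <- hi + pad
  o <- order(reads$start)
  ps <- reads$start[o]; ss <- reads$strand[o]
  if (homozygous_side == "right") { ps <- rev(ps); ss <- rev(ss) }
  opp <- flip_strand(homozygous_strand)
  in_window <- if (homozygous_side == "right") ps >= wlo & ps < whi
               else ps >= wlo & ps < whi
  n <- length(ps)
  for (t in which(ss == opp & in_window)) {
    if (t <= n_before) next
    if (!all(ss[(t - n_before):(t - 1L)] == homozygous_strand)) next
    fw <- ss[t:min(n, t + n_following - 1L)]
    if (sum(fw == opp) < min_opposite) next
    bounds <- sort(as.numeric(c(ps[t - 1L], ps[t])))
    return(list(interval = bounds, refined = TRUE))
  }
  list(interval = as.numeric(interval), refined = FALSE)
}

#' Detect and localize template-strand transitions in one library
#'
#' Per chromosome: mask deviant bins, compute the (W-C)/(W+C) ratio track,
#' segment by CBS, then refine every changepoint first by iterative
#' re-binning ([refine_interval()]) and then at read level
#' ([walker_refine()]).  Events are classified by their flanking states and
#' the chromosome's copy number: homozygous-to-heterozygous transitions are
#' SCEs, WW-to-CC (or the reverse) transitions are misorientation
#' candidates, and any switch on a monosomic chromosome is a haploid
#' switch.  A failure on one chromosome is reported as a warning and does
#' not abort the library.
#'
#' @param reads a [read_set()].
#' @param counts optional pre-computed [bin_reads()]; recomputed otherwise.
#' @param bin_size bin width (default 200 kb).
#' @param sd_threshold bin-filter threshold (default 0.2; see
#'   [filter_bins()]).
#' @param ploidy optional [call_ploidy()] result; computed otherwise.
#' @param min_reads_refine refinement stop threshold (default 50).
#' @param alpha,nperm,seed CBS parameters.
#' @return data.frame of events (`library`, `chrom`, `start`, `end`,
#'   `left_state`, `right_state`, `class`, `terminal`, `gross_start`,
#'   `gross_end`, `refined_start`, `refined_end`, `walker_ok`,
#'   `refine_iterations`) with the per-event refinement traces attached as
#'   attribute `"traces"`.
#' @export
detect_events <- function(reads, counts = NULL, bin_size = 200000L,
                          sd_threshold = 0.2, ploidy = NULL,
                          min_reads_refine = 50L, alpha = 0.01,
                          nperm = 1000L, seed = 42L) {
  stopifnot(inherits(reads, "ReadSet"))
  counts <- counts %||% bin_reads(reads, bin_size)
  mask <- filter_bins(counts, sd_threshold)
  ploidy <- ploidy %||% call_ploidy(counts)
  events <- NULL
  traces <- list()
  for (ci in seq_along(counts$W)) {
    ch <- names(counts$W)[ci]
    res <- tryCatch(
      detect_chrom_events(reads, counts, ch, mask[[ch]], ploidy,
                          min_reads_refine, alpha, nperm,
                          seed + 1000L * ci),
      error = function(e) {
        warning(sprintf("chromosome %s skipped: %s", ch,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) {
      events <- rbind(events, res$events)
      traces <- c(traces, res$traces)
    }
  }
  events <- events %||% data.frame(
    library = character(), chrom = character(), start = numeric(),
    end = numeric(), left_state = character(), right_state = character(),
    class = character(), terminal = logical(), gross_start = numeric(),
    gross_end = numeric(), refined_start = numeric(),
    refined_end = numeric(), walker_ok = logical(),
    refine_iterations = integer())
  rownames(events) <- NULL
  attr(events, "traces") <- traces
  events
}

detect_chrom_events <- function(reads, counts, chrom, mask, ploidy,
                                min_reads_refine, alpha, nperm, seed) {
  len <- counts$chrom_lengths[[chrom]]
  cn <- ploidy$copy_number[match(chrom, ploidy$chrom)]
  if (is.na(cn)) cn <- 2L
  track <- compute_ratio_track(counts, chrom, mask)
  if (sum(!track$masked) < 2L) return(NULL)  # nothing detectable
  seg <- segment_track(track, alpha, nperm, seed)
  cps <- seg$changepoints
  if (!nrow(cps)) return(NULL)
  r <- chrom_reads(reads, chrom)
  rows <- NULL
  traces <- list()
  for (k in seq_len(nrow(cps))) {
    gross <- c(cps$start[k], cps$end[k])
    left_state <- level_to_state(cps$left_level[k], cn)
    right_state <- level_to_state(cps$right_level[k], cn)
    width <- gross[2] - gross[1]
    terminal <- (gross[1] - width / 2) <= 0 || (gross[2] + width / 2) >= len
    ref <- refine_interval(gross, r, len, min_reads = min_reads_refine,
                           alpha = alpha, nperm = nperm, seed = seed + k)
    side <- if (is_homozygous_state(left_state)) "left"
            else if (is_homozygous_state(right_state)) "right"
            else "left"
    hom_state <- if (side == "left") left_state else right_state
    hom_strand <- if (hom_state %in% c("WW", "W")) "W" else "C"
    wk <- walker_refine(ref$interval, r, side, hom_strand)
    cls <- if (cn == 1L) "haploid-switch"
           else if (all(c(left_state, right_state) %in% c("WW", "CC")))
             "misorientation-candidate"
           else "SCE"
    rows <- rbind(rows, data.frame(
      library = reads$library, chrom = chrom,
      start = wk$interval[1], end = wk$interval[2],
      left_state = left_state, right_state = right_state, class = cls,
      terminal = terminal, gross_start = gross[1], gross_end = gross[2],
      refined_start = ref$interval[1], refined_end = ref$interval[2],
      walker_ok = wk$refined, refine_iterations = nrow(ref$trace)))
    traces[[sprintf("%s_%s_%d", reads$library, chrom, k)]] <- ref$trace
  }
  list(events = rows, traces = traces)
}
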