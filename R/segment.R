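#' Recursive circular binary segmentation of a numeric track
#'
#' Finds changepoints by recursively applying the CBS arc scan with a
#' permutation test (strict exceedances; fixed internal RNG so results do
#' not depend on R's RNG state).
#'
#' @param x numeric vector (no NAs).
#' @param alpha permutation significance level (default 0.01).
#' @param nperm number of permutations (default 1000).
#' @param seed integer seed for the permutation RNG.
#' @return sorted integer vector of changepoints; value k means a boundary
#'   between elements k and k+1.
#' @export
cbs_segment <- function(x, alpha = 0.01, nperm = 1000L, seed = 42L) {
  recurse <- function(lo, hi, sd) {
    n <- hi - lo + 1L
    if (n < 2L) return(integer())
    res <- cbs_scan(x[lo:hi], nperm, alpha, sd)
    if (!isTRUE(res$significant)) return(integer())
    bps <- integer()
    if (res$i > 0L) bps <- c(bps, res$i)
    if (res$j < n) bps <- c(bps, res$j)
    if (!length(bps)) return(integer())
    bps <- sort(unique(bps))
    gl <- lo - 1L + bps
    edges <- c(lo - 1L, gl, hi)
    sub <- unlist(lapply(seq_len(length(edges) - 1L), function(k)
      recurse(edges[k] + 1L, edges[k + 1L], sd + k)))
    sort(unique(c(gl, sub)))
  }
  recurse(1L, length(x), as.integer(seed))
}

#' Per-bin template-strand ratio track
#'
#' Raw ratio r = (W - C)/(W + C) per bin, plus the rounded level in
#' \{-1, 0, 1\} (ties away from zero): 1 when all reads map to Watson (WW),
#' -1 when all map to Crick (CC), 0 for an equal number of both (WC).
#' Empty bins are masked (ratio undefined); an additional exclusion mask
#' (from [filter_bins()]) can be supplied.
#'
#' @param counts a [bin_reads()] object.
#' @param chrom chromosome name.
#' @param mask optional logical vector (TRUE = excluded) per bin.
#' @return data.frame: `bin` (0-based), `start`, `end`, `W`, `C`, `ratio`,
#'   `level`, `masked`.
#' @export
compute_ratio_track <- function(counts, chrom, mask = NULL) {
  W <- counts$W[[chrom]]
  C <- counts$C[[chrom]]
  if (is.null(W)) stop_bad("no counts for chromosome %s", chrom)
  tot <- W + C
  ratio <- ifelse(tot > 0, (W - C) / tot, NA_real_)
  level <- ifelse(tot > 0, round_half_away(ratio), NA_integer_)
  masked <- tot == 0
  if (!is.null(mask)) masked <- masked | mask
  bb <- bin_bounds(counts, chrom)
  data.frame(bin = seq_along(W) - 1L, start = bb$start, end = bb$end,
             W = W, C = C, ratio = ratio, level = level, masked = masked)
}

#' Mask bins with unexpected read depth
#'
#' Bins whose total read count deviates from the per-bin mean by more than
#' `sd_threshold` standard deviations are excluded before segmentation
#' (collapsed repeats, dropped regions).  Mean and SD are computed per
#' chromosome, so a monosomic (e.g. male X) chromosome -- whose depth is
#' half the library average by construction -- is compared against its own
#' baseline rather than masked wholesale.  The comparison is strict, so a
#' zero-variance chromosome masks nothing.  `sd_threshold = Inf` disables
#' masking.
#'
#' @param counts a [bin_reads()] object.
#' @param sd_threshold SD multiplier (default 0.2).
#' @return named list of logical mask vectors (TRUE = excluded) per
#'   chromosome.
#' @export
filter_bins <- function(counts, sd_threshold = 0.2) {
  tot <- lapply(names(counts$W), function(ch)
    counts$W[[ch]] + counts$C[[ch]])
  names(tot) <- names(counts$W)
  lapply(tot, function(v) {
    if (length(v) < 2 || !is.finite(sd_threshold))
      return(rep(FALSE, length(v)))
    abs(v - mean(v)) > sd_threshold * stats::sd(v)
  })
}

#' Segment a ratio track into integer template levels
#'
#' Runs CBS on the raw ratios of the unmasked bins, rounds each resulting
#' segment mean to the nearest of \{-1, 0, 1\} and merges neighbouring
#' segments with equal level, so the track receives only the three template
#' calls (WW / WC / CC).  Each changepoint is reported as the two-bin
#' interval spanning the last bin of one segment and the first bin of the
#' next, in true chromosome coordinates (masked bins in between are
#' spanned).
#'
#' @param track a [compute_ratio_track()] data.frame.
#' @param alpha,nperm,seed CBS permutation parameters.
#' @return list: `segments` data.frame (`start`, `end` in bp over unmasked
#'   bins, `first_bin`, `last_bin`, `mean`, `level`, `n_bins`) and
#'   `changepoints` data.frame (`start`, `end`, `left_level`,
#'   `right_level`, `left_bin`, `right_bin`).
#' @export
segment_track <- function(track, alpha = 0.01, nperm = 1000L, seed = 42L) {
  use <- which(!track$masked)
  empty <- list(
    segments = data.frame(start = numeric(), end = numeric(),
                          first_bin = integer(), last_bin = integer(),
                          mean = numeric(), level = integer(),
                          n_bins = integer()),
    changepoints = data.frame(start = numeric(), end = numeric(),
                              left_level = integer(),
                              right_level = integer(),
                              left_bin = integer(), right_bin = integer()))
  if (length(use) < 2L) {
    if (!length(use)) warning("all bins masked; no segments")
    return(empty)
  }
  x <- track$ratio[use]
  bps <- cbs_segment(x, alpha, nperm, seed)
  edges <- c(0L, bps, length(x))
  seg <- data.frame(from = edges[-length(edges)] + 1L, to = edges[-1])
  seg$mean <- vapply(seq_len(nrow(seg)), function(k)
    mean(x[seg$from[k]:seg$to[k]]), numeric(1))
  seg$level <- pmax(-1L, pmin(1L, round_half_away(seg$mean)))
  ## merge neighbouring segments that round to the same template level
  keep <- c(TRUE, seg$level[-1] != seg$level[-nrow(seg)])
  grp <- cumsum(keep)
  seg <- do.call(rbind, lapply(split(seg, grp), function(s) {
    w <- s$to - s$from + 1L
    data.frame(from = s$from[1], to = s$to[nrow(s)],
               mean = sum(s$mean * w) / sum(w), level = s$level[1])
  }))
  seg$first_bin <- track$bin[use[seg$from]]
  seg$last_bin <- track$bin[use[seg$to]]
  seg$n_bins <- seg$to - seg$from + 1L
  seg$start <- track$start[use[seg$from]]
  seg$end <- track$end[use[seg$to]]
  segments <- seg[, c("start", "end", "first_bin", "last_bin",
                      "mean", "level", "n_bins")]
  rownames(segments) <- NULL
  if (nrow(seg) < 2L) return(list(segments = segments,
                                  changepoints = empty$changepoints))
  k <- seq_len(nrow(seg) - 1L)
  changepoints <- data.frame(
    start = track$start[use[seg$to[k]]],
    end = track$end[use[seg$from[k + 1L]]],
    left_level = seg$level[k], right_level = seg$level[k + 1L],
    left_bin = seg$last_bin[k], right_bin = seg$first_bin[k + 1L])
  list(segments = segments, changepoints = changepoints)
}
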