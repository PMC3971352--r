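#' Call the template-strand state of one chromosome
#'
#' The chromosome-wide ratio (W - C)/(W + C) is rounded to the nearest of
#' -1, 0, 1 (ties away from zero), giving CC, WC or WW for a diploid
#' chromosome.  Monosomic chromosomes are called W or C by majority strand.
#' Chromosomes with fewer than `min_reads` reads are "unknown".
#'
#' @param counts a [bin_reads()] object.
#' @param chrom chromosome name.
#' @param copy_number integer copy number (from [call_ploidy()]; 2 assumed).
#' @param min_reads informativeness minimum (default 20 reads).
#' @return one-row data.frame: `chrom`, `state`, `W`, `C`, `informative`.
#' @export
call_chromosome_state <- function(counts, chrom, copy_number = 2L,
                                  min_reads = 20L) {
  stopifnot(inherits(counts, "BinnedCounts"))
  W <- sum(counts$W[[chrom]])
  C <- sum(counts$C[[chrom]])
  state <- if (W + C < min_reads) "unknown"
  else if (copy_number == 1L) {
    if (W >= C) "W" else "C"
  } else {
    lv <- round_half_away((W - C) / (W + C))
    c("CC", "WC", "WW")[lv + 2L]
  }
  data.frame(chrom = chrom, state = state, W = W, C = C,
             informative = state != "unknown")
}

#' Call template states for every chromosome of a library
#'
#' @param counts a [bin_reads()] object.
#' @param ploidy optional result of [call_ploidy()]; monosomic chromosomes
#'   are then called W/C.
#' @param min_reads informativeness minimum per chromosome.
#' @return data.frame of per-chromosome state calls (one row per
#'   chromosome) with the library identifier attached.
#' @export
call_library_states <- function(counts, ploidy = NULL, min_reads = 20L) {
  cn <- function(ch) {
    if (is.null(ploidy)) return(2L)
    i <- match(ch, ploidy$chrom)
    if (is.na(i)) 2L else ploidy$copy_number[i]
  }
  out <- do.call(rbind, lapply(names(counts$W), function(ch)
    call_chromosome_state(counts, ch, cn(ch), min_reads)))
  out$library <- counts$library %||% "lib"
  out
}

#' Library background metric
#'
#' Percentage of spurious non-template-strand reads, pooled over the
#' homozygously inherited chromosomes: Crick reads on WW (or W) chromosomes
#' and Watson reads on CC (or C) chromosomes, divided by all reads on those
#' chromosomes.  Undefined (NA, `defined = FALSE`) when a library has no
#' homozygous chromosome; such libraries are reported, not dropped.
#'
#' @param calls per-chromosome state calls from [call_library_states()].
#' @return list: `library`, `background` (percent, NA if undefined),
#'   `n_homozygous`, `defined`.
#' @export
background_metric <- function(calls) {
  hom <- calls[is_homozygous_state(calls$state), , drop = FALSE]
  if (!nrow(hom))
    return(list(library = calls$library[1] %||% "lib", background = NA_real_,
                n_homozygous = 0L, defined = FALSE))
  opp <- ifelse(hom$state %in% c("WW", "W"), hom$C, hom$W)
  tot <- hom$W + hom$C
  list(library = hom$library[1] %||% "lib",
       background = 100 * sum(opp) / sum(tot),
       n_homozygous = nrow(hom), defined = TRUE)
}

#' Call per-chromosome copy number from relative read depth
#'
#' Relative depth d = chromosome mean per-bin depth / library mean per-bin
#' depth; copy number n = round(2 d), halves rounding away from zero.  A
#' relative depth of 0.5 is a monosome (n = 1), 1.5 a triploid chromosome
#' (n = 3), 1.0 the diploid baseline.
#'
#' @param counts a [bin_reads()] object.
#' @return data.frame: `chrom`, `depth` (relative), `copy_number`.
#' @export
call_ploidy <- function(counts) {
  stopifnot(inherits(counts, "BinnedCounts"))
  tot <- vapply(names(counts$W), function(ch)
    sum(counts$W[[ch]]) + sum(counts$C[[ch]]), numeric(1))
  nb <- vapply(names(counts$W), function(ch)
    length(counts$W[[ch]]), numeric(1))
  if (sum(tot) == 0) stop_bad("zero library depth; cannot call ploidy")
  if (length(tot) < 2)
    warning("library average from a single chromosome; ploidy calls weak")
  lib_mean <- sum(tot) / sum(nb)
  d <- (tot / nb) / lib_mean
  data.frame(chrom = names(counts$W), depth = unname(d),
             copy_number = round_half_away(2 * unname(d)))
}

#' Segregation summary across libraries
#'
#' Per chromosome, tallies WW/WC/CC calls across libraries and tests them
#' against the expected segregation ratio (default 1:2:1, the null under
#' independent random segregation of the two homologues) with a chi-squared
#' goodness-of-fit test; p-values are Holm-adjusted across chromosomes.
#' Chromosomes with no informative diploid call in any library are excluded
#' and listed.
#'
#' @param calls_list list of per-library call data.frames
#'   ([call_library_states()]).
#' @param expected expected WW:WC:CC ratio (default `c(1, 2, 1)`).
#' @return list: `summary` data.frame (`chrom`, `nWW`, `nWC`, `nCC`,
#'   frequencies, `p`, `p_adj`), `excluded` character vector.
#' @export
segregation_summary <- function(calls_list, expected = c(1, 2, 1)) {
  if (length(calls_list) < 2)
    stop_bad("segregation summary needs >= 2 libraries")
  all <- do.call(rbind, calls_list)
  chroms <- unique(all$chrom)
  rows <- lapply(chroms, function(ch) {
    st <- all$state[all$chrom == ch]
    n <- c(nWW = sum(st == "WW"), nWC = sum(st == "WC"),
           nCC = sum(st == "CC"))
    if (sum(n) == 0) return(NULL)
    p <- suppressWarnings(
      stats::chisq.test(n, p = expected / sum(expected))$p.value)
    data.frame(chrom = ch, nWW = n[["nWW"]], nWC = n[["nWC"]],
               nCC = n[["nCC"]],
               fWW = n[["nWW"]] / sum(n), fWC = n[["nWC"]] / sum(n),
               fCC = n[["nCC"]] / sum(n), p = p)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (!is.null(out)) out$p_adj <- stats::p.adjust(out$p, method = "holm")
  list(summary = out, excluded = chroms[!keep])
}
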