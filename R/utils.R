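#' @useDynLib strandtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to the nearest integer, halves away from zero
#'
#' Tie-break used everywhere a continuous ratio or relative depth is snapped
#' to an integer level (e.g. a ratio of exactly 0.5 becomes 1, -0.5 becomes
#' -1), so that the mapping is symmetric under swapping Watson and Crick.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

flip_strand <- function(s) c(W = "C", C = "W")[s]

is_homozygous_state <- function(state) state %in% c("WW", "CC", "W", "C")

mirror_state <- function(state) {
  map <- c(WW = "CC", CC = "WW", WC = "WC", W = "C", C = "W",
           unknown = "unknown")
  unname(map[state])
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a ReadSet
#'
#' A ReadSet holds the strand-labelled aligned reads of one Strand-seq
#' library together with the chromosome-length table of the reference the
#' reads were aligned to.  Reads are stored sorted by (chromosome, start).
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based bp),
#'   `strand` ("W" or "C"), `mapq` (integer), `duplicate` (logical).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param library library identifier string.
#' @return object of class `ReadSet`.
#' @export
read_set <- function(reads, chrom_lengths, library = "lib") {
  stopifnot(is.data.frame(reads))
  need <- c("chrom", "start", "strand")
  if (!all(need %in% names(reads)))
    stop_bad("reads must have columns %s", paste(need, collapse = ", "))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_bad("chrom_lengths must be a named vector")
  if (!"mapq" %in% names(reads)) reads$mapq <- rep(60L, nrow(reads))
  if (!"duplicate" %in% names(reads)) reads$duplicate <- rep(FALSE, nrow(reads))
  bad <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(bad))
    stop_bad("read on unknown chromosome: %s", paste(bad, collapse = ", "))
  if (any(!reads$strand %in% c("W", "C")))
    stop_bad("strand must be 'W' or 'C'")
  if (any(reads$start < 0))
    stop_bad("negative read start position")
  over <- reads$start >= chrom_lengths[reads$chrom]
  if (any(over))
    stop_bad("read beyond chromosome end on %s at %d",
             reads$chrom[which(over)[1]], reads$start[which(over)[1]])
  o <- order(match(reads$chrom, names(chrom_lengths)), reads$start)
  reads <- reads[o, , drop = FALSE]
  rownames(reads) <- NULL
  structure(list(library = library, reads = reads,
                 chrom_lengths = chrom_lengths),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %d reads on %d sequences\n",
              x$library, nrow(x$reads), length(x$chrom_lengths)))
  invisible(x)
}

#' @export
print.BinnedCounts <- function(x, ...) {
  cat(sprintf("BinnedCounts: bin %d bp, %d sequences, %d reads\n",
              x$bin_size, length(x$W), sum(unlist(x$W)) + sum(unlist(x$C))))
  invisible(x)
}

n_bins_for <- function(len, bin_size) as.integer(ceiling(len / bin_size))
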