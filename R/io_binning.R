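#' Load aligned reads from BAM or strand-annotated BED
#'
#' Plus-strand alignments are labelled Crick ("C"), minus-strand alignments
#' Watson ("W").  Duplicate-flagged reads, secondary alignments and reads
#' below the mapping-quality threshold are removed.  Coordinates are 0-based
#' half-open throughout.
#'
#' @param path BAM file (chromosome lengths taken from the header) or
#'   six-column strand BED (`chrom start end name score strand`; score is
#'   treated as mapping quality; `chrom_lengths` required).
#' @param min_quality minimum mapping quality to retain (default 10).
#' @param drop_duplicates drop duplicate-flagged reads (default TRUE; BED
#'   records carry no duplicate flag).
#' @param chrom_lengths named vector of chromosome lengths; required for BED
#'   input, overrides the header if given for BAM.
#' @param library library identifier (default: file base name).
#' @param keep_secondary keep secondary alignments (default FALSE).
#' @return a [read_set()], sorted by (chromosome, position).
#' @export
load_reads <- function(path, min_quality = 10L, drop_duplicates = TRUE,
                       chrom_lengths = NULL, library = NULL,
                       keep_secondary = FALSE) {
  if (!file.exists(path)) stop_bad("cannot read %s", path)
  library <- library %||% sub("\\.(bam|bed)$", "", basename(path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    chrom_lengths <- chrom_lengths %||% hdr
    b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "mapq", "flag")))[[1]]
    keep <- !is.na(b$pos)
    flag <- b$flag[keep]
    df <- data.frame(chrom = as.character(b$rname[keep]),
                     start = b$pos[keep] - 1L,
                     strand = ifelse(as.character(b$strand[keep]) == "-",
                                     "W", "C"),
                     mapq = ifelse(is.na(b$mapq[keep]), 0L, b$mapq[keep]),
                     duplicate = bitwAnd(flag, 1024L) > 0L)
    if (!keep_secondary) {
      pri <- bitwAnd(flag, 256L) == 0L
      df <- df[pri, , drop = FALSE]
    }
  } else {
    if (is.null(chrom_lengths))
      stop_bad("chrom_lengths required for BED input")
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#",
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "numeric", "numeric",
                                           "character", "numeric", "character"))
    df <- df[!grepl("^track", df$chrom), , drop = FALSE]
    df <- data.frame(chrom = df$chrom, start = df$start,
                     strand = ifelse(df$strand %in% c("-", "W"), "W", "C"),
                     mapq = as.integer(df$score), duplicate = FALSE)
  }
  bad <- setdiff(unique(df$chrom), names(chrom_lengths))
  if (length(bad))
    stop_bad("record on chromosome absent from length table: %s",
             paste(bad, collapse = ", "))
  if (drop_duplicates) df <- df[!df$duplicate, , drop = FALSE]
  df <- df[df$mapq >= min_quality, , drop = FALSE]
  if (!nrow(df))
    warning(sprintf("library '%s': no reads pass filters", library))
  read_set(df, chrom_lengths, library = library)
}

#' Read a two-column chromosome-length table (TSV: name, length)
#'
#' @param path TSV file.
#' @return named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}

#' Bin directional reads into fixed-size windows
#'
#' A read starting at position p contributes to bin `floor(p / bin_size)`;
#' the trailing partial bin is kept, so each chromosome has
#' `ceiling(length / bin_size)` bins.
#'
#' @param reads a [read_set()].
#' @param bin_size bin width in bp (default 200 kb).
#' @return object of class `BinnedCounts`: per chromosome, integer vectors
#'   `W` and `C` of per-bin Watson and Crick read counts.
#' @export
bin_reads <- function(reads, bin_size = 200000L) {
  stopifnot(inherits(reads, "ReadSet"), bin_size >= 1)
  lens <- reads$chrom_lengths
  r <- reads$reads
  count_one <- function(ch, strand) {
    nb <- n_bins_for(lens[[ch]], bin_size)
    sel <- r$chrom == ch & r$strand == strand
    if (!any(sel)) return(integer(nb))
    as.integer(tabulate(floor(r$start[sel] / bin_size) + 1L, nbins = nb))
  }
  chroms <- names(lens)
  structure(list(bin_size = as.integer(bin_size), chrom_lengths = lens,
                 library = reads$library,
                 W = lapply(stats::setNames(nm = chroms), count_one,
                            strand = "W"),
                 C = lapply(stats::setNames(nm = chroms), count_one,
                            strand = "C")),
            class = "BinnedCounts")
}

bin_bounds <- function(counts, chrom) {
  nb <- length(counts$W[[chrom]])
  start <- (seq_len(nb) - 1) * counts$bin_size
  end <- pmin(start + counts$bin_size, counts$chrom_lengths[[chrom]])
  data.frame(start = start, end = end)
}
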