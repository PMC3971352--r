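#' Strand-seq simulation configuration
#'
#' Describes a set of single-cell Strand-seq libraries with known truth.
#' Each diploid chromosome inherits templates WW, WC or CC with probability
#' 1/4, 1/2, 1/4 (independent segregation of the two homologues); haploid
#' chromosomes inherit W or C with probability 1/2.  Reads are single-end
#' point intervals of fixed length placed uniformly at random along the
#' genome (read count per chromosome proportional to length times copy
#' number), each read labelled with the template strand of the homologue it
#' came from.  A configurable fraction of reads ("background") is reassigned
#' to the opposite strand, emulating incomplete removal of the
#' BrdU-substituted nascent strand.  Sister chromatid exchanges are planted
#' on one homologue, flipping its template downstream of the breakpoint;
#' misoriented reference segments invert the strand label (and mirror the
#' position) of every read falling inside them in every library; orphan
#' scaffold extractions relabel reads from a source interval onto a separate
#' contig, optionally in reverse orientation.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_libraries number of libraries to simulate.
#' @param mean_reads expected read count per library (Poisson).
#' @param background fraction in \[0,1\] of reads flipped to the non-template
#'   strand.
#' @param sce_rate expected number of SCEs per chromosome per library
#'   (Poisson, uniform positions); ignored for chromosomes given explicit
#'   positions.
#' @param sce_positions optional list of length `n_libraries`; element i is a
#'   data.frame with columns `chrom`, `pos` giving explicit SCE positions for
#'   library i.
#' @param haploid character vector of haploid (e.g. sex) chromosome names.
#' @param misoriented optional data.frame `chrom`, `start`, `end` of
#'   misoriented reference segments.
#' @param scaffolds optional data.frame `chrom`, `start`, `end`, `name`,
#'   `orientation` ("same"/"reverse") of orphan-scaffold extractions.
#' @param ploidy optional named integer vector of per-chromosome copy-number
#'   overrides.
#' @param read_length read length in bp (fixed).
#' @param seed integer random seed; a fixed seed makes all outputs
#'   byte-identical.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(chrom_lengths, n_libraries = 1L, mean_reads = 10000,
                       background = 0, sce_rate = 0, sce_positions = NULL,
                       haploid = character(), misoriented = NULL,
                       scaffolds = NULL, ploidy = NULL, read_length = 50L,
                       seed = 1L) {
  if (is.null(names(chrom_lengths)))
    stop_bad("chrom_lengths must be named")
  if (background < 0 || background > 1)
    stop_bad("background rate must be in [0,1]")
  if (!is.null(sce_positions)) {
    if (length(sce_positions) != n_libraries)
      stop_bad("sce_positions must have one element per library")
    for (df in sce_positions) {
      if (is.null(df)) next
      bad <- df$pos <= 0 | df$pos >= chrom_lengths[df$chrom]
      if (any(is.na(bad)) || any(bad))
        stop_bad("SCE positions must lie strictly inside their chromosome")
    }
  }
  segs <- rbind(
    if (!is.null(misoriented)) misoriented[, c("chrom", "start", "end")],
    if (!is.null(scaffolds))   scaffolds[, c("chrom", "start", "end")])
  if (!is.null(segs) && nrow(segs) > 1) {
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop_bad("misoriented segments / scaffold extractions overlap on %s", ch)
    }
  }
  if (!is.null(haploid) && length(haploid)) {
    ploidy <- ploidy %||% integer()
    ploidy[setdiff(haploid, names(ploidy))] <- 1L
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_libraries = as.integer(n_libraries),
                 mean_reads = mean_reads, background = background,
                 sce_rate = sce_rate, sce_positions = sce_positions,
                 haploid = haploid, misoriented = misoriented,
                 scaffolds = scaffolds, ploidy = ploidy,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

copy_number_of <- function(config, chrom) {
  p <- config$ploidy
  if (!is.null(p) && chrom %in% names(p)) as.integer(p[[chrom]]) else 2L
}

library_seed <- function(config, library_index) {
  as.integer((as.numeric(config$seed) * 7919 +
              as.numeric(library_index) * 104729) %% 2147483647)
}

## Draws the per-homologue starting templates for one library.  Called with
## the library RNG stream already seeded; simulate_inheritance() and
## simulate_library() share this prefix so their state draws agree.
draw_templates <- function(config) {
  lapply(stats::setNames(nm = names(config$chrom_lengths)), function(ch) {
    n <- copy_number_of(config, ch)
    sample(c("W", "C"), n, replace = TRUE)
  })
}

state_label <- function(templates) {
  if (length(templates) == 1L) return(templates)
  nw <- sum(templates == "W")
  if (length(templates) == 2L)
    return(c("CC", "WC", "WW")[nw + 1L])
  paste0(c(rep("W", nw), rep("C", length(templates) - nw)), collapse = "")
}

#' Simulate template-strand inheritance for one library
#'
#' @param config a [sim_config()] object.
#' @param library_index library number (1-based).
#' @return named character vector of per-chromosome template states
#'   (WW/WC/CC for diploid, W/C for haploid chromosomes).
#' @export
simulate_inheritance <- function(config, library_index) {
  stopifnot(inherits(config, "SimConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(library_seed(config, library_index))
  vapply(draw_templates(config), state_label, character(1))
}

## Template strand of homologue h at position p: the starting strand,
## flipped once for each SCE breakpoint at or before p.
template_at <- function(start_strand, breaks, pos) {
  flips <- sum(breaks <= pos)
  if (flips %% 2 == 0) start_strand else flip_strand(start_strand)
}

#' Simulate one Strand-seq library
#'
#' @inheritParams simulate_inheritance
#' @return list with elements `reads` (a [read_set()]) and `truth`
#'   (class `SimTruth`): per-chromosome starting states, planted SCEs with
#'   exact positions and flanking states, copy numbers, and the misoriented
#'   segment / scaffold tables in force.
#' @export
simulate_library <- function(config, library_index) {
  stopifnot(inherits(config, "SimConfig"))
  lens <- config$chrom_lengths
  copies <- vapply(stats::setNames(nm = names(lens)),
                   function(ch) copy_number_of(config, ch), integer(1))
  wt <- lens * copies / 2
  if (any(config$mean_reads * wt / sum(wt) < 1))
    stop_bad("mean reads per chromosome < 1; increase mean_reads")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(library_seed(config, library_index))

  templates <- draw_templates(config)
  states <- vapply(templates, state_label, character(1))

  ## plant SCEs: explicit positions for this library, else Poisson by rate
  sces <- NULL
  explicit <- if (!is.null(config$sce_positions))
    config$sce_positions[[library_index]]
  for (ch in names(lens)) {
    pos <- if (!is.null(explicit)) explicit$pos[explicit$chrom == ch]
           else if (config$sce_rate > 0)
             stats::runif(stats::rpois(1, config$sce_rate), 1, lens[[ch]] - 1)
           else numeric()
    if (!length(pos)) next
    hom <- sample.int(copies[[ch]], length(pos), replace = TRUE)
    sces <- rbind(sces, data.frame(chrom = ch, pos = floor(pos),
                                   homologue = hom))
  }
  hom_breaks <- lapply(stats::setNames(nm = names(lens)), function(ch)
    lapply(seq_len(copies[[ch]]), function(h) {
      if (is.null(sces)) numeric()
      else sort(sces$pos[sces$chrom == ch & sces$homologue == h])
    }))
  if (!is.null(sces)) {
    fl <- t(vapply(seq_len(nrow(sces)), function(i) {
      ch <- sces$chrom[i]; p <- sces$pos[i]
      st <- function(at) state_label(vapply(seq_len(copies[[ch]]), function(h)
        template_at(templates[[ch]][h], hom_breaks[[ch]][[h]], at), character(1)))
      c(st(p - 1), st(p))
    }, character(2)))
    sces$left_state <- fl[, 1]
    sces$right_state <- fl[, 2]
  }

  ## place reads
  n_reads <- stats::rpois(1, config$mean_reads)
  per_chrom <- as.vector(stats::rmultinom(1, n_reads, wt / sum(wt)))
  names(per_chrom) <- names(lens)
  rl <- config$read_length
  reads <- do.call(rbind, lapply(names(lens), function(ch) {
    n <- per_chrom[[ch]]
    if (n == 0) return(NULL)
    start <- floor(stats::runif(n, 0, max(lens[[ch]] - rl, 1)))
    hom <- sample.int(copies[[ch]], n, replace = TRUE)
    strand <- character(n)
    for (h in seq_len(copies[[ch]])) {
      sel <- hom == h
      if (!any(sel)) next
      bk <- sort(hom_breaks[[ch]][[h]])
      flips <- if (length(bk)) findInterval(start[sel], bk) else 0L
      base <- templates[[ch]][h]
      strand[sel] <- ifelse(flips %% 2 == 0, base, flip_strand(base))
    }
    data.frame(chrom = ch, start = start, strand = strand)
  }))

  out_lens <- lens
  ## misoriented reference segments: strand label inverted, position mirrored
  mis <- config$misoriented
  if (!is.null(mis) && nrow(mis)) {
    for (i in seq_len(nrow(mis))) {
      sel <- reads$chrom == mis$chrom[i] &
             reads$start >= mis$start[i] & reads$start < mis$end[i]
      if (any(sel)) {
        reads$strand[sel] <- flip_strand(reads$strand[sel])
        reads$start[sel] <- pmax(mis$start[i],
          mis$start[i] + mis$end[i] - reads$start[sel] - rl)
      }
    }
  }
  ## orphan-scaffold extraction: relabel reads onto the scaffold contig
  sc <- config$scaffolds
  if (!is.null(sc) && nrow(sc)) {
    for (i in seq_len(nrow(sc))) {
      len_i <- sc$end[i] - sc$start[i]
      out_lens[sc$name[i]] <- len_i
      sel <- reads$chrom == sc$chrom[i] &
             reads$start >= sc$start[i] & reads$start < sc$end[i]
      if (!any(sel)) next
      off <- reads$start[sel] - sc$start[i]
      if (identical(sc$orientation[i], "reverse")) {
        off <- pmax(0, len_i - off - rl)
        reads$strand[sel] <- flip_strand(reads$strand[sel])
      }
      reads$chrom[sel] <- sc$name[i]
      reads$start[sel] <- off
    }
  }
  ## spurious background: each read flipped with probability `background`
  if (config$background > 0 && nrow(reads)) {
    hit <- stats::runif(nrow(reads)) < config$background
    reads$strand[hit] <- flip_strand(reads$strand[hit])
  }

  truth <- structure(list(
    library = sprintf("lib%03d", library_index),
    states = states,
    sces = sces %||% data.frame(chrom = character(), pos = numeric(),
                                homologue = integer(),
                                left_state = character(),
                                right_state = character()),
    copy_number = copies,
    misoriented = mis,
    scaffolds = sc), class = "SimTruth")

  list(reads = read_set(reads %||% data.frame(chrom = character(),
                                              start = numeric(),
                                              strand = character()),
                        out_lens, library = truth$library),
       truth = truth)
}

#' Fragment a simulated genome into contigs
#'
#' Splits each chromosome into non-overlapping fragments that tile it,
#' emitting a contig table whose names carry no information about the source
#' chromosome, plus the truth mapping contig -> (chromosome, offset,
#' orientation).  Selected contigs can be recorded in inverted orientation,
#' in which case [remap_reads_to_contigs()] flips their reads' strand and
#' mirrors positions, emulating a misassembled early-build reference.
#'
#' @param config a [sim_config()] object.
#' @param n_per_chrom number of equal-size fragments per chromosome
#'   (recycled), or NULL if `breaks` given.
#' @param breaks optional named list of internal breakpoint vectors per
#'   chromosome.
#' @param invert character vector of contig names (assigned in order
#'   "ctg0001", ...) to record in inverted orientation.
#' @return data.frame (class `ContigTable`) with columns `contig`, `chrom`,
#'   `start`, `end`, `orientation` ("+"/"-"); this table is its own truth.
#' @export
fragment_genome <- function(config, n_per_chrom = 3L, breaks = NULL,
                            invert = character()) {
  stopifnot(inherits(config, "SimConfig"))
  lens <- config$chrom_lengths
  lens <- lens[setdiff(names(lens),
                       if (!is.null(config$scaffolds)) config$scaffolds$name)]
  nper <- rep_len(n_per_chrom %||% 1L, length(lens))
  tab <- do.call(rbind, lapply(seq_along(lens), function(k) {
    ch <- names(lens)[k]
    bk <- if (!is.null(breaks)) sort(breaks[[ch]])
          else round(seq(0, lens[[ch]], length.out = nper[k] + 1))[-c(1, nper[k] + 1)]
    if (any(bk <= 0 | bk >= lens[[ch]]))
      stop_bad("fragment breakpoints outside chromosome %s", ch)
    edge <- c(0, bk, lens[[ch]])
    if (any(diff(edge) <= 0))
      stop_bad("overlapping or empty fragments on %s", ch)
    data.frame(chrom = ch, start = edge[-length(edge)], end = edge[-1])
  }))
  tab$contig <- sprintf("ctg%04d", seq_len(nrow(tab)))
  tab$orientation <- ifelse(tab$contig %in% invert, "-", "+")
  tab <- tab[, c("contig", "chrom", "start", "end", "orientation")]
  class(tab) <- c("ContigTable", "data.frame")
  tab
}

#' Re-map a library's reads onto a fragmented (contig) reference
#'
#' @param reads a [read_set()] aligned to the intact chromosomes.
#' @param contigs a [fragment_genome()] contig table.
#' @return a [read_set()] in contig coordinates; reads falling on no contig
#'   (e.g. extracted scaffolds) are dropped.
#' @export
remap_reads_to_contigs <- function(reads, contigs) {
  stopifnot(inherits(reads, "ReadSet"))
  r <- reads$reads
  keep <- r$chrom %in% contigs$chrom
  r <- r[keep, , drop = FALSE]
  idx <- rep(NA_integer_, nrow(r))
  for (i in seq_len(nrow(contigs))) {
    sel <- r$chrom == contigs$chrom[i] &
           r$start >= contigs$start[i] & r$start < contigs$end[i]
    idx[sel] <- i
  }
  r <- r[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  off <- r$start - contigs$start[idx]
  len <- contigs$end[idx] - contigs$start[idx]
  rev <- contigs$orientation[idx] == "-"
  off[rev] <- pmax(0, len[rev] - off[rev] - 1)
  r$strand[rev] <- flip_strand(r$strand[rev])
  r$start <- off
  r$chrom <- contigs$contig[idx]
  clens <- stats::setNames(contigs$end - contigs$start, contigs$contig)
  read_set(r, clens, library = reads$library)
}

#' Write a ReadSet as a strand-annotated BED file
#'
#' Six-column BED (`chrom start end name score strand`, 0-based half-open);
#' Crick reads on "+", Watson reads on "-"; score carries mapping quality.
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @param read_length read length used for the end coordinate.
#' @return `path`, invisibly.
#' @export
write_strand_bed <- function(reads, path, read_length = 50L) {
  r <- reads$reads
  df <- data.frame(chrom = r$chrom, start = r$start,
                   end = r$start + read_length,
                   name = sprintf("read%06d", seq_len(nrow(r))),
                   score = r$mapq,
                   strand = ifelse(r$strand == "C", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ReadSet as a coordinate-sorted BAM file
#'
#' @param reads a [read_set()].
#' @param path output BAM path (".bam" appended if missing).
#' @param read_length read length for CIGAR/sequence.
#' @return path of the BAM written, invisibly.
#' @export
write_library_bam <- function(reads, path, read_length = 50L) {
  r <- reads$reads
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  on.exit(close(con), add = TRUE)
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in names(reads$chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                       as.integer(reads$chrom_lengths[[ch]])), con)
  if (nrow(r)) {
    flag <- ifelse(r$strand == "W", 16L, 0L) +
            ifelse(r$duplicate, 1024L, 0L)
    writeLines(sprintf("read%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(nrow(r)), flag, r$chrom, r$start + 1L,
                       r$mapq, read_length,
                       strrep("A", read_length)), con)
  }
  close(con); on.exit()
  dest <- sub("\\.bam$", "", path)
  out <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(out)
}

#' Write the simulator truth ledger as CSV files
#'
#' @param truths list of `SimTruth` objects (one per library).
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
write_truth_csv <- function(truths, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- do.call(rbind, lapply(truths, function(t)
    data.frame(library = t$library, chrom = names(t$states),
               state = unname(t$states),
               copy_number = unname(t$copy_number[names(t$states)]))))
  sces <- do.call(rbind, lapply(truths, function(t)
    if (nrow(t$sces)) cbind(library = t$library, t$sces)))
  f1 <- file.path(dir, "truth_states.csv")
  f2 <- file.path(dir, "truth_sces.csv")
  utils::write.csv(states, f1, row.names = FALSE)
  utils::write.csv(sces %||% data.frame(), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
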