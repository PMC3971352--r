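# Small fixture builders shared across test files; everything is generated
# in code, no stored data.

# BinnedCounts built directly from count vectors (named lists W, C).
make_counts <- function(W, C, bin_size = 200000L, chrom_lengths = NULL,
                        library = "libT") {
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(W, function(v) length(v) * bin_size, numeric(1))
  structure(list(bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths, library = library,
                 W = W, C = C),
            class = "BinnedCounts")
}

# ReadSet with reads at regular spacing; strand from a template-state step
# function: `states` is a data.frame(start, end, state) tiling the
# chromosome, WC positions drawing W/C at random.
regular_reads <- function(chrom_len, spacing, states, chrom = "chr1",
                          library = "libR", seed = 1) {
  set.seed(seed)
  start <- seq(spacing / 2, chrom_len - spacing / 2, by = spacing)
  strand <- character(length(start))
  for (k in seq_len(nrow(states))) {
    sel <- start >= states$start[k] & start < states$end[k]
    st <- states$state[k]
    strand[sel] <- switch(st,
      WW = "W", W = "W", CC = "C", C = "C",
      WC = sample(c("W", "C"), sum(sel), replace = TRUE))
  }
  read_set(data.frame(chrom = chrom, start = start, strand = strand),
           stats::setNames(chrom_len, chrom), library = library)
}

# Simple state-call data.frame for segregation tests.
fake_calls <- function(lib, chroms, states, W = 100, C = 100) {
  data.frame(chrom = chroms, state = states, W = W, C = C,
             informative = states != "unknown", library = lib)
}
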