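# Hand-built region-state fixture: two diploid chromosomes, no SCEs, so one
# region each; states per library chosen explicitly.
mk_region_states <- function(states_by_chrom, len = 1e7) {
  out <- list()
  for (ch in names(states_by_chrom)) {
    m <- matrix(states_by_chrom[[ch]], nrow = 1,
                dimnames = list(NULL, names(states_by_chrom[[ch]])))
    out[[ch]] <- list(regions = data.frame(start = 0, end = len),
                      states = m, haploid = FALSE)
  }
  out
}

mk_scaffold_states <- function(states) {
  list(states = data.frame(library = names(states), state = unname(states),
                           W = 50, C = 50, informative = states != "unknown"),
       haploid_candidate = FALSE, n_informative = sum(states != "unknown"))
}

test_that("a WW scaffold scores zero against a WC chromosome", {
  libs <- paste0("lib", 1:12)
  ss <- mk_scaffold_states(stats::setNames(rep("WW", 12), libs))
  rs <- mk_region_states(list(
    chrA = stats::setNames(rep("WC", 12), libs),
    chrB = stats::setNames(rep("WW", 12), libs)))
  pl <- map_scaffold(ss, rs, "frag1", 4e5)
  expect_equal(pl$chrom, "chrB")
  sc <- pl$scores
  expect_equal(sc$concordance[sc$chrom == "chrA"], 0)
  expect_equal(sc$concordance[sc$chrom == "chrB"], 100)
  expect_equal(pl$orientation, "same")
  expect_true(pl$confident)
})

test_that("WW-vs-CC matches vote for the reverse orientation", {
  libs <- paste0("lib", 1:15)
  sts <- stats::setNames(c(rep("WW", 7), rep("CC", 8)), libs)
  ss <- mk_scaffold_states(sts)
  rs <- mk_region_states(list(chrA = stats::setNames(invert_states(sts),
                                                     libs)))
  pl <- map_scaffold(ss, rs, "frag1", 4e5)
  expect_equal(pl$concordance, 100)
  expect_equal(pl$orientation, "reverse")
})

test_that("concordance arithmetic matches matches/informative", {
  libs <- paste0("lib", 1:56)
  sts <- stats::setNames(rep("WW", 56), libs)
  region <- sts
  region[1:5] <- "WC"   # five libraries disagree
  ss <- mk_scaffold_states(sts)
  rs <- mk_region_states(list(chrA = region))
  pl <- map_scaffold(ss, rs, "frag1", 4e5)
  expect_equal(pl$concordance, 100 * 51 / 56, tolerance = 1e-9)
  expect_equal(round(pl$concordance, 1), 91.1)
  expect_equal(pl$n_informative, 56)
})

test_that("confidence needs more than 10 libraries and more than 60 percent", {
  libs <- paste0("lib", 1:10)
  ss <- mk_scaffold_states(stats::setNames(rep("WW", 10), libs))
  rs <- mk_region_states(list(chrA = stats::setNames(rep("WW", 10), libs)))
  pl <- map_scaffold(ss, rs)
  expect_false(pl$confident)   # exactly 10 informative is not enough
  libs2 <- paste0("lib", 1:20)
  sts <- stats::setNames(c(rep("WW", 12), rep("WC", 8)), libs2)
  ss2 <- mk_scaffold_states(sts)
  rs2 <- mk_region_states(list(chrA = stats::setNames(rep("WW", 20), libs2)))
  pl2 <- map_scaffold(ss2, rs2)
  expect_equal(pl2$concordance, 60)
  expect_false(pl2$confident)  # exactly 60% is not enough
})

test_that("SCE-split regions localize a scaffold to part of a chromosome", {
  libs <- paste0("lib", 1:14)
  counts_list <- lapply(libs, function(l) {
    W <- list(chrA = rep(30L, 50), frag1 = 40L)
    C <- list(chrA = rep(0L, 50), frag1 = 0L)
    W$chrA[26:50] <- 15L
    C$chrA[26:50] <- 15L
    make_counts(W, C, chrom_lengths = c(chrA = 1e7, frag1 = 2e5),
                library = l)
  })
  ev <- data.frame(library = libs, chrom = "chrA", start = 5e6 - 1e3,
                   end = 5e6 + 1e3, left_state = "WW", right_state = "WC",
                   class = "SCE")
  events_list <- split(ev, seq_len(nrow(ev)))
  rs <- region_state_matrix(counts_list, events_list, c(chrA = 1e7))
  expect_equal(nrow(rs$chrA$regions), 2)
  ss <- call_scaffold_states(counts_list, "frag1")
  pl <- map_scaffold(ss, rs, "frag1", 2e5)
  expect_equal(pl$chrom, "chrA")
  expect_equal(pl$end, 5e6)    # the WW half, left of the SCE
  expect_equal(pl$concordance, 100)
})

test_that("simulated reverse-extracted scaffold is placed and oriented", {
  sc <- data.frame(chrom = "chr1", start = 4e6, end = 4.4e6,
                   name = "frag9", orientation = "reverse")
  cfg <- sim_config(c(chr1 = 1e7, chr2 = 1e7), n_libraries = 20,
                    mean_reads = 8000, background = 0, scaffolds = sc,
                    seed = 61)
  counts_list <- list(); events_list <- list()
  for (i in 1:20) {
    sim <- simulate_library(cfg, i)
    counts_list[[i]] <- bin_reads(sim$reads)
    events_list[[i]] <- detect_events(sim$reads, counts_list[[i]], seed = 2)
  }
  lens <- counts_list[[1]]$chrom_lengths
  rs <- region_state_matrix(counts_list, events_list,
                            lens[c("chr1", "chr2")])
  ss <- call_scaffold_states(counts_list, "frag9")
  pl <- map_scaffold(ss, rs, "frag9", 4e5)
  expect_equal(pl$chrom, "chr1")
  expect_equal(pl$concordance, 100)
  expect_true(pl$confident)
  expect_equal(pl$orientation, "reverse")
})

gap_tab <- function(...) {
  g <- rbind(...)
  data.frame(chrom = g[, 1], start = as.numeric(g[, 2]),
             end = as.numeric(g[, 3]), type = g[, 4])
}

test_that("gap cross-referencing picks qualifying gaps in priority order", {
  pl <- structure(list(scaffold = "s", size = 5e4, chrom = "chr1",
                       start = 0, end = 2e6, orientation = "same",
                       concordance = 95, n_informative = 30,
                       confident = TRUE, ambiguous = FALSE, gaps = NULL),
                  class = "ScaffoldPlacement")
  g1 <- gap_tab(c("chr1", 1e6, 1.1e6, "bridged"))
  out <- crossref_gaps(pl, g1)
  expect_equal(out$gaps$primary$start, 1e6)
  expect_equal(out$gaps$n_bridged, 1)
  expect_null(out$gaps$alternates)

  g2 <- gap_tab(c("chr1", 2e5, 3e5, "unbridged"),
                c("chr1", 5e5, 7e5, "unbridged"),
                c("chr1", 9e5, 9.6e5, "unbridged"))
  out2 <- crossref_gaps(pl, g2)
  expect_equal(out2$gaps$primary$start, 5e5)   # largest unbridged first
  expect_equal(nrow(out2$gaps$alternates), 2)

  g3 <- gap_tab(c("chr1", 1e6, 1.02e6, "bridged"))
  out3 <- crossref_gaps(pl, g3)   # bridged gap smaller than the scaffold
  expect_null(out3$gaps$primary)
  expect_equal(out3$gaps$n_bridged, 1)
  expect_identical(crossref_gaps(pl, NULL)$gaps, NULL)
})

test_that("reference rewriting flips misorientations as an involution", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")))
  mis <- data.frame(chrom = "chr1", start = 10, end = 20)
  once <- update_reference(seqs, mis)
  s0 <- as.character(seqs[[1]])
  s1 <- as.character(once$sequences[[1]])
  manual <- paste0(substr(s0, 1, 10),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(s0, 11, 20)))),
                   substr(s0, 21, 50))
  expect_equal(s1, manual)
  expect_equal(names(once$sequences), "chr1_v2")
  names(once$sequences) <- "chr1"
  twice <- update_reference(once$sequences, mis)
  expect_equal(as.character(twice$sequences[[1]]), s0)
})

test_that("a placed scaffold restores the original chromosome sequence", {
  set.seed(10)
  s0 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  gap_start <- 800; gap_end <- 1400
  frag <- substr(s0, gap_start + 1, gap_end)
  frag_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  gapped <- paste0(substr(s0, 1, gap_start), strrep("N", 600),
                   substr(s0, gap_end + 1, 2000))
  seqs <- Biostrings::DNAStringSet(c(chr1 = gapped, frag9 = frag_rc))
  pl <- structure(list(scaffold = "frag9", size = 600, chrom = "chr1",
                       start = 0, end = 2000, orientation = "reverse",
                       concordance = 100, n_informative = 20,
                       confident = TRUE, ambiguous = FALSE,
                       gaps = list(primary = data.frame(
                         chrom = "chr1", start = gap_start, end = gap_end,
                         type = "unbridged", length = 600))),
                  class = "ScaffoldPlacement")
  out <- update_reference(seqs, NULL, list(pl))
  expect_equal(as.character(out$sequences[["chr1_v2"]]), s0)
  expect_false("frag9" %in% names(out$sequences))
  expect_error(update_reference(
    seqs, data.frame(chrom = "chr1", start = 700, end = 900),
    list(pl)), "overlap")
})
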