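# A 100 Mb chromosome at exactly one read per 10 kb with a CC->WC switch at
# 50 Mb: the regular spacing gives every 200 kb bin exactly 20 reads, so no
# bin is depth-filtered and the first segmentation pass localizes the event
# to the two adjacent bins.
fixture_regular_sce <- function(seed = 1) {
  regular_reads(1e8, 1e4,
                data.frame(start = c(0, 5e7), end = c(5e7, 1e8),
                           state = c("CC", "WC")),
                seed = seed)
}

test_that("first-pass interval is two bins and refinement starts at 80 kb bins", {
  rs <- fixture_regular_sce()
  bc <- bin_reads(rs, 200000)
  tr <- compute_ratio_track(bc, "chr1", filter_bins(bc, 0.2)$chr1)
  seg <- segment_track(tr)
  expect_equal(nrow(seg$changepoints), 1)
  width <- seg$changepoints$end - seg$changepoints$start
  expect_equal(width, 400000)
  expect_lte(seg$changepoints$start, 5e7)
  expect_gte(seg$changepoints$end, 5e7)
  # refinement needs read density; at 1 read / 10 kb the two-bin interval
  # holds 40 reads, under the 50-read floor, so it is returned unrefined
  sparse <- refine_interval(c(seg$changepoints$start, seg$changepoints$end),
                            rs, 1e8, chrom = "chr1")
  expect_false(sparse$refined)
  dense <- regular_reads(1e8, 2e3,
                         data.frame(start = c(0, 5e7), end = c(5e7, 1e8),
                                    state = c("CC", "WC")), seed = 4)
  ref <- refine_interval(c(seg$changepoints$start, seg$changepoints$end),
                         dense, 1e8, chrom = "chr1")
  expect_equal(ref$trace$bin_size[1], 80000)
  expect_true(ref$refined)
  expect_lte(ref$interval[1], 5e7 + 2e3)
  expect_gte(ref$interval[2], 5e7 - 2e3)
})

test_that("refinement traces nest inside padded predecessors with shrinking widths", {
  rs <- regular_reads(1e8, 2e3,
                      data.frame(start = c(0, 5e7), end = c(5e7, 1e8),
                                 state = c("CC", "WC")), seed = 3)
  ref <- refine_interval(c(4.98e7, 5.02e7), rs, 1e8, chrom = "chr1")
  tr <- ref$trace
  expect_gt(nrow(tr), 1)
  widths <- tr$end - tr$start
  expect_true(all(diff(widths) <= 0))
  prev <- c(4.98e7, 5.02e7)
  for (k in seq_len(nrow(tr))) {
    pad <- (prev[2] - prev[1]) / 2
    expect_gte(tr$start[k], prev[1] - pad)
    expect_lte(tr$end[k], prev[2] + pad)
    prev <- c(tr$start[k], tr$end[k])
  }
})

test_that("refinement stops below the 50-read floor, returning the input", {
  rs <- read_set(data.frame(chrom = "chr1",
                            start = seq(1000, 49000, by = 1000),
                            strand = c(rep("C", 25), rep("W", 24))),
                 c(chr1 = 1e6))
  ref <- refine_interval(c(0, 50000), rs, 1e6, chrom = "chr1")
  expect_equal(ref$interval, c(0, 50000))
  expect_false(ref$refined)
  expect_equal(nrow(ref$trace), 0)
})

test_that("walker reports the gap between straddling reads on a clean transition", {
  pos <- seq(1000, by = 500, length.out = 50)
  rs <- read_set(data.frame(chrom = "chr1", start = pos,
                            strand = c(rep("C", 30), rep("W", 20))),
                 c(chr1 = 1e6))
  wk <- walker_refine(c(pos[25], pos[35]), rs, "left", "C", chrom = "chr1")
  expect_true(wk$refined)
  expect_equal(wk$interval, c(pos[30], pos[31]))
})

test_that("walker rejects a spurious read inside the homozygous run", {
  # the 20-read window after the spurious Watson read sees only Crick
  # template, so the 4-of-20 check rejects it and the true boundary wins
  strands <- c(rep("C", 15), "W", rep("C", 24), rep("W", 20))
  pos <- seq(1000, by = 500, length.out = length(strands))
  rs <- read_set(data.frame(chrom = "chr1", start = pos, strand = strands),
                 c(chr1 = 1e6))
  wk <- walker_refine(c(pos[5], pos[55]), rs, "left", "C", chrom = "chr1")
  expect_true(wk$refined)
  expect_equal(wk$interval, c(pos[40], pos[41]))
})

test_that("walker equals the literal-rule scanner on random read vectors", {
  set.seed(202)
  for (case in 1:250) {
    n <- sample(40:80, 1)
    cp <- sample(15:(n - 15), 1)
    bg <- runif(1, 0, 0.1)
    strands <- c(ifelse(runif(cp) < bg, "W", "C"),
                 sample(c("W", "C"), n - cp, replace = TRUE))
    pos <- sort(sample(1:(n * 100), n))
    rs <- read_set(data.frame(chrom = "chr1", start = pos, strand = strands),
                   c(chr1 = n * 100 + 1))
    got <- walker_refine(c(0, n * 100 + 1), rs, "left", "C", chrom = "chr1")
    want <- walker_oracle(pos, strands, "C")
    if (is.null(want)) {
      expect_false(got$refined)
    } else {
      expect_true(got$refined)
      expect_equal(got$interval, want)
    }
  }
})

test_that("right-side scanning mirrors left-side scanning", {
  strands <- c(rep("W", 12), sample(c("W", "C"), 30, replace = TRUE,
                                    prob = c(.5, .5)), rep("C", 30))
  pos <- seq(500, by = 500, length.out = length(strands))
  rs <- read_set(data.frame(chrom = "chr1", start = pos, strand = strands),
                 c(chr1 = 1e6))
  wk <- walker_refine(c(min(pos), max(pos)), rs, "right", "C",
                      chrom = "chr1")
  mirror <- read_set(data.frame(chrom = "chr1",
                                start = max(pos) + min(pos) - rev(pos),
                                strand = rev(strands)),
                     c(chr1 = 1e6))
  wk2 <- walker_refine(c(min(pos), max(pos)), mirror, "left", "C",
                       chrom = "chr1")
  expect_equal(wk$refined, wk2$refined)
  if (wk$refined)
    expect_equal(sort(max(pos) + min(pos) - wk$interval), wk2$interval)
})

test_that("detect_events recovers planted SCEs and classifies transitions", {
  sce <- data.frame(chrom = "chr1",
                    pos = c(1.2e7, 3.1e7, 4.6e7, 6.4e7, 7.7e7, 9.3e7))
  cfg <- sim_config(c(chr1 = 1e8, chr2 = 3e7), n_libraries = 3,
                    mean_reads = 156000, background = 0.01,
                    sce_positions = rep(list(sce), 3), seed = 55)
  sim <- simulate_library(cfg, 2)
  ev <- detect_events(sim$reads, seed = 7)
  ev1 <- ev[ev$chrom == "chr1", ]
  expect_equal(nrow(ev1), 6)
  expect_true(all(ev1$class == "SCE"))
  for (p in sce$pos)
    expect_true(any(ev1$gross_start <= p & ev1$gross_end >= p))
  # every reported interval nests: walker within refined within gross span
  expect_true(all(ev$start >= ev$refined_start - (ev$refined_end - ev$refined_start) / 2))
  expect_true(all(ev$end <= ev$refined_end + (ev$refined_end - ev$refined_start) / 2))
})

test_that("planted WW<->CC flips are classed misorientation-candidate, not SCE", {
  mis <- data.frame(chrom = "chr1", start = 3e7, end = 3.6e7)
  cfg <- sim_config(c(chr1 = 8e7, chr2 = 3e7), n_libraries = 10,
                    mean_reads = 110000, background = 0.01,
                    misoriented = mis, seed = 77)
  found <- 0
  for (i in 1:10) {
    sim <- simulate_library(cfg, i)
    if (!sim$truth$states[["chr1"]] %in% c("WW", "CC")) next
    ev <- detect_events(sim$reads, seed = 7)
    ev1 <- ev[ev$chrom == "chr1", ]
    expect_equal(nrow(ev1), 2)
    expect_true(all(ev1$class == "misorientation-candidate"))
    found <- found + 1
    if (found >= 2) break
  }
  expect_gte(found, 2)
})

test_that("switches on monosomic chromosomes are classed haploid-switch", {
  cfg <- sim_config(c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7, chrX = 2e7),
                    n_libraries = 4,
                    mean_reads = 70000, background = 0.01,
                    haploid = "chrX",
                    sce_positions = rep(list(data.frame(chrom = "chrX",
                                                        pos = 1.1e7)), 4),
                    seed = 88)
  sim <- simulate_library(cfg, 1)
  ev <- detect_events(sim$reads, seed = 3)
  evx <- ev[ev$chrom == "chrX", ]
  expect_equal(nrow(evx), 1)
  expect_equal(evx$class, "haploid-switch")
  expect_true(all(evx$left_state %in% c("W", "C")))
})

test_that("relabelling W<->C mirrors event states and preserves intervals", {
  cfg <- sim_config(c(chr1 = 5e7, chr2 = 5e7), mean_reads = 120000,
                    background = 0.02,
                    sce_positions = list(data.frame(chrom = "chr1",
                                                    pos = 2.2e7)),
                    seed = 99)
  sim <- simulate_library(cfg, 1)
  ev <- detect_events(sim$reads, seed = 5)
  flipped <- sim$reads
  flipped$reads$strand <- flip_strand(flipped$reads$strand)
  ev2 <- detect_events(flipped, seed = 5)
  expect_equal(nrow(ev), nrow(ev2))
  o <- order(ev$chrom, ev$start)
  o2 <- order(ev2$chrom, ev2$start)
  expect_equal(ev$start[o], ev2$start[o2])
  expect_equal(ev$end[o], ev2$end[o2])
  expect_equal(mirror_state(ev$left_state[o]), ev2$left_state[o2])
  expect_equal(mirror_state(ev$right_state[o]), ev2$right_state[o2])
})
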