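# Long-format state table for a contig x library state matrix given as a
# named list of per-contig state vectors over the same libraries.
mk_states <- function(per_contig) {
  libs <- paste0("lib", seq_along(per_contig[[1]]))
  do.call(rbind, lapply(names(per_contig), function(ctg)
    data.frame(contig = ctg, library = libs, state = per_contig[[ctg]])))
}

test_that("all-WC libraries and all-WC contigs are excluded with reasons", {
  st <- mk_states(list(
    c1 = c("WW", "CC", "WC", "WW"),
    c2 = c("WW", "CC", "WC", "WW"),
    c3 = c("WC", "WC", "WC", "WC")))   # degenerate contig
  st$state[st$library == "lib3"] <- "WC"  # failed library
  sm <- build_state_matrix(st)
  expect_false("lib3" %in% colnames(sm$states))
  expect_false("c3" %in% rownames(sm$states))
  expect_setequal(sm$excluded$name, c("lib3", "c3"))
  clean <- build_state_matrix(mk_states(list(
    a = c("WW", "WC", "CC"), b = c("WW", "CC", "CC"))))
  expect_equal(dim(clean$states), c(2L, 3L))
  expect_equal(nrow(clean$excluded), 0)
})

test_that("contigs below the length floor are dropped before analysis", {
  st <- mk_states(list(a = c("WW", "WC"), b = c("WW", "WC"),
                       tiny = c("CC", "WC")))
  sm <- build_state_matrix(st, contig_lengths = c(a = 5e4, b = 5e4,
                                                  tiny = 5e3))
  expect_false("tiny" %in% rownames(sm$states))
})

test_that("concordance modes separate identity, inversion and independence", {
  v <- rep(c("WW", "WC", "CC", "WC"), 10)
  expect_equal(state_concordance(v, v, "all")$concordance, 1.0)
  inv <- invert_states(v)
  hom <- state_concordance(v, inv, "homozygous")
  expect_equal(hom$concordance, 0.0)
  expect_equal(hom$n, sum(v %in% c("WW", "CC")))
  # independent 1:2:1 segregation matches at exactly 3/8 in expectation
  expect_equal(independent_match_prob(), 3 / 8)
  set.seed(31)
  a <- sample(c("WW", "WC", "CC"), 4000, TRUE, c(1, 2, 1) / 4)
  b <- sample(c("WW", "WC", "CC"), 4000, TRUE, c(1, 2, 1) / 4)
  got <- state_concordance(a, b, "all")$concordance
  expect_lt(abs(got - 3 / 8), 3 * sqrt(3 / 8 * 5 / 8 / 4000))
})

test_that("greedy clustering splits by threshold and is name-deterministic", {
  base <- rep(c("WW", "WC", "CC", "WC", "WW"), 4)
  off <- base
  off[1:12] <- invert_states(off[1:12])  # 40% agreement with base
  lg <- cluster_linkage_groups(build_state_matrix(mk_states(list(
    a = base, b = base, c = off))))
  expect_equal(length(lg$groups), 2)
  sizes <- vapply(lg$groups, nrow, 1L)
  expect_setequal(sizes, c(2L, 1L))
  lg2 <- cluster_linkage_groups(build_state_matrix(mk_states(list(
    a = base, b = base, c = off))), threshold = 1.01)
  expect_equal(length(lg2$groups), 3)
})

test_that("noiseless fragmented chromosomes re-cluster into pure groups", {
  cfg <- sim_config(c(chr1 = 5e6, chr2 = 5e6), n_libraries = 60,
                    mean_reads = 2000, background = 0, seed = 71)
  tab <- fragment_genome(cfg, n_per_chrom = 10)
  states <- NULL
  for (i in 1:60) {
    sim <- simulate_library(cfg, i)
    bc <- bin_reads(remap_reads_to_contigs(sim$reads, tab), 100000)
    calls <- call_library_states(bc, min_reads = 10)
    states <- rbind(states, data.frame(contig = calls$chrom,
                                       library = calls$library,
                                       state = calls$state))
  }
  sm <- build_state_matrix(states)
  lg <- cluster_linkage_groups(sm)
  expect_equal(length(lg$groups), 2)
  for (g in lg$groups) {
    src <- unique(tab$chrom[match(g$contig, tab$contig)])
    expect_equal(length(src), 1)
  }
})

test_that("greedy reorientation recovers planted inversions and merges groups", {
  set.seed(5)
  chrom_states <- t(replicate(6, sample(c("WW", "WC", "CC"), 40, TRUE,
                                        c(1, 2, 1) / 4)))
  per_contig <- list()
  for (k in 1:6) per_contig[[paste0("c", k)]] <- chrom_states[1, ]
  # contigs c4..c6 are the same chromosome recorded in reverse orientation
  for (k in 4:6) per_contig[[paste0("c", k)]] <-
    invert_states(per_contig[[paste0("c", k)]])
  sm <- build_state_matrix(mk_states(per_contig))
  lg <- cluster_linkage_groups(sm)
  expect_equal(length(lg$groups), 2)
  merged <- reorient_and_merge(lg, sm)
  expect_equal(length(merged$groups), 1)
  g <- merged$groups[[1]]
  flips <- stats::setNames(g$orientation, g$contig)
  expect_equal(length(unique(flips[c("c1", "c2", "c3")])), 1)
  expect_equal(length(unique(flips[c("c4", "c5", "c6")])), 1)
  expect_false(flips[["c1"]] == flips[["c4"]])
  expect_gte(merged$n_inversions, 1)
})

test_that("already-consistent groups see zero inversions", {
  v <- rep(c("WW", "CC", "WC", "WW"), 10)
  sm <- build_state_matrix(mk_states(list(a = v, b = v, c = v)))
  lg <- cluster_linkage_groups(sm)
  merged <- reorient_and_merge(lg, sm)
  expect_equal(merged$n_inversions, 0L)
})

test_that("haploid-behaving contigs are routed to their own clustering", {
  cfg <- sim_config(c(chr1 = 4e6, chrX = 4e6), n_libraries = 30,
                    mean_reads = 2000, background = 0, haploid = "chrX",
                    seed = 81)
  tab <- fragment_genome(cfg, n_per_chrom = 4)
  states <- NULL
  for (i in 1:30) {
    sim <- simulate_library(cfg, i)
    bc <- bin_reads(remap_reads_to_contigs(sim$reads, tab), 100000)
    calls <- call_library_states(bc, min_reads = 10)
    states <- rbind(states, data.frame(contig = calls$chrom,
                                       library = calls$library,
                                       state = calls$state))
  }
  sm <- build_state_matrix(states)
  sep <- separate_haploid(sm)
  x_ctgs <- tab$contig[tab$chrom == "chrX"]
  expect_setequal(sep$haploid_contigs, x_ctgs)
  expect_equal(length(sep$clusters$groups), 1)
  expect_setequal(sep$clusters$groups[[1]]$contig, x_ctgs)
  expect_false(any(x_ctgs %in% rownames(sep$diploid$states)))
})

test_that("one spurious homozygous call keeps a diploid contig diploid", {
  v <- rep(c("WW", "WC", "CC", "WC", "WC"), 4)
  w <- v; w[2] <- "WW"
  sm <- build_state_matrix(mk_states(list(a = v, b = w, hap = rep("WW", 20))))
  sep <- separate_haploid(sm)
  expect_identical(sep$haploid_contigs, "hap")
  expect_true(all(c("a", "b") %in% rownames(sep$diploid$states)))
})

test_that("contig ordering follows the genetic distance chain", {
  d <- matrix(c(0, .1, .2,
                .1, 0, .1,
                .2, .1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  res <- strandtools:::tsp_path(d)
  expect_equal(res$length, 0.2)
  expect_true(identical(res$order, c(1L, 2L, 3L)) ||
              identical(res$order, 1:3) || identical(rev(res$order), 1:3) ||
              identical(res$order, c(3, 2, 1)))
})

test_that("heuristic path length equals the brute-force optimum up to n = 8", {
  set.seed(12)
  for (n in c(4, 5, 6, 7, 8)) {
    for (rep in 1:4) {
      m <- matrix(runif(n * n), n, n)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      expect_equal(strandtools:::tsp_path(d)$length, tsp_bruteforce(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical-state groups are returned unordered; paths never beat identity", {
  v <- rep(c("WW", "WC"), 10)
  sm <- build_state_matrix(mk_states(list(a = v, b = v, c = v)))
  grp <- data.frame(contig = c("a", "b", "c"), orientation = "+")
  ord <- order_contigs(grp, sm)
  expect_false(ord$ordered)
  expect_equal(ord$contigs, c("a", "b", "c"))
  set.seed(2)
  per_contig <- lapply(stats::setNames(nm = paste0("k", 1:6)), function(i)
    sample(c("WW", "WC", "CC"), 30, TRUE))
  sm2 <- build_state_matrix(mk_states(per_contig))
  grp2 <- data.frame(contig = names(per_contig), orientation = "+")
  ord2 <- order_contigs(grp2, sm2)
  d <- contig_distances(grp2, sm2)
  identity_len <- sum(d[cbind(1:5, 2:6)])
  expect_lte(ord2$path_length, identity_len + 1e-12)
})
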