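#' Build the contig-by-library template-state matrix
#'
#' Libraries where every informative contig inherited WC templates are
#' dropped (a failed Strand-seq library carries no directional signal), as
#' are contigs that are WC in every informative library (degenerate
#' sequence that cannot be placed).  Contigs below `min_length` are removed
#' before anything else.
#'
#' @param states long data.frame with columns `contig`, `library`, `state`
#'   (WW/WC/CC/W/C/unknown), e.g. rbind of [call_library_states()] run on
#'   contig-mapped counts.
#' @param contig_lengths optional named vector for the length filter.
#' @param min_length minimum contig length in bp (default 10 kb).
#' @return list of class `StateMatrix`: `states` character matrix (contigs
#'   x libraries), `informative` per-contig informative-library counts,
#'   `excluded` data.frame (`what`, `name`, `reason`).
#' @export
build_state_matrix <- function(states, contig_lengths = NULL,
                               min_length = 10000) {
  excluded <- data.frame(what = character(), name = character(),
                         reason = character())
  if (!is.null(contig_lengths)) {
    short <- names(contig_lengths)[contig_lengths < min_length]
    if (length(short)) {
      excluded <- rbind(excluded, data.frame(
        what = "contig", name = short,
        reason = sprintf("shorter than %d bp", as.integer(min_length))))
      states <- states[!states$contig %in% short, , drop = FALSE]
    }
  }
  contigs <- sort(unique(states$contig))
  libs <- sort(unique(states$library))
  if (length(libs) < 2 || length(contigs) < 2)
    stop_bad("state matrix needs >= 2 contigs and >= 2 libraries")
  mat <- matrix("unknown", length(contigs), length(libs),
                dimnames = list(contigs, libs))
  mat[cbind(match(states$contig, contigs), match(states$library, libs))] <-
    states$state
  all_wc <- function(v) {
    inf <- v != "unknown"
    any(inf) && all(v[inf] == "WC")
  }
  bad_lib <- apply(mat, 2, all_wc)
  if (any(bad_lib))
    excluded <- rbind(excluded, data.frame(
      what = "library", name = colnames(mat)[bad_lib],
      reason = "WC on every contig (probable failed library)"))
  mat <- mat[, !bad_lib, drop = FALSE]
  bad_ctg <- apply(mat, 1, all_wc)
  if (any(bad_ctg))
    excluded <- rbind(excluded, data.frame(
      what = "contig", name = rownames(mat)[bad_ctg],
      reason = "WC in every library (probable degenerate sequence)"))
  mat <- mat[!bad_ctg, , drop = FALSE]
  if (!nrow(mat) || !ncol(mat))
    stop_bad("everything excluded from the state matrix")
  structure(list(states = mat,
                 informative = rowSums(mat != "unknown"),
                 excluded = excluded),
            class = "StateMatrix")
}

#' Template-state concordance between two contigs
#'
#' All-states mode: fraction of mutually informative libraries with an
#' identical state (contigs on the same chromosome approach 1; independent
#' chromosomes sit near the chance rate of 1:2:1 segregation).
#' Homozygous-only mode restricts to libraries where both contigs are
#' homozygous (WW/CC or W/C); two contigs from the same chromosome in
#' opposite orientation then score near 0, which is the orientation signal.
#'
#' @param a,b state vectors over the same libraries.
#' @param mode `"all"` or `"homozygous"`.
#' @return list: `concordance` (fraction, NA when no mutually informative
#'   library), `n` informative pair count.
#' @export
state_concordance <- function(a, b, mode = c("all", "homozygous")) {
  mode <- match.arg(mode)
  use <- a != "unknown" & b != "unknown"
  if (mode == "homozygous") {
    hom <- c("WW", "CC", "W", "C")
    use <- use & a %in% hom & b %in% hom
  }
  n <- sum(use)
  if (!n) return(list(concordance = NA_real_, n = 0L))
  list(concordance = mean(a[use] == b[use]), n = n)
}

group_consensus <- function(mat, members) {
  if (length(members) == 1L) return(mat[members, ])
  apply(mat[members, , drop = FALSE], 2, function(v) {
    v <- v[v != "unknown"]
    if (!length(v)) return("unknown")
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) "unknown" else names(tb)[1]
  })
}

#' Cluster contigs into linkage groups by shared template inheritance
#'
#' Seeded greedy clustering: the two contigs informative in the most
#' libraries found the first group(s) (joined when their all-states
#' concordance reaches `threshold`); every remaining contig, in descending
#' informative count (names break ties), joins the best-matching existing
#' group -- the group state per library being the majority over members --
#' or founds a new one.  Singletons are allowed.
#'
#' @param matrix a [build_state_matrix()] object.
#' @param threshold concordance required to join (default 0.85).
#' @return list of class `LinkageGroups`: `groups` = list of data.frames
#'   (`contig`, `orientation` = "+"), `threshold`.
#' @export
cluster_linkage_groups <- function(matrix, threshold = 0.85) {
  mat <- matrix$states
  ord <- order(-matrix$informative[rownames(mat)], rownames(mat))
  contigs <- rownames(mat)[ord]
  groups <- list()
  consensus <- list()
  for (ctg in contigs) {
    best <- 0L; best_c <- -1
    for (g in seq_along(groups)) {
      sc <- state_concordance(mat[ctg, ], consensus[[g]], "all")
      if (!is.na(sc$concordance) && sc$concordance > best_c) {
        best_c <- sc$concordance; best <- g
      }
    }
    if (best > 0L && best_c >= threshold) {
      groups[[best]] <- c(groups[[best]], ctg)
      consensus[[best]] <- group_consensus(mat, groups[[best]])
    } else {
      groups[[length(groups) + 1L]] <- ctg
      consensus[[length(groups)]] <- mat[ctg, ]
    }
  }
  structure(list(
    groups = lapply(groups, function(g)
      data.frame(contig = g, orientation = rep("+", length(g)))),
    threshold = threshold), class = "LinkageGroups")
}

invert_states <- function(v) {
  map <- c(WW = "CC", CC = "WW", WC = "WC", W = "C", C = "W",
           unknown = "unknown")
  out <- unname(map[v])
  names(out) <- names(v)
  out
}

total_hom_concordance <- function(consensus) {
  n <- length(consensus)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- state_concordance(consensus[[i]], consensus[[j]], "homozygous")
    if (!is.na(sc$concordance)) tot <- tot + sc$concordance
  }
  tot
}

#' Reorient misoriented linkage groups and merge concordant ones
#'
#' Opposite-orientation groups from the same chromosome are maximally
#' dissimilar in homozygous-only concordance (WW swapped with CC), so a
#' greedy pass iteratively inverts the group whose inversion most increases
#' the summed pairwise homozygous-only concordance, stopping when no
#' inversion improves it (a group is never inverted twice in a row; hard
#' cap 100 iterations).  Groups whose concordance then exceeds the
#' clustering threshold are merged; member orientation flags record every
#' inversion.
#'
#' @param groups a [cluster_linkage_groups()] result.
#' @param matrix the [build_state_matrix()] used to build them.
#' @param threshold merge threshold (default: the clustering threshold).
#' @return list of class `LinkageGroups` with updated membership and
#'   orientations, plus `concordance_matrix` (homozygous-only, for heat
#'   plotting) and `n_inversions`.
#' @export
reorient_and_merge <- function(groups, matrix,
                               threshold = groups$threshold) {
  mat <- matrix$states
  members <- lapply(groups$groups, function(g) g$contig)
  orient <- lapply(groups$groups, function(g)
    stats::setNames(g$orientation, g$contig))
  consensus <- lapply(members, function(m) group_consensus(mat, m))
  flipped <- rep(FALSE, length(members))
  last <- 0L
  n_inv <- 0L
  for (it in seq_len(100L)) {
    base <- total_hom_concordance(consensus)
    best_gain <- 0; best_g <- 0L
    for (g in seq_along(consensus)) {
      if (g == last) next  # oscillation guard
      trial <- consensus
      trial[[g]] <- invert_states(trial[[g]])
      gain <- total_hom_concordance(trial) - base
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_g <- g }
    }
    if (best_g == 0L) break
    consensus[[best_g]] <- invert_states(consensus[[best_g]])
    orient[[best_g]][] <- ifelse(orient[[best_g]] == "+", "-", "+")
    flipped[best_g] <- !flipped[best_g]
    last <- best_g
    n_inv <- n_inv + 1L
    if (it == 100L) warning("reorientation iteration cap reached")
  }
  ## merge groups whose (reoriented) concordance exceeds the threshold
  n <- length(consensus)
  if (n > 1) {
    pair_start <- integer(); pair_end <- integer()
    link <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sc <- state_concordance(consensus[[i]], consensus[[j]], "all")
      if (!is.na(sc$concordance) && sc$concordance >= threshold)
        link[i, j] <- link[j, i] <- TRUE
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (link[i, j] && comp[j] != comp[i]) {
          comp[c(i, j)] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    merged_members <- list(); merged_orient <- list()
    for (cid in sort(unique(comp))) {
      idx <- which(comp == cid)
      merged_members[[length(merged_members) + 1L]] <-
        unlist(members[idx], use.names = FALSE)
      merged_orient[[length(merged_orient) + 1L]] <-
        do.call(c, orient[idx])
    }
    members <- merged_members
    orient <- merged_orient
    consensus <- lapply(members, function(m) group_consensus(mat, m))
  }
  cm <- matrix(NA_real_, length(consensus), length(consensus))
  for (i in seq_along(consensus)) for (j in seq_along(consensus)) {
    sc <- state_concordance(consensus[[i]], consensus[[j]], "homozygous")
    cm[i, j] <- sc$concordance
  }
  structure(list(
    groups = lapply(seq_along(members), function(k)
      data.frame(contig = members[[k]],
                 orientation = unname(orient[[k]][members[[k]]]))),
    threshold = threshold, concordance_matrix = cm,
    n_inversions = n_inv), class = "LinkageGroups")
}

#' Separate haploid-behaving contigs for independent clustering
#'
#' Contigs never observed WC across their informative libraries (the
#' haploid signature: a single template strand is inherited, never both)
#' are routed to their own clustering on W/C states.  A diploid contig with
#' an occasional homozygous call keeps its WC observations and stays on the
#' diploid route.
#'
#' @param matrix a [build_state_matrix()] object.
#' @param min_informative minimum informative libraries before a contig can
#'   be routed haploid (default 5).
#' @param threshold clustering threshold for the haploid set.
#' @return list: `haploid_contigs`, `clusters` ([cluster_linkage_groups()]
#'   on the haploid subset, or NULL), `diploid` (`StateMatrix` of the
#'   rest).
#' @export
separate_haploid <- function(matrix, min_informative = 5L,
                             threshold = 0.85) {
  mat <- matrix$states
  is_hap <- apply(mat, 1, function(v) {
    inf <- v != "unknown"
    sum(inf) >= min_informative && !any(v[inf] == "WC")
  })
  hap <- rownames(mat)[is_hap]
  clusters <- NULL
  if (length(hap) >= 2) {
    sub <- mat[hap, , drop = FALSE]
    sub[sub == "WW"] <- "W"
    sub[sub == "CC"] <- "C"
    sm <- structure(list(states = sub,
                         informative = rowSums(sub != "unknown"),
                         excluded = data.frame()), class = "StateMatrix")
    clusters <- cluster_linkage_groups(sm, threshold)
  }
  dip <- mat[!is_hap, , drop = FALSE]
  list(haploid_contigs = hap, clusters = clusters,
       diploid = structure(list(states = dip,
                                informative = rowSums(dip != "unknown"),
                                excluded = matrix$excluded),
                           class = "StateMatrix"))
}

## exact shortest Hamiltonian path by Held-Karp dynamic programming;
## affordable up to ~12 contigs (2^n * n^2)
tsp_exact <- function(d) {
  n <- nrow(d)
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, full, n)      # dp[mask, last]: best path over mask
  par <- matrix(0L, full, n)
  for (s in seq_len(n)) dp[bitwShiftL(1L, s - 1L), s] <- 0
  for (mask in seq_len(full)) {
    for (last in seq_len(n)) {
      cur <- dp[mask, last]
      if (!is.finite(cur)) next
      if (bitwAnd(mask, bitwShiftL(1L, last - 1L)) == 0L) next
      for (nxt in seq_len(n)) {
        bit <- bitwShiftL(1L, nxt - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nm <- bitwOr(mask, bit)
        cand <- cur + d[last, nxt]
        if (cand < dp[nm, nxt]) {
          dp[nm, nxt] <- cand
          par[nm, nxt] <- last
        }
      }
    }
  }
  last <- which.min(dp[full, ])
  best_len <- dp[full, last]
  path <- integer(n)
  mask <- full
  for (k in n:1) {
    path[k] <- last
    prev <- par[mask, last]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, last - 1L)))
    last <- prev
  }
  list(order = path, length = best_len)
}

## shortest Hamiltonian path: exact for small groups, otherwise
## best-of-all-starts nearest neighbour + 2-opt
tsp_path <- function(d, exact_max = 12L) {
  n <- nrow(d)
  if (n <= exact_max) return(tsp_exact(d))
  path_len <- function(p) sum(d[cbind(p[-n], p[-1])])
  best <- NULL; best_len <- Inf
  for (s in seq_len(n)) {
    left <- setdiff(seq_len(n), s)
    p <- s
    while (length(left)) {
      nxt <- left[which.min(d[p[length(p)], left])]
      p <- c(p, nxt)
      left <- setdiff(left, nxt)
    }
    if (path_len(p) < best_len) { best <- p; best_len <- path_len(p) }
  }
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      q <- best
      q[i:j] <- rev(q[i:j])
      ql <- path_len(q)
      if (ql < best_len - 1e-12) {
        best <- q; best_len <- ql; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(order = best, length = best_len)
}

#' Pairwise genetic-distance matrix of a linkage group
#'
#' Distance = fraction of mutually informative libraries in which the two
#' contigs differ in (orientation-corrected) state; SCEs accumulate with
#' physical separation, so the distance grows along the chromosome like a
#' genetic map distance.  Pairs with no mutually informative library get
#' the maximum distance 1 with a warning.
#'
#' @param group one group data.frame (`contig`, `orientation`).
#' @param matrix the [build_state_matrix()] object.
#' @return numeric distance matrix.
#' @export
contig_distances <- function(group, matrix) {
  mat <- matrix$states[group$contig, , drop = FALSE]
  flip <- group$orientation == "-"
  for (k in which(flip)) mat[k, ] <- invert_states(mat[k, ])
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(group$contig, group$contig))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    sc <- state_concordance(mat[i, ], mat[j, ], "all")
    if (is.na(sc$concordance)) {
      warning(sprintf("no mutually informative library for %s / %s; distance set to 1",
                      group$contig[i], group$contig[j]))
      d[i, j] <- d[j, i] <- 1
    } else d[i, j] <- d[j, i] <- 1 - sc$concordance
  }
  d
}

#' Order the contigs of a linkage group along the chromosome
#'
#' Approximates the shortest Hamiltonian path through the pairwise
#' genetic-distance matrix (nearest neighbour from every start, then 2-opt
#' until no improving move; deterministic).  Groups whose contigs share an
#' identical inheritance pattern in every library cannot be ordered (no SCE
#' ever separated them) and are returned in input order, flagged.
#'
#' @param group one group data.frame (`contig`, `orientation`).
#' @param matrix the [build_state_matrix()] object.
#' @return list of class `ContigOrder`: `contigs` (ordered), `distances`
#'   (consecutive), `path_length`, `ordered` flag.
#' @export
order_contigs <- function(group, matrix) {
  if (nrow(group) < 2)
    return(structure(list(contigs = group$contig, distances = numeric(),
                          path_length = 0, ordered = FALSE),
                     class = "ContigOrder"))
  d <- contig_distances(group, matrix)
  if (all(d == 0))
    return(structure(list(contigs = group$contig,
                          distances = rep(0, nrow(group) - 1L),
                          path_length = 0, ordered = FALSE),
                     class = "ContigOrder"))
  res <- tsp_path(d)
  ord <- group$contig[res$order]
  structure(list(contigs = ord,
                 distances = d[cbind(res$order[-length(res$order)],
                                     res$order[-1])],
                 path_length = res$length, ordered = TRUE),
            class = "ContigOrder")
}
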