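# Independent oracles, deliberately written as plain literal-rule code with
# no shared machinery with the package implementation.

# Walker rule, transcribed directly: scan reads in order, take the first
# opposite-strand read whose 10 predecessors are all template-strand and
# whose window of (up to) 20 reads starting at itself holds >= 4
# opposite-strand reads; report the span between it and its predecessor.
walker_oracle <- function(pos, strand, hom) {
  opp <- if (hom == "W") "C" else "W"
  n <- length(pos)
  for (t in seq_len(n)) {
    if (strand[t] != opp) next
    if (t <= 10) next
    ok_before <- TRUE
    for (k in (t - 10):(t - 1)) if (strand[k] != hom) ok_before <- FALSE
    if (!ok_before) next
    cnt <- 0
    for (k in t:min(n, t + 19)) if (strand[k] == opp) cnt <- cnt + 1
    if (cnt < 4) next
    return(sort(c(pos[t - 1], pos[t])))
  }
  NULL
}

# Exhaustive shortest Hamiltonian path by permutation enumeration (n <= 8).
tsp_bruteforce <- function(d) {
  n <- nrow(d)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    len <- sum(d[cbind(p[-n], p[-1])])
    if (len < best) best <- len
  }
  best
}

# Textbook chi-squared goodness-of-fit p-value against a ratio.
chisq_oracle <- function(obs, ratio = c(1, 2, 1)) {
  E <- sum(obs) * ratio / sum(ratio)
  X2 <- sum((obs - E)^2 / E)
  stats::pchisq(X2, df = length(obs) - 1, lower.tail = FALSE)
}

# Textbook Holm step-down adjustment.
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact match probability of two independently segregating diploid
# chromosomes under 1:2:1, by enumeration of the 9 state pairs.
independent_match_prob <- function() {
  states <- c("WW", "WC", "CC")
  prob <- c(0.25, 0.5, 0.25)
  tot <- 0
  for (i in 1:3) for (j in 1:3)
    if (states[i] == states[j]) tot <- tot + prob[i] * prob[j]
  tot
}
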