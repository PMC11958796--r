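# Independent oracles and small fixture builders used across test files.
# These deliberately use naive formulations (double loops, explicit pair
# enumeration) so they share no code path with the package implementation.

# Jensen-Shannon divergence by direct evaluation of the two KL sums.
naive_jsd <- function(p, q, base = 2) {
  m <- (p + q) / 2
  kl <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) kl <- kl + 0.5 * p[i] * log(p[i] / m[i], base)
    if (q[i] > 0) kl <- kl + 0.5 * q[i] * log(q[i] / m[i], base)
  }
  kl
}

naive_jsd_matrix <- function(rel, base = 2, as_distance = TRUE) {
  n <- nrow(rel)
  out <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      v <- naive_jsd(rel[i, ], rel[j, ], base)
      if (as_distance) v <- sqrt(max(v, 0))
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

# ANOSIM R by explicit pair enumeration and the rank formula.
brute_anosim_R <- function(d, groups) {
  n <- nrow(d)
  vals <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  r <- rank(vals)
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# random relative-abundance table
random_rel <- function(n, p, seed = 1, concentration = 1) {
  set.seed(seed)
  m <- matrix(rgamma(n * p, concentration), n, p)
  m <- m / rowSums(m)
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("a%03d", seq_len(p)))
  rel_abund(m)
}

# random count table with all entries positive enough to survive filters
random_counts <- function(n, p, depth = 2000, seed = 1) {
  set.seed(seed)
  m <- t(sapply(seq_len(n), function(i)
    rmultinom(1, depth, rgamma(p, 2))[, 1]))
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("a%03d", seq_len(p)))
  count_table(m)
}

# tiny TSV writer for reader tests
write_tsv_raw <- function(lines, path) writeLines(lines, path)
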