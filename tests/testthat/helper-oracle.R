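# Independent oracles, deliberately written via different routes than the
# package internals.

# Enumerates every j term of both maxima with explicit loops, then applies
# the case rule. No vectorized max-trickery shared with ks_statistic().
ks_brute <- function(ranks, n) {
  r <- sort(ranks)
  m <- length(r)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(m)) {
    ta <- j / m - r[j] / n
    tb <- r[j] / n - (j - 1) / m
    if (ta > a) a <- ta
    if (tb > b) b <- tb
  }
  ks <- if (a > b) a else if (b > a) -b else a
  list(a = a, b = b, ks = ks)
}

# Running sum as the literal step function: walk positions 1..n, counting
# hits with a membership test at each step.
running_sum_brute <- function(ranks, n) {
  m <- length(ranks)
  d <- numeric(n)
  hits <- 0L
  for (pos in seq_len(n)) {
    if (pos %in% ranks) hits <- hits + 1L
    d[pos] <- hits / m - pos / n
  }
  d
}

# all nonempty subsets of 1..n as a list of integer vectors
all_subsets <- function(n) {
  out <- list()
  for (m in seq_len(n))
    out <- c(out, utils::combn(n, m, simplify = FALSE))
  out
}

# tiny deterministic Kd matrix builders for connectivity tests
tiny_kd_matrix <- function(values, drugs, kinases) {
  activity_matrix(matrix(values, nrow = length(drugs), byrow = TRUE,
                         dimnames = list(drugs, kinases)), "kd")
}
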