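# Independent brute-force oracles, written directly from the statistic
# definitions with plain loops. They share no code with the package paths
# they check.

oracle_stats <- function(counts, e = rep(2L, ncol(counts))) {
  counts <- as.matrix(counts)
  n <- nrow(counts); t_ <- ncol(counts)
  kt <- ht <- numeric(t_)
  for (t in seq_len(t_)) {
    v <- counts[, t]; v <- v[!is.na(v)]
    states <- unique(v)
    m <- vapply(states, function(s) sum(v == s), integer(1))
    kt[t] <- 1 - max(m) / length(v)
    ms <- sort(m, decreasing = TRUE)
    ht[t] <- sum((seq_along(ms) - 1) * ms) / length(v)
  }
  q <- numeric(0)
  for (i in seq_len(n)) {
    obs <- which(!is.na(counts[i, ]))
    if (length(obs)) q <- c(q, sum(counts[i, obs] != e[obs]))
  }
  dev <- 0; nobs <- 0
  for (i in seq_len(n)) for (t in seq_len(t_)) {
    if (!is.na(counts[i, t])) {
      dev <- dev + abs(counts[i, t] - e[t]); nobs <- nobs + 1
    }
  }
  list(I = 100 * mean(kt), A = mean(q), AN = mean(q) / t_,
       D = dev / nobs, H = mean(ht))
}

# hand step-up BH: q_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o][j] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# per-basepair expansion oracle for the binned-state reduction: expand every
# bin into unit positions and average, rounding halves away from zero
oracle_collapse <- function(bins, states) {
  chroms <- unique(bins$chrom)
  cells <- colnames(states)
  out <- matrix(NA_integer_, length(cells), length(chroms),
                dimnames = list(cells, chroms))
  for (ch in chroms) {
    idx <- which(bins$chrom == ch)
    for (j in seq_along(cells)) {
      vals <- numeric(0)
      for (i in idx) {
        if (!is.na(states[i, j]))
          vals <- c(vals, rep(states[i, j], bins$end[i] - bins$start[i]))
      }
      if (length(vals)) {
        mu <- mean(vals)
        out[j, ch] <- if (mu - floor(mu) == 0.5) as.integer(floor(mu)) + 1L
                      else as.integer(round(mu))
      }
    }
  }
  out
}

# random complete matrix generator for property tests
random_matrix <- function(n, t_, states = 0:6, source = "FISH") {
  cnv_matrix(matrix(sample(states, n * t_, replace = TRUE), n, t_),
             source = source)
}
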