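# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive quantities by direct enumeration, without
# touching the package's own implementations.

oracle_soft_borda <- function(P) {
  k <- nrow(P)
  s <- numeric(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) s[i] <- s[i] + P[i, j]
    }
  }
  s
}

oracle_kendall_distance <- function(a, b) {
  k <- length(a)
  d <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (any(is.na(c(a[i], a[j], b[i], b[j])))) next
      if ((a[i] - a[j]) * (b[i] - b[j]) < 0) d <- d + 1L
    }
  }
  d
}

oracle_tau_b <- function(a, b) {
  k <- length(a)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      da <- a[i] - a[j]
      db <- b[i] - b[j]
      if (da * db > 0) conc <- conc + 1
      if (da * db < 0) disc <- disc + 1
      if (da == 0 && db != 0) tx <- tx + 1
      if (db == 0 && da != 0) ty <- ty + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

oracle_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

# total Kendall distance of a complete ordering (given as a rank vector)
# to a set of possibly partial rankings
oracle_total_distance <- function(rank_vec, R) {
  sum(vapply(
    seq_len(nrow(R)),
    function(v) oracle_kendall_distance(rank_vec, R[v, ]),
    integer(1)
  ))
}

# exhaustive minimum total Kendall distance over all complete rankings
oracle_min_distance <- function(R) {
  k <- ncol(R)
  best <- Inf
  for (ord in oracle_permutations(k)) {
    r <- integer(k)
    r[ord] <- seq_len(k)
    best <- min(best, oracle_total_distance(r, R))
  }
  best
}

# random partial ranking: a min-rank ranking of n_obs observed conditions
random_partial_ranking <- function(k, n_obs = k) {
  r <- rep(NA_integer_, k)
  obs <- sample.int(k, n_obs)
  r[obs] <- rank(runif(n_obs), ties.method = "min")
  r
}

# sample complete rankings from a Plackett-Luce model (sequential draws)
sample_pl_rankings <- function(weights, n) {
  k <- length(weights)
  t(replicate(n, {
    remaining <- seq_len(k)
    ord <- integer(k)
    for (s in seq_len(k)) {
      pick <- remaining[sample.int(
        length(remaining), 1,
        prob = weights[remaining]
      )]
      ord[s] <- pick
      remaining <- setdiff(remaining, pick)
    }
    r <- integer(k)
    r[ord] <- seq_len(k)
    r
  }))
}

# small deterministic 3 x 4 yield table with two unobserved cells
tiny_table <- function() {
  yield_table(rbind(
    c(80, 50, 20, 5),
    c(30, NA, 70, NA),
    c(10, 60, 40, 90)
  ))
}

# a quick, well-separated dataset for ranker tests
quick_dataset <- function(n = 30, k = 4, seed = 42, ...) {
  generate_dataset(synthetic_spec(
    n_substrates = n, k_conditions = k,
    n_archetypes = min(3, k), seed = seed, ...
  ))
}
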