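#' Convert a row of yields to a ranking over conditions
#'
#' Observed conditions are ranked by descending yield with the competition
#' ("min-rank") convention for ties: conditions tied on yield all receive the
#' smallest rank of the tied block, so a prediction tied with the best yield
#' counts as rank 1. Unobserved conditions stay `NA` and carry no rank.
#'
#' @param yields_row Numeric vector of yields; `NA` = unobserved.
#' @return Integer vector of ranks (1 = best), `NA` where unobserved.
#' @examples
#' yields_to_ranking(c(80, 50, 20, 0))
#' yields_to_ranking(c(50, 50, 20, 0))
#' yields_to_ranking(c(30, NA, 70, NA))
#' @export
yields_to_ranking <- function(yields_row) {
  obs <- !is.na(yields_row)
  if (!any(obs)) abort("cannot rank a substrate with no observed conditions")
  r <- rep(NA_integer_, length(yields_row))
  r[obs] <- as.integer(rank(-yields_row[obs], ties.method = "min"))
  r
}

# rankings -> n x k matrix (rows = voters); accepts a list of rank vectors
# or an already-formed matrix
as_ranking_matrix <- function(rankings, k = NULL) {
  if (is.list(rankings)) {
    lens <- lengths(rankings)
    if (length(rankings) == 0) abort("empty list of rankings")
    if (length(unique(lens)) != 1) abort("rankings must share one label set")
    rankings <- do.call(rbind, rankings)
  }
  if (!is.matrix(rankings)) rankings <- matrix(rankings, nrow = 1)
  if (nrow(rankings) == 0) abort("empty list of rankings")
  if (!is.null(k) && ncol(rankings) != k) {
    abort(sprintf("rankings have %d labels, expected %d", ncol(rankings), k))
  }
  rankings
}

#' Borda aggregation of (possibly partial) rankings
#'
#' Each input ranking contributes a score of `k - rank` for every condition
#' it ranks; conditions missing from a ranking contribute the score of the
#' middle rank, `k - (k + 1) / 2`. Total scores across rankings are
#' returned; sorting them (see [rank_from_scores()]) yields the aggregate
#' ranking.
#'
#' @param rankings List of rank vectors (or matrix, rows = rankings) over a
#'   common set of `k` conditions; `NA` = label missing from that ranking.
#' @param k Number of conditions; inferred when omitted.
#' @return Numeric vector of `k` Borda scores (higher = better).
#' @examples
#' borda_aggregate(list(c(1, 2, 3, 4)))
#' borda_aggregate(list(c(1, 2, NA, NA)))      # middle-rank imputation
#' @seealso [soft_borda()], [rank_from_scores()]
#' @export
borda_aggregate <- function(rankings, k = NULL) {
  R <- as_ranking_matrix(rankings, k)
  k <- ncol(R)
  S <- k - R
  S[is.na(S)] <- k - (k + 1) / 2
  colSums(S)
}

#' Soft Borda scores from pairwise preference probabilities
#'
#' The probabilistic Borda variant used by pairwise-comparison rankers:
#' condition `i` scores the sum over `j != i` of the probability that `i` is
#' preferred over `j`.
#'
#' @param pair_probs `k x k` numeric matrix; `pair_probs[i, j]` is the
#'   probability that condition `i` beats condition `j`. Off-diagonal entries
#'   must lie in `[0, 1]` with `pair_probs[i, j] + pair_probs[j, i] = 1`;
#'   the diagonal is ignored.
#' @return Numeric vector of `k` scores.
#' @export
soft_borda <- function(pair_probs) {
  if (!is.matrix(pair_probs) || nrow(pair_probs) != ncol(pair_probs)) {
    abort("`pair_probs` must be a square matrix")
  }
  p <- pair_probs
  diag(p) <- 0
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    abort("pairwise preference probabilities must lie in [0, 1]")
  }
  off <- upper.tri(p)
  if (any(abs((p + t(p))[off] - 1) > 1e-8)) {
    abort("pair_probs[i, j] + pair_probs[j, i] must equal 1")
  }
  rowSums(p)
}

#' Turn scores into a complete, strictly ordered ranking
#'
#' Sorts scores descending and breaks ties deterministically: first by the
#' optional `tiebreak` vector (higher wins — typically the mean training
#' yield of each condition), then by lower condition index.
#'
#' @param scores Numeric score vector (higher = better).
#' @param tiebreak Optional numeric vector of the same length.
#' @return Integer permutation of `1:k` (1 = best).
#' @export
rank_from_scores <- function(scores, tiebreak = NULL) {
  k <- length(scores)
  if (is.null(tiebreak)) tiebreak <- numeric(k)
  tiebreak[is.na(tiebreak)] <- -Inf
  ord <- order(-scores, -tiebreak, seq_len(k))
  r <- integer(k)
  r[ord] <- seq_len(k)
  r
}

#' Kendall distance between two (possibly partial) rankings
#'
#' Number of discordant pairs, counted only over condition pairs ranked in
#' both rankings; pairs tied in either ranking are not discordant.
#'
#' @param a,b Rank vectors of equal length (`NA` = unranked).
#' @return Nonnegative integer count of discordant pairs.
#' @export
kendall_distance <- function(a, b) {
  if (length(a) != length(b)) abort("rankings must have the same length")
  ok <- which(!is.na(a) & !is.na(b))
  if (length(ok) < 2) return(0L)
  a <- a[ok]
  b <- b[ok]
  pr <- combn(length(ok), 2)
  da <- sign(a[pr[1, ]] - a[pr[2, ]])
  db <- sign(b[pr[1, ]] - b[pr[2, ]])
  sum(da * db < 0)
}

#' Configuration for Mallows consensus search
#'
#' @param max_exact_k Largest `k` for which the consensus is found by
#'   exhaustive enumeration of all `k!` orderings (default 8; `8! = 40320`
#'   orderings score in well under a second). Above it a Borda-initialized
#'   adjacent-swap local search with random restarts is used.
#' @param local_search_restarts Number of random restarts (default 10).
#' @param seed Seed for the restart shuffles (default 1).
#' @return A `mallows_config` list.
#' @export
mallows_config <- function(max_exact_k = 8, local_search_restarts = 10, seed = 1) {
  if (max_exact_k < 2) abort("max_exact_k must be >= 2")
  structure(
    list(
      max_exact_k = as.integer(max_exact_k),
      local_search_restarts = as.integer(local_search_restarts),
      seed = as.integer(seed)
    ),
    class = "mallows_config"
  )
}

# all permutations of 1..k as a k! x k matrix (orderings)
all_orderings <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) {
    blk <- cbind(
      sub[, seq_len(pos - 1), drop = FALSE],
      k,
      sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE]
    )
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

# pairwise strict-preference counts: N[i, j] = number of rankings placing i
# strictly before j (both observed)
preference_counts <- function(R) {
  k <- ncol(R)
  N <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      both <- !is.na(R[, i]) & !is.na(R[, j])
      N[i, j] <- sum(R[both, i] < R[both, j])
      N[j, i] <- sum(R[both, j] < R[both, i])
    }
  }
  N
}

# total Kendall distance of each ordering (rows of P) to the voter set
# summarised by preference counts N
ordering_distances <- function(P, N) {
  k <- ncol(P)
  tot <- numeric(nrow(P))
  for (p in seq_len(k - 1)) {
    for (q in (p + 1):k) {
      # P ranks P[, p] before P[, q]; voters preferring P[, q] are discordant
      tot <- tot + N[cbind(P[, q], P[, p])]
    }
  }
  tot
}

#' Mallows maximum-likelihood consensus ranking
#'
#' The mode of a Mallows model over the input rankings, i.e. the complete
#' ranking minimizing the total Kendall distance to the voters (partial
#' rankings contribute over their observed pairs). For `k <=
#' cfg$max_exact_k` the global minimizer is found by exhaustive enumeration;
#' for larger `k`, a Borda-initialized adjacent-swap local search with
#' seeded random restarts is used. Among equally good orderings the
#' lexicographically smallest is returned, so the result is deterministic.
#'
#' @param rankings List (or matrix) of rank vectors; `NA` allowed.
#' @param cfg A [mallows_config()].
#' @return Integer rank vector over all `k` conditions (a permutation).
#' @export
mallows_consensus <- function(rankings, cfg = mallows_config()) {
  R <- as_ranking_matrix(rankings)
  k <- ncol(R)
  N <- preference_counts(R)
  if (k <= cfg$max_exact_k) {
    P <- all_orderings(k)
    d <- ordering_distances(P, N)
    best <- which(d == min(d))
    if (length(best) > 1) {
      # lexicographically smallest ordering among the minimizers
      key <- do.call(order, as.data.frame(P[best, , drop = FALSE]))
      best <- best[key[1]]
    }
    ordering <- P[best, ]
  } else {
    ordering <- local_search_consensus(N, k, cfg)
  }
  r <- integer(k)
  r[ordering] <- seq_len(k)
  r
}

local_search_consensus <- function(N, k, cfg) {
  dist_of <- function(ord) ordering_distances(matrix(ord, 1), N)
  # adjacent-swap pass, then single-item insertion moves (the standard
  # Kemeny neighborhood); insertion escapes the local optima that adjacent
  # swaps alone get stuck in
  sweep_ordering <- function(ord) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (p in seq_len(k - 1)) {
        a <- ord[p]
        b <- ord[p + 1]
        # swapping replaces discordance N[b, a] with N[a, b]
        if (N[a, b] < N[b, a]) {
          ord[p] <- b
          ord[p + 1] <- a
          improved <- TRUE
        }
      }
      cur_d <- dist_of(ord)
      for (p in seq_len(k)) {
        for (q in seq_len(k)) {
          if (q == p) next
          cand <- append(ord[-p], ord[p], after = q - 1)
          d <- dist_of(cand)
          if (d < cur_d) {
            ord <- cand
            cur_d <- d
            improved <- TRUE
          }
        }
      }
    }
    ord
  }
  # Borda initialization (middle-imputation handled upstream via N)
  borda_scores <- rowSums(N)
  start <- order(-borda_scores, seq_len(k))
  best <- sweep_ordering(start)
  best_d <- dist_of(best)
  withr::with_seed(cfg$seed, {
    for (r in seq_len(cfg$local_search_restarts)) {
      cand <- sweep_ordering(sample.int(k))
      d <- dist_of(cand)
      if (d < best_d ||
          (d == best_d && isTRUE(order_lex_less(cand, best)))) {
        best <- cand
        best_d <- d
      }
    }
  })
  best
}

order_lex_less <- function(a, b) {
  i <- which(a != b)
  length(i) > 0 && a[i[1]] < b[i[1]]
}

#' Fit a Plackett-Luce model to (possibly partial) rankings
#'
#' Maximum-likelihood Plackett-Luce weights fitted by
#' minorization-maximization. Each ranking is treated as a complete ordering
#' of its observed labels (top-order list); min-rank ties are broken by
#' condition index. Conditions that never appear ranked above another
#' condition cannot be estimated and are floored at `1 / (10 k)` with a
#' warning.
#'
#' @param rankings List (or matrix) of rank vectors; `NA` allowed.
#' @param max_iter Maximum MM iterations (default 200).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @return Object of class `pl_fit`: `weights` (positive, summing to 1),
#'   `loglik_trace` (nondecreasing), `n_iter`, `converged`.
#' @examples
#' fit <- plackett_luce_fit(list(c(1, 2), c(1, 2), c(1, 2), c(2, 1)))
#' fit$weights  # ~ c(0.75, 0.25)
#' @export
plackett_luce_fit <- function(rankings, max_iter = 200, tol = 1e-8) {
  R <- as_ranking_matrix(rankings)
  k <- ncol(R)
  # orderings of observed labels, ties broken by condition index
  orders <- lapply(seq_len(nrow(R)), function(i) {
    obs <- which(!is.na(R[i, ]))
    obs[order(R[i, obs], obs)]
  })
  orders <- orders[lengths(orders) >= 2]
  wins <- numeric(k)
  compared_above <- rep(FALSE, k)
  for (o in orders) {
    m <- length(o)
    wins[o[-m]] <- wins[o[-m]] + 1
    compared_above[o[-m]] <- TRUE
  }
  uncompared <- !compared_above
  if (length(orders) == 0) {
    warn("no rankings with >= 2 observed labels; returning uniform weights")
    return(structure(
      list(
        weights = rep(1 / k, k), loglik_trace = numeric(0),
        n_iter = 0L, converged = TRUE
      ),
      class = "pl_fit"
    ))
  }
  w <- rep(1 / k, k)
  trace <- numeric(0)
  loglik <- function(w) {
    ll <- 0
    for (o in orders) {
      m <- length(o)
      for (s in seq_len(m - 1)) {
        set <- o[s:m]
        ll <- ll + log(w[o[s]]) - log(sum(w[set]))
      }
    }
    ll
  }
  converged <- FALSE
  iter <- 0L
  prev <- -Inf
  floor_w <- 1 / (10 * k)
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- numeric(k)
    for (o in orders) {
      m <- length(o)
      for (s in seq_len(m - 1)) {
        set <- o[s:m]
        denom[set] <- denom[set] + 1 / sum(w[set])
      }
    }
    est <- denom > 0 & wins > 0
    w_new <- w
    w_new[est] <- wins[est] / denom[est]
    # labels never winning a stage: MM sends them to zero; keep a tiny
    # positive mass so weights remain a valid PL parameter
    w_new[denom > 0 & wins == 0] <- min(w_new[est]) * 1e-6
    w_new <- w_new / sum(w_new)
    w <- w_new
    ll <- loglik(w)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  if (any(uncompared)) {
    warn(sprintf(
      "condition(s) never ranked above another: %s; weight floored",
      paste(which(uncompared), collapse = ", ")
    ))
    # never below an estimated weight: on near-noiseless data the MM
    # estimates can fall under 1/(10k), and an inestimable condition must
    # not leapfrog an estimated one
    w[uncompared] <- min(floor_w, min(w[compared_above]) / 2)
    w <- w / sum(w)
  }
  structure(
    list(weights = w, loglik_trace = trace, n_iter = iter, converged = converged),
    class = "pl_fit"
  )
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf(
    "<pl_fit> k = %d, %d MM iterations (%s)\n",
    length(x$weights), x$n_iter,
    if (x$converged) "converged" else "max_iter reached"
  ))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
tidy.pl_fit <- function(x, ...) {
  tibble(
    condition = seq_along(x$weights),
    weight = x$weights,
    rank = rank_from_scores(x$weights)
  )
}

#' @export
glance.pl_fit <- function(x, ...) {
  tibble(
    k = length(x$weights),
    logLik = if (length(x$loglik_trace)) x$loglik_trace[length(x$loglik_trace)] else NA_real_,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
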