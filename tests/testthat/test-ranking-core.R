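test_that("yields_to_ranking follows the min-rank convention and keeps NAs", {
  expect_equal(yields_to_ranking(c(80, 50, 20, 0)), c(1L, 2L, 3L, 4L))
  expect_equal(yields_to_ranking(c(50, 50, 20, 0)), c(1L, 1L, 3L, 4L))
  expect_equal(
    yields_to_ranking(c(30, NA, 70, NA)),
    c(2L, NA, 1L, NA)
  )
  expect_error(yields_to_ranking(c(NA, NA)), "no observed")
})

test_that("ranking a strict ordering loses no information", {
  withr::with_seed(11, {
    for (i in 1:20) {
      y <- sample(seq(5, 100, by = 5), 6)
      r <- yields_to_ranking(y)
      expect_equal(order(r), order(-y))
    }
  })
})

test_that("Borda scores match the linear score with middle-rank imputation", {
  expect_equal(borda_aggregate(list(c(1, 2, 3, 4))), c(3, 2, 1, 0))
  # missing labels score k - (k+1)/2 = 1.5 for k = 4
  expect_equal(borda_aggregate(list(c(1, 2, NA, NA))), c(3, 2, 1.5, 1.5))
  # a single complete voter is reproduced exactly
  withr::with_seed(7, {
    for (i in 1:10) {
      r <- sample.int(5)
      expect_equal(rank_from_scores(borda_aggregate(list(r))), r)
    }
  })
})

test_that("Borda aggregate equals exhaustive enumeration by total score", {
  votes <- list(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  scores <- borda_aggregate(votes)
  # enumerate all 6 permutations; the best total-score ordering must sort
  # the conditions by their aggregate scores
  perms <- oracle_permutations(3)
  totals <- vapply(perms, function(ord) sum(scores[ord] * c(2, 1, 0)), numeric(1))
  best <- perms[[which.max(totals)]]
  agg <- rank_from_scores(scores)
  expect_equal(order(agg), best)
})

test_that("Borda aggregation is invariant to voter order and to fully-missing voters", {
  withr::with_seed(21, {
    for (i in 1:10) {
      votes <- lapply(1:5, function(.) random_partial_ranking(4, sample(2:4, 1)))
      s1 <- borda_aggregate(votes)
      s2 <- borda_aggregate(votes[sample.int(5)])
      expect_equal(s1, s2)
      with_ghost <- borda_aggregate(c(votes, list(rep(NA_integer_, 4))))
      expect_equal(with_ghost - s1, rep(1.5, 4))
      expect_equal(rank_from_scores(with_ghost), rank_from_scores(s1))
    }
  })
})

test_that("soft Borda handles symmetric, dominant and random matrices", {
  P <- matrix(0.5, 4, 4)
  expect_equal(soft_borda(P), rep(1.5, 4))
  Q <- matrix(0.5, 3, 3)
  Q[1, 2:3] <- 1
  Q[2:3, 1] <- 0
  expect_equal(soft_borda(Q), c(2, 0.5, 0.5))
  withr::with_seed(5, {
    for (i in 1:10) {
      R <- matrix(0, 4, 4)
      for (a in 1:3) {
        for (b in (a + 1):4) {
          p <- runif(1)
          R[a, b] <- p
          R[b, a] <- 1 - p
        }
      }
      expect_equal(soft_borda(R), oracle_soft_borda(R))
    }
  })
  bad <- matrix(0.5, 3, 3)
  bad[1, 2] <- 1.4
  expect_error(soft_borda(bad), "\\[0, 1\\]")
})

test_that("Kendall distance counts discordant both-observed pairs", {
  expect_equal(kendall_distance(1:4, 1:4), 0L)
  expect_equal(kendall_distance(1:4, 4:1), 6L)
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- random_partial_ranking(5, sample(2:5, 1))
      b <- random_partial_ranking(5, sample(2:5, 1))
      expect_equal(kendall_distance(a, b), oracle_kendall_distance(a, b))
    }
  })
})

test_that("exact Mallows consensus is the global Kendall-distance minimizer", {
  votes <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 3, 4))
  expect_equal(mallows_consensus(votes), c(1L, 2L, 3L, 4L))
  # unanimity returns the shared ranking
  u <- rbind(c(3, 1, 4, 2), c(3, 1, 4, 2))
  expect_equal(mallows_consensus(u), c(3L, 1L, 4L, 2L))
  withr::with_seed(41, {
    for (i in 1:15) {
      R <- t(replicate(5, random_partial_ranking(4, sample(2:4, 1))))
      cons <- mallows_consensus(R)
      expect_equal(oracle_total_distance(cons, R), oracle_min_distance(R))
      # never worse than the Borda aggregate
      borda <- rank_from_scores(borda_aggregate(R))
      expect_lte(
        oracle_total_distance(cons, R),
        oracle_total_distance(borda, R)
      )
    }
  })
})

test_that("Plackett-Luce MM recovers the closed-form binary MLE", {
  fit <- plackett_luce_fit(list(c(1, 2), c(1, 2), c(1, 2), c(2, 1)))
  expect_equal(fit$weights, c(0.75, 0.25), tolerance = 1e-4)
})

test_that("Plackett-Luce log-likelihood trace is nondecreasing", {
  withr::with_seed(51, {
    for (i in 1:5) {
      R <- t(replicate(12, random_partial_ranking(4, sample(2:4, 1))))
      fit <- suppressWarnings(plackett_luce_fit(R))
      expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    }
  })
})

test_that("unanimous rankings give strictly decreasing Plackett-Luce weights", {
  fit <- suppressWarnings(
    plackett_luce_fit(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4)))
  )
  expect_true(all(diff(fit$weights) < 0))
  expect_true(all(fit$weights > 0))
})

test_that("Plackett-Luce recovers the weight ordering from simulated data", {
  true_w <- c(0.45, 0.3, 0.15, 0.1)
  withr::with_seed(61, {
    R <- sample_pl_rankings(true_w, 500)
  })
  fit <- plackett_luce_fit(R)
  expect_equal(order(-fit$weights), order(-true_w))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("a condition never ranked above another is floored with a warning", {
  expect_warning(
    fit <- plackett_luce_fit(rbind(c(1, 2, NA), c(2, 1, NA))),
    "never ranked above"
  )
  expect_true(fit$weights[3] > 0)
  expect_equal(which.min(fit$weights), 3L)
})
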