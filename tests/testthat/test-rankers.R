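all_models <- c(
  "rpc", "lrrf", "ibm", "ibpl", "knn", "baseline", "rfr", "rfc", "mlrfc"
)

test_that("fitting rejects conditions with zero observations", {
  y <- rbind(c(10, 20, NA), c(30, 40, NA))
  tbl <- yield_table(y, condition_ids = c("A", "B", "C"))
  expect_error(
    fit_ranker(matrix(rnorm(4), 2, 2), tbl, "baseline"),
    "zero observations.*C"
  )
})

test_that("every ranker is deterministic given data and seed", {
  ds <- quick_dataset(n = 25)
  for (model in all_models) {
    X <- if (model %in% c("ibm", "ibpl", "knn")) ds$fingerprints else ds$features
    f1 <- fit_ranker(X, ds$table, model, seed = 3)
    f2 <- fit_ranker(X, ds$table, model, seed = 3)
    expect_identical(
      predict_ranking(f1, X),
      predict_ranking(f2, X),
      info = model
    )
  }
})

test_that("a strictly dominant condition is ranked first by every model", {
  withr::with_seed(77, {
    n <- 24
    y <- cbind(
      runif(n, 80, 95), runif(n, 40, 60),
      runif(n, 20, 35), runif(n, 1, 10)
    )
    X <- matrix(abs(rnorm(n * 6)), n, 6)
    tbl <- yield_table(y)
    for (model in all_models) {
      fit <- fit_ranker(X, tbl, model, seed = 1, n_neighbors = 3)
      R <- predict_ranking(fit, X)
      expect_true(all(R[, 1] == 1), info = model)
    }
  })
})

test_that("rankings are complete permutations and top-k slices them", {
  ds <- quick_dataset(n = 20, k = 5)
  fit <- fit_ranker(ds$features, ds$table, "rpc", seed = 2)
  R <- predict_ranking(fit, ds$features)
  expect_true(all(apply(R, 1, sort) == 1:5))
  Tk <- predict_topk(fit, ds$features, 3)
  expect_equal(dim(Tk), c(20, 3))
  expect_true(all(apply(Tk, 1, anyDuplicated) == 0))
  expect_equal(predict_topk(fit, ds$features, 5)[1, ], order(R[1, ]))
  expect_equal(
    predict_topk(fit, ds$features, 1)[, 1],
    apply(R, 1, which.min)
  )
  expect_error(predict_topk(fit, ds$features, 9), "between 1 and")
})

test_that("RPC trains one pairwise model per condition pair on both-observed rows", {
  ds <- quick_dataset(n = 10)
  fit <- fit_ranker(ds$features, ds$table, "rpc", seed = 1)
  pairs <- rpc_pair_examples(fit)
  expect_equal(nrow(pairs), choose(4, 2))
  expect_equal(pairs$n_examples, rep(10L, 6))
  # masking 2 of 4 conditions: each pairwise dataset keeps exactly the
  # substrates with both pair members observed
  masked <- apply_mask(ds$table, 2, seed = 9)
  fit_m <- fit_ranker(ds$features, masked, "rpc", seed = 1)
  counts <- rpc_pair_examples(fit_m)$n_examples
  obs <- !is.na(masked$yields)
  pr <- utils::combn(4, 2)
  expected <- vapply(
    seq_len(ncol(pr)),
    function(p) sum(obs[, pr[1, p]] & obs[, pr[2, p]]),
    integer(1)
  )
  expect_equal(counts, expected)
})

test_that("RPC reproduces training rankings on separable data", {
  ds <- generate_dataset(synthetic_spec(
    n_substrates = 40, n_archetypes = 3, yield_sd = 0.5, substrate_sd = 0,
    feature_noise_sd = 0.1, seed = 5
  ))
  fit <- fit_ranker(ds$features, ds$table, "rpc", seed = 1)
  R <- predict_ranking(fit, ds$features)
  truth <- t(apply(ds$table$yields, 1, yields_to_ranking))
  expect_gte(mean(R == truth), 0.97)
})

test_that("IBM returns the shared ranking of unanimous neighbors", {
  y <- rbind(c(20, 80, 50, 5), c(21, 82, 52, 6), c(19, 79, 49, 4), c(90, 10, 20, 30))
  X <- rbind(c(1, 0), c(1, 0.1), c(1, -0.1), c(-5, 8))
  tbl <- yield_table(y)
  fit <- fit_ranker(X, tbl, "ibm", n_neighbors = 3, similarity = "euclidean")
  r <- predict_ranking(fit, matrix(c(1, 0), 1))
  expect_equal(unname(r[1, ]), c(3L, 1L, 2L, 4L))
})

test_that("KNN with one neighbor returns that neighbor's own ranking", {
  ds <- quick_dataset(n = 15)
  fit <- fit_ranker(ds$fingerprints, ds$table, "knn", n_neighbors = 1)
  R <- predict_ranking(fit, ds$fingerprints)
  truth <- t(apply(ds$table$yields, 1, yields_to_ranking))
  expect_equal(unname(R), unname(truth))
})

test_that("KNN matches a brute-force neighbor-mean oracle", {
  withr::with_seed(19, {
    n <- 12
    X <- matrix(rpois(n * 8, 1.5), n, 8)
    y <- matrix(runif(n * 4, 1, 99), n, 4)
    y[sample(length(y), 6)] <- NA
    y[rowSums(!is.na(y)) == 0, 1] <- 50
    tbl <- yield_table(y)
    fit <- fit_ranker(X, tbl, "knn", n_neighbors = 4, similarity = "tanimoto")
    q <- matrix(rpois(8, 1.5), 1, 8)
    sims <- apply(X, 1, function(r) sum(pmin(q, r)) / sum(pmax(q, r)))
    nbrs <- order(-sims, seq_len(n))[1:4]
    m <- colMeans(y[nbrs, , drop = FALSE], na.rm = TRUE)
    pred <- predict_ranking(fit, q)[1, ]
    obs <- which(!is.nan(m))
    # among conditions observed in the neighborhood, order follows mean yield
    expect_equal(order(pred[obs]), obs[order(-m[obs])])
  })
})

test_that("the baseline ranks by mean observed training yield", {
  y <- rbind(c(60, 40, 20, 10), c(60, 40, 20, 10))
  fit <- fit_ranker(NULL, yield_table(y), "baseline")
  expect_equal(unname(predict_ranking(fit, matrix(0, 1, 1))[1, ]), 1:4)
  # masked cells are excluded from the means (loop oracle)
  y2 <- rbind(c(10, NA, 90, 4), c(80, 20, NA, 6), c(30, 25, 50, 5))
  tbl <- yield_table(y2)
  fit2 <- fit_ranker(NULL, tbl, "baseline")
  means <- vapply(1:4, function(c) mean(y2[!is.na(y2[, c]), c]), numeric(1))
  expect_equal(
    unname(predict_ranking(fit2, matrix(0, 1, 1))[1, ]),
    rank(-means, ties.method = "first")
  )
})

test_that("the regressor uses one-hot condition features and recovers additive effects", {
  ds <- generate_dataset(synthetic_spec(
    n_substrates = 40, n_archetypes = 1, yield_sd = 1, substrate_sd = 10, seed = 8
  ))
  fit <- fit_ranker(ds$features, ds$table, "rfr", seed = 1)
  expect_equal(dim(fit$condition_features), c(4L, 4L))
  R <- predict_ranking(fit, ds$features)
  truth <- yields_to_ranking(ds$truth$profiles[1, ])
  expect_gte(mean(t(R) == truth), 0.9)
})

test_that("the multi-class classifier's top condition is its predicted class", {
  ds <- quick_dataset(n = 30)
  fit <- fit_ranker(ds$features, ds$table, "rfc", seed = 1)
  R <- predict_ranking(fit, ds$features)
  probs <- predict(fit$rf, data = as.data.frame(ds$features), num.threads = 1)$predictions
  top <- apply(R, 1, which.min)
  argmax <- as.integer(colnames(probs))[apply(probs, 1, which.max)]
  expect_gte(mean(top == argmax), 0.95) # differs only at probability ties
})

test_that("classifier labels come from observed cells only under masking", {
  ds <- quick_dataset(n = 20)
  masked <- apply_mask(ds$table, 2, seed = 3)
  fit <- fit_ranker(ds$features, masked, "rfc", seed = 1)
  for (i in seq_along(fit$train_labels)) {
    lab <- fit$train_labels[i]
    expect_false(is.na(masked$yields[i, lab]))
    expect_equal(
      masked$yields[i, lab],
      max(masked$yields[i, ], na.rm = TRUE)
    )
  }
})

test_that("the multi-label selector emits k_select distinct conditions", {
  ds <- generate_dataset(preset_spec("ullmann-like-18"))
  fit <- fit_ranker(ds$features, ds$table, "mlrfc", seed = 1)
  expect_equal(fit$top_t, 4L)
  Tk <- predict_topk(fit, ds$features, 4)
  expect_equal(dim(Tk), c(28, 4))
  expect_true(all(apply(Tk, 1, anyDuplicated) == 0))
})

test_that("label rankers emit complete rankings from heavily masked training data", {
  ds <- quick_dataset(n = 30)
  masked <- apply_mask(ds$table, 2, seed = 11)
  for (model in c("rpc", "lrrf", "ibm", "ibpl")) {
    X <- if (model %in% c("ibm", "ibpl")) ds$fingerprints else ds$features
    fit <- fit_ranker(X, masked, model, seed = 1)
    R <- predict_ranking(fit, X)
    expect_true(all(apply(R, 1, sort) == 1:4), info = model)
  }
})
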