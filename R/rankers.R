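#' Fit a reaction-condition ranker
#'
#' Fits one of the prediction strategies that map substrate features to a
#' ranking over a fixed set of candidate reaction conditions:
#'
#' * `"rpc"` — ranking by pairwise comparison: one probability random forest
#'   per condition pair, trained on substrates where both pair members were
#'   observed; predictions aggregate pairwise preference probabilities with
#'   [soft_borda()].
#' * `"lrrf"` — label ranking random forest: a best-condition classifier
#'   forest; at prediction time the query is routed to a leaf in each tree,
#'   the full rankings of that leaf's training substrates are
#'   Borda-aggregated with middle-rank imputation for missing labels (first
#'   aggregation), and the per-tree rankings are Borda-aggregated again
#'   (second aggregation).
#' * `"ibm"` / `"ibpl"` — instance-based rankers: the query's `n_neighbors`
#'   most similar training substrates vote through a Mallows consensus
#'   ([mallows_consensus()]) or a Plackett-Luce fit
#'   ([plackett_luce_fit()], ranked by descending weight).
#' * `"knn"` — conditions ranked by mean observed yield across the nearest
#'   neighbors; conditions unobserved in every neighbor are placed at the
#'   middle rank.
#' * `"baseline"` — the substrate-independent ranking by mean observed
#'   training yield (the "use what usually works" strategy).
#' * `"rfr"` — a yield regressor on concatenated substrate-and-condition
#'   features; conditions ranked by predicted yield.
#' * `"rfc"` — a multi-class classifier of the best observed condition;
#'   conditions ranked by class probability.
#' * `"mlrfc"` — a multi-label classifier (one binary forest per condition,
#'   positives = the substrate's top-`top_t` observed conditions);
#'   conditions ranked by the probability of a positive label.
#'
#' All tree ensembles are `ranger` forests run single-threaded with a fixed
#' seed, so fitting and prediction are fully reproducible.
#'
#' @param features Numeric matrix or data frame of substrate features, one
#'   row per substrate of `table`. Instance-based models are typically given
#'   count fingerprints (Tanimoto similarity), tree ensembles continuous
#'   descriptors. May be `NULL` for `"baseline"`.
#' @param table A [yield_table()] of training outcomes.
#' @param model Ranker name (see above).
#' @param num_trees Trees per forest (default 100).
#' @param n_neighbors Neighborhood size for `"ibm"`, `"ibpl"`, `"knn"`
#'   (default 5).
#' @param similarity `"tanimoto"` (count-generalized, `sum min / sum max`),
#'   `"euclidean"`, or `"auto"` (tanimoto when all features are
#'   nonnegative, as for fingerprints; euclidean otherwise).
#' @param condition_features Optional `k x d` matrix of condition
#'   descriptors for `"rfr"`; defaults to a one-hot encoding.
#' @param top_t Positive-label cutoff for `"mlrfc"`: a condition is a
#'   positive label when it is among the substrate's `top_t` best observed
#'   conditions. Default `min(4, k - 1)`.
#' @param mallows A [mallows_config()] for `"ibm"`.
#' @param seed Integer seed controlling all randomness in the fit.
#'
#' @return An object of class `c("<model>_ranker", "label_ranker")`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_substrates = 30, seed = 1))
#' fit <- fit_ranker(ds$features, ds$table, model = "rpc", seed = 1)
#' predict(fit, ds$features[1:3, ])
#' @export
fit_ranker <- function(features, table,
                       model = c(
                         "rpc", "lrrf", "ibm", "ibpl", "knn",
                         "baseline", "rfr", "rfc", "mlrfc"
                       ),
                       num_trees = 100, n_neighbors = 5,
                       similarity = c("auto", "tanimoto", "euclidean"),
                       condition_features = NULL, top_t = NULL,
                       mallows = mallows_config(), seed = 1) {
  model <- match.arg(model)
  similarity <- match.arg(similarity)
  if (!inherits(table, "yield_table")) abort("`table` must be a yield_table")
  k <- n_conditions(table)
  n <- n_substrates(table)
  unobserved <- colSums(!is.na(table$yields)) == 0
  if (any(unobserved)) {
    abort(sprintf(
      "condition(s) with zero observations: %s",
      paste(table$condition_ids[unobserved], collapse = ", ")
    ))
  }
  if (model != "baseline") {
    features <- prepare_features(features)
    if (nrow(features) != n) {
      abort(sprintf("%d feature rows for %d substrates", nrow(features), n))
    }
  } else {
    features <- NULL
  }
  state <- list(
    model = model,
    k = k,
    n_train = n,
    condition_ids = table$condition_ids,
    mean_yields = condition_means(table),
    feature_names = if (!is.null(features)) colnames(features),
    num_trees = num_trees,
    seed = as.integer(seed)
  )
  state <- switch(model,
    rpc = c(state, fit_rpc(features, table, num_trees, seed)),
    lrrf = c(state, fit_lrrf(features, table, num_trees, seed, state$mean_yields)),
    ibm = ,
    ibpl = ,
    knn = c(state, fit_instance(features, table, n_neighbors, similarity, mallows)),
    baseline = state,
    rfr = c(state, fit_rfr(features, table, condition_features, num_trees, seed)),
    rfc = c(state, fit_rfc(features, table, num_trees, seed, state$mean_yields)),
    mlrfc = c(state, fit_mlrfc(features, table, top_t, num_trees, seed))
  )
  structure(state, class = c(paste0(model, "_ranker"), "label_ranker"))
}

prepare_features <- function(features) {
  if (is.null(features)) abort("this model requires substrate features")
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.numeric(features)) abort("features must be numeric")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  features
}

# ground-truth best observed condition per substrate; ties broken by higher
# mean training yield, then lower condition index
best_conditions <- function(table, mean_yields = condition_means(table)) {
  vapply(seq_len(n_substrates(table)), function(i) {
    y <- table$yields[i, ]
    cands <- which(y == max(y, na.rm = TRUE))
    cands[order(-mean_yields[cands], cands)][1]
  }, integer(1))
}

ranger_quiet <- function(...) {
  ranger::ranger(..., num.threads = 1, verbose = FALSE)
}

# ---------------------------------------------------------------- RPC ----

fit_rpc <- function(features, table, num_trees, seed) {
  k <- n_conditions(table)
  pairs <- combn(k, 2)
  fits <- vector("list", ncol(pairs))
  n_examples <- integer(ncol(pairs))
  fallbacks <- character(0)
  df <- as.data.frame(features)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    yi <- table$yields[, i]
    yj <- table$yields[, j]
    both <- !is.na(yi) & !is.na(yj)
    n_examples[p] <- sum(both)
    use <- both & yi != yj
    y <- factor(ifelse(yi[use] > yj[use], "first", "second"),
      levels = c("first", "second")
    )
    if (sum(use) >= 2 && nlevels(droplevels(y)) == 2) {
      fits[[p]] <- ranger_quiet(
        x = df[use, , drop = FALSE], y = y,
        num.trees = num_trees, probability = TRUE,
        seed = seed + p
      )
    } else if (sum(use) >= 1) {
      # unanimous (or single) preference: smoothed constant probability
      fits[[p]] <- list(const = (sum(y == "first") + 0.5) / (length(y) + 1))
      fallbacks <- c(fallbacks, sprintf("pair (%d,%d): single-class", i, j))
    } else {
      fits[[p]] <- list(const = 0.5)
      fallbacks <- c(fallbacks, sprintf("pair (%d,%d): no examples", i, j))
    }
  }
  list(pairs = pairs, pair_fits = fits, n_pair_examples = n_examples,
       fallbacks = fallbacks)
}

predict_rpc <- function(object, df) {
  k <- object$k
  n <- nrow(df)
  out <- matrix(0L, n, k)
  P <- array(0, c(n, k, k))
  for (p in seq_len(ncol(object$pairs))) {
    i <- object$pairs[1, p]
    j <- object$pairs[2, p]
    fit <- object$pair_fits[[p]]
    if (inherits(fit, "ranger")) {
      pr <- predict(fit, data = df, num.threads = 1)$predictions[, "first"]
    } else {
      pr <- rep(fit$const, n)
    }
    P[, i, j] <- pr
    P[, j, i] <- 1 - pr
  }
  for (r in seq_len(n)) {
    scores <- soft_borda(P[r, , ])
    out[r, ] <- rank_from_scores(scores, object$mean_yields)
  }
  out
}

#' Number of training examples per pairwise comparison of an RPC fit
#'
#' One entry per condition pair (`choose(k, 2)` of them): the number of
#' training substrates with both pair members observed.
#'
#' @param object A fitted `"rpc"` ranker.
#' @return Tibble with columns `cond_a`, `cond_b`, `n_examples`.
#' @export
rpc_pair_examples <- function(object) {
  if (!inherits(object, "rpc_ranker")) abort("not an RPC ranker")
  tibble(
    cond_a = object$condition_ids[object$pairs[1, ]],
    cond_b = object$condition_ids[object$pairs[2, ]],
    n_examples = object$n_pair_examples
  )
}

# --------------------------------------------------------------- LRRF ----

fit_lrrf <- function(features, table, num_trees, seed, mean_yields) {
  k <- n_conditions(table)
  labels <- best_conditions(table, mean_yields)
  df <- as.data.frame(features)
  rf <- ranger_quiet(
    x = df, y = factor(labels),
    num.trees = num_trees, seed = seed
  )
  train_nodes <- predict(rf, data = df, type = "terminalNodes",
    num.threads = 1
  )$predictions
  # per-substrate Borda score rows with middle-rank imputation
  R <- t(apply(table$yields, 1, yields_to_ranking))
  S <- k - R
  S[is.na(S)] <- k - (k + 1) / 2
  list(rf = rf, train_nodes = train_nodes, train_scores = S)
}

predict_lrrf <- function(object, df) {
  k <- object$k
  n <- nrow(df)
  qn <- predict(object$rf, data = df, type = "terminalNodes",
    num.threads = 1
  )$predictions
  agg <- matrix(0, n, k)
  for (t in seq_len(ncol(object$train_nodes))) {
    tn <- object$train_nodes[, t]
    SB <- rowsum(object$train_scores, group = tn)
    nodes <- as.integer(rownames(SB))
    leaf_scores <- SB[match(qn[, t], nodes), , drop = FALSE]
    for (r in seq_len(n)) {
      tree_rank <- rank_from_scores(leaf_scores[r, ], object$mean_yields)
      agg[r, ] <- agg[r, ] + (k - tree_rank)
    }
  }
  out <- matrix(0L, n, k)
  for (r in seq_len(n)) {
    out[r, ] <- rank_from_scores(agg[r, ], object$mean_yields)
  }
  out
}

# ----------------------------------------------- instance-based models ----

fit_instance <- function(features, table, n_neighbors, similarity, mallows) {
  if (n_neighbors > n_substrates(table)) {
    abort("n_neighbors exceeds the number of training substrates")
  }
  if (similarity == "auto") {
    similarity <- if (all(features >= 0)) "tanimoto" else "euclidean"
  }
  R <- t(apply(table$yields, 1, yields_to_ranking))
  list(
    train_x = features, train_rankings = R, train_yields = table$yields,
    n_neighbors = n_neighbors, similarity = similarity, mallows = mallows
  )
}

#' Count-generalized Tanimoto similarity
#'
#' `sum(min(x, y)) / sum(max(x, y))`, the natural extension of the Tanimoto
#' coefficient to count fingerprints (it reduces to the usual bit version on
#' 0/1 vectors). Two all-zero vectors have similarity 0 by convention.
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(x, y) {
  den <- sum(pmax(x, y))
  if (den == 0) return(0)
  sum(pmin(x, y)) / den
}

nearest_neighbors <- function(object, query) {
  n <- nrow(object$train_x)
  if (object$similarity == "tanimoto") {
    s <- vapply(seq_len(n), function(i) {
      tanimoto_similarity(query, object$train_x[i, ])
    }, numeric(1))
    ord <- order(-s, seq_len(n))
  } else {
    d <- sqrt(colSums((t(object$train_x) - query)^2))
    ord <- order(d, seq_len(n))
  }
  ord[seq_len(object$n_neighbors)]
}

predict_instance <- function(object, df, model) {
  k <- object$k
  X <- as.matrix(df)
  out <- matrix(0L, nrow(X), k)
  for (r in seq_len(nrow(X))) {
    nbrs <- nearest_neighbors(object, X[r, ])
    Rn <- object$train_rankings[nbrs, , drop = FALSE]
    out[r, ] <- switch(model,
      ibm = mallows_consensus(Rn, object$mallows),
      ibpl = {
        w <- suppressWarnings(plackett_luce_fit(Rn))$weights
        rank_from_scores(w, object$mean_yields)
      },
      knn = {
        m <- suppressWarnings(colMeans(object$train_yields[nbrs, , drop = FALSE],
          na.rm = TRUE
        ))
        pos <- rep((k + 1) / 2, k)
        obs <- which(!is.nan(m))
        pos[obs] <- rank(-m[obs], ties.method = "min")
        rank_from_scores(-pos, object$mean_yields)
      }
    )
  }
  out
}

# ---------------------------------------------------------- comparators ----

fit_rfr <- function(features, table, condition_features, num_trees, seed) {
  k <- n_conditions(table)
  if (is.null(condition_features)) {
    condition_features <- diag(k) # one-hot reagent encoding
  }
  condition_features <- as.matrix(condition_features)
  if (nrow(condition_features) != k) {
    abort(sprintf("condition_features must have %d rows (one per condition)", k))
  }
  colnames(condition_features) <- paste0("cf", seq_len(ncol(condition_features)))
  obs <- which(!is.na(table$yields), arr.ind = TRUE)
  x <- cbind(
    features[obs[, "row"], , drop = FALSE],
    condition_features[obs[, "col"], , drop = FALSE]
  )
  rf <- ranger_quiet(
    x = as.data.frame(x), y = table$yields[obs],
    num.trees = num_trees, seed = seed
  )
  list(rf = rf, condition_features = condition_features)
}

predict_rfr <- function(object, df) {
  k <- object$k
  n <- nrow(df)
  out <- matrix(0L, n, k)
  for (r in seq_len(n)) {
    x <- cbind(
      df[rep(r, k), , drop = FALSE],
      as.data.frame(object$condition_features)
    )
    pred <- predict(object$rf, data = x, num.threads = 1)$predictions
    out[r, ] <- rank_from_scores(pred, object$mean_yields)
  }
  out
}

fit_rfc <- function(features, table, num_trees, seed, mean_yields) {
  labels <- best_conditions(table, mean_yields)
  rf <- ranger_quiet(
    x = as.data.frame(features), y = factor(labels),
    num.trees = num_trees, probability = TRUE, seed = seed
  )
  list(rf = rf, train_labels = labels)
}

predict_rfc <- function(object, df) {
  k <- object$k
  probs <- predict(object$rf, data = df, num.threads = 1)$predictions
  full <- matrix(0, nrow(df), k)
  full[, as.integer(colnames(probs))] <- probs
  t(apply(full, 1, rank_from_scores, tiebreak = object$mean_yields))
}

fit_mlrfc <- function(features, table, top_t, num_trees, seed) {
  k <- n_conditions(table)
  top_t <- top_t %||% min(4L, k - 1L)
  if (top_t < 1 || top_t >= k) abort("top_t must be in [1, k - 1]")
  R <- t(apply(table$yields, 1, yields_to_ranking))
  labels <- !is.na(R) & R <= top_t
  df <- as.data.frame(features)
  fits <- vector("list", k)
  for (c in seq_len(k)) {
    y <- factor(ifelse(labels[, c], "pos", "neg"), levels = c("neg", "pos"))
    if (nlevels(droplevels(y)) == 2) {
      fits[[c]] <- ranger_quiet(
        x = df, y = y, num.trees = num_trees,
        probability = TRUE, seed = seed + c
      )
    } else {
      fits[[c]] <- list(const = mean(labels[, c]))
    }
  }
  list(label_fits = fits, top_t = top_t)
}

predict_mlrfc <- function(object, df) {
  k <- object$k
  probs <- vapply(seq_len(k), function(c) {
    fit <- object$label_fits[[c]]
    if (inherits(fit, "ranger")) {
      predict(fit, data = df, num.threads = 1)$predictions[, "pos"]
    } else {
      rep(fit$const, nrow(df))
    }
  }, numeric(nrow(df)))
  probs <- matrix(probs, nrow = nrow(df))
  t(apply(probs, 1, rank_from_scores, tiebreak = object$mean_yields))
}

# -------------------------------------------------------- predict API ----

#' Predict complete condition rankings
#'
#' @param object A fitted [fit_ranker()] object.
#' @param features Feature matrix/data frame of query substrates (ignored by
#'   the baseline, where one row per requested prediction is still used to
#'   size the output).
#' @return Integer matrix, one row per query substrate, holding a complete
#'   ranking (permutation of `1:k`, 1 = best); columns follow the training
#'   condition order.
#' @export
predict_ranking <- function(object, features) {
  UseMethod("predict_ranking")
}

#' @export
predict_ranking.label_ranker <- function(object, features) {
  if (object$model == "baseline") {
    n <- if (is.null(features)) 1L else nrow(as.matrix(features))
    r <- rank_from_scores(object$mean_yields)
    out <- matrix(rep(r, each = n), n, object$k)
  } else {
    df <- as.data.frame(prepare_features(features))
    names(df) <- object$feature_names
    out <- switch(object$model,
      rpc = predict_rpc(object, df),
      lrrf = predict_lrrf(object, df),
      ibm = ,
      ibpl = ,
      knn = predict_instance(object, df, object$model),
      rfr = predict_rfr(object, df),
      rfc = predict_rfc(object, df),
      mlrfc = predict_mlrfc(object, df)
    )
  }
  storage.mode(out) <- "integer"
  colnames(out) <- object$condition_ids
  out
}

#' Predict the top-k conditions to try
#'
#' The first `k_select` conditions of the predicted ranking; for the
#' multi-label classifier these are the `k_select` conditions with the
#' highest probability of a positive label.
#'
#' @inheritParams predict_ranking
#' @param k_select Number of conditions to nominate (`1 <= k_select <= k`).
#' @return Integer matrix of condition indices, one row per substrate,
#'   `k_select` columns ordered best-first.
#' @export
predict_topk <- function(object, features, k_select) {
  if (k_select < 1 || k_select > object$k) {
    abort(sprintf("k_select must be between 1 and %d", object$k))
  }
  R <- predict_ranking(object, features)
  out <- t(apply(R, 1, function(r) order(r)[seq_len(k_select)]))
  if (k_select == 1) out <- matrix(out, ncol = 1)
  out
}

#' @export
predict.label_ranker <- function(object, features, type = c("ranking", "topk"),
                                 k_select = NULL, ...) {
  type <- match.arg(type)
  if (type == "ranking") {
    R <- predict_ranking(object, features)
    tibble(
      substrate = rep(seq_len(nrow(R)), each = object$k),
      condition = rep(object$condition_ids, times = nrow(R)),
      rank = as.integer(t(R))
    )
  } else {
    k_select <- k_select %||% min(4L, object$k)
    Tk <- predict_topk(object, features, k_select)
    tibble(
      substrate = rep(seq_len(nrow(Tk)), each = k_select),
      pick_order = rep(seq_len(k_select), times = nrow(Tk)),
      condition = object$condition_ids[as.integer(t(Tk))]
    )
  }
}

#' @export
print.label_ranker <- function(x, ...) {
  cat(sprintf(
    "<label_ranker: %s> %d conditions, %d training substrates\n",
    x$model, x$k, x$n_train
  ))
  invisible(x)
}

#' @export
glance.label_ranker <- function(x, ...) {
  tibble(
    model = x$model,
    k = x$k,
    n_train = x$n_train,
    num_trees = x$num_trees,
    seed = x$seed
  )
}
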