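#' Define an evaluation protocol
#'
#' Bundles the cross-validation scheme, training-set masking, top-k
#' selection settings and model list for [run_protocol()].
#'
#' @param models Character vector of ranker names (see [fit_ranker()]).
#' @param cv `"auto"` (leave-one-out for 40 or fewer substrates, otherwise
#'   `n_folds`-fold), `"loo"`, or an integer number of folds.
#' @param n_folds Folds used when `cv = "auto"` resolves to k-fold
#'   (default 5).
#' @param mask_per_substrate Number of observed conditions additionally
#'   masked per *training* substrate in each mask replicate (default 0 =
#'   no masking). Test rows are never touched.
#' @param mask_reps Number of independent mask replicates per fold
#'   (default 10 when masking, 1 otherwise).
#' @param k_select Optional number of conditions each model may nominate;
#'   when set, selection-level metrics are also recorded.
#' @param metric A [metric_config()].
#' @param seed Integer seed; folds, masks, and all model fits derive from it.
#' @param ... Hyperparameters forwarded to [fit_ranker()] (`num_trees`,
#'   `n_neighbors`, `top_t`, ...).
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(models = c("baseline", "rpc", "lrrf", "ibm", "ibpl"),
                          cv = "auto", n_folds = 5, mask_per_substrate = 0,
                          mask_reps = if (mask_per_substrate > 0) 10 else 1,
                          k_select = NULL, metric = metric_config(),
                          seed = 1, ...) {
  known <- c("rpc", "lrrf", "ibm", "ibpl", "knn", "baseline", "rfr", "rfc", "mlrfc")
  bad <- setdiff(models, known)
  if (length(bad)) abort(sprintf("unknown model(s): %s", paste(bad, collapse = ", ")))
  if (mask_reps < 1) abort("mask_reps must be >= 1")
  structure(
    list(
      models = models, cv = cv, n_folds = n_folds,
      mask_per_substrate = as.integer(mask_per_substrate),
      mask_reps = as.integer(mask_reps),
      k_select = k_select, metric = metric, seed = as.integer(seed),
      ranker_args = list(...)
    ),
    class = "eval_protocol"
  )
}

#' Cross-validation folds
#'
#' @param n_substrates Number of substrates.
#' @param protocol An [eval_protocol()] (its `cv`, `n_folds` and `seed`
#'   fields are used).
#' @return List of folds, each a list with `train` and `test` index vectors;
#'   test sets are disjoint and cover all substrates.
#' @export
make_folds <- function(n_substrates, protocol = eval_protocol()) {
  cv <- protocol$cv
  if (identical(cv, "auto")) {
    cv <- if (n_substrates <= 40) "loo" else protocol$n_folds
  }
  if (identical(cv, "loo")) {
    n_folds <- n_substrates
  } else {
    n_folds <- as.integer(cv)
    if (n_folds < 2) abort("need at least 2 folds")
  }
  if (n_substrates < n_folds) abort("fewer substrates than folds")
  assignment <- withr::with_seed(
    protocol$seed,
    sample(rep_len(seq_len(n_folds), n_substrates))
  )
  lapply(seq_len(n_folds), function(f) {
    test <- which(assignment == f)
    list(train = setdiff(seq_len(n_substrates), test), test = test)
  })
}

#' Randomly mask observed conditions of a yield table
#'
#' Emulates sparsely populated training data: for every selected substrate,
#' `m` of its observed conditions are set to unobserved, chosen uniformly
#' without replacement. Each substrate retains at least one observation.
#'
#' @param table A [yield_table()].
#' @param m Conditions to mask per substrate (`m < k`).
#' @param seed Integer seed.
#' @param rows Substrate indices to mask (default: all).
#' @return A new [yield_table()] with additional `NA` cells.
#' @export
apply_mask <- function(table, m, seed = 1, rows = seq_len(n_substrates(table))) {
  k <- n_conditions(table)
  if (m >= k) abort("cannot mask m >= k conditions per substrate")
  if (m == 0) return(table)
  y <- table$yields
  withr::with_seed(seed, {
    for (i in rows) {
      obs <- which(!is.na(y[i, ]))
      if (length(obs) <= m) {
        abort(sprintf(
          "substrate %d has only %d observed conditions; cannot mask %d",
          i, length(obs), m
        ))
      }
      y[i, obs[sample.int(length(obs), m)]] <- NA_real_
    }
  })
  yield_table(y, table$substrate_ids, table$condition_ids)
}

route_features <- function(model, features, fingerprints) {
  instance_based <- model %in% c("ibm", "ibpl", "knn")
  if (instance_based && !is.null(fingerprints)) fingerprints else features
}

#' Run a cross-validated evaluation of condition rankers
#'
#' For every model x fold x mask replicate: fit on the (optionally masked)
#' training partition, predict complete rankings for the untouched test
#' partition, and record penalized MRR, top-1 accuracy and mean Kendall tau
#' (plus selection-level metrics when `k_select` is set). Everything is
#' deterministic given the protocol seed.
#'
#' @param features Substrate feature matrix (used by all models; instance-
#'   based models use `fingerprints` instead when provided).
#' @param table A [yield_table()].
#' @param protocol An [eval_protocol()].
#' @param fingerprints Optional count-fingerprint matrix routed to the
#'   instance-based models (`ibm`, `ibpl`, `knn`).
#' @return An `eval_report` with `records` (one row per model x fold x mask
#'   replicate) and `predictions` (one row per test substrate per cell);
#'   see [tidy.eval_report()], [glance.eval_report()], [compare_models()].
#' @export
run_protocol <- function(features, table, protocol = eval_protocol(),
                         fingerprints = NULL) {
  n <- n_substrates(table)
  k <- n_conditions(table)
  folds <- make_folds(n, protocol)
  # metrics require a scorable ground truth: only fully observed test rows
  complete_rows <- which(rowSums(is.na(table$yields)) == 0)
  if (length(complete_rows) == 0) {
    abort("no substrate has a fully observed condition row; metrics cannot be computed")
  }
  records <- list()
  predictions <- list()
  failures <- list()
  for (f in seq_along(folds)) {
    train <- folds[[f]]$train
    test <- intersect(folds[[f]]$test, complete_rows)
    if (length(test) == 0) next
    test_table <- slice_table(table, test)
    truth_ranks <- t(apply(test_table$yields, 1, yields_to_ranking))
    for (rep in seq_len(protocol$mask_reps)) {
      mask_seed <- protocol$seed + 7919L * f + 104729L * rep
      train_table <- slice_table(table, train)
      if (protocol$mask_per_substrate > 0) {
        train_table <- apply_mask(train_table, protocol$mask_per_substrate,
          seed = mask_seed
        )
      }
      for (model in protocol$models) {
        X <- route_features(model, features, fingerprints)
        fit <- tryCatch(
          do.call(fit_ranker, c(
            list(
              features = if (is.null(X)) NULL else X[train, , drop = FALSE],
              table = train_table, model = model,
              seed = protocol$seed + f
            ),
            protocol$ranker_args
          )),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1]] <- tibble(
            model = model, fold = f, mask_rep = rep,
            message = conditionMessage(fit)
          )
          next
        }
        Xtest <- if (is.null(X)) matrix(0, length(test), 1) else X[test, , drop = FALSE]
        R <- predict_ranking(fit, Xtest)
        picks <- apply(R, 1, which.min)
        scores <- vapply(seq_along(test), function(i) {
          reciprocal_rank_score(picks[i], test_table$yields[i, ], protocol$metric)
        }, numeric(1))
        taus <- vapply(seq_along(test), function(i) {
          suppressWarnings(kendall_tau(R[i, ], truth_ranks[i, ], protocol$metric))
        }, numeric(1))
        rec <- tibble(
          model = model, fold = f, mask_rep = rep,
          mrr = mean(scores),
          top1 = top1_accuracy(picks, test_table),
          tau = mean(taus, na.rm = TRUE),
          n_test = length(test)
        )
        if (!is.null(protocol$k_select)) {
          Tk <- predict_topk(fit, Xtest, protocol$k_select)
          sel <- lapply(seq_along(test), function(i) {
            selection_scores(Tk[i, ], test_table$yields[i, ], protocol$metric)
          })
          rec$sel_top1 <- mean(vapply(sel, `[[`, numeric(1), "top1"))
          rec$sel_rr <- mean(vapply(sel, `[[`, numeric(1), "rr"))
        }
        records[[length(records) + 1]] <- rec
        predictions[[length(predictions) + 1]] <- tibble(
          model = model, fold = f, mask_rep = rep,
          substrate = test,
          pick = picks,
          pick_rank = vapply(
            seq_along(test),
            function(i) yields_to_ranking(test_table$yields[i, ])[picks[i]],
            integer(1)
          ),
          pick_yield = test_table$yields[cbind(seq_along(test), picks)]
        )
      }
    }
  }
  structure(
    list(
      records = bind_rows(records),
      predictions = bind_rows(predictions),
      failures = bind_rows(failures),
      protocol = protocol,
      n_folds = length(folds),
      condition_ids = table$condition_ids,
      k = k
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d models x %d folds x %d mask rep(s)\n",
    length(unique(x$records$model)), x$n_folds, x$protocol$mask_reps
  ))
  print(glance(x))
  invisible(x)
}

#' Per-cell metric records of an evaluation report
#'
#' @param x An `eval_report` from [run_protocol()].
#' @param ... Unused.
#' @return Tibble with one row per model x fold x mask replicate.
#' @export
tidy.eval_report <- function(x, ...) x$records

#' Model-level aggregates of an evaluation report
#'
#' Metrics are first averaged over mask replicates within each fold, then
#' over folds; the pooled mean over all cells and the spread of MRR across
#' mask replicates are reported alongside.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per model.
#' @export
glance.eval_report <- function(x, ...) {
  has_sel <- "sel_rr" %in% names(x$records)
  per_fold <- x$records %>%
    group_by(.data$model, .data$fold) %>%
    summarise(
      across(dplyr::any_of(c("mrr", "top1", "tau", "sel_top1", "sel_rr")), mean),
      mrr_sd_masks = stats::sd(.data$mrr),
      .groups = "drop"
    )
  out <- per_fold %>%
    group_by(.data$model) %>%
    summarise(
      across(dplyr::any_of(c("mrr", "top1", "tau", "sel_top1", "sel_rr")), mean),
      mrr_sd_masks = mean(.data$mrr_sd_masks, na.rm = TRUE),
      .groups = "drop"
    )
  pooled <- x$records %>%
    group_by(.data$model) %>%
    summarise(mrr_pooled = mean(.data$mrr), .groups = "drop")
  left_join(out, pooled, by = "model") %>%
    arrange(match(.data$model, x$protocol$models))
}

#' Variance of MRR across mask replicates
#'
#' One row per model x fold: the standard deviation of MRR across the mask
#' replicates of that fold — the spread diagnostic used to compare how
#' robustly different model families cope with missing training data.
#'
#' @param report An `eval_report`.
#' @return Tibble with columns `model`, `fold`, `mrr_sd`.
#' @export
mask_variance <- function(report) {
  report$records %>%
    group_by(.data$model, .data$fold) %>%
    summarise(mrr_sd = stats::sd(.data$mrr), .groups = "drop")
}

#' Pairwise model comparison
#'
#' Cross-tabulates, over all test substrates (and mask replicates), the
#' ground-truth rank of the condition picked by model A against the rank of
#' the condition picked by model B, and collects the signed yield difference
#' `yield(A's pick) - yield(B's pick)` for substrates where the two models
#' picked different conditions.
#'
#' @param report An `eval_report` containing both models.
#' @param model_a,model_b Model names.
#' @param table The [yield_table()] the report was computed on.
#' @return A `model_comparison` with `contingency` (k x k count matrix,
#'   rows = rank of A's pick) and `yield_diff` (tibble).
#' @export
compare_models <- function(report, model_a, model_b, table) {
  pa <- report$predictions %>% filter(.data$model == model_a)
  pb <- report$predictions %>% filter(.data$model == model_b)
  if (nrow(pa) == 0 || nrow(pb) == 0) abort("both models must be in the report")
  key <- c("fold", "mask_rep", "substrate")
  merged <- left_join(pa, pb, by = key, suffix = c("_a", "_b"))
  if (anyNA(merged$pick_b)) abort("models were not evaluated on identical folds")
  k <- report$k
  contingency <- matrix(0L, k, k, dimnames = list(
    rank_a = seq_len(k), rank_b = seq_len(k)
  ))
  for (i in seq_len(nrow(merged))) {
    ra <- merged$pick_rank_a[i]
    rb <- merged$pick_rank_b[i]
    contingency[ra, rb] <- contingency[ra, rb] + 1L
  }
  differing <- merged %>%
    filter(.data$pick_a != .data$pick_b) %>%
    mutate(yield_diff = .data$pick_yield_a - .data$pick_yield_b)
  structure(
    list(
      model_a = model_a, model_b = model_b,
      contingency = contingency,
      yield_diff = differing %>%
        dplyr::select(dplyr::all_of(key), "pick_a", "pick_b", "yield_diff")
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s (rows) vs %s (cols)\n", x$model_a, x$model_b))
  print(x$contingency)
  invisible(x)
}

#' Adversarial (y-scramble) control
#'
#' Breaks the substrate-to-outcome link by permuting whole yield rows across
#' substrates (features fixed), then evaluates the protocol on each shuffled
#' dataset. An honest model falls to chance-level MRR on shuffled data
#' (0.52 for four conditions without failed reactions); a model "passes" the
#' control when its real-data MRR exceeds the shuffled distribution.
#'
#' @inheritParams run_protocol
#' @param n_shuffles Number of independent row shuffles (default 20). With
#'   `n_shuffles = 0` this is identical to [run_protocol()].
#' @param run_observed Also evaluate the unshuffled data (default TRUE).
#' @return For `n_shuffles = 0`, an `eval_report`. Otherwise an
#'   `adversarial_control` with `shuffled` (tibble: model, shuffle, mrr),
#'   `observed` (the real-data `eval_report`, or NULL) and `summary`.
#' @export
adversarial_control <- function(features, table, protocol = eval_protocol(),
                                n_shuffles = 20, fingerprints = NULL,
                                run_observed = TRUE) {
  if (n_shuffles == 0) {
    return(run_protocol(features, table, protocol, fingerprints))
  }
  shuffled <- list()
  for (s in seq_len(n_shuffles)) {
    perm <- withr::with_seed(
      protocol$seed + 65537L * s,
      sample.int(n_substrates(table))
    )
    tbl_s <- yield_table(
      table$yields[perm, , drop = FALSE],
      substrate_ids = table$substrate_ids[perm],
      condition_ids = table$condition_ids
    )
    rep_s <- run_protocol(features, tbl_s, protocol, fingerprints)
    shuffled[[s]] <- glance(rep_s) %>%
      dplyr::transmute(.data$model, shuffle = s, mrr = .data$mrr)
  }
  shuffled <- bind_rows(shuffled)
  observed <- if (run_observed) {
    run_protocol(features, table, protocol, fingerprints)
  }
  summary <- shuffled %>%
    group_by(.data$model) %>%
    summarise(
      mean_shuffled_mrr = mean(.data$mrr),
      q95_shuffled_mrr = stats::quantile(.data$mrr, 0.95),
      .groups = "drop"
    )
  if (!is.null(observed)) {
    summary <- left_join(
      summary,
      glance(observed) %>% dplyr::select("model", observed_mrr = "mrr"),
      by = "model"
    ) %>%
      mutate(passes = .data$observed_mrr > .data$q95_shuffled_mrr)
  }
  structure(
    list(shuffled = shuffled, observed = observed, summary = summary,
         n_shuffles = n_shuffles),
    class = "adversarial_control"
  )
}

#' @export
print.adversarial_control <- function(x, ...) {
  cat(sprintf("<adversarial_control> %d shuffles\n", x$n_shuffles))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.adversarial_control <- function(x, ...) x$shuffled

#' @export
glance.adversarial_control <- function(x, ...) x$summary
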