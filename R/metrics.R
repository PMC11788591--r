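#' Metric configuration
#'
#' @param failure_penalty Reciprocal-rank score assigned when the
#'   recommended reaction gave no product (default 0.04): a failed reaction
#'   is worse than any sub-optimal yield, whose floor is `1/k`.
#' @param zero_yield_threshold Yield at or below which a reaction counts as
#'   failed (default 0; raise it for raw analytical responses where
#'   below-noise signals should count as failures).
#' @param tau_variant Kendall tau variant, `"b"` (tie-corrected, default) or
#'   `"a"`.
#' @return A `metric_config` list.
#' @export
metric_config <- function(failure_penalty = 0.04, zero_yield_threshold = 0,
                          tau_variant = c("b", "a")) {
  if (failure_penalty < 0 || failure_penalty >= 1) {
    abort("failure_penalty must be in [0, 1)")
  }
  structure(
    list(
      failure_penalty = failure_penalty,
      zero_yield_threshold = zero_yield_threshold,
      tau_variant = match.arg(tau_variant)
    ),
    class = "metric_config"
  )
}

#' Penalized reciprocal-rank score of one recommendation
#'
#' The reciprocal of the ground-truth (competition) rank of the recommended
#' condition among the substrate's observed yields: 1 for the best
#' condition, 0.5 for the second best, and so on. If the recommended
#' reaction failed (yield at or below `zero_yield_threshold`), the score is
#' the failure penalty (default 0.04) regardless of rank, since a failed
#' reaction is worse than any sub-optimal yield.
#'
#' @param predicted_top Condition index (or id) recommended for the substrate.
#' @param truth_row Numeric vector of the substrate's observed yields
#'   (`NA` = unobserved).
#' @param cfg A [metric_config()].
#' @return A score in `[failure_penalty, 1]`.
#' @examples
#' reciprocal_rank_score(2, c(80, 60, 40, 20))  # second best -> 0.5
#' reciprocal_rank_score(4, c(50, 30, 10, 0))   # failed -> 0.04
#' @export
reciprocal_rank_score <- function(predicted_top, truth_row, cfg = metric_config()) {
  idx <- resolve_condition(predicted_top, length(truth_row), names(truth_row))
  if (is.na(truth_row[idx])) {
    abort(sprintf("recommended condition %s was not observed for this substrate", predicted_top))
  }
  if (truth_row[idx] <= cfg$zero_yield_threshold) {
    return(cfg$failure_penalty)
  }
  1 / yields_to_ranking(truth_row)[idx]
}

resolve_condition <- function(x, k, cond_names = NULL) {
  if (is.character(x) && !is.null(cond_names)) {
    idx <- match(x, cond_names)
    if (is.na(idx)) abort(sprintf("unknown condition '%s'", x))
    return(idx)
  }
  idx <- as.integer(x)
  if (is.na(idx) || idx < 1 || idx > k) abort(sprintf("condition index %s out of range", x))
  idx
}

#' Mean reciprocal rank over a test set
#'
#' @param predictions Vector of recommended condition indices (or ids), one
#'   per substrate of `table`.
#' @param table A [yield_table()] holding the ground-truth yields.
#' @param cfg A [metric_config()].
#' @return Mean of [reciprocal_rank_score()] across substrates. For
#'   reference: with 4 conditions and no failed reactions, uniform-random
#'   recommendation has expectation `(1 + 1/2 + 1/3 + 1/4) / 4 = 0.52`.
#' @export
mrr <- function(predictions, table, cfg = metric_config()) {
  n <- n_substrates(table)
  if (length(predictions) != n) {
    abort(sprintf("%d predictions for %d substrates", length(predictions), n))
  }
  mean(vapply(seq_len(n), function(i) {
    row <- setNames(table$yields[i, ], table$condition_ids)
    reciprocal_rank_score(predictions[i], row, cfg)
  }, numeric(1)))
}

#' Top-1 accuracy
#'
#' Fraction of substrates whose recommended condition attains the maximal
#' observed yield; ties with the maximum count as hits.
#'
#' @inheritParams mrr
#' @return Accuracy in `[0, 1]`.
#' @export
top1_accuracy <- function(predictions, table) {
  n <- n_substrates(table)
  if (length(predictions) != n) {
    abort(sprintf("%d predictions for %d substrates", length(predictions), n))
  }
  mean(vapply(seq_len(n), function(i) {
    row <- table$yields[i, ]
    idx <- resolve_condition(predictions[i], length(row), table$condition_ids)
    if (is.na(row[idx])) abort("recommended condition was not observed for this substrate")
    as.numeric(row[idx] == max(row, na.rm = TRUE))
  }, numeric(1)))
}

#' Kendall rank correlation between predicted and ground-truth rankings
#'
#' Computed from concordant/discordant pair counts over condition pairs
#' ranked in both inputs. The tie-corrected tau-b is the default, since
#' ground-truth yield rankings can contain ties; tau-a is available. A
#' perfect ranking gives 1, a full reversal -1, random orderings average 0.
#'
#' @param pred,truth Rank vectors over the same `k` conditions; `NA` entries
#'   in `truth` restrict the computation to both-observed pairs (with a
#'   warning).
#' @param cfg A [metric_config()] (controls the tau variant).
#' @return Correlation in `[-1, 1]` (`NA` if fewer than two comparable pairs).
#' @export
kendall_tau <- function(pred, truth, cfg = metric_config()) {
  if (length(pred) != length(truth)) abort("rankings must have the same length")
  if (anyNA(truth)) {
    warn("incomplete ground-truth ranking: tau computed over both-observed pairs")
  }
  ok <- which(!is.na(pred) & !is.na(truth))
  if (length(ok) < 2) return(NA_real_)
  a <- pred[ok]
  b <- truth[ok]
  pr <- combn(length(ok), 2)
  da <- sign(a[pr[1, ]] - a[pr[2, ]])
  db <- sign(b[pr[1, ]] - b[pr[2, ]])
  conc <- sum(da * db > 0)
  disc <- sum(da * db < 0)
  tie_a <- sum(da == 0 & db != 0)
  tie_b <- sum(db == 0 & da != 0)
  if (cfg$tau_variant == "a") {
    return((conc - disc) / ncol(pr))
  }
  denom <- sqrt((conc + disc + tie_a) * (conc + disc + tie_b))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

#' Score a top-k selection of conditions
#'
#' For the scenario where a model nominates `k_select` conditions for
#' experimental evaluation: among the selected conditions, the one with the
#' highest actual yield is taken, and its reciprocal ground-truth rank is
#' the selection score (the failure penalty applies if every selected
#' reaction failed). Top-1 is 1 exactly when the selection contains a
#' ground-truth best condition.
#'
#' @param selected Ordered vector of selected condition indices (or ids).
#' @param truth_row Numeric vector of the substrate's yields.
#' @param cfg A [metric_config()].
#' @return Named list with `top1` (0/1) and `rr`.
#' @export
selection_scores <- function(selected, truth_row, cfg = metric_config()) {
  if (length(selected) == 0) abort("empty selection")
  idx <- vapply(selected, resolve_condition, integer(1),
    k = length(truth_row), cond_names = names(truth_row)
  )
  if (anyNA(truth_row[idx])) {
    abort("selection contains a condition not observed for this substrate")
  }
  if (all(truth_row[idx] <= cfg$zero_yield_threshold)) {
    return(list(top1 = 0, rr = cfg$failure_penalty))
  }
  best_sel <- idx[which.max(truth_row[idx])]
  r <- yields_to_ranking(truth_row)[best_sel]
  list(top1 = as.numeric(r == 1), rr = 1 / r)
}
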