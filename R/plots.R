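#' Plot an evaluation report as a model-by-fold MRR heatmap
#'
#' @param object An `eval_report`.
#' @param metric Metric column to display (default `"mrr"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, metric = "mrr", ...) {
  df <- object$records %>%
    group_by(.data$model, .data$fold) %>%
    summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$fold),
    y = factor(.data$model, levels = rev(object$protocol$models)),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$value)),
      size = 3
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = metric) +
    ggplot2::labs(x = "CV fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise model comparison contingency table
#'
#' Tiles count test substrates by the ground-truth rank of each model's
#' pick; the diagonal holds substrates where both models picked conditions
#' of equal quality.
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- as.data.frame(as.table(object$contingency))
  names(df) <- c("rank_a", "rank_b", "n")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank_b, y = .data$rank_a, fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(name = "substrates") +
    ggplot2::labs(
      x = sprintf("rank of %s's pick", object$model_b),
      y = sprintf("rank of %s's pick", object$model_a)
    ) +
    ggplot2::theme_minimal()
}

#' Density of MRR spread across mask replicates
#'
#' Visualizes, per model, the distribution over CV folds of the standard
#' deviation of MRR across mask replicates — models trained on suboptimal
#' labels under masking show visibly wider spread.
#'
#' @param report An `eval_report` run with `mask_reps > 1`.
#' @return A ggplot object.
#' @export
plot_mask_variance <- function(report) {
  df <- mask_variance(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mrr_sd, colour = .data$model)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "sd of MRR across data masks", y = "density") +
    ggplot2::theme_minimal()
}
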