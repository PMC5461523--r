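#' Plot cross-validation AUCs
#'
#' One point per round with the mean as a horizontal line.
#'
#' @param object An `rf_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_cv <- function(object, ...) {
  df <- tibble::tibble(round = seq_along(object$auc), auc = object$auc)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$round), y = .data$auc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = "dashed") +
    ggplot2::labs(x = "CV round", y = "AUC (pooled out-of-fold)",
                  title = sprintf("Mean AUC = %.3f over %d rounds",
                                  object$mean_auc, object$n_rounds)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance report
#'
#' Hit fractions per feature, colored by status; only the `top_n`
#' features by hit fraction are shown.
#'
#' @param object A `boruta_report`.
#' @param top_n Number of features to display (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boruta_report <- function(object, top_n = 30, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(hit_rate = .data$hits / pmax(.data$rounds, 1)) |>
    dplyr::slice_max(.data$hit_rate, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$hit_rate),
    y = .data$hit_rate, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Hit fraction (beat best shadow)",
                  fill = "Status") +
    ggplot2::theme_minimal()
}

#' Plot a genome-scan prediction track
#'
#' Score profile along each chromosome (window midpoint vs score).
#'
#' @param object A `prediction_track`.
#' @param score_threshold Optional horizontal reference line (default
#'   0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prediction_track <- function(object, score_threshold = 0.8, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$score)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = score_threshold, linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (bp)", y = "Enhancer score") +
    ggplot2::theme_minimal()
}

#' Compare score distributions between two window groups
#'
#' The plot behind the DHS / non-DHS diagnostics: overlaid score
#' densities.
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param labels Length-2 character vector of group names.
#' @return A ggplot.
#' @export
plot_score_groups <- function(scores_a, scores_b,
                              labels = c("DHS", "non-DHS")) {
  df <- tibble::tibble(
    score = c(scores_a, scores_b),
    group = rep(labels, c(length(scores_a), length(scores_b)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 30) +
    ggplot2::labs(x = "Prediction score", y = "Windows", fill = NULL) +
    ggplot2::theme_minimal()
}
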