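#' Tidy a cross-validation report
#'
#' @param x An `rf_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per round (`round`, `auc`).
#' @export
tidy.rf_cv <- function(x, ...) {
  tibble::tibble(round = seq_along(x$auc), auc = x$auc)
}

#' One-row summary of a cross-validation report
#'
#' @param x An `rf_cv` object.
#' @param ... Unused.
#' @return One-row tibble with `mean_auc`, `min_auc`, `max_auc`,
#'   `n_rounds`, `n_folds`, `n_trees`.
#' @export
glance.rf_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, min_auc = min(x$auc),
                 max_auc = max(x$auc), n_rounds = x$n_rounds,
                 n_folds = x$n_folds, n_trees = x$n_trees)
}

#' Tidy a feature-importance report
#'
#' @param x A `boruta_report`.
#' @param ... Unused.
#' @return The report as a plain tibble (feature, status, hits, rounds,
#'   z_mean).
#' @export
tidy.boruta_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a feature-importance report
#'
#' @param x A `boruta_report`.
#' @param ... Unused.
#' @return One-row tibble with status counts and rounds completed.
#' @export
glance.boruta_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_important = sum(x$status == "Important"),
    n_tentative = sum(x$status == "Tentative"),
    n_unimportant = sum(x$status == "Unimportant"),
    rounds_completed = attr(x, "rounds_completed")
  )
}

#' One-row summary of a fitted forest model
#'
#' @param x An `rf_model`.
#' @param ... Unused.
#' @return Tibble of model metadata (feature count, trees, OOB error).
#' @export
glance.rf_model <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_features = length(x$feature_names),
    oob_error = x$fit$prediction.error
  )
}
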