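#' Balance positive and negative training sets
#'
#' Both sets are cut to the size of the smaller one; the subset is drawn
#' uniformly without replacement from the larger set, the smaller set
#' passes through unchanged.
#'
#' @param pos_rows,neg_rows Data frames (or matrices) of training rows;
#'   plain vectors (e.g. row indices) are also accepted.
#' @param seed Integer seed for the subset draw.
#' @return A list with `pos` and `neg`, both with
#'   `min(NROW(pos), NROW(neg))` rows.
#' @export
balance_sets <- function(pos_rows, neg_rows, seed) {
  n_pos <- NROW(pos_rows); n_neg <- NROW(neg_rows)
  if (n_pos == 0 || n_neg == 0) stop("both sets must be nonempty", call. = FALSE)
  m <- min(n_pos, n_neg)
  take <- function(x, idx) {
    if (is.data.frame(x) || is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  }
  withr::with_seed(seed, {
    pos <- if (n_pos > m) take(pos_rows, sort(sample.int(n_pos, m))) else pos_rows
    neg <- if (n_neg > m) take(neg_rows, sort(sample.int(n_neg, m))) else neg_rows
    list(pos = pos, neg = neg)
  })
}

#' Train a random-forest classifier
#'
#' A standard random forest: each of `n_trees` trees is grown on a
#' bootstrap sample with random feature subsetting at each split, Gini
#' split criterion, and nodes grown to purity. The model's score for an
#' input is the fraction of trees voting positive.
#'
#' @param X Feature matrix: tibble/data frame of numeric columns (an
#'   `element_id` column is dropped automatically).
#' @param y Binary labels (0/1, logical, or 2-level factor), positive
#'   class = 1/`TRUE`.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; training is deterministic given it.
#' @param keep_inbag Record per-tree inbag counts (needed for
#'   out-of-bag permutation importance; default `TRUE`).
#' @return An `rf_model` object wrapping the fitted ensemble together
#'   with its feature names and seed.
#' @importFrom ranger ranger
#' @export
train_forest <- function(X, y, n_trees = 100, seed, keep_inbag = TRUE) {
  X <- feature_frame(X)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  stopifnot(nrow(X) == length(y))
  fit <- ranger::ranger(
    x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
    num.trees = n_trees, splitrule = "gini", min.node.size = 1,
    keep.inbag = keep_inbag, seed = seed, num.threads = 1,
    classification = TRUE
  )
  structure(
    list(fit = fit, feature_names = names(X), n_trees = n_trees,
         seed = seed, y = y),
    class = "rf_model"
  )
}

# strip id column, keep numeric feature columns
feature_frame <- function(X) {
  X <- tibble::as_tibble(X)
  X[setdiff(names(X), "element_id")]
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  y
}

#' Score inputs with a forest
#'
#' The score is the fraction of trees voting positive, so values are
#' multiples of `1 / n_trees` in `[0, 1]`. Columns are aligned to the
#' model's feature names by name, so column order does not matter.
#'
#' @param model An `rf_model`.
#' @param X Feature matrix with (at least) the model's feature columns.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, X) {
  X <- feature_frame(X)
  missing <- setdiff(model$feature_names, names(X))
  if (length(missing) > 0) {
    stop("feature matrix lacks model columns: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  X <- X[model$feature_names]
  pred <- stats::predict(model$fit, data = as.data.frame(X),
                         predict.all = TRUE, num.threads = 1)$predictions
  # per-tree class indices (1 = negative, 2 = positive)
  rowMeans(pred == 2)
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (equivalent to the probability that a
#' random positive outscores a random negative), with ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)) # 0.75
compute_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validation of the forest classifier
#'
#' Each round re-balances the classes with a round-specific seed (drawing
#' an independent subset of the larger class), assigns stratified folds,
#' trains on k-1 folds, scores the held-out fold, and computes one AUC on
#' the pooled out-of-fold scores. The report's headline number is the
#' mean AUC over rounds.
#'
#' @param X Feature matrix (tibble; `element_id` column ignored).
#' @param y Binary labels.
#' @param n_folds Folds per round (default 10).
#' @param n_rounds Rounds of training (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return An `rf_cv` object: list with `auc` (per-round numeric),
#'   `mean_auc`, `fold_auc` (per-round per-fold tibble), and the
#'   configuration.
#' @export
cross_validate <- function(X, y, n_folds = 10, n_rounds = 10,
                           n_trees = 100, seed) {
  X <- feature_frame(X)
  y <- as_binary_labels(y)
  if (min(table(y)) < n_folds) {
    stop("each class needs at least n_folds samples", call. = FALSE)
  }
  round_seeds <- derive_seeds(seed, 2 * n_rounds)
  fold_rows <- list()
  auc <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    bal <- balance_sets(which(y == 1), which(y == 0),
                        seed = round_seeds[2 * r - 1])
    idx <- c(bal$pos, bal$neg)
    Xr <- X[idx, , drop = FALSE]; yr <- y[idx]
    folds <- withr::with_seed(round_seeds[2 * r], {
      f <- integer(length(yr))
      for (cl in c(0L, 1L)) {
        w <- which(yr == cl)
        f[w] <- sample(rep_len(seq_len(n_folds), length(w)))
      }
      f
    })
    oof <- numeric(length(yr))
    for (k in seq_len(n_folds)) {
      train <- folds != k
      model <- train_forest(Xr[train, , drop = FALSE], yr[train],
                            n_trees = n_trees,
                            seed = (round_seeds[2 * r] %% 2100000000L) + k,
                            keep_inbag = FALSE)
      oof[!train] <- predict_scores(model, Xr[!train, , drop = FALSE])
      fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
        round = r, fold = k,
        auc = compute_auc(oof[!train], yr[!train])
      )
    }
    auc[r] <- compute_auc(oof, yr)
  }
  structure(
    list(auc = auc, mean_auc = mean(auc),
         fold_auc = dplyr::bind_rows(fold_rows),
         n_folds = n_folds, n_rounds = n_rounds, n_trees = n_trees,
         seed = seed),
    class = "rf_cv"
  )
}

#' @export
print.rf_cv <- function(x, ...) {
  cat(sprintf(
    "Cross-validation: %d rounds x %d folds, %d trees\n  mean AUC = %.4f (round range %.4f - %.4f)\n",
    x$n_rounds, x$n_folds, x$n_trees, x$mean_auc, min(x$auc), max(x$auc)
  ))
  invisible(x)
}

#' Two-tailed z-test for an AUC difference
#'
#' The standard error follows the Hanley-McNeil formula evaluated at the
#' expected AUC `auc_b`: with `A = auc_b`, `Q1 = A/(2-A)`,
#' `Q2 = 2A^2/(1+A)`,
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`;
#' the p-value is the two-tailed normal tail of
#' `z = (auc_a - auc_b)/SE`.
#'
#' @param auc_a Tested AUC (in (0,1)).
#' @param auc_b Expected AUC (in (0,1)).
#' @param n_pos,n_neg Class sizes (at least 2 each).
#' @return A list with `z`, `se`, `p_value`.
#' @export
auc_difference_test <- function(auc_a, auc_b, n_pos, n_neg) {
  stopifnot(auc_a > 0, auc_a < 1, auc_b > 0, auc_b < 1,
            n_pos >= 2, n_neg >= 2)
  A <- auc_b
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se2 <- (A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
            (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg)
  if (se2 <= 0) stop("degenerate standard error", call. = FALSE)
  se <- sqrt(se2)
  z <- (auc_a - auc_b) / se
  list(z = z, se = se, p_value = 2 * stats::pnorm(-abs(z)))
}

# deterministic sub-seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}
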