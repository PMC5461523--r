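#' Append shadow features to a matrix
#'
#' For every original column a copy with independently permuted rows is
#' appended, named with the `shadow_` prefix. Shadow columns carry the
#' same marginal distribution as their source but no association with the
#' labels; they calibrate what "important by chance" looks like.
#'
#' @param X Feature tibble (numeric columns).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `2 * ncol(X)` columns.
#' @export
shadow_matrix <- function(X, seed) {
  X <- feature_frame(X)
  if (ncol(X) == 0 || nrow(X) == 0) stop("X must be nonempty", call. = FALSE)
  withr::with_seed(seed, {
    shadows <- purrr::map(X, ~ .x[sample.int(length(.x))])
  })
  names(shadows) <- paste0("shadow_", names(X))
  dplyr::bind_cols(X, tibble::as_tibble(shadows))
}

#' Out-of-bag permutation importance as z-scores
#'
#' For each feature: every tree's accuracy on its out-of-bag samples is
#' compared with its accuracy after the feature's column is permuted;
#' the importance is `z = mean(loss) / (sd(loss) / sqrt(n_trees))` over
#' trees. Features never used by any tree get z = 0.
#'
#' @param model `rf_model` trained with `keep_inbag = TRUE`.
#' @param X Training feature matrix (same rows the model was fit on).
#' @param y Training labels.
#' @param seed Integer seed for the permutation draws.
#' @param n_permutations Independent permutation replicates per feature,
#'   assigned to trees round-robin. With 1 (the default, cheapest) all
#'   trees share one permutation, which leaves the z-scores exchangeable
#'   between real and shadow features - all that shadow-based selection
#'   needs - but correlated across trees, so their null scale exceeds 1;
#'   larger values restore the per-tree independence of the classical
#'   out-of-bag importance and with it the standard-normal null
#'   calibration.
#' @return Named numeric vector of z-scores, one per model feature.
#' @export
permutation_importance_z <- function(model, X, y, seed,
                                     n_permutations = 1) {
  X <- feature_frame(X)[model$feature_names]
  y <- as_binary_labels(y)
  inbag <- model$fit$inbag.counts
  if (is.null(inbag)) {
    stop("model has no inbag records; train with keep_inbag = TRUE",
         call. = FALSE)
  }
  oob <- !do.call(cbind, inbag) > 0   # n x trees, TRUE where out-of-bag
  ntree <- model$n_trees
  K <- min(n_permutations, ntree)
  base <- stats::predict(model$fit, data = as.data.frame(X),
                         predict.all = TRUE, num.threads = 1)$predictions
  correct0 <- base == (y + 1L)
  oob_n <- pmax(colSums(oob), 1L)
  acc0 <- colSums(correct0 & oob) / oob_n
  perm_idx <- withr::with_seed(seed, {
    purrr::map(seq_along(model$feature_names), function(j) {
      purrr::map(seq_len(K), ~ sample.int(nrow(X)))
    })
  })
  tree_block <- rep_len(seq_len(K), ntree)  # permutation replicate per tree
  z <- vapply(seq_along(model$feature_names), function(j) {
    accj <- numeric(ntree)
    for (k in seq_len(K)) {
      Xp <- X
      Xp[[j]] <- Xp[[j]][perm_idx[[j]][[k]]]
      pred <- stats::predict(model$fit, data = as.data.frame(Xp),
                             predict.all = TRUE, num.threads = 1)$predictions
      sel <- tree_block == k
      accj[sel] <- (colSums((pred == (y + 1L)) & oob) / oob_n)[sel]
    }
    loss <- acc0 - accj
    s <- stats::sd(loss)
    if (s == 0) {
      if (mean(loss) == 0) 0 else sign(mean(loss)) * Inf
    } else {
      mean(loss) / (s / sqrt(ntree))
    }
  }, numeric(1))
  stats::setNames(z, model$feature_names)
}

#' All-relevant feature selection against shadow features
#'
#' Runs up to `max_rounds` rounds. Each round appends freshly permuted
#' shadow columns, trains a forest, computes out-of-bag permutation
#' importance z-scores, and records a hit for every real feature whose z
#' exceeds the best shadow z. After each round, each undecided feature's
#' hit count is tested two-sidedly against Binomial(rounds, 0.5) with
#' Bonferroni correction over the currently undecided features:
#' significantly high goes to `Important`, significantly low to
#' `Unimportant`; decided features are (by default) removed and shadows
#' rebuilt. Whatever is undecided when rounds run out is `Tentative`.
#'
#' @param X Feature tibble.
#' @param y Binary labels (balanced upstream).
#' @param max_rounds Maximum rounds (default 100).
#' @param alpha Significance level before Bonferroni (default 0.01).
#' @param seed Integer seed.
#' @param n_trees Trees per round's forest (default 100).
#' @param remove_decided Drop decided features from later rounds
#'   (default `TRUE`).
#' @param adjust_over Scope of the Bonferroni correction: `"all"`
#'   (default) divides alpha by the total feature count every round, as
#'   the classical algorithm does; `"undecided"` divides by the number
#'   of currently undecided features, which grows anticonservative late
#'   in a run as survivors face ever-looser thresholds under repeated
#'   testing.
#' @return A `boruta_report`: tibble with columns `feature`, `status`
#'   (`Important` / `Unimportant` / `Tentative`), `hits`,
#'   `rounds`, `z_mean`; attributes carry `alpha`, `max_rounds`, `seed`.
#' @export
boruta <- function(X, y, max_rounds = 100, alpha = 0.01, seed,
                   n_trees = 100, remove_decided = TRUE,
                   adjust_over = c("all", "undecided")) {
  adjust_over <- match.arg(adjust_over)
  X <- feature_frame(X)
  y <- as_binary_labels(y)
  features <- names(X)
  status <- stats::setNames(rep("Tentative", length(features)), features)
  hits <- stats::setNames(integer(length(features)), features)
  rounds_run <- stats::setNames(integer(length(features)), features)
  z_sum <- stats::setNames(numeric(length(features)), features)
  undecided <- features
  round_seeds <- derive_seeds(seed, max(3 * max_rounds, 3))
  completed <- 0L
  while (completed < max_rounds && length(undecided) > 0) {
    r <- completed + 1L
    Xr <- X[undecided]
    ext <- shadow_matrix(Xr, seed = round_seeds[3 * r - 2])
    model <- train_forest(ext, y, n_trees = n_trees,
                          seed = round_seeds[3 * r - 1] %% 2100000000L)
    z <- permutation_importance_z(model, ext, y,
                                  seed = round_seeds[3 * r])
    shadow_z <- z[startsWith(names(z), "shadow_")]
    real_z <- z[undecided]
    best_shadow <- max(shadow_z)
    hit <- real_z > best_shadow
    hits[undecided] <- hits[undecided] + as.integer(hit)
    rounds_run[undecided] <- r
    z_sum[undecided] <- z_sum[undecided] + real_z
    completed <- r
    # two-sided binomial decisions with Bonferroni correction
    m <- if (adjust_over == "all") length(features) else length(undecided)
    p_hi <- stats::pbinom(hits[undecided] - 1L, r, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[undecided], r, 0.5)
    p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
    sig <- p_two < alpha / m
    new_imp <- undecided[sig & p_hi < p_lo]
    new_unimp <- undecided[sig & p_lo <= p_hi]
    status[new_imp] <- "Important"
    status[new_unimp] <- "Unimportant"
    if (remove_decided) {
      undecided <- setdiff(undecided, c(new_imp, new_unimp))
    }
  }
  if (completed < 5) {
    warning("fewer than 5 rounds completed; all features left Tentative",
            call. = FALSE)
    status[] <- "Tentative"
  }
  out <- tibble::tibble(
    feature = features,
    status = unname(status[features]),
    hits = unname(hits[features]),
    rounds = unname(rounds_run[features]),
    z_mean = unname(ifelse(rounds_run[features] > 0,
                           z_sum[features] / rounds_run[features], 0))
  )
  structure(out, class = c("boruta_report", class(out)),
            alpha = alpha, max_rounds = max_rounds, seed = seed,
            rounds_completed = completed)
}

#' @export
print.boruta_report <- function(x, ...) {
  tab <- table(factor(x$status,
                      levels = c("Important", "Tentative", "Unimportant")))
  cat(sprintf(
    "Boruta report: %d features after %d rounds\n  Important: %d  Tentative: %d  Unimportant: %d\n",
    nrow(x), attr(x, "rounds_completed"), tab[["Important"]],
    tab[["Tentative"]], tab[["Unimportant"]]
  ))
  NextMethod()
}
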