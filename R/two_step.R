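#' Select predicted promoter windows from a prediction track
#'
#' Promoter predictions are the windows with score strictly above the
#' threshold that contain at least one TSS (half-open containment).
#' A uniform seeded subsample of `n` windows is returned (all of them if
#' fewer qualify).
#'
#' @param track `prediction_track` from a first-step classifier.
#' @param tss TSS tibble (`chrom`, `pos`, `strand`).
#' @param score_threshold Strict score cutoff (default 0.8).
#' @param n Subsample size (default 50).
#' @param seed Seed for the subsample.
#' @return Interval tibble of selected promoter windows.
#' @export
select_promoter_windows <- function(track, tss, score_threshold = 0.8,
                                    n = 50, seed) {
  qual <- track[track$score > score_threshold &
                  count_points_in(track, tss) > 0, , drop = FALSE]
  if (nrow(qual) == 0) {
    stop("no windows qualify as promoter predictions", call. = FALSE)
  }
  if (nrow(qual) > n) {
    idx <- withr::with_seed(seed, sort(sample.int(nrow(qual), n)))
    qual <- qual[idx, , drop = FALSE]
  }
  qual
}

#' Adjust interval lengths about their midpoints
#'
#' Each interval is extended or shrunken to exactly `target` bases while
#' keeping its midpoint (`floor((start + end) / 2)`), up to the 1-base
#' shift forced by parity. Intervals running off a chromosome edge are
#' shifted inward, preserving length.
#'
#' @param intervals Interval tibble.
#' @param target Target length in bp (default 1500).
#' @param chrom_lengths Named vector of chromosome lengths (for edge
#'   clamping; optional, no upper clamp when missing).
#' @return Interval tibble of the same rows, all of width `target`.
#' @export
normalize_length <- function(intervals, target = 1500,
                             chrom_lengths = NULL) {
  stopifnot(target >= 1)
  mid <- (intervals$start + intervals$end) %/% 2L
  start <- mid - target %/% 2L
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    maxlen <- chrom_lengths[intervals$chrom]
    if (any(is.na(maxlen))) {
      stop("chromosome length missing for some intervals", call. = FALSE)
    }
    if (any(maxlen < target)) {
      stop("chromosome shorter than target length", call. = FALSE)
    }
    start <- pmin(start, as.integer(maxlen) - as.integer(target))
  }
  out <- intervals
  out$start <- as.integer(start)
  out$end <- as.integer(start + target)
  validate_intervals(out)
}

#' Train the anti-promoter filter forest
#'
#' The second-step classifier of the two-step design: random genomic
#' sequences are the POSITIVE class and predicted promoter windows the
#' NEGATIVE class, so a high score means "not promoter-like". Both sets
#' are length-normalized to `target_length` about their midpoints,
#' featurized with k-mers only, balanced, and fit with [train_forest()].
#'
#' @param random_intervals Interval tibble of random sequences.
#' @param promoter_windows Interval tibble of predicted promoters.
#' @param genome Genome tibble.
#' @param k k-mer length (default 4).
#' @param seed Integer seed.
#' @param n_trees Trees (default 100).
#' @param target_length Normalized sequence length (default 1500).
#' @return An `rf_model` scoring "random-like" (anti-promoter) as 1.
#' @export
train_promoter_filter <- function(random_intervals, promoter_windows,
                                  genome, k = 4, seed, n_trees = 100,
                                  target_length = 1500) {
  chrom_lengths <- stats::setNames(nchar(genome$sequence), genome$id)
  rnd <- normalize_length(random_intervals, target_length, chrom_lengths)
  prm <- normalize_length(promoter_windows, target_length, chrom_lengths)
  bal <- balance_sets(rnd, prm, seed = seed)
  fm_rnd <- build_feature_matrix(bal$pos, genome, tracks = NULL, k = k)
  fm_prm <- build_feature_matrix(bal$neg, genome, tracks = NULL, k = k)
  X <- dplyr::bind_rows(fm_rnd, fm_prm)
  y <- c(rep(1L, nrow(fm_rnd)), rep(0L, nrow(fm_prm)))
  train_forest(X, y, n_trees = n_trees, seed = seed)
}

#' Bundle an enhancer model and a promoter filter into a two-step model
#'
#' @param enhancer_model `rf_model` trained enhancer-vs-random.
#' @param promoter_filter `rf_model` trained random-vs-promoter (from
#'   [train_promoter_filter()]).
#' @return A `two_step_model` object.
#' @export
two_step_model <- function(enhancer_model, promoter_filter) {
  stopifnot(inherits(enhancer_model, "rf_model"),
            inherits(promoter_filter, "rf_model"))
  structure(list(enhancer_model = enhancer_model,
                 promoter_filter = promoter_filter),
            class = "two_step_model")
}

#' Combined two-step score
#'
#' Elementwise product of the enhancer score and the anti-promoter
#' score: a sequence scores high only if it resembles the enhancers AND
#' does not resemble the promoters. The product is always at most the
#' smaller of the two component scores.
#'
#' @param model `two_step_model`.
#' @param X Feature matrix compatible with both component models (the
#'   promoter filter uses its own, k-mer-only, column subset).
#' @return Numeric score vector in `[0, 1]`.
#' @export
combined_score <- function(model, X) {
  predict_scores(model$enhancer_model, X) *
    predict_scores(model$promoter_filter, X)
}
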