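#' Tile a genome into overlapping windows
#'
#' Per chromosome, windows start at `0, step, 2*step, ...` while
#' `start + length` fits on the chromosome. Windows containing at least
#' one `N` are dropped.
#'
#' @param genome Genome tibble (`id`, `sequence`).
#' @param length Window length in bp (default 1500).
#' @param step Distance between window starts in bp (default 750).
#' @return Interval tibble of retained windows, sorted by (chrom, start).
#' @export
make_windows <- function(genome, length = 1500, step = 750) {
  stopifnot(length >= 1, step >= 1)
  out <- purrr::map(seq_len(nrow(genome)), function(i) {
    L <- nchar(genome$sequence[i])
    if (L < length) return(NULL)
    starts <- seq.int(0L, L - length, by = step)
    w <- interval_tbl(genome$id[i], starts, starts + length)
    sq <- Biostrings::DNAString(genome$sequence[i])
    n_in_window <- Biostrings::letterFrequency(
      Biostrings::Views(sq, start = starts + 1L, end = starts + length), "N"
    )[, 1]
    w[n_in_window == 0, , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Score every genome window with a trained forest
#'
#' Builds the window feature matrix ([build_feature_matrix()]) and scores
#' it with [predict_scores()]. The result is a prediction track: windows
#' plus voting-fraction scores, serializable as 5-column BED via
#' [write_bed()].
#'
#' @param model `rf_model` (its feature names must be producible from
#'   `k` and `tracks`).
#' @param genome Genome tibble.
#' @param tracks Named list of signal tracks (or `NULL` for k-mer-only
#'   models).
#' @param k k-mer length used by the model (default 4).
#' @param window_length,step Window geometry (defaults 1500 / 750).
#' @return Interval tibble of windows with a `score` column in `[0, 1]`,
#'   class `prediction_track`.
#' @export
scan_genome <- function(model, genome, tracks = NULL, k = 4,
                        window_length = 1500, step = 750) {
  windows <- make_windows(genome, length = window_length, step = step)
  if (nrow(windows) == 0) {
    out <- windows
    out$score <- numeric(0)
    return(structure(out, class = c("prediction_track", class(out))))
  }
  fm <- build_feature_matrix(windows, genome, tracks, k = k)
  windows$score <- predict_scores(model, fm)
  structure(windows, class = c("prediction_track", class(windows)))
}

#' Partition window predictions by DHS-cluster overlap
#'
#' A window belongs to the DHS group iff its total overlap with the
#' cluster set is at least `min_overlap` bases; all other windows are
#' non-DHS. Windows containing at least one TSS are removed from both
#' groups. Optionally each group is subsampled to `n` windows (uniformly,
#' seeded), and the comparison can be restricted to one chromosome.
#'
#' @param track `prediction_track` (windows with scores).
#' @param clusters Interval tibble of DHS clusters.
#' @param min_overlap Minimum overlap in bases (default 100).
#' @param tss TSS tibble (`chrom`, `pos`, `strand`) or `NULL`.
#' @param n Optional per-group subsample size.
#' @param seed Seed for the subsample (required when `n` is given).
#' @param chrom Optional chromosome filter.
#' @return List with `dhs_scores` and `non_dhs_scores` numeric vectors.
#' @export
overlap_partition <- function(track, clusters, min_overlap = 100,
                              tss = NULL, n = NULL, seed = NULL,
                              chrom = NULL) {
  if (!is.null(chrom)) track <- track[track$chrom %in% chrom, , drop = FALSE]
  if (!is.null(tss) && nrow(track) > 0) {
    track <- track[count_points_in(track, tss) == 0, , drop = FALSE]
  }
  ov <- total_overlap_bp(track, clusters)
  dhs <- track$score[ov >= min_overlap]
  non <- track$score[ov < min_overlap]
  if (!is.null(n)) {
    stopifnot(!is.null(seed))
    withr::with_seed(seed, {
      if (length(dhs) > n) dhs <- sample(dhs, n)
      if (length(non) > n) non <- sample(non, n)
    })
  }
  list(dhs_scores = dhs, non_dhs_scores = non)
}

#' Partition windows by chromatin-signal extremes
#'
#' The DHS set is the `n` windows with the highest aggregate (summed)
#' signal; the non-DHS set is a uniform sample of `n` windows from those
#' whose maximum per-base signal is strictly below `max_threshold`. Ties
#' at the top-n boundary are broken by (chrom, start).
#'
#' @param windows Interval tibble of candidate windows.
#' @param signal `signal_track` (e.g. DNase signal).
#' @param n Windows per set (default 1000).
#' @param max_threshold Strict upper bound on max per-base signal for
#'   non-DHS eligibility (default 10).
#' @param seed Seed for the non-DHS draw.
#' @return List with `dhs_windows` and `non_dhs_windows` interval
#'   tibbles.
#' @export
top_signal_partition <- function(windows, signal, n = 1000,
                                 max_threshold = 10, seed) {
  agg <- aggregate_signal(windows, signal)
  mx <- max_signal(windows, signal)
  if (nrow(windows) < n) {
    stop(sprintf("only %d windows available for a DHS set of %d",
                 nrow(windows), n), call. = FALSE)
  }
  ord <- order(-agg, windows$chrom, windows$start)
  dhs <- windows[ord[seq_len(n)], , drop = FALSE]
  eligible <- which(mx < max_threshold)
  if (length(eligible) < n) {
    stop(sprintf(
      "only %d windows with max signal < %s available for a non-DHS set of %d",
      length(eligible), format(max_threshold), n
    ), call. = FALSE)
  }
  non_idx <- withr::with_seed(seed, sample(eligible, n))
  list(dhs_windows = dhs,
       non_dhs_windows = windows[sort(non_idx), , drop = FALSE])
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Normal approximation with tie correction (the default of
#' [stats::wilcox.test()] for samples with ties / moderate n).
#'
#' @param scores_a,scores_b Numeric vectors (both nonempty).
#' @return A list with `statistic` (U for the first sample) and
#'   `p_value`.
#' @export
rank_sum_test <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(scores_a, scores_b))) == 1) {
    # all values tied: no evidence of a shift
    return(list(statistic = length(scores_a) * length(scores_b) / 2,
                p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    scores_a, scores_b, exact = FALSE, correct = TRUE
  ))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' TSS-proximal enrichment of high-scoring windows
#'
#' High-score windows (score strictly above `score_threshold`) are
#' classified as TSS-proximal iff they intersect the
#' `proximal_distance`-base interval immediately upstream of any TSS
#' (strand-aware: upstream means lower coordinates for `+`, higher for
#' `-`). Returns the proximal fraction and the one-sided binomial tail
#' probability of at least the observed count under `baseline_fraction`.
#' Because real-scale scans make this tail smaller than the smallest
#' positive double, the log10 p-value is also returned.
#'
#' @param track `prediction_track`.
#' @param tss TSS tibble (`chrom`, `pos`, `strand`).
#' @param score_threshold High-score cutoff, strict (default 0.8).
#' @param proximal_distance Upstream distance in bp (default 1500).
#' @param baseline_fraction Expected proximal fraction under the null,
#'   e.g. measured on the random training set.
#' @return List with `n_high`, `n_proximal`, `fraction`, `p_value`,
#'   `log10_p`.
#' @export
tss_proximal_enrichment <- function(track, tss, score_threshold = 0.8,
                                    proximal_distance = 1500,
                                    baseline_fraction) {
  stopifnot(baseline_fraction > 0, baseline_fraction < 1)
  high <- track[track$score > score_threshold, , drop = FALSE]
  if (nrow(high) == 0) stop("no windows above the score threshold",
                            call. = FALSE)
  prox <- is_tss_proximal(high, tss, proximal_distance)
  binomial_enrichment(sum(prox), nrow(high), baseline_fraction)
}

# TRUE for windows intersecting the upstream interval of any TSS
is_tss_proximal <- function(windows, tss, proximal_distance) {
  up_start <- ifelse(tss$strand == "-", tss$pos + 1L,
                     tss$pos - proximal_distance)
  up_end <- ifelse(tss$strand == "-", tss$pos + 1L + proximal_distance,
                   tss$pos)
  up_start <- pmax(up_start, 0L)
  keep <- up_end > up_start
  upstream <- tibble::tibble(chrom = tss$chrom[keep],
                             start = as.integer(up_start[keep]),
                             end = as.integer(up_end[keep]))
  overlaps_any(windows, upstream)
}

# one-sided binomial tail P(X >= k | n, p0), computed on the log scale so
# enrichments far beyond double underflow still report a finite log10 p
binomial_enrichment <- function(k, n, p0) {
  log_p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  list(
    n_high = n, n_proximal = k, fraction = k / n,
    p_value = exp(log_p), log10_p = log_p / log(10)
  )
}
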