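#' Tissue specifications for positive-set selection
#'
#' A tissue spec names the tissue terms whose presence includes an element
#' and whose presence excludes it. The built-in specs encode the
#' heart/brain dichotomy: heart = heart activity (among others) but no
#' brain-related activity; brain = activity in at least one of hindbrain,
#' midbrain, forebrain, neural tube, cranial nerve, but no heart activity;
#' nonspecific = the union of the two.
#'
#' @param name One of `"heart"`, `"brain"`, `"nonspecific"`, or
#'   `"custom"`.
#' @param include,exclude Character vectors of tissue terms (used for
#'   `"custom"`; ignored otherwise).
#' @return A `tissue_spec` list with elements `name`, `include`,
#'   `exclude`.
#' @export
tissue_spec <- function(name, include = NULL, exclude = NULL) {
  brain_terms <- c("hindbrain", "midbrain", "forebrain", "neural tube",
                   "cranial nerve")
  spec <- switch(name,
    heart = list(include = "heart", exclude = brain_terms),
    brain = list(include = brain_terms, exclude = "heart"),
    nonspecific = list(include = NULL, exclude = NULL),
    custom = list(include = tolower(include), exclude = tolower(exclude)),
    stop("unknown tissue spec '", name, "'", call. = FALSE)
  )
  if (length(intersect(spec$include, spec$exclude)) > 0) {
    stop("include and exclude terms must be disjoint", call. = FALSE)
  }
  structure(c(list(name = name), spec), class = "tissue_spec")
}

#' Select a positive training set by tissue activity
#'
#' An element is kept iff it is active, its tissue set intersects the
#' spec's include terms, and it shares no term with the exclude terms.
#' The nonspecific set is the union of the heart- and brain-selected
#' elements, deduplicated by id.
#'
#' @param elements Annotation tibble (interval columns, `id`, `active`,
#'   list column `tissues`).
#' @param spec A [tissue_spec()] or a spec name.
#' @return Tibble of selected elements, input order preserved.
#' @export
select_positive_set <- function(elements, spec) {
  if (is.character(spec)) spec <- tissue_spec(spec)
  if (identical(spec$name, "nonspecific")) {
    heart <- select_positive_set(elements, tissue_spec("heart"))
    brain <- select_positive_set(elements, tissue_spec("brain"))
    return(dplyr::distinct(dplyr::bind_rows(heart, brain), .data$id,
                           .keep_all = TRUE))
  }
  keep <- purrr::map_lgl(seq_len(nrow(elements)), function(i) {
    ts <- elements$tissues[[i]]
    elements$active[i] &&
      length(intersect(ts, spec$include)) > 0 &&
      length(intersect(ts, spec$exclude)) == 0
  })
  elements[keep, , drop = FALSE]
}

#' Fit a negative-binomial length distribution by moment matching
#'
#' Matches the negative binomial's mean and variance to the sample
#' moments: `size r = m^2 / (v - m)`, `prob p = m / v`. Requires
#' overdispersion (`v > m`); on equi- or under-dispersed lengths the
#' caller should fall back to bootstrap resampling of the empirical
#' lengths (see [sample_negative_set()]).
#'
#' @param lengths Numeric vector of at least 2 element lengths.
#' @return A list with `size`, `prob`, `mean`, `variance` (class
#'   `nb_params`).
#' @export
#' @examples
#' fit_length_distribution(c(1200, 1500, 2100, 900, 1800))
fit_length_distribution <- function(lengths) {
  if (length(lengths) < 2) stop("need at least 2 lengths", call. = FALSE)
  m <- mean(lengths)
  v <- stats::var(lengths)
  if (v <= m) {
    stop(sprintf(
      paste0("lengths are not overdispersed (variance %.3f <= mean %.3f); ",
             "a negative binomial cannot be moment-matched - fall back to ",
             "bootstrap resampling of the empirical lengths"), v, m
    ), call. = FALSE)
  }
  structure(
    list(size = m^2 / (v - m), prob = m / v, mean = m, variance = v),
    class = "nb_params"
  )
}

# Draw n lengths from fitted NB params (or bootstrap the empirical
# lengths when NULL), truncated to [min_len, max_len].
draw_lengths <- function(n, params, empirical, min_len, max_len) {
  raw <- if (is.null(params)) {
    sample(empirical, n, replace = TRUE)
  } else {
    stats::rnbinom(n, size = params$size, prob = params$prob)
  }
  pmin(pmax(raw, min_len), max_len)
}

#' Chromatin-coverage filter for candidate negatives
#'
#' A candidate interval fails when the number of tracks covering less
#' than `min_fraction` of its bases with positive signal exceeds
#' `max_failing` of all tracks (defaults: less than 10% of signal in more
#' than a quarter of the tracks). With no tracks the filter passes
#' vacuously.
#'
#' @param intervals Interval tibble.
#' @param tracks Named list of `signal_track` objects (possibly empty).
#' @param min_fraction Coverage fraction below which a track counts as
#'   failing (default 0.10).
#' @param max_failing Fraction of tracks that may fail before the
#'   candidate is rejected (default 0.25, strict inequality).
#' @return Logical vector, `TRUE` where the interval passes.
#' @export
passes_signal_filter <- function(intervals, tracks, min_fraction = 0.10,
                                 max_failing = 0.25) {
  if (is.null(tracks) || length(tracks) == 0) {
    return(rep(TRUE, nrow(intervals)))
  }
  failing <- rowSums(vapply(
    tracks,
    function(tr) covered_fraction(intervals, tr) < min_fraction,
    logical(nrow(intervals))
  ) |> matrix(nrow = nrow(intervals)))
  failing <= max_failing * length(tracks)
}

#' Sample a matched random negative set
#'
#' Negatives preserve the chromosome and length distribution of the
#' positive set: each candidate's chromosome is drawn from the positives'
#' empirical chromosome frequencies, its length from the moment-matched
#' negative binomial of the positive lengths (bootstrap fallback when not
#' overdispersed), truncated to fit the chromosome, and its start
#' uniformly. Candidates containing any `N`, overlapping a positive
#' element, or failing [passes_signal_filter()] are rejected and redrawn.
#'
#' @param genome Genome tibble (`id`, `sequence`).
#' @param positives Interval tibble of positive elements.
#' @param tracks Named list of signal tracks for the coverage filter
#'   (`NULL` to skip it).
#' @param n Number of negatives to sample.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param min_length Lower truncation for drawn lengths (default 50).
#' @param exclude_overlap Reject candidates overlapping the exclusion
#'   set (default `TRUE`).
#' @param exclude Interval tibble of regions negatives must not overlap
#'   (default: the positives themselves). Passing the full annotation
#'   keeps every tested element - positive or not - out of the random
#'   set.
#' @param max_tries Retry budget (default `1000 * n`).
#' @return Interval tibble of `n` accepted negatives with ids
#'   `neg_1..neg_n`.
#' @export
sample_negative_set <- function(genome, positives, tracks = NULL, n,
                                seed, min_length = 50L,
                                exclude_overlap = TRUE,
                                exclude = positives,
                                max_tries = 1000 * n) {
  stopifnot(n >= 1, nrow(positives) >= 1)
  pos_lengths <- interval_width(positives)
  params <- tryCatch(fit_length_distribution(pos_lengths),
                     error = function(e) NULL)
  chrom_len <- stats::setNames(nchar(genome$sequence), genome$id)
  chrom_tab <- table(positives$chrom)
  chrom_pool <- names(chrom_tab)
  chrom_prob <- as.numeric(chrom_tab) / sum(chrom_tab)
  has_n <- function(ch, s, e) {
    # any N within [s, e): check against precomputed N positions
    v <- n_pos[[ch]]
    length(v) > 0 && any(v >= s & v < e)
  }
  n_pos <- lapply(stats::setNames(genome$id, genome$id), function(ch) {
    s <- genome$sequence[genome$id == ch][1]
    as.integer(gregexpr("N", s, fixed = TRUE)[[1]]) - 1L
  })
  n_pos <- lapply(n_pos, function(v) v[v >= 0])

  withr::with_seed(seed, {
    accepted <- list()
    tries <- 0L
    batch <- max(64L, 2L * n)
    while (length(accepted) < n && tries < max_tries) {
      m <- min(batch, max_tries - tries)
      tries <- tries + m
      ch <- sample(chrom_pool, m, replace = TRUE, prob = chrom_prob)
      len <- draw_lengths(m, params, pos_lengths, min_length,
                          max_len = chrom_len[ch])
      start <- floor(stats::runif(m, 0, chrom_len[ch] - len + 1))
      cand <- interval_tbl(ch, start, start + len)
      ok <- !purrr::pmap_lgl(
        list(cand$chrom, cand$start, cand$end), has_n
      )
      if (exclude_overlap && any(ok)) {
        ok[ok] <- !overlaps_any(cand[ok, , drop = FALSE], exclude)
      }
      if (!is.null(tracks) && length(tracks) > 0 && any(ok)) {
        ok[ok] <- passes_signal_filter(cand[ok, , drop = FALSE], tracks)
      }
      accepted <- c(accepted, split(cand[ok, , drop = FALSE],
                                    seq_len(sum(ok))))
    }
    if (length(accepted) < n) {
      stop(sprintf(
        "negative sampling exhausted %d tries with %d accepted (rate %.3f)",
        tries, length(accepted), length(accepted) / tries
      ), call. = FALSE)
    }
    out <- dplyr::bind_rows(accepted[seq_len(n)])
    out$id <- sprintf("neg_%d", seq_len(n))
    out
  })
}
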