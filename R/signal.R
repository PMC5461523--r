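# Signal-track queries.
#
# A signal_track is a sorted tibble of disjoint constant segments
# (chrom, start, end, value) with implicit 0 outside coverage. All queries
# below are exact on the piecewise-constant model and vectorized over
# query intervals via per-chromosome prefix sums.

# Prefix-sum machinery: for one chromosome's segments, S(x) = integral of
# f over [0, x). Evaluated by locating x among segment boundaries.
chrom_prefix <- function(seg) {
  list(
    start = seg$start, end = seg$end, value = seg$value,
    cum = c(0, cumsum(seg$value * (seg$end - seg$start)))
  )
}

prefix_eval <- function(pf, x) {
  # integral of the track from 0 to x
  i <- findInterval(x, pf$start)          # last segment with start <= x
  out <- pf$cum[i + 1L]
  sel <- which(i > 0)
  if (length(sel) > 0) {
    ii <- i[sel]
    # subtract the part of segment i beyond x (when x falls inside it)
    out[sel] <- out[sel] - pf$value[ii] * pmax(0, pf$end[ii] - x[sel])
  }
  out
}

split_track <- function(track) {
  split(tibble::as_tibble(track), track$chrom)
}

# Generic per-interval reduction over a track: fun(prefix, starts, ends)
query_track <- function(intervals, track, fun, default = 0) {
  out <- rep(default, nrow(intervals))
  if (is.null(track) || nrow(track) == 0 || nrow(intervals) == 0) return(out)
  by_chrom <- split_track(track)
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    seg <- by_chrom[[ch]]
    if (is.null(seg)) next
    pf <- chrom_prefix(seg)
    out[qi] <- fun(pf, intervals$start[qi], intervals$end[qi])
  }
  out
}

#' Aggregate (summed) signal over intervals
#'
#' Sum of the per-base signal over each interval, with uncovered bases
#' contributing 0.
#'
#' @param intervals Interval tibble.
#' @param track `signal_track` tibble.
#' @return Numeric vector, one value per interval.
#' @export
aggregate_signal <- function(intervals, track) {
  query_track(intervals, track, function(pf, s, e) {
    prefix_eval(pf, e) - prefix_eval(pf, s)
  })
}

#' Mean signal over intervals
#'
#' Length-weighted mean of the piecewise-constant signal over each
#' interval `[start, end)`; positions outside track coverage count as 0.
#' Intervals on chromosomes absent from the track get mean 0 with a
#' warning.
#'
#' @inheritParams aggregate_signal
#' @return Numeric vector of means, one per interval.
#' @export
mean_signal <- function(intervals, track) {
  missing_chrom <- setdiff(unique(intervals$chrom), unique(track$chrom))
  if (length(missing_chrom) > 0) {
    warning("chromosome(s) absent from signal track: ",
            paste(missing_chrom, collapse = ", "), "; mean signal is 0 there",
            call. = FALSE)
  }
  aggregate_signal(intervals, track) / interval_width(intervals)
}

#' Fraction of bases with positive signal over intervals
#'
#' @inheritParams aggregate_signal
#' @return Numeric vector in `[0, 1]`, one value per interval.
#' @export
covered_fraction <- function(intervals, track) {
  pos <- track[track$value > 0, , drop = FALSE]
  if (nrow(pos) > 0) {
    pos$value <- 1
    pos <- signal_track(pos)
  }
  query_track(intervals, pos, function(pf, s, e) {
    prefix_eval(pf, e) - prefix_eval(pf, s)
  }) / interval_width(intervals)
}

#' Maximum per-base signal over intervals
#'
#' @inheritParams aggregate_signal
#' @return Numeric vector of per-interval maxima (0 where uncovered).
#' @export
max_signal <- function(intervals, track) {
  out <- numeric(nrow(intervals))
  if (nrow(track) == 0 || nrow(intervals) == 0) return(out)
  by_chrom <- split_track(track)
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    seg <- by_chrom[[ch]]
    if (is.null(seg)) next
    # index range of segments overlapping [s, e): starts < e and ends > s
    lo <- findInterval(intervals$start[qi], seg$end) + 1L  # first seg with end > s
    hi <- findInterval(intervals$end[qi] - 1e-9, seg$start)  # last seg with start < e
    for (j in seq_along(qi)) {
      if (lo[j] > hi[j]) next
      mx <- max(seg$value[lo[j]:hi[j]])
      # uncovered gaps inside the interval imply a 0 floor, but max of
      # nonnegative values is unaffected
      out[qi[j]] <- mx
    }
  }
  out
}
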