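#' Build a genomic-interval tibble
#'
#' Intervals are the package's coordinate currency: a tibble with columns
#' `chrom`, `start`, `end` and optionally `id`, `strand`, `score`.
#' Coordinates follow the BED convention everywhere: 0-based, half-open
#' `[start, end)`.
#'
#' @param chrom Character vector of chromosome names (nonempty strings).
#' @param start,end Integer-like vectors; `0 <= start < end`.
#' @param id Optional character vector of element ids.
#' @param strand Optional strand vector; values in `"+", "-", "*"`
#'   (`"*"` = unknown).
#' @param score Optional numeric score column.
#' @return A tibble with one row per interval.
#' @export
#' @examples
#' interval_tbl("chr1", 0, 1500)
interval_tbl <- function(chrom, start, end, id = NULL, strand = NULL,
                         score = NULL) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  )
  if (!is.null(id)) out$id <- as.character(id)
  if (!is.null(strand)) out$strand <- as.character(strand)
  if (!is.null(score)) out$score <- as.numeric(score)
  validate_intervals(out)
}

#' Validate an interval tibble
#'
#' Checks the interval invariants (`0 <= start < end`, nonempty `chrom`,
#' strand in `+`/`-`/`*`) and returns the input invisibly unchanged.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return `x`, as a tibble.
#' @export
validate_intervals <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval chrom must be a nonempty string", call. = FALSE)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid interval at row %d: need 0 <= start < end, got [%s, %s)",
      bad[1], x$start[bad[1]], x$end[bad[1]]
    ), call. = FALSE)
  }
  if ("strand" %in% names(x) &&
      !all(x$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'", call. = FALSE)
  }
  x
}

# interval widths
interval_width <- function(x) x$end - x$start

# sort by (chrom, start, end) -- the package's canonical order
sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# Total per-query overlap (in bases) between query intervals and a subject
# interval set, via IRanges. Returns a vector aligned with rows of `query`.
total_overlap_bp <- function(query, subject) {
  out <- numeric(nrow(query))
  if (nrow(subject) == 0 || nrow(query) == 0) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    sr <- IRanges::reduce(sr)
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[qi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

# TRUE for each query interval that overlaps any subject interval by >= 1 bp
overlaps_any <- function(query, subject) {
  total_overlap_bp(query, subject) > 0
}

# Count of points (chrom, pos; 0-based) contained in each query interval
count_points_in <- function(query, points) {
  out <- integer(nrow(query))
  if (nrow(points) == 0 || nrow(query) == 0) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    pi <- which(points$chrom == ch)
    if (length(pi) == 0) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    pr <- IRanges::IRanges(start = points$pos[pi] + 1L, width = 1L)
    out[qi] <- out[qi] + IRanges::countOverlaps(qr, pr)
  }
  out
}
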