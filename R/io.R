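#' Read a FASTA file into a genome tibble
#'
#' Sequences are uppercased and any character outside `A,C,G,T,N` is
#' replaced by `N` (with a warning), mirroring how downstream k-mer
#' counting treats ambiguity: only `N` is recognized as ambiguous.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header up to first whitespace) and
#'   `sequence` (uppercase character).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  sq <- toupper(as.character(seqs))
  n_amb <- sum(vapply(sq, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_amb > 0) {
    warning(sprintf(
      "%d non-ACGTN characters mapped to N while reading %s", n_amb, path
    ), call. = FALSE)
    sq <- gsub("[^ACGTN]", "N", sq)
  }
  tibble::tibble(id = ids, sequence = unname(sq))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::BStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED file
#'
#' Accepts 3+ tab-separated columns following the BED convention (0-based,
#' half-open). Column 4 becomes `id` and column 6 `strand` when present.
#'
#' @param path Path to a BED file.
#' @return Interval tibble in file order; `score` column when a numeric
#'   column 5 is present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(interval_tbl(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which.min(lengths(fields))), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop(sprintf("BED parse error at line %d: invalid coordinates '%s'",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (ncol_min >= 4) out$id <- vapply(fields, `[[`, "", 4L)
  if (ncol_min >= 5) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (ncol_min >= 6) {
    strand <- vapply(fields, `[[`, "", 6L)
    strand[!strand %in% c("+", "-")] <- "*"
    out$strand <- strand
  }
  validate_intervals(out)
}

#' Write intervals (optionally with scores) as BED
#'
#' Coordinates round-trip exactly through [read_bed()]. When a `score`
#' column is present it is written to BED column 5 with 6 decimal places;
#' scores must lie in `[0, 1]`.
#'
#' @param x Interval tibble (columns `chrom`, `start`, `end`, optional
#'   `id`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  has_score <- "score" %in% names(x)
  has_strand <- "strand" %in% names(x)
  if (has_score && nrow(x) > 0 &&
      (min(x$score) < 0 || max(x$score) > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  id <- if ("id" %in% names(x)) x$id else {
    sprintf("%s:%d-%d", x$chrom, x$start, x$end)
  }
  cols <- list(x$chrom, x$start, x$end)
  if (has_score || has_strand) {
    cols <- c(cols, list(id, if (has_score) sprintf("%.6f", x$score) else "0"))
  } else if ("id" %in% names(x)) {
    cols <- c(cols, list(id))
  }
  if (has_strand) cols <- c(cols, list(x$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signal track (bedGraph or fixedStep wiggle)
#'
#' The track is a piecewise-constant nonnegative signal; positions not
#' covered by any segment read as 0. Overlapping segments and negative
#' values are rejected.
#'
#' @param path Path to a bedGraph (`chrom start end value`) or fixedStep
#'   WIG file.
#' @return A signal-track tibble with columns `chrom`, `start`, `end`,
#'   `value`, sorted by (chrom, start), with class `signal_track`.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (any(grepl("^fixedStep", lines))) {
    seg <- parse_fixedstep(lines)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 4)
    if (length(bad) > 0) {
      stop(sprintf("bedGraph parse error at line %d: need 4 columns", bad[1]),
           call. = FALSE)
    }
    seg <- tibble::tibble(
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 2L)),
      end = as.integer(vapply(fields, `[[`, "", 3L)),
      value = as.numeric(vapply(fields, `[[`, "", 4L))
    )
  }
  signal_track(seg)
}

# fixedStep blocks: "fixedStep chrom=<c> start=<1-based> step=<s> [span=<w>]"
parse_fixedstep <- function(lines) {
  hdr <- grepl("^fixedStep", lines)
  block <- cumsum(hdr)
  if (block[1] == 0) stop("fixedStep file must start with a header", call. = FALSE)
  segs <- lapply(split(seq_along(lines), block), function(idx) {
    h <- lines[idx[1]]
    get_kv <- function(key, default = NA) {
      m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
      if (length(m) == 0) return(default)
      sub(paste0(key, "="), "", m)
    }
    chrom <- get_kv("chrom")
    start1 <- as.integer(get_kv("start"))
    step <- as.integer(get_kv("step", "1"))
    span <- as.integer(get_kv("span", "1"))
    vals <- as.numeric(lines[idx[-1]])
    if (length(vals) == 0) return(NULL)
    starts0 <- start1 - 1L + step * (seq_along(vals) - 1L)
    tibble::tibble(chrom = chrom, start = starts0,
                   end = starts0 + span, value = vals)
  })
  dplyr::bind_rows(segs)
}

#' Construct a signal track from a segment table
#'
#' @param seg Data frame with columns `chrom`, `start`, `end`, `value`.
#' @return Sorted, validated `signal_track` tibble.
#' @export
signal_track <- function(seg) {
  seg <- validate_intervals(seg)
  stopifnot("value" %in% names(seg))
  if (any(is.na(seg$value))) stop("signal values must be numeric", call. = FALSE)
  if (any(seg$value < 0)) {
    stop(sprintf("signal parse error: negative value %s at row %d",
                 seg$value[which(seg$value < 0)[1]], which(seg$value < 0)[1]),
         call. = FALSE)
  }
  seg <- sort_intervals(seg)
  ov <- seg |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      overlap = any(.data$start[-1] < .data$end[-length(.data$end)]),
      .groups = "drop"
    )
  if (nrow(seg) > 1 && any(ov$overlap)) {
    stop("signal parse error: overlapping segments on ",
         ov$chrom[ov$overlap][1], call. = FALSE)
  }
  structure(seg, class = c("signal_track", class(seg)))
}

#' Write a signal track as bedGraph
#'
#' @param track `signal_track` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   formatC(track$value, format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tissue-activity annotation table
#'
#' The table is tab-separated with columns: chrom, start, end, element id,
#' activity flag (`1`/`0` or `positive`/`negative`), and a semicolon-joined
#' list of tissue terms (may be empty for inactive elements). Tissue terms
#' are lowercased and trimmed.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with interval columns, `id`, `active` (logical) and
#'   `tissues` (list column of character vectors).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5)
  if (length(bad) > 0) {
    stop(sprintf("annotation parse error at line %d: need >= 5 columns",
                 bad[1]), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop(sprintf("annotation parse error at line %d: invalid coordinates",
                 bad[1]), call. = FALSE)
  }
  flag <- tolower(vapply(fields, `[[`, "", 5L))
  active <- flag %in% c("1", "true", "positive", "yes")
  tissues <- lapply(fields, function(f) {
    if (length(f) < 6 || !nzchar(trimws(f[[6]]))) return(character())
    terms <- trimws(tolower(strsplit(f[[6]], ";", fixed = TRUE)[[1]]))
    sort(unique(terms[nzchar(terms)]))
  })
  active[lengths(tissues) == 0] <- FALSE
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end,
    id = vapply(fields, `[[`, "", 4L),
    active = active, tissues = tissues
  ) |> validate_intervals()
}

#' Write an annotation table
#'
#' @param elements Annotation tibble as returned by
#'   [read_annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(elements, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    elements$chrom, elements$start, elements$end, elements$id,
    as.integer(elements$active),
    vapply(elements$tissues, paste, "", collapse = ";")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table
#'
#' Accepts BED-like rows. For an interval row, the TSS position is the
#' start coordinate on the `+` strand and `end - 1` on the `-` strand;
#' a row whose interval has width 1 is treated as a point. Output is
#' sorted by (chrom, position).
#'
#' @param path Path to a BED-like TSS file (strand in column 6).
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`.
#' @export
read_tss_table <- function(path) {
  bed <- read_bed(path)
  strand <- if ("strand" %in% names(bed)) bed$strand else rep("+", nrow(bed))
  pos <- ifelse(strand == "-", bed$end - 1L, bed$start)
  tibble::tibble(chrom = bed$chrom, pos = as.integer(pos), strand = strand) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write a TSS table as 6-column BED points
#'
#' @param tss TSS tibble (`chrom`, `pos`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", tss$chrom, tss$pos, tss$pos + 1L,
                   sprintf("tss_%d", seq_len(nrow(tss))), tss$strand)
  writeLines(lines, path)
  invisible(path)
}
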