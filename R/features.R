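#' Build the element-by-feature matrix
#'
#' Rows are elements (input order preserved); columns are the canonical
#' k-mer frequencies followed by one mean-signal column per track, in the
#' order the track list is given. This is the feature representation the
#' forest classifiers train on: sequence composition plus chromatin
#' signal.
#'
#' @param elements Interval tibble; an `id` column is used for row ids
#'   (generated from coordinates otherwise).
#' @param genome Genome tibble (`id`, `sequence`) as from [read_fasta()].
#' @param tracks Named list of `signal_track` objects (may be empty or
#'   `NULL` for a k-mer-only matrix).
#' @param k k-mer word length (default 4).
#' @return A tibble: `element_id` column, then `(4^k - P)/2 + P` k-mer
#'   columns in `[0, 1]`, then one nonnegative column per track.
#' @export
build_feature_matrix <- function(elements, genome, tracks = NULL, k = 4) {
  elements <- validate_intervals(elements)
  alphabet <- canonical_kmers(k)
  ids <- if ("id" %in% names(elements)) elements$id else {
    sprintf("%s:%d-%d", elements$chrom, elements$start, elements$end)
  }
  chrom_len <- stats::setNames(nchar(genome$sequence), genome$id)
  missing <- setdiff(unique(elements$chrom), genome$id)
  if (length(missing) > 0) {
    stop("elements on chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  oob <- which(elements$end > chrom_len[elements$chrom])
  if (length(oob) > 0) {
    stop(sprintf("element '%s' extends beyond chromosome %s",
                 ids[oob[1]], elements$chrom[oob[1]]), call. = FALSE)
  }
  if (any(interval_width(elements) < k)) {
    stop("all elements must be at least k bases long", call. = FALSE)
  }

  km <- matrix(0, nrow = nrow(elements), ncol = length(alphabet),
               dimnames = list(NULL, alphabet))
  for (ch in unique(elements$chrom)) {
    idx <- which(elements$chrom == ch)
    seq_ch <- Biostrings::DNAString(genome$sequence[genome$id == ch][1])
    km[idx, ] <- kmer_frequency_matrix(
      seq_ch, elements$start[idx], elements$end[idx], alphabet
    )
  }
  out <- tibble::as_tibble(km)
  if (!is.null(tracks) && length(tracks) > 0) {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
      stop("tracks must be a named list", call. = FALSE)
    }
    for (nm in names(tracks)) {
      out[[nm]] <- mean_signal(elements, tracks[[nm]])
    }
  }
  dplyr::bind_cols(tibble::tibble(element_id = ids), out)
}

#' Extract the numeric feature columns of a feature matrix
#'
#' @param fm Feature matrix tibble from [build_feature_matrix()].
#' @return Tibble of numeric feature columns (no `element_id`).
#' @export
feature_columns <- function(fm) {
  fm[setdiff(names(fm), "element_id")]
}

#' Write / read a feature matrix as TSV
#'
#' @param fm Feature matrix tibble.
#' @param path File path.
#' @return `path` invisibly for the writer; the tibble for the reader.
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_tsv(fm, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
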