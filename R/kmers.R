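#' Reverse complement of DNA strings
#'
#' `N` maps to `N`; input must be over `A,C,G,T,N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Canonical k-mer alphabet
#'
#' Each k-mer over `A,C,G,T` is identified with its reverse complement;
#' the canonical representative is the alphabetically first of the pair,
#' i.e. the second alphabetical member of each reverse-complement pair is
#' excluded. For k = 4 this yields 136 features.
#'
#' @param k Word length, between 1 and 8.
#' @return Character vector of canonical k-mers, sorted alphabetically,
#'   of length `(4^k - P)/2 + P` where `P` is the number of
#'   reverse-complement palindromes (`4^(k/2)` for even k, 0 for odd k).
#' @export
#' @examples
#' length(canonical_kmers(4)) # 136
canonical_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 8 || k != round(k)) {
    stop("k must be an integer in [1, 8]", call. = FALSE)
  }
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  sort(unique(pmin(words, rc)))
}

#' Canonical k-mer frequencies of a sequence
#'
#' For each canonical k-mer, the frequency is the number of length-k
#' windows whose canonical form equals it (i.e. occurrences of the k-mer
#' or its reverse complement), divided by the full sequence length
#' (including `N` positions). Windows containing `N` are skipped and
#' contribute to no k-mer.
#'
#' @param sequence A single DNA string over `A,C,G,T,N` (or a
#'   `DNAString`).
#' @param k Word length, or a precomputed alphabet from
#'   [canonical_kmers()] via `alphabet`.
#' @param alphabet Optional canonical alphabet (character vector); defaults
#'   to `canonical_kmers(k)`.
#' @return Named numeric vector over the canonical alphabet.
#' @export
#' @examples
#' kmer_frequencies("ACGT", 2)[c("AC", "CG")] # 0.5, 0.25
kmer_frequencies <- function(sequence, k, alphabet = canonical_kmers(k)) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1)
  len <- nchar(sequence)
  if (len < k) stop("sequence shorter than k", call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k
  )
  fold_kmer_counts(counts, alphabet) / len
}

# Fold raw 4^k k-mer counts onto the canonical alphabet:
# canonical count = count(word) + count(revcomp) for non-palindromes,
# count(word) for palindromes.
fold_kmer_counts <- function(counts, alphabet) {
  words <- names(counts)
  rc <- kmer_rc_table(nchar(words[1]))[words]
  folded <- counts
  nonpal <- words != rc
  folded[nonpal] <- counts[nonpal] + counts[rc[nonpal]]
  folded[alphabet]
}

# memoized reverse-complement lookup per k
kmer_rc_env <- new.env(parent = emptyenv())
kmer_rc_table <- function(k) {
  key <- as.character(k)
  if (is.null(kmer_rc_env[[key]])) {
    words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)
    ))
    kmer_rc_env[[key]] <- stats::setNames(rc, words)
  }
  kmer_rc_env[[key]]
}

# Canonical k-mer frequency matrix for many windows over one chromosome
# sequence (a DNAString); rows = windows, columns = alphabet. Uses
# Biostrings views so genome scans do not materialize per-window strings.
kmer_frequency_matrix <- function(chrom_seq, starts0, ends0, alphabet) {
  k <- nchar(alphabet[1])
  v <- Biostrings::Views(chrom_seq, start = starts0 + 1L, end = ends0)
  counts <- Biostrings::oligonucleotideFrequency(v, width = k)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  words <- colnames(counts)
  rc <- kmer_rc_table(k)[words]
  nonpal <- words != rc
  counts[, nonpal] <- counts[, nonpal] + counts[, rc[nonpal]]
  counts[, alphabet, drop = FALSE] / (ends0 - starts0)
}
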