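# Shared fixtures and independent oracles for the test suite.
#
# Expensive objects (the default synthetic bundle and models trained on
# it) are built once per session and memoized in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the default study fixture: 2 Mb genome, 150 heart + 150 brain
# enhancers, 60 promoters (30 heart-active, 15 brain-active)
default_fixture <- function() {
  cached("fixture", generate_fixture(synth_config(seed = 7)))
}

# k-mer-only training matrix for one tissue on the default fixture;
# negatives avoid every planted element
tissue_training <- function(tissue, seed) {
  cached(paste0("train_", tissue), {
    fx <- default_fixture()
    pos <- select_positive_set(fx$elements, tissue)
    neg <- sample_negative_set(fx$genome, pos, NULL, n = nrow(pos),
                               seed = seed, exclude = fx$elements)
    fm_pos <- build_feature_matrix(pos, fx$genome, NULL, k = 4)
    fm_neg <- build_feature_matrix(neg, fx$genome, NULL, k = 4)
    list(X = dplyr::bind_rows(fm_pos, fm_neg),
         y = rep(1:0, c(nrow(fm_pos), nrow(fm_neg))),
         pos = pos, neg = neg)
  })
}

heart_model <- function() {
  cached("heart_model", {
    tr <- tissue_training("heart", seed = 11)
    train_forest(tr$X, tr$y, seed = 11)
  })
}

heart_scan <- function() {
  cached("heart_scan", {
    fx <- default_fixture()
    scan_genome(heart_model(), fx$genome, NULL, k = 4)
  })
}

element_features <- function() {
  cached("element_features", {
    fx <- default_fixture()
    build_feature_matrix(fx$elements, fx$genome, NULL, k = 4)
  })
}

# ---- independent oracles ------------------------------------------------

# brute-force reverse complement (no Biostrings)
oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), ""))
}

# brute-force canonical alphabet: enumerate all 4^k words, fold
oracle_canonical <- function(k) {
  words <- do.call(paste0, expand.grid(
    rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE
  ))
  sort(unique(pmin(words, oracle_revcomp(words))))
}

# naive window-scan canonical k-mer frequencies
oracle_kmer_freq <- function(seq, k, alphabet = oracle_canonical(k)) {
  n <- nchar(seq)
  counts <- stats::setNames(numeric(length(alphabet)), alphabet)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      canon <- min(w, oracle_revcomp(w))
      counts[canon] <- counts[canon] + 1
    }
  }
  counts / n
}

# brute-force AUC: pairwise concordance with ties counted half
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
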