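ann_row <- function(id, active, tissues) {
  tibble::tibble(chrom = "chr1", start = 0L, end = 1000L, id = id,
                 active = active, tissues = list(tissues))
}

test_that("positive-set selection implements the include/exclude rule", {
  ann <- dplyr::bind_rows(
    ann_row("heart_limb", TRUE, c("heart", "limb")),
    ann_row("heart_fb", TRUE, c("heart", "forebrain")),
    ann_row("fb_only", TRUE, "forebrain"),
    ann_row("inactive", FALSE, character()),
    ann_row("midbrain", TRUE, c("midbrain", "neural tube"))
  )
  heart <- select_positive_set(ann, "heart")
  brain <- select_positive_set(ann, "brain")
  expect_equal(heart$id, "heart_limb")          # heart among others, no brain
  expect_equal(brain$id, c("fb_only", "midbrain"))
  # activity in both heart and a brain tissue excludes from BOTH sets
  expect_false("heart_fb" %in% c(heart$id, brain$id))
  expect_false("inactive" %in% c(heart$id, brain$id))
  ns <- select_positive_set(ann, "nonspecific")
  expect_setequal(ns$id, c("heart_limb", "fb_only", "midbrain"))
  expect_error(select_positive_set(ann, "kidney"), "unknown")
})

test_that("exhaustive truth table over heart/brain term combinations", {
  terms <- c("heart", "forebrain", "limb")
  combos <- expand.grid(h = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        l = c(TRUE, FALSE))
  ann <- dplyr::bind_rows(purrr::pmap(combos, function(h, b, l) {
    ts <- c(if (h) "heart", if (b) "forebrain", if (l) "limb")
    if (is.null(ts)) ts <- character()
    ann_row(paste0("e", h, b, l), length(ts) > 0, ts)
  }))
  heart <- select_positive_set(ann, "heart")$id
  brain <- select_positive_set(ann, "brain")$id
  for (i in seq_len(nrow(combos))) {
    id <- ann$id[i]
    expect_equal(id %in% heart, combos$h[i] && !combos$b[i])
    expect_equal(id %in% brain, combos$b[i] && !combos$h[i])
  }
})

test_that("negative-binomial moment matching is exact", {
  # lengths engineered to have m = 1500, v = 300000
  p <- fit_length_distribution(c(1500 - sqrt(3e5), 1500, 1500 + sqrt(3e5)))
  expect_equal(p$prob, 1500 / 300000, tolerance = 1e-9)
  expect_equal(p$size, 1500^2 / (300000 - 1500), tolerance = 1e-9)
  expect_equal(p$size, 7.5377, tolerance = 1e-4)
  # implied moments match the fitted moments
  expect_equal(p$size * (1 - p$prob) / p$prob, p$mean, tolerance = 1e-6)
  expect_equal(p$size * (1 - p$prob) / p$prob^2, p$variance,
               tolerance = 1e-6)
  expect_error(fit_length_distribution(c(1000, 1000, 1000)),
               "overdispersed")
  expect_error(fit_length_distribution(1500), "at least 2")
})

test_that("fitted distribution recovers its moments by Monte Carlo", {
  lens <- withr::with_seed(5, round(rnorm(200, 1000, sqrt(9e4))))
  pars <- fit_length_distribution(lens)
  draws <- withr::with_seed(6, {
    rnbinom(1e5, size = pars$size, prob = pars$prob)
  })
  expect_equal(mean(draws), pars$mean, tolerance = 0.02)
  expect_equal(var(draws), pars$variance, tolerance = 0.05)
})

test_that("signal filter fails only above a quarter of tracks", {
  mk <- function(frac) {
    # track covering `frac` of [0, 1000) with positive signal
    signal_track(tibble::tibble(chrom = "chr1", start = 0L,
                                end = as.integer(max(1, 1000 * frac)),
                                value = 1))
  }
  iv <- interval_tbl("chr1", 0, 1000)
  # covered fractions (1, 1, 1, 0.05): one failing track = 25%, passes
  tr4 <- list(a = mk(1), b = mk(1), c = mk(1), d = mk(0.05))
  expect_true(passes_signal_filter(iv, tr4))
  # (1, 1, 0.05, 0.05): two failing = 50% > 25%, fails
  tr4b <- list(a = mk(1), b = mk(1), c = mk(0.05), d = mk(0.05))
  expect_false(passes_signal_filter(iv, tr4b))
  expect_true(passes_signal_filter(iv, list()))
  # boundary: exactly 10% coverage is not "less than 10%"
  tr1 <- list(a = mk(0.1))
  expect_true(all(passes_signal_filter(iv, tr1)))
})

test_that("negative sampling respects chromosome, N and overlap rules", {
  fx <- default_fixture()
  pos <- select_positive_set(fx$elements, "heart")
  # degenerate chromosome distribution: positives forced onto one chrom
  pos1 <- pos[pos$chrom == pos$chrom[1], ]
  neg <- sample_negative_set(fx$genome, pos1, NULL, n = 30, seed = 3)
  expect_true(all(neg$chrom == pos1$chrom[1]))
  # never overlaps the exclusion set, never contains N
  neg2 <- sample_negative_set(fx$genome, pos, NULL, n = 100, seed = 4,
                              exclude = fx$elements)
  expect_equal(sum(enhancerf:::total_overlap_bp(neg2, fx$elements)), 0)
  seqs <- purrr::pmap_chr(neg2[c("chrom", "start", "end")],
                          function(chrom, start, end) {
    substr(fx$genome$sequence[fx$genome$id == chrom], start + 1, end)
  })
  expect_false(any(grepl("N", seqs, fixed = TRUE)))
  # determinism
  neg3 <- sample_negative_set(fx$genome, pos, NULL, n = 100, seed = 4,
                              exclude = fx$elements)
  expect_identical(neg2, neg3)
})

test_that("negatives avoid N-rich chromosomes entirely", {
  genome <- tibble::tibble(
    id = c("chrN", "chrC"),
    sequence = c(strrep("N", 20000), withr::with_seed(8, random_dna(20000)))
  )
  pos <- interval_tbl(c("chrN", "chrC"), c(0, 0), c(500, 500))
  neg <- sample_negative_set(genome, pos, NULL, n = 40, seed = 9,
                             exclude_overlap = FALSE)
  expect_true(all(neg$chrom == "chrC"))
})

test_that("sampled negative lengths recover the positive mean", {
  genome <- tibble::tibble(id = "chr1",
                           sequence = withr::with_seed(10, random_dna(3e5)))
  lens <- withr::with_seed(11, pmax(100, rnbinom(120, size = 7.5377,
                                                 prob = 0.005)))
  starts <- seq(0, by = 2200, length.out = 120)
  pos <- interval_tbl("chr1", starts, pmin(starts + lens, 3e5))
  neg <- sample_negative_set(genome, pos, NULL, n = 500, seed = 12,
                             exclude_overlap = FALSE)
  expect_equal(mean(neg$end - neg$start), mean(pos$end - pos$start),
               tolerance = 0.05)
})
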