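test_that("window tiling follows the start rule and drops N windows", {
  g <- tibble::tibble(id = "chr1",
                      sequence = withr::with_seed(1, random_dna(3750)))
  w <- make_windows(g)
  expect_equal(w$start, c(0L, 750L, 1500L, 2250L))
  expect_true(all(w$end - w$start == 1500))

  g$sequence <- withr::with_seed(1, random_dna(1499))
  expect_equal(nrow(make_windows(g)), 0)

  # an N kills exactly the windows covering it, keeps the rest
  s <- withr::with_seed(2, random_dna(3750))
  substr(s, 101, 101) <- "N"   # 0-based position 100: only window [0,1500)
  w <- make_windows(tibble::tibble(id = "chr1", sequence = s))
  expect_equal(w$start, c(750L, 1500L, 2250L))
  substr(s, 801, 801) <- "N"   # 0-based 800: also kills [750, 2250)
  w <- make_windows(tibble::tibble(id = "chr1", sequence = s))
  expect_equal(w$start, c(1500L, 2250L))
})

test_that("window coverage is bounded by length/step per base", {
  g <- tibble::tibble(id = "c", sequence = withr::with_seed(3, random_dna(9000)))
  w <- make_windows(g, length = 1500, step = 750)
  cover <- integer(9000)
  for (i in seq_len(nrow(w))) {
    idx <- (w$start[i] + 1):w$end[i]
    cover[idx] <- cover[idx] + 1
  }
  expect_lte(max(cover), ceiling(1500 / 750))
  expect_true(all(w$end <= 9000))
})

test_that("genome scanning reproduces training scores on identical input", {
  fx <- default_fixture()
  trk <- heart_scan()
  expect_s3_class(trk, "prediction_track")
  expect_true(all(trk$score >= 0 & trk$score <= 1))
  # a window's score equals the score of its feature row
  m <- heart_model()
  fm <- build_feature_matrix(trk[7, ], fx$genome, NULL, k = 4)
  expect_equal(predict_scores(m, fm), trk$score[7])
  # all-N chromosome scans to an empty track
  gN <- tibble::tibble(id = "chrN", sequence = strrep("N", 5000))
  expect_equal(nrow(scan_genome(m, gN, NULL, 4)), 0)
})

test_that("planted-enhancer windows outscore background windows", {
  fx <- default_fixture()
  trk <- heart_scan()
  heart_el <- fx$elements[fx$elements$class == "heart", ]
  in_heart <- enhancerf:::total_overlap_bp(trk, heart_el) >= 750
  in_any <- enhancerf:::total_overlap_bp(trk, fx$elements) > 0
  enh <- trk$score[in_heart]
  bg <- trk$score[!in_any]
  expect_gte(length(enh), 100)
  expect_gte(length(bg), 100)
  expect_gt(mean(enh), mean(bg))
  expect_lt(rank_sum_test(enh, bg)$p_value, 1e-3)
})

test_that("DHS overlap partition honors the 100 bp boundary and TSS rule", {
  trk <- structure(
    interval_tbl("chr1", c(0, 1500, 3000), c(1500, 3000, 4500),
                 score = c(0.9, 0.2, 0.5)),
    class = c("prediction_track", class(tibble::tibble()))
  )
  clusters <- interval_tbl("chr1", 1400, 1510)
  grp <- overlap_partition(trk, clusters, min_overlap = 100)
  # window [0,1500) overlaps min(1500,1510)-1400 = 100 bases -> DHS;
  # window [1500,3000) overlaps only 10 -> non-DHS
  expect_equal(grp$dhs_scores, 0.9)
  expect_equal(grp$non_dhs_scores, c(0.2, 0.5))
  # overlap 99 is non-DHS
  grp99 <- overlap_partition(trk, interval_tbl("chr1", 1401, 1510),
                             min_overlap = 100)
  expect_length(grp99$dhs_scores, 0)
  # a fragmented cluster set counts TOTAL overlap
  frag <- interval_tbl("chr1", c(1400, 0), c(1480, 20))
  grpF <- overlap_partition(trk, frag, min_overlap = 100)
  expect_equal(grpF$dhs_scores, 0.9)           # 80 + 20 bases
  # windows containing a TSS leave both groups
  tss <- tibble::tibble(chrom = "chr1", pos = 700L, strand = "+")
  grpT <- overlap_partition(trk, clusters, min_overlap = 100, tss = tss)
  expect_equal(sort(c(grpT$dhs_scores, grpT$non_dhs_scores)), c(0.2, 0.5))
})

test_that("top-signal partition uses strict thresholds and seeded draws", {
  w <- interval_tbl("chr1", seq(0, 4500, 1500), seq(1500, 6000, 1500))
  sig <- signal_track(tibble::tibble(
    chrom = "chr1", start = c(0L, 2000L), end = c(1500L, 2001L),
    value = c(100, 10)
  ))
  part <- top_signal_partition(w, sig, n = 1, max_threshold = 10, seed = 1)
  expect_equal(part$dhs_windows$start, 0L)
  # the window touching the value-10 base fails the strict < 10 rule
  expect_false(1500 %in% part$non_dhs_windows$start)
  eligible <- w[max_signal(w, sig) < 10, ]
  expect_true(all(part$non_dhs_windows$start %in% eligible$start))
  # all-zero signal: every window eligible, DHS tie-broken by position
  zero <- signal_track(tibble::tibble(chrom = "chr1", start = 0L,
                                      end = 1L, value = 0))
  p0 <- top_signal_partition(w, zero, n = 2, max_threshold = 10, seed = 2)
  expect_equal(p0$dhs_windows$start, c(0L, 1500L))
  expect_error(top_signal_partition(w[1:2, ], sig, n = 3, seed = 1),
               "windows")
})

test_that("rank-sum test matches exact small-sample results", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation of 3 vs 3: exact two-sided p = 2/choose(6,3) = 0.1
  exact <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value
  approx <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value
  expect_equal(approx, stats::wilcox.test(c(1, 2, 3), c(4, 5, 6),
                                          exact = FALSE)$p.value)
  expect_lt(abs(approx - exact), 0.05)
  # a 1-sd shift at n = 200 per side is decisively detected
  withr::with_seed(5, {
    a <- rnorm(200); b <- rnorm(200, 1)
  })
  expect_lt(rank_sum_test(b, a)$p_value, 1e-4)
  expect_error(rank_sum_test(numeric(), 1:3), "nonempty")
})

test_that("TSS-proximal classification is strand-aware", {
  trk <- structure(
    interval_tbl("chr1", c(5001, 8000), c(6501, 9500),
                 score = c(0.9, 0.9)),
    class = c("prediction_track", class(tibble::tibble()))
  )
  # minus-strand TSS at 5000: upstream is [5001, 6501)
  tss_minus <- tibble::tibble(chrom = "chr1", pos = 5000L, strand = "-")
  enr <- tss_proximal_enrichment(trk, tss_minus, baseline_fraction = 0.09)
  expect_equal(enr$n_proximal, 1)
  # plus-strand TSS at 5000: upstream is [3500, 5000), neither window
  tss_plus <- tibble::tibble(chrom = "chr1", pos = 5000L, strand = "+")
  enr2 <- tss_proximal_enrichment(trk, tss_plus, baseline_fraction = 0.09)
  expect_equal(enr2$n_proximal, 0)
  # observed at baseline: p near 0.5 for large n
  many <- structure(
    interval_tbl("chr1", seq(0, 999) * 3000, seq(0, 999) * 3000 + 1500,
                 score = rep(0.9, 1000)),
    class = c("prediction_track", class(tibble::tibble()))
  )
  tss_some <- tibble::tibble(chrom = "chr1",
                             pos = (seq_len(90) * 33000L + 1600L),
                             strand = rep("-", 90))
  enr3 <- tss_proximal_enrichment(many, tss_some,
                                  baseline_fraction = 0.09)
  expect_gt(enr3$p_value, 0.2)
  expect_lt(enr3$p_value, 0.8)
  expect_error(
    tss_proximal_enrichment(
      structure(interval_tbl("chr1", 0, 10, score = 0.1),
                class = c("prediction_track", "tbl_df", "tbl", "data.frame")),
      tss_plus, baseline_fraction = 0.09
    ),
    "threshold"
  )
})

test_that("promoter bias reproduces on the default fixture", {
  fx <- default_fixture()
  trk <- heart_scan()
  baseline <- mean(enhancerf:::is_tss_proximal(trk, fx$tss, 1500))
  enr <- tss_proximal_enrichment(trk, fx$tss, baseline_fraction = baseline)
  expect_gt(enr$fraction, baseline)
  expect_lt(enr$log10_p, log10(0.01))
  # the rank-sum diagnostic fires too: TSS-window scores exceed the rest
  tssw <- enhancerf:::count_points_in(trk, fx$tss) > 0
  expect_lt(rank_sum_test(trk$score[tssw], trk$score[!tssw])$p_value, 0.01)
})
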