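small_config <- function(seed = 17, ...) {
  synth_config(
    chrom_lengths = c(chr1 = 100000L, chr2 = 100000L),
    n_enhancers = c(heart = 20L, brain = 20L),
    n_promoters = 10L, promoter_activity = c(heart = 5L, brain = 2L),
    seed = seed, ...
  )
}

test_that("genome generation is seeded, uniform, and honors N-blocks", {
  cfg <- small_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  # composition of a 100 kb chromosome: each base near 0.25
  tab <- table(strsplit(g1$sequence[1], "")[[1]]) / 100000
  expect_true(all(abs(tab - 0.25) < 0.01))
  # different seed, different genome
  g3 <- generate_genome(small_config(seed = 18))
  expect_false(identical(g1$sequence, g3$sequence))
  # N-block stamped exactly where configured
  cfgN <- synth_config(chrom_lengths = c(chr1 = 1000L),
                       n_enhancers = c(heart = 0L, brain = 0L),
                       n_promoters = 0L,
                       promoter_activity = c(heart = 0L, brain = 0L),
                       max_element_length = 900L,
                       n_blocks = interval_tbl("chr1", 50, 60), seed = 1)
  gN <- generate_genome(cfgN)
  expect_equal(substr(gN$sequence, 51, 60), strrep("N", 10))
  expect_false(grepl("N", paste0(substr(gN$sequence, 1, 50),
                                 substr(gN$sequence, 61, 1000))))
})

test_that("planted elements do not overlap and are seed-stable", {
  cfg <- small_config()
  g <- generate_genome(cfg)
  pl1 <- plant_elements(g, cfg)
  pl2 <- plant_elements(g, cfg)
  expect_identical(pl1, pl2)
  el <- dplyr::arrange(pl1$elements, chrom, start)
  by_chrom <- split(el, el$chrom)
  for (ch in by_chrom) {
    if (nrow(ch) > 1) expect_true(all(ch$start[-1] >= ch$end[-nrow(ch)]))
  }
  expect_equal(sum(el$class == "heart"), 20)
  expect_equal(sum(el$class == "promoter"), 10)
  # promoter activity annotation: 5 heart-active, 2 brain-active, 3 inactive
  prom <- el[el$class == "promoter", ]
  expect_equal(sum(vapply(prom$tissues, identical, TRUE, "heart")), 5)
  expect_equal(sum(vapply(prom$tissues, identical, TRUE, "forebrain")), 2)
  expect_equal(sum(!prom$active), 3)
  # one TSS per promoter, inside the element
  expect_equal(nrow(pl1$tss), 10)
  # zero elements leave the genome untouched
  cfg0 <- synth_config(chrom_lengths = c(chr1 = 10000L),
                       n_enhancers = c(heart = 0L, brain = 0L),
                       n_promoters = 0L,
                       promoter_activity = c(heart = 0L, brain = 0L),
                       max_element_length = 5000L, seed = 2)
  g0 <- generate_genome(cfg0)
  expect_identical(plant_elements(g0, cfg0)$genome, g0)
})

test_that("planted k-mers reach their configured enrichment over background", {
  cfg <- small_config()
  fx <- generate_fixture(cfg)
  heart_el <- fx$elements[fx$elements$class == "heart", ]
  fm <- build_feature_matrix(heart_el, fx$genome, NULL, 4)
  bg <- sample_negative_set(fx$genome, heart_el, NULL, n = 40, seed = 3,
                            exclude = fx$elements)
  fm_bg <- build_feature_matrix(bg, fx$genome, NULL, 4)
  # odds 5 planted GATA: mean frequency > 3x background frequency
  expect_gt(mean(fm$GATA), 3 * mean(fm_bg$GATA))
  expect_gt(mean(fm$CAGC), 3 * mean(fm_bg$CAGC))
  # unplanted control k-mer stays near background
  expect_lt(mean(fm$ATAT), 3 * mean(fm_bg$ATAT))
})

test_that("signal tracks elevate marked classes and respect gain zero", {
  cfg <- small_config()
  fx <- generate_fixture(cfg)
  heart_el <- fx$elements[fx$elements$class == "heart", ]
  ctrl <- sample_negative_set(fx$genome, heart_el, NULL, n = 40, seed = 5,
                              exclude = fx$elements)
  m_el <- mean_signal(heart_el, fx$tracks$heart_mark)
  m_ctrl <- mean_signal(ctrl, fx$tracks$heart_mark)
  expect_gt(mean(m_el), 5 * mean(m_ctrl))
  # brain track is not elevated over heart elements
  expect_lt(mean(mean_signal(heart_el, fx$tracks$brain_mark)),
            mean(mean_signal(fx$elements[fx$elements$class == "brain", ],
                             fx$tracks$brain_mark)) / 5)
  expect_true(all(fx$tracks$heart_mark$value >= 0))
  # gain 0: statistically identical over elements and background
  cfg0 <- small_config(tracks = list(flat = list(marks = "heart",
                                                 gain = 0)))
  fx0 <- generate_fixture(cfg0)
  h0 <- fx0$elements[fx0$elements$class == "heart", ]
  ctrl0 <- sample_negative_set(fx0$genome, h0, NULL, n = 200, seed = 6,
                               exclude = fx0$elements,
                               min_length = 500L)
  p <- rank_sum_test(mean_signal(h0, fx0$tracks$flat),
                     mean_signal(ctrl0, fx0$tracks$flat))$p_value
  expect_gt(p, 0.01)
  # determinism
  t1 <- generate_signal_tracks(fx$genome, fx$elements, cfg)
  t2 <- generate_signal_tracks(fx$genome, fx$elements, cfg)
  expect_identical(t1, t2)
})

test_that("fixture bundles are complete and byte-identical across runs", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- write_fixture_bundle(d1, cfg)
  expect_equal(man$seed, cfg$seed)
  files <- c("genome.fa", "annotation.tsv", "tss.bed", "dhs.bed",
             "track_enh_mark.bedGraph", "manifest.json")
  expect_true(all(file.exists(file.path(d1, files))))
  write_fixture_bundle(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  # the bundle is readable by the io layer and internally consistent
  g <- read_fasta(file.path(d1, "genome.fa"))
  ann <- read_annotation_table(file.path(d1, "annotation.tsv"))
  tss <- read_tss_table(file.path(d1, "tss.bed"))
  expect_equal(nrow(ann), 50)
  expect_equal(nrow(tss), 10)
  expect_equal(sort(g$id), sort(names(cfg$chrom_lengths)))
})

test_that("infeasible placement fails with a clear error", {
  cfg <- synth_config(chrom_lengths = c(chr1 = 6000L),
                      n_enhancers = c(heart = 40L, brain = 0L),
                      n_promoters = 0L,
                      promoter_activity = c(heart = 0L, brain = 0L),
                      min_element_length = 1000L,
                      max_element_length = 2000L, seed = 3)
  g <- generate_genome(cfg)
  expect_error(plant_elements(g, cfg), "infeasible")
})
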