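#' Pipeline run configuration
#'
#' Collects every numeric constant of the pipeline with its standard
#' default: 4-mers, 100-tree forests, 10x10 stratified cross-validation,
#' 1500 bp windows every 750 bp, high-score threshold 0.8, TSS-proximal
#' distance 1500 bp, DHS overlap 100 bp, up to 100 Boruta rounds at
#' alpha 0.01. Configurations round-trip through YAML.
#'
#' @param k k-mer length.
#' @param n_trees Trees per forest.
#' @param n_folds,n_rounds Cross-validation geometry.
#' @param window_length,step Genome-scan window geometry (bp).
#' @param score_threshold High-score cutoff (strict).
#' @param proximal_distance TSS-proximal distance (bp).
#' @param min_overlap DHS-overlap threshold (bp).
#' @param boruta_max_rounds,alpha Feature-selection parameters.
#' @param seed Master seed.
#' @param paths Named list of input paths (`genome`, `annotation`,
#'   `tracks`, `tss`, `dhs`), possibly empty.
#' @return A `run_config` list.
#' @export
run_config <- function(k = 4, n_trees = 100, n_folds = 10, n_rounds = 10,
                       window_length = 1500, step = 750,
                       score_threshold = 0.8, proximal_distance = 1500,
                       min_overlap = 100, boruta_max_rounds = 100,
                       alpha = 0.01, seed = 1L, paths = list()) {
  structure(
    list(k = k, n_trees = n_trees, n_folds = n_folds, n_rounds = n_rounds,
         window_length = window_length, step = step,
         score_threshold = score_threshold,
         proximal_distance = proximal_distance, min_overlap = min_overlap,
         boruta_max_rounds = boruta_max_rounds, alpha = alpha,
         seed = as.integer(seed), paths = paths),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For the reader, a `run_config`; for the writer, `path`
#'   invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run one pipeline subcommand
#'
#' The programmatic core of the command-line tool. Subcommands:
#' `simulate` (write a fixture bundle), `featurize`, `make-negatives`,
#' `train`, `cv`, `boruta`, `scan`, `dhs-compare`, `promoter-bias`,
#' `two-step`, `report`. Each writes its artifacts under `outdir` and
#' returns them invisibly.
#'
#' @param name Subcommand name.
#' @param config A [run_config()] whose `paths` name the inputs.
#' @param outdir Output directory (default `"."`).
#' @param tissue Tissue spec name for set selection (default
#'   `"nonspecific"`).
#' @return The subcommand's main artifact, invisibly.
#' @export
run_subcommand <- function(name, config, outdir = ".",
                           tissue = "nonspecific") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    "simulate" = write_fixture_bundle(
      outdir, synth_config(seed = config$seed)
    ),
    "featurize" = {
      inp <- load_inputs(config)
      pos <- select_positive_set(inp$annotation, tissue)
      fm <- build_feature_matrix(pos, inp$genome, inp$tracks, k = config$k)
      write_feature_matrix(fm, file.path(outdir, "features.tsv"))
      invisible(fm)
    },
    "make-negatives" = {
      inp <- load_inputs(config)
      pos <- select_positive_set(inp$annotation, tissue)
      neg <- sample_negative_set(inp$genome, pos, inp$tracks,
                                 n = nrow(pos), seed = config$seed,
                                 exclude = inp$annotation)
      write_bed(neg, file.path(outdir, "negatives.bed"))
      invisible(neg)
    },
    "train" = ,
    "cv" = {
      inp <- load_inputs(config)
      ts <- training_matrix(inp, config, tissue)
      if (name == "train") {
        model <- train_forest(ts$X, ts$y, n_trees = config$n_trees,
                              seed = config$seed)
        saveRDS(model, file.path(outdir, "model.rds"))
        invisible(model)
      } else {
        cv <- cross_validate(ts$X, ts$y, n_folds = config$n_folds,
                             n_rounds = config$n_rounds,
                             n_trees = config$n_trees, seed = config$seed)
        readr::write_tsv(tibble::tibble(round = seq_along(cv$auc),
                                        auc = cv$auc),
                         file.path(outdir, "cv_auc.tsv"))
        jsonlite::write_json(list(mean_auc = cv$mean_auc),
                             file.path(outdir, "cv_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        invisible(cv)
      }
    },
    "boruta" = {
      inp <- load_inputs(config)
      ts <- training_matrix(inp, config, tissue)
      rep <- boruta(ts$X, ts$y, max_rounds = config$boruta_max_rounds,
                    alpha = config$alpha, seed = config$seed,
                    n_trees = config$n_trees)
      readr::write_tsv(rep, file.path(outdir, "boruta.tsv"))
      invisible(rep)
    },
    "scan" = {
      inp <- load_inputs(config)
      model <- readRDS(config$paths$model)
      track <- scan_genome(model, inp$genome, inp$tracks, k = config$k,
                           window_length = config$window_length,
                           step = config$step)
      write_bed(track, file.path(outdir, "predictions.bed"))
      invisible(track)
    },
    "promoter-bias" = {
      inp <- load_inputs(config)
      track <- read_bed(config$paths$predictions)
      enr <- tss_proximal_enrichment(
        track, inp$tss, score_threshold = config$score_threshold,
        proximal_distance = config$proximal_distance,
        baseline_fraction = config$baseline_fraction %||% 0.09
      )
      jsonlite::write_json(enr, file.path(outdir, "promoter_bias.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(enr)
    },
    "dhs-compare" = {
      inp <- load_inputs(config)
      track <- read_bed(config$paths$predictions)
      grp <- overlap_partition(track, inp$dhs,
                               min_overlap = config$min_overlap,
                               tss = inp$tss)
      rs <- rank_sum_test(grp$dhs_scores, grp$non_dhs_scores)
      out <- list(n_dhs = length(grp$dhs_scores),
                  n_non_dhs = length(grp$non_dhs_scores),
                  mean_dhs = mean(grp$dhs_scores),
                  mean_non_dhs = mean(grp$non_dhs_scores),
                  p_value = rs$p_value)
      jsonlite::write_json(out, file.path(outdir, "dhs_compare.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    "two-step" = {
      inp <- load_inputs(config)
      model <- readRDS(config$paths$model)
      track <- read_bed(config$paths$predictions)
      prom <- select_promoter_windows(track, inp$tss,
                                      score_threshold = config$score_threshold,
                                      seed = config$seed)
      rnd <- sample_negative_set(inp$genome, prom, tracks = NULL,
                                 n = max(nrow(prom), 50), seed = config$seed)
      filt <- train_promoter_filter(rnd, prom, inp$genome, k = config$k,
                                    seed = config$seed)
      ts_model <- two_step_model(model, filt)
      saveRDS(ts_model, file.path(outdir, "two_step_model.rds"))
      invisible(ts_model)
    },
    stop("unknown subcommand '", name, "'", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read the inputs named in config$paths (each optional)
load_inputs <- function(config) {
  p <- config$paths
  list(
    genome = if (!is.null(p$genome)) read_fasta(p$genome),
    annotation = if (!is.null(p$annotation)) read_annotation_table(p$annotation),
    tss = if (!is.null(p$tss)) read_tss_table(p$tss),
    dhs = if (!is.null(p$dhs)) read_bed(p$dhs),
    tracks = if (!is.null(p$tracks)) {
      trk <- lapply(p$tracks, read_signal_track)
      names(trk) <- names(p$tracks) %||%
        sub("\\.(bedGraph|bedgraph|wig)$", "", basename(unlist(p$tracks)))
      trk
    }
  )
}

# positive + matched negative feature matrix for one tissue; negatives
# are kept clear of every annotated element, not just the positives
training_matrix <- function(inp, config, tissue) {
  pos <- select_positive_set(inp$annotation, tissue)
  neg <- sample_negative_set(inp$genome, pos, inp$tracks,
                             n = nrow(pos), seed = config$seed,
                             exclude = inp$annotation)
  fm_pos <- build_feature_matrix(pos, inp$genome, inp$tracks, k = config$k)
  fm_neg <- build_feature_matrix(neg, inp$genome, inp$tracks, k = config$k)
  list(X = dplyr::bind_rows(fm_pos, fm_neg),
       y = c(rep(1L, nrow(fm_pos)), rep(0L, nrow(fm_neg))))
}
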