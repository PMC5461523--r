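#' Configuration of the synthetic genome generator
#'
#' The generator builds a uniform-composition random genome and plants
#' three element classes on it: heart enhancers, brain enhancers, and
#' promoters. Each class is enriched for its own k-mers; the heart and
#' brain sets are canonical-disjoint so tissue specificity is
#' recoverable. Two deliberate couplings reproduce the promoter bias
#' seen in real enhancer training data: (1) a configurable number of
#' promoter elements are annotated as tissue-active
#' (`promoter_activity`), emulating promoter-overlapping sequences in
#' enhancer training sets, so a classifier trained on the selected
#' positives learns the promoter signature as a positive pattern; and
#' (2) brain enhancers share one CpG-like k-mer with the promoter
#' signature, giving the tissue classifiers a promoter-driven
#' cross-prediction component that the two-step filter can remove.
#' Signal tracks carry half-normal baseline noise plus an additive
#' elevation (`signal_gain`) over the element classes they mark.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_enhancers Named vector: planted enhancers per tissue class.
#' @param n_promoters Number of planted promoter elements.
#' @param promoter_activity Named vector: how many promoter elements are
#'   annotated active in each tissue (the rest stay inactive). Must sum
#'   to at most `n_promoters`.
#' @param element_length_mean,element_length_var Moments of the
#'   negative-binomial enhancer-length distribution (bp).
#' @param promoter_length_mean,promoter_length_var Moments of the
#'   promoter-element length distribution (bp); promoter regions are
#'   longer than the scan window by default so that windows can lie
#'   fully inside them.
#' @param min_element_length,max_element_length Truncation bounds (bp).
#' @param enriched_kmers Named list (`heart`, `brain`, `promoter`) of
#'   the k-mers enriched within each class: either a named numeric
#'   vector (names = k-mers, values = per-k-mer enrichment odds) or a
#'   plain character vector (odds taken from `enrichment_odds`).
#' @param enrichment_odds Fallback target odds of an enriched k-mer's
#'   frequency over background (> 1), used for k-mers given without
#'   their own odds.
#' @param promoter_tss_offset Fraction of a promoter element lying
#'   upstream of its TSS (default 0.8: the TSS sits inside the element,
#'   near its downstream end, as in a CpG-island promoter).
#' @param tracks Named list of track specs, each a list with `marks`
#'   (classes the track elevates) and optional `gain`.
#' @param signal_gain Default additive signal elevation over marked
#'   elements.
#' @param noise_sd Scale of the half-normal baseline noise.
#' @param signal_bin Bin width (bp) of the piecewise-constant tracks.
#' @param n_blocks Optional interval tibble of N-blocks to stamp into
#'   the genome (for window-exclusion tests).
#' @param seed Integer master seed; everything downstream is
#'   deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(chrom_lengths = c(chr1 = 500000L, chr2 = 500000L,
                                           chr3 = 500000L, chr4 = 500000L),
                         n_enhancers = c(heart = 150L, brain = 150L),
                         n_promoters = 60L,
                         promoter_activity = c(heart = 30L, brain = 15L),
                         element_length_mean = 1500,
                         element_length_var = 3e5,
                         promoter_length_mean = 2400,
                         promoter_length_var = 3e5,
                         min_element_length = 300L,
                         max_element_length = 5000L,
                         enriched_kmers = list(
                           heart = c(GATA = 5, CAGC = 5),
                           brain = c(CTAA = 2, GCGC = 5, CGCG = 5,
                                     ACGC = 5, CGCA = 5, CCGC = 5,
                                     GCGA = 5),
                           promoter = c(GCGC = 5, CGCG = 5, ACGC = 5,
                                        CGCA = 5, CCGC = 5, GCGA = 5)
                         ),
                         enrichment_odds = 5,
                         promoter_tss_offset = 0.8,
                         tracks = list(
                           enh_mark = list(marks = c("heart", "brain")),
                           prom_mark = list(marks = "promoter"),
                           heart_mark = list(marks = "heart"),
                           brain_mark = list(marks = "brain")
                         ),
                         signal_gain = 10,
                         noise_sd = 0.1,
                         signal_bin = 50L,
                         n_blocks = NULL,
                         seed = 1L) {
  stopifnot(all(chrom_lengths > 0), all(n_enhancers >= 0), n_promoters >= 0,
            enrichment_odds > 1, element_length_var > element_length_mean,
            promoter_length_var > promoter_length_mean,
            max_element_length <= min(chrom_lengths),
            sum(promoter_activity) <= n_promoters,
            promoter_tss_offset > 0, promoter_tss_offset < 1)
  per_kmer_odds <- unlist(lapply(enriched_kmers, function(x) {
    if (is.numeric(x)) x else numeric()
  }))
  stopifnot(all(per_kmer_odds > 1))
  kmer_names <- function(x) if (is.numeric(x)) names(x) else x
  canon <- function(s) if (length(s) == 0) character() else {
    pmin(s, reverse_complement(s))
  }
  shared <- intersect(canon(kmer_names(enriched_kmers$heart)),
                      canon(kmer_names(enriched_kmers$brain)))
  if (length(shared) > 0) {
    warning("heart and brain enriched k-mers share canonical forms: ",
            paste(shared, collapse = ", "), call. = FALSE)
  }
  structure(
    list(chrom_lengths = chrom_lengths, n_enhancers = n_enhancers,
         n_promoters = n_promoters, promoter_activity = promoter_activity,
         element_length_mean = element_length_mean,
         element_length_var = element_length_var,
         promoter_length_mean = promoter_length_mean,
         promoter_length_var = promoter_length_var,
         min_element_length = as.integer(min_element_length),
         max_element_length = as.integer(max_element_length),
         enriched_kmers = enriched_kmers,
         enrichment_odds = enrichment_odds,
         promoter_tss_offset = promoter_tss_offset, tracks = tracks,
         signal_gain = signal_gain, noise_sd = noise_sd,
         signal_bin = as.integer(signal_bin), n_blocks = n_blocks,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate the random background genome
#'
#' I.i.d. uniform A/C/G/T per base, with configured N-blocks stamped in
#' afterwards. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return Genome tibble (`id`, `sequence`).
#' @export
generate_genome <- function(config) {
  seeds <- derive_seeds(config$seed, 1)
  withr::with_seed(seeds[1], {
    seqs <- vapply(config$chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
  genome <- tibble::tibble(id = names(config$chrom_lengths),
                           sequence = unname(seqs))
  if (!is.null(config$n_blocks)) {
    for (i in seq_len(nrow(config$n_blocks))) {
      b <- config$n_blocks[i, ]
      j <- which(genome$id == b$chrom)
      substr(genome$sequence[j], b$start + 1L, b$end) <-
        strrep("N", b$end - b$start)
    }
  }
  genome
}

# number of copies of one enriched k-mer to write into an element so its
# canonical frequency is about `odds` times the uniform background
# expectation (2/4^k per position for a non-palindromic pair, 1/4^k for a
# palindrome)
n_insertions <- function(len, kmer, odds) {
  k <- nchar(kmer)
  pal <- kmer == reverse_complement(kmer)
  background <- len * (if (pal) 1 else 2) / 4^k
  max(1L, as.integer(round((odds - 1) * background)))
}

# Write a class's enriched k-mers into a sequence fragment at
# non-overlapping, k-aligned slots (sampled without replacement), so the
# achieved per-k-mer frequency matches the requested insertion count
# exactly instead of being diluted by overwrites. All k-mers of one
# class must share one length.
plant_kmers <- function(frag, kmers, odds) {
  len <- nchar(frag)
  k <- nchar(kmers[1])
  stopifnot(all(nchar(kmers) == k))
  n_ins <- vapply(kmers, function(km) n_insertions(len, km, odds[[km]]),
                  integer(1))
  n_slots <- len %/% k
  if (sum(n_ins) > n_slots) {
    stop(sprintf(
      "enriched k-mer insertion demand (%d slots) exceeds element capacity (%d)",
      sum(n_ins), n_slots
    ), call. = FALSE)
  }
  slots <- sample.int(n_slots, sum(n_ins))
  owner <- rep(seq_along(kmers), n_ins)
  for (i in seq_along(slots)) {
    p <- (slots[i] - 1L) * k + 1L
    substr(frag, p, p + k - 1L) <- kmers[owner[i]]
  }
  frag
}

#' Plant enhancer and promoter elements on a genome
#'
#' Elements are placed without overlap (uniform chromosome and start,
#' bounded rejection), with lengths drawn from the moment-matched
#' negative binomial. Within each element the class's enriched k-mers
#' are written at random positions, in numbers calibrated so each k-mer's
#' frequency is about `enrichment_odds` times background. Promoter
#' elements sit immediately upstream of synthetic TSS records (strand
#' chosen at random), which are emitted alongside.
#'
#' @param genome Genome tibble from [generate_genome()].
#' @param config A [synth_config()].
#' @return List with `genome` (modified), `elements` (annotation tibble
#'   with `class` column; enhancers active with their tissue term,
#'   promoters inactive), and `tss` (tibble `chrom`, `pos`, `strand`).
#' @export
plant_elements <- function(genome, config) {
  seeds <- derive_seeds(config$seed, 3)
  classes <- c(rep(names(config$n_enhancers), config$n_enhancers),
               rep("promoter", config$n_promoters))
  if (length(classes) == 0) {
    return(list(genome = genome,
                elements = empty_annotation(), tss = empty_tss()))
  }
  chrom_len <- stats::setNames(nchar(genome$sequence), genome$id)
  nb_par <- function(m, v) list(size = m^2 / (v - m), prob = m / v)
  placed <- withr::with_seed(seeds[2], {
    is_prom <- classes == "promoter"
    lens <- integer(length(classes))
    lens[!is_prom] <- draw_lengths(
      sum(!is_prom),
      params = nb_par(config$element_length_mean, config$element_length_var),
      empirical = NULL,
      min_len = config$min_element_length,
      max_len = config$max_element_length
    )
    lens[is_prom] <- draw_lengths(
      sum(is_prom),
      params = nb_par(config$promoter_length_mean, config$promoter_length_var),
      empirical = NULL,
      min_len = config$min_element_length,
      max_len = config$max_element_length
    )
    place_nonoverlapping(lens, chrom_len, config$n_blocks)
  })
  placed$class <- classes
  placed$id <- sprintf("%s_%d", classes, stats::ave(
    seq_along(classes), classes, FUN = seq_along
  ))

  # write enriched k-mers into each element
  seqs <- stats::setNames(genome$sequence, genome$id)
  tss_rows <- list()
  withr::with_seed(seeds[3], {
    for (i in seq_len(nrow(placed))) {
      cls <- placed$class[i]
      spec <- config$enriched_kmers[[cls]]
      kmers <- if (is.numeric(spec)) names(spec) else spec
      odds <- if (is.numeric(spec)) spec else {
        stats::setNames(rep(config$enrichment_odds, length(spec)), spec)
      }
      len <- placed$end[i] - placed$start[i]
      if (length(kmers) > 0) {
        frag <- substr(seqs[placed$chrom[i]], placed$start[i] + 1L,
                       placed$end[i])
        frag <- plant_kmers(frag, kmers, odds)
        substr(seqs[placed$chrom[i]], placed$start[i] + 1L,
               placed$end[i]) <- frag
      }
      if (cls == "promoter") {
        # the TSS sits inside the element, promoter_tss_offset of its
        # length from the upstream end (strand-aware)
        strand <- sample(c("+", "-"), 1)
        up <- floor(config$promoter_tss_offset * len)
        tss_rows[[length(tss_rows) + 1]] <- tibble::tibble(
          chrom = placed$chrom[i],
          pos = if (strand == "+") placed$start[i] + up
                else placed$end[i] - 1L - up,
          strand = strand
        )
      }
    }
  })
  genome$sequence <- unname(seqs[genome$id])

  tss <- if (length(tss_rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(tss_rows), .data$chrom, .data$pos)
  } else {
    empty_tss()
  }
  tss <- tss[tss$pos >= 0 & tss$pos < chrom_len[tss$chrom], , drop = FALSE]
  # promoter activity annotation: the first promoter_activity["heart"]
  # promoters are annotated heart-active, the next brain-active, the rest
  # inactive (emulates promoter-overlapping sequences in enhancer
  # training data)
  prom_rank <- cumsum(placed$class == "promoter") * (placed$class == "promoter")
  act <- config$promoter_activity
  n_h <- if ("heart" %in% names(act)) act[["heart"]] else 0L
  n_b <- if ("brain" %in% names(act)) act[["brain"]] else 0L
  prom_tissue <- function(r) {
    if (r >= 1 && r <= n_h) "heart"
    else if (r > n_h && r <= n_h + n_b) "forebrain"
    else character()
  }
  tissues <- purrr::map(seq_len(nrow(placed)), function(i) {
    switch(placed$class[i], heart = "heart", brain = "forebrain",
           promoter = prom_tissue(prom_rank[i]))
  })
  elements <- tibble::tibble(
    chrom = placed$chrom, start = placed$start, end = placed$end,
    id = placed$id, class = placed$class,
    active = lengths(tissues) > 0,
    tissues = tissues
  )
  list(genome = genome, elements = validate_intervals(elements), tss = tss)
}

empty_annotation <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 id = character(), class = character(), active = logical(),
                 tissues = list())
}
empty_tss <- function() {
  tibble::tibble(chrom = character(), pos = integer(), strand = character())
}

# place elements of the given lengths uniformly without overlap,
# avoiding N-blocks; bounded retries
place_nonoverlapping <- function(lens, chrom_len, n_blocks = NULL,
                                 max_tries = 200 * length(lens)) {
  taken <- lapply(chrom_len, function(...) NULL)  # per-chrom occupied list
  out_chrom <- character(length(lens))
  out_start <- integer(length(lens))
  chroms <- names(chrom_len)
  tries <- 0L
  for (i in order(-lens)) {   # place long elements first
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("element placement infeasible after ", max_tries, " tries",
             call. = FALSE)
      }
      ch <- sample(chroms, 1, prob = chrom_len)
      s <- sample.int(chrom_len[[ch]] - lens[i] + 1L, 1) - 1L
      e <- s + lens[i]
      occ <- taken[[ch]]
      clash <- !is.null(occ) && any(s < occ[, 2] & e > occ[, 1])
      if (!clash && !is.null(n_blocks)) {
        nb <- n_blocks[n_blocks$chrom == ch, , drop = FALSE]
        clash <- nrow(nb) > 0 && any(s < nb$end & e > nb$start)
      }
      if (!clash) {
        taken[[ch]] <- rbind(occ, c(s, e))
        out_chrom[i] <- ch
        out_start[i] <- s
        break
      }
    }
  }
  tibble::tibble(chrom = out_chrom, start = out_start,
                 end = out_start + as.integer(lens))
}

#' Generate signal tracks over a planted genome
#'
#' Each configured track is piecewise constant over `signal_bin`-wide
#' bins: half-normal baseline noise (|N(0, noise_sd)|) everywhere, plus
#' the track's `gain` added over bins overlapping elements of the
#' classes it marks. Values are strictly nonnegative.
#'
#' @param genome Genome tibble.
#' @param elements Annotation tibble with a `class` column (from
#'   [plant_elements()]).
#' @param config A [synth_config()].
#' @return Named list of `signal_track` objects.
#' @export
generate_signal_tracks <- function(genome, elements, config) {
  seeds <- derive_seeds(config$seed, 4 + length(config$tracks))
  chrom_len <- stats::setNames(nchar(genome$sequence), genome$id)
  bin <- config$signal_bin
  out <- list()
  for (t in seq_along(config$tracks)) {
    spec <- config$tracks[[t]]
    gain <- if (!is.null(spec$gain)) spec$gain else config$signal_gain
    marked <- elements[elements$class %in% spec$marks, , drop = FALSE]
    segs <- withr::with_seed(seeds[4 + t], {
      purrr::map(genome$id, function(ch) {
        L <- chrom_len[[ch]]
        starts <- seq.int(0L, L - 1L, by = bin)
        ends <- pmin(starts + bin, L)
        vals <- abs(stats::rnorm(length(starts), 0, config$noise_sd))
        me <- marked[marked$chrom == ch, , drop = FALSE]
        if (nrow(me) > 0) {
          hit <- total_overlap_bp(
            tibble::tibble(chrom = ch, start = starts, end = ends), me
          ) > 0
          vals[hit] <- vals[hit] + gain
        }
        tibble::tibble(chrom = ch, start = starts, end = ends, value = vals)
      })
    })
    out[[names(config$tracks)[t]]] <- signal_track(dplyr::bind_rows(segs))
  }
  out
}

#' Generate a complete in-memory fixture
#'
#' Convenience wrapper running [generate_genome()], [plant_elements()]
#' and [generate_signal_tracks()] and deriving a DHS-cluster set from the
#' planted elements (all enhancers and promoters are open chromatin in
#' this toy world).
#'
#' @param config A [synth_config()].
#' @return List with `genome`, `elements`, `tss`, `tracks`, `dhs`,
#'   `config`.
#' @export
generate_fixture <- function(config = synth_config()) {
  genome <- generate_genome(config)
  planted <- plant_elements(genome, config)
  tracks <- generate_signal_tracks(planted$genome, planted$elements, config)
  dhs <- planted$elements[, c("chrom", "start", "end", "id")]
  list(genome = planted$genome, elements = planted$elements,
       tss = planted$tss, tracks = tracks, dhs = dhs, config = config)
}

#' Write a fixture bundle to disk
#'
#' Emits the genome FASTA, annotation TSV, TSS BED, DHS BED, one
#' bedGraph per signal track, and a JSON manifest echoing the
#' configuration and seed. Re-running with the same configuration
#' produces a byte-identical bundle.
#'
#' @param outdir Output directory (created if missing).
#' @param config A [synth_config()].
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
write_fixture_bundle <- function(outdir, config = synth_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_fixture(config)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.tsv"),
    tss = file.path(outdir, "tss.bed"),
    dhs = file.path(outdir, "dhs.bed"),
    tracks = stats::setNames(
      file.path(outdir, sprintf("track_%s.bedGraph", names(fx$tracks))),
      names(fx$tracks)
    )
  )
  write_fasta(fx$genome, paths$genome)
  write_annotation_table(fx$elements, paths$annotation)
  write_tss_table(fx$tss, paths$tss)
  write_bed(fx$dhs, paths$dhs)
  for (nm in names(fx$tracks)) {
    write_signal_track(fx$tracks[[nm]], paths$tracks[[nm]])
  }
  manifest <- list(
    seed = config$seed,
    chrom_lengths = as.list(config$chrom_lengths),
    n_enhancers = as.list(config$n_enhancers),
    n_promoters = config$n_promoters,
    element_length_mean = config$element_length_mean,
    element_length_var = config$element_length_var,
    enrichment_odds = config$enrichment_odds,
    enriched_kmers = config$enriched_kmers,
    signal_gain = config$signal_gain,
    noise_sd = config$noise_sd,
    files = c(genome = "genome.fa", annotation = "annotation.tsv",
              tss = "tss.bed", dhs = "dhs.bed",
              stats::setNames(basename(paths$tracks),
                              paste0("track_", names(paths$tracks))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
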