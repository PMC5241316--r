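#' Derive reproducible per-stage seeds from a master seed
#'
#' Splits one master seed into named integer sub-seeds (all below 2^31) so
#' that each pipeline stage, and each replicate network instance, can be
#' re-run in isolation.
#'
#' @param master Master seed (integer).
#' @param n_instances Number of replicate network instances.
#' @return A list with `build`, `stimuli`, `train`, `test` (vectors of
#'   length `n_instances`) and `analyze` (scalar).
#' @export
derive_seeds <- function(master, n_instances = 1) {
  mix <- function(k) {
    # splitmix-style integer hash, kept in [1, 2^31 - 2]
    x <- (as.double(master) * 2654435761 + k * 40503 + 12345) %% 2147483647
    as.integer(x) + 1L
  }
  list(build = vapply(seq_len(n_instances), function(i) mix(1000 + i), 1L),
       stimuli = vapply(seq_len(n_instances), function(i) mix(2000 + i), 1L),
       train = vapply(seq_len(n_instances), function(i) mix(3000 + i), 1L),
       test = vapply(seq_len(n_instances), function(i) mix(4000 + i), 1L),
       analyze = mix(5000))
}

#' Print the schedule sizes of a configuration without simulating
#'
#' @param config A [sim_config()] object.
#' @return Invisibly, a list with `training_trials`, `testing_trials`,
#'   `steps_per_trial`, `testing_steps` and `cells`.
#' @export
dry_run <- function(config = sim_config()) {
  n_areas <- nrow(area_table(config$scale))
  training <- config$n_words * config$trials_per_pattern
  testing <- 2L * config$n_words * config$trials_per_stimulus
  steps <- config$baseline_steps + config$stim_steps + config$post_steps
  out <- list(
    training_trials = training,
    testing_trials = testing,
    steps_per_trial = steps,
    testing_steps = testing * steps,
    cells = 2L * n_areas * config$grid^2
  )
  cat(sprintf("scale: %s (%d areas, %d cells)\n", config$scale, n_areas,
              out$cells))
  cat(sprintf("training: %d trials (%d per pattern x %d patterns)\n",
              training, config$trials_per_pattern, config$n_words))
  cat(sprintf("testing: %d trials x %d steps = %d simulation steps\n",
              testing, steps, out$testing_steps))
  invisible(out)
}

#' Run one replicate of the full experiment
#'
#' Builds a network, generates word and pseudoword stimuli, trains, and
#' records testing trials: the simulation half of the pipeline for one
#' network instance, with one seed controlling everything.
#'
#' @param config A [sim_config()] object.
#' @param seed Instance seed (controls build, stimuli, training order and
#'   all simulation noise).
#' @return A list with `connectome` (trained), `stimuli`, `recordings`,
#'   `training` (schedule + weight log) and `seed`.
#' @export
run_instance <- function(config = sim_config("miniature"), seed = 1) {
  seeds <- derive_seeds(seed)
  set.seed(seeds$build[1])
  connectome <- build_architecture(config)
  set.seed(seeds$stimuli[1])
  stimuli <- make_pseudowords(make_word_patterns(config))
  set.seed(seeds$train[1])
  training <- run_training(connectome, stimuli, config)
  set.seed(seeds$test[1])
  recordings <- run_testing(training$connectome, stimuli, config)
  list(connectome = training$connectome, stimuli = stimuli,
       recordings = recordings,
       training = training[c("schedule", "log")], seed = seed)
}

#' Word-versus-pseudoword spectral analysis of one instance
#'
#' The paper-style analysis chain applied to one instance's recordings:
#' band-averaged induced power per condition, the word minus pseudoword
#' contrast in a stimulus window, the frequency of maximal word-induced
#' power, and seed-to-primary-area coherence per word category.
#'
#' @param recordings A `spikelex_recordings` containing both conditions.
#' @param band Frequency band of interest (Hz).
#' @param window Stimulus window (s relative to onset) for summary means.
#' @param freqs_full Frequency axis for the peak-frequency scan.
#' @param coherence_areas Seed and the two target areas for the category
#'   dissociation (`NULL` to skip).
#' @return A list with `induced_word`, `induced_pseudo` (areas x bins),
#'   `times`, `contrast` (scalar window mean difference), `peak_freq`,
#'   and `coherence` (data frame, one row per category x target).
#' @export
analyze_instance <- function(recordings, band = c(20, 40),
                             window = c(0, 0.5), freqs_full = 4:100,
                             coherence_areas = c(seed = "M1_i",
                                                 object = "V1",
                                                 action = "M1_L")) {
  w_tr <- which(recordings$meta$condition == "word")
  p_tr <- which(recordings$meta$condition == "pseudoword")
  freqs_band <- seq(band[1], band[2])
  tw <- induced_power(recordings, w_tr, freqs = freqs_band)
  tp <- induced_power(recordings, p_tr, freqs = freqs_band)
  bw <- band_average(tw, band)
  bp <- band_average(tp, band)
  tsel <- tw$times >= window[1] & tw$times <= window[2]
  contrast <- mean(bw[, tsel], na.rm = TRUE) - mean(bp[, tsel], na.rm = TRUE)
  twf <- induced_power(recordings, w_tr, freqs = freqs_full)
  pf <- peak_frequency(twf, window = window)
  coh <- NULL
  if (!is.null(coherence_areas)) {
    for (cat_ in c("object", "action")) {
      trs <- which(recordings$meta$condition == "word" &
                     recordings$meta$category == cat_)
      for (tgt in c("object", "action")) {
        ch <- wavelet_coherence(recordings, coherence_areas[["seed"]],
                                coherence_areas[[tgt]], trs,
                                freqs = freqs_band)
        csel <- ch$times >= window[1] & ch$times <= window[2]
        coh <- rbind(coh, data.frame(
          category = cat_, target = coherence_areas[[tgt]],
          grounded = cat_ == tgt,
          coherence = mean(ch$coherence[, csel], na.rm = TRUE)))
      }
    }
  }
  list(induced_word = bw, induced_pseudo = bp, times = tw$times,
       contrast = contrast, peak_freq = pf, coherence = coh)
}

#' Run the multi-replicate word/pseudoword experiment
#'
#' The top-level pipeline: simulates `n_instances` independently seeded
#' network instances end to end ([run_instance()]), analyses each
#' ([analyze_instance()]), and pools the per-instance band-averaged
#' induced power into the cluster-based permutation test and the
#' peak-amplitude test.
#'
#' @param config A [sim_config()] object (miniature scale recommended;
#'   full scale is long-running).
#' @param n_instances Number of replicate instances.
#' @param seed Master seed.
#' @param n_perm Permutations for the cluster test.
#' @param keep_recordings Keep each instance's raw recordings in the
#'   result (large).
#' @param freqs_full Frequency axis for the peak-frequency scan, passed
#'   to [analyze_instance()].
#' @param verbose Print a line per instance.
#' @return An object of class `spikelex_experiment`: per-instance
#'   summaries, the pooled cluster test, the peak-amplitude test, and the
#'   configuration.
#' @export
run_experiment <- function(config = sim_config("miniature"),
                           n_instances = 5, seed = 1, n_perm = 1000,
                           keep_recordings = FALSE, freqs_full = 4:100,
                           verbose = TRUE) {
  seeds <- derive_seeds(seed, n_instances)
  inst <- vector("list", n_instances)
  ana <- vector("list", n_instances)
  peaks_w <- peaks_p <- numeric(n_instances)
  for (i in seq_len(n_instances)) {
    inst_i <- run_instance(config, seeds$train[i])
    ana[[i]] <- analyze_instance(inst_i$recordings, freqs_full = freqs_full)
    pk <- peak_serp_amplitude(inst_i$recordings)
    peaks_w[i] <- mean(pk$peak[pk$condition == "word"])
    peaks_p[i] <- mean(pk$peak[pk$condition == "pseudoword"])
    if (verbose) {
      message(sprintf(
        "instance %d/%d: induced 20-40 Hz contrast %.3g, peak %d Hz",
        i, n_instances, ana[[i]]$contrast, ana[[i]]$peak_freq))
    }
    if (keep_recordings) inst[[i]] <- inst_i
  }
  n_areas <- nrow(ana[[1]]$induced_word)
  nb <- ncol(ana[[1]]$induced_word)
  arr <- function(field) {
    a <- array(NA_real_, c(n_instances, n_areas, nb))
    for (i in seq_len(n_instances)) a[i, , ] <- ana[[i]][[field]]
    a
  }
  set.seed(seeds$analyze)
  cluster <- cluster_permutation_test(arr("induced_word"),
                                      arr("induced_pseudo"), n_perm = n_perm)
  peak_test <- peak_amplitude_test(peaks_w, peaks_p)
  structure(list(
    analyses = ana, instances = if (keep_recordings) inst else NULL,
    times = ana[[1]]$times,
    contrasts = vapply(ana, `[[`, numeric(1), "contrast"),
    peak_freqs = vapply(ana, `[[`, numeric(1), "peak_freq"),
    coherence = do.call(rbind, c(lapply(seq_len(n_instances), function(i) {
      cbind(instance = i, ana[[i]]$coherence)
    }), list(make.row.names = FALSE))),
    cluster = cluster, peak_amplitude = peak_test,
    peaks_word = peaks_w, peaks_pseudo = peaks_p,
    config = config, seed = seed
  ), class = "spikelex_experiment")
}

#' @exportS3Method base::print
print.spikelex_experiment <- function(x, ...) {
  n <- length(x$contrasts)
  cat(sprintf("<spikelex_experiment> %d instances, master seed %d\n",
              n, x$seed))
  cat(sprintf("  induced 20-40 Hz word-pseudoword contrast > 0 in %d/%d instances\n",
              sum(x$contrasts > 0), n))
  cat(sprintf("  word-induced peak frequencies: %s Hz\n",
              paste(x$peak_freqs, collapse = ", ")))
  if (!is.null(x$cluster$clusters)) {
    cat(sprintf("  cluster test: %d suprathreshold cluster(s), min p = %.4g\n",
                nrow(x$cluster$clusters), x$cluster$min_p))
  } else {
    cat("  cluster test: no suprathreshold clusters (p = 1)\n")
  }
  cat(sprintf("  peak amplitude (word vs pseudoword): t(%d) = %.2f, p = %.3g\n",
              x$peak_amplitude$df, x$peak_amplitude$t, x$peak_amplitude$p))
  invisible(x)
}

#' Export the statistical results of an experiment as delimited text
#'
#' Writes two TSV files: `clusters.tsv` (cluster extents, masses, p
#' values) and `summary.tsv` (per-instance contrasts, peak frequencies,
#' coherence means, peak amplitudes).
#'
#' @param experiment A `spikelex_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- experiment$cluster$clusters
  if (is.null(cl)) {
    cl <- data.frame(site = integer(0), from = integer(0), to = integer(0),
                     sign = integer(0), mass = numeric(0), p = numeric(0))
  }
  utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  n <- length(experiment$contrasts)
  summ <- data.frame(
    instance = seq_len(n),
    induced_contrast = experiment$contrasts,
    peak_freq = experiment$peak_freqs,
    peak_amp_word = experiment$peaks_word,
    peak_amp_pseudo = experiment$peaks_pseudo
  )
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(experiment$coherence)) {
    utils::write.table(experiment$coherence,
                       file.path(dir, "coherence.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
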