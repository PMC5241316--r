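#' Randomly ordered training schedule
#'
#' Every word appears exactly `trials_per_pattern` times, in a uniformly
#' random order (3000 trials per word, 36,000 trials in total, at the
#' default full scale).
#'
#' @param n_words Number of word patterns.
#' @param trials_per_pattern Learning trials per word.
#' @return Integer vector of word indices, one per learning trial.
#' @export
training_schedule <- function(n_words, trials_per_pattern) {
  sample(rep(seq_len(n_words), trials_per_pattern))
}

#' Simulate word learning (semantic grounding)
#'
#' Runs the full training schedule in learning mode (learning values of
#' `k2` and `kG`, plasticity on at every step). Each learning trial
#' presents one word's sensorimotor pattern triplet — constant
#' suprathreshold drive to the active cells of its primary areas — for
#' `t_on` steps, followed by `isi` noise-only steps; network state carries
#' over between trials (no reset during learning).
#'
#' @param connectome A `spikelex_connectome` (naive or pre-trained).
#' @param stimuli A `spikelex_stimuli`.
#' @param config A [sim_config()] object.
#' @param schedule Optional pre-built schedule (defaults to
#'   [training_schedule()] under the current RNG).
#' @param snapshot_every Record the mean E->E weight every this many
#'   trials (`NULL` to disable).
#' @param verbose Print progress every 10% of the schedule.
#' @return A list with the trained `connectome`, the `schedule`, the final
#'   `state` and a `log` data frame of weight snapshots.
#' @export
run_training <- function(connectome, stimuli, config = sim_config(),
                         schedule = NULL, snapshot_every = NULL,
                         verbose = FALSE) {
  params <- set_mode(config$params, "learning")
  if (is.null(schedule)) {
    schedule <- training_schedule(length(stimuli$words),
                                  config$trials_per_pattern)
  }
  state <- new_state(connectome)
  ext_by_word <- lapply(stimuli$words, stimulus_drive,
                        connectome = connectome, amp = config$stim_amp)
  log_trial <- integer(0)
  log_w <- numeric(0)
  n <- length(schedule)
  for (i in seq_len(n)) {
    w <- schedule[i]
    r <- simulate_steps(state, connectome, params, config$t_on,
                        ext = ext_by_word[[w]], learn = TRUE, record = FALSE)
    r <- simulate_steps(r$state, r$connectome, params, config$isi,
                        learn = TRUE, record = FALSE)
    state <- r$state
    connectome <- r$connectome
    if (!is.null(snapshot_every) && i %% snapshot_every == 0) {
      log_trial <- c(log_trial, i)
      log_w <- c(log_w, mean(connectome$W_ee@x))
    }
    if (verbose && i %% max(1L, n %/% 10L) == 0L) {
      message("training trial ", i, "/", n,
              " (mean E->E weight ", signif(mean(connectome$W_ee@x), 4), ")")
    }
  }
  list(connectome = connectome, schedule = schedule, state = state,
       log = data.frame(trial = log_trial, mean_weight = log_w))
}

#' Record testing trials for all word and pseudoword stimuli
#'
#' Testing mode: testing values of `k2` and `kG`, plasticity frozen. Each
#' trial starts with a global network reset (all state variables 0),
#' followed by a noise-only baseline, stimulation of area A1 only with the
#' stimulus's auditory pattern, and a noise-only post-stimulus interval
#' (1.5 s + 0.5 s + 1 s = 3 s, i.e. 3000 + 1000 + 2000 steps, at the
#' defaults). The per-area S-ERP (sum of excitatory membrane potentials)
#' and total spike count are recorded at every step.
#'
#' @param connectome A trained `spikelex_connectome`.
#' @param stimuli A `spikelex_stimuli` with pseudowords built.
#' @param config A [sim_config()] object.
#' @param conditions Which stimulus sets to run (`"word"`,
#'   `"pseudoword"`, or both).
#' @return An object of class `spikelex_recordings`: `serp` and `spikes`
#'   arrays `[areas x steps x trials]`, a `meta` data frame (stimulus id,
#'   condition, category, trial index), the trial segmentation and the
#'   sampling step.
#' @export
run_testing <- function(connectome, stimuli, config = sim_config(),
                        conditions = c("word", "pseudoword")) {
  params <- set_mode(config$params, "testing")
  if ("pseudoword" %in% conditions && is.null(stimuli$pseudowords)) {
    stop("stimuli has no pseudowords; call make_pseudowords() first")
  }
  stim_list <- list()
  meta <- NULL
  if ("word" %in% conditions) {
    for (w in seq_along(stimuli$words)) {
      stim_list <- c(stim_list, list(list(A1 = stimuli$words[[w]]$A1)))
      meta <- rbind(meta, data.frame(
        stimulus = paste0("word_", w), condition = "word",
        category = stimuli$category[w]))
    }
  }
  if ("pseudoword" %in% conditions) {
    for (p in seq_along(stimuli$pseudowords)) {
      stim_list <- c(stim_list, list(list(A1 = as.integer(stimuli$pseudowords[[p]]))))
      meta <- rbind(meta, data.frame(
        stimulus = paste0("pseudoword_", p), condition = "pseudoword",
        category = NA_character_))
    }
  }
  steps <- config$baseline_steps + config$stim_steps + config$post_steps
  n_areas <- nrow(connectome$areas)
  n_trials <- nrow(meta) * config$trials_per_stimulus
  serp <- array(NA_real_, c(n_areas, steps, n_trials),
                dimnames = list(connectome$areas$name, NULL, NULL))
  spikes <- serp
  meta_all <- meta[rep(seq_len(nrow(meta)), each = config$trials_per_stimulus), ]
  meta_all$trial <- seq_len(n_trials)
  rownames(meta_all) <- NULL

  tr <- 0L
  for (s in seq_along(stim_list)) {
    ext <- stimulus_drive(connectome, stim_list[[s]], config$stim_amp)
    for (rep_i in seq_len(config$trials_per_stimulus)) {
      tr <- tr + 1L
      state <- new_state(connectome)   # global network reset
      r1 <- simulate_steps(state, connectome, params, config$baseline_steps)
      r2 <- simulate_steps(r1$state, connectome, params, config$stim_steps,
                           ext = ext)
      r3 <- simulate_steps(r2$state, connectome, params, config$post_steps)
      serp[, , tr] <- cbind(r1$serp, r2$serp, r3$serp)
      spikes[, , tr] <- cbind(r1$spikes, r2$spikes, r3$spikes)
    }
  }
  structure(list(
    serp = serp, spikes = spikes, meta = meta_all,
    areas = connectome$areas$name, dt = params$dt,
    baseline_steps = config$baseline_steps,
    stim_steps = config$stim_steps, post_steps = config$post_steps
  ), class = "spikelex_recordings")
}

#' @exportS3Method base::print
print.spikelex_recordings <- function(x, ...) {
  cat(sprintf("<spikelex_recordings> %d trials x %d areas x %d steps (dt = %g ms)\n",
              dim(x$serp)[3], dim(x$serp)[1], dim(x$serp)[2], x$dt))
  print(table(x$meta$condition))
  invisible(x)
}

#' Time axis of a testing trial
#'
#' Seconds relative to stimulus onset: the first stimulation step is time
#' 0, baseline times are negative.
#'
#' @param recordings A `spikelex_recordings`.
#' @return Numeric vector, one time per recorded step.
#' @export
trial_times <- function(recordings) {
  steps <- dim(recordings$serp)[2]
  ((seq_len(steps) - 1) - recordings$baseline_steps) * recordings$dt / 1000
}

#' Serialise / restore recordings
#'
#' Lossless round-trip of the recording container.
#'
#' @param recordings A `spikelex_recordings`.
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
write_recordings <- function(recordings, path) {
  saveRDS(recordings, path)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "spikelex_recordings")) stop("not a recordings file: ", path)
  x
}

#' Identify the cell assembly of each word
#'
#' Presents each word's auditory (A1) pattern in noise-free testing mode
#' (`k2 = 0`, plasticity frozen) after a global reset, and collects the
#' time-averaged firing-rate estimate `omega_E` of every excitatory cell.
#' Cells whose time-average exceeds `gamma` times the network-wide mean
#' are taken as members of that word's assembly; assemblies of different
#' words may overlap.
#'
#' @param connectome A trained `spikelex_connectome`.
#' @param stimuli A `spikelex_stimuli`.
#' @param config A [sim_config()] object.
#' @param gamma Membership threshold as a multiple of the network mean.
#' @param n_steps Presentation length in steps.
#' @return A list with `members` (per word, global excitatory-cell ids)
#'   and `counts` (words x areas matrix of member counts).
#' @export
identify_cell_assemblies <- function(connectome, stimuli,
                                     config = sim_config(), gamma = 5,
                                     n_steps = 500) {
  params <- set_mode(config$params, "testing")
  params$k2 <- 0
  n_areas <- nrow(connectome$areas)
  members <- vector("list", length(stimuli$words))
  counts <- matrix(0L, length(stimuli$words), n_areas,
                   dimnames = list(paste0("word_", seq_along(stimuli$words)),
                                   connectome$areas$name))
  for (w in seq_along(stimuli$words)) {
    ext <- stimulus_drive(connectome, list(A1 = stimuli$words[[w]]$A1),
                          config$stim_amp)
    r <- simulate_steps(new_state(connectome), connectome, params, n_steps,
                        ext = ext, record = FALSE)
    avg <- r$omega_E_mean
    thr <- gamma * mean(avg)
    m <- which(avg > thr)
    members[[w]] <- m
    counts[w, ] <- tabulate(connectome$area_of[m], nbins = n_areas)
  }
  list(members = members, counts = counts)
}
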