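# Small fixtures built in code. A "toy" configuration is the miniature
# preset shrunk further so oracle comparisons against scalar reference
# implementations stay fast (<50 cells per area).

toy_config <- function(...) {
  sim_config("miniature", grid = 5L, n_exc_nb = 3L, n_inh_nb = 3L,
             cells_per_pattern = 3L, sub_square = 2L, n_words = 4L,
             trials_per_pattern = 5L, t_on = 4L, isi = 6L,
             baseline_steps = 40L, stim_steps = 20L, post_steps = 20L,
             trials_per_stimulus = 2L, ...)
}

toy_connectome <- function(seed = 1, ...) {
  set.seed(seed)
  build_architecture(toy_config(...))
}

# Recordings container around a given serp array, for spectral tests that
# need controlled signals rather than simulated ones.
fake_recordings <- function(serp, dt = 0.5, baseline_steps = dim(serp)[2] %/% 2,
                            condition = rep("word", dim(serp)[3])) {
  if (is.null(dimnames(serp)[[1]])) {
    dimnames(serp) <- list(paste0("area", seq_len(dim(serp)[1])), NULL, NULL)
  }
  structure(list(
    serp = serp, spikes = serp * 0,
    meta = data.frame(stimulus = paste0("s", seq_len(dim(serp)[3])),
                      condition = condition, category = NA,
                      trial = seq_len(dim(serp)[3])),
    areas = dimnames(serp)[[1]], dt = dt,
    baseline_steps = baseline_steps,
    stim_steps = (dim(serp)[2] - baseline_steps) %/% 2,
    post_steps = dim(serp)[2] - baseline_steps -
      (dim(serp)[2] - baseline_steps) %/% 2
  ), class = "spikelex_recordings")
}
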