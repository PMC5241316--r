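# The word/pseudoword experiment at the default miniature study
# conditions is expensive (five independently trained replicate networks),
# so it is simulated once and shared by the tests that examine different
# aspects of its outcome.

.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function() {
  if (is.null(.experiment_cache$exp)) {
    .experiment_cache$exp <- run_experiment(
      sim_config("miniature"), n_instances = 5, seed = 1,
      n_perm = 1000, verbose = FALSE)
  }
  .experiment_cache$exp
}
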