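#' Model parameters of the spiking network
#'
#' Scalar constants of the cell equations: membrane leak-integration,
#' spike output with adaptation, the low-pass estimators of firing rate and
#' area activity, and the Hebbian learning rule. Defaults are the typical
#' values used in the simulations; the `mode` argument switches the noise
#' amplitude `k2` and the global-inhibition strength `kG` jointly between
#' their learning and testing values.
#'
#' @param mode `"learning"` or `"testing"`. Learning uses `k2 = 5 * (24/dt)`
#'   and `kG = 0.75`; testing uses `k2 = 50 * (24/dt)` and `kG = 0.60`.
#' @param dt Integration step in ms (Euler scheme).
#' @param ... Named overrides for any parameter listed below.
#'
#' @return An object of class `spikelex_params`: a named list with fields
#'   `tau_exc`, `tau_inh` (membrane time constants, in simulation steps),
#'   `k1` (input rescaling), `k2` (noise amplitude), `kG` (global-inhibition
#'   strength), `thresh` (spiking threshold), `alpha` (adaptation strength),
#'   `tau_adapt`, `tau_favg`, `tau_glob` (time constants of adaptation,
#'   rate estimate, and global inhibition, in steps), `theta_plus`,
#'   `theta_minus` (postsynaptic potential thresholds for LTP/LTD),
#'   `theta_pre` (presynaptic rate threshold), `delta` (learning increment),
#'   `dt` (ms) and `mode`.
#' @export
#' @examples
#' p <- model_params("testing")
#' p$kG    # 0.60
#' p$k2    # 50 * (24 / 0.5) = 2400
model_params <- function(mode = c("testing", "learning"), dt = 0.5, ...) {
  mode <- match.arg(mode)
  p <- list(
    tau_exc    = 2.5,
    tau_inh    = 5,
    k1         = 0.01,
    k2         = if (mode == "learning") 5 * (24 / dt) else 50 * (24 / dt),
    kG         = if (mode == "learning") 0.75 else 0.60,
    thresh     = 0.18,
    alpha      = 7.0,
    tau_adapt  = 10,
    tau_favg   = 30,
    tau_glob   = 12,
    theta_plus = 0.15,
    theta_minus = 0.14,
    theta_pre  = 0.05,
    delta      = 0.0008,
    dt         = dt,
    mode       = mode
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  class(p) <- "spikelex_params"
  validate_params(p)
  p
}

#' @exportS3Method base::print
print.spikelex_params <- function(x, ...) {
  cat("<spikelex_params> mode =", x$mode, "\n")
  flds <- setdiff(names(x), "mode")
  for (f in flds) cat(sprintf("  %-11s %g\n", f, x[[f]]))
  invisible(x)
}

validate_params <- function(p) {
  tc <- c("tau_exc", "tau_inh", "tau_adapt", "tau_favg", "tau_glob")
  for (f in tc) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      stop("parameter '", f, "' must be a positive time constant")
    }
  }
  if (p$dt <= 0) stop("parameter 'dt' must be > 0")
  if (p$delta <= 0) stop("parameter 'delta' must be > 0")
  if (p$theta_minus >= p$theta_plus) {
    stop("'theta_minus' must be strictly below 'theta_plus'")
  }
  invisible(p)
}

#' Switch a parameter set between learning and testing mode
#'
#' Re-derives the mode-dependent pair (`k2`, `kG`) while keeping every other
#' (possibly overridden) field.
#'
#' @param params A [model_params()] object.
#' @param mode `"learning"` or `"testing"`.
#' @return A `spikelex_params` object in the requested mode.
#' @export
set_mode <- function(params, mode = c("testing", "learning")) {
  mode <- match.arg(mode)
  params$mode <- mode
  params$k2 <- if (mode == "learning") 5 * (24 / params$dt) else 50 * (24 / params$dt)
  params$kG <- if (mode == "learning") 0.75 else 0.60
  validate_params(params)
  params
}

#' Full simulation configuration
#'
#' Bundles the cell-equation constants ([model_params()]) with the
#' architectural and protocol settings that the model text leaves open
#' (connection probability profile, weight ceiling, stimulus amplitude,
#' learning-trial timing), all exposed here so every choice is explicit
#' and serialisable.
#'
#' The `"full"` scale is the default study condition: 12 areas of 25x25
#' excitatory + 25x25 inhibitory cells, 12 words (6 object, 6 action) of
#' 19-cell patterns, 3000 learning trials per word, and 3-s testing trials
#' (1.5 s baseline, 0.5 s stimulation, 1 s post-stimulus at a 0.5-ms step).
#' The `"miniature"` scale is the same code path shrunk for desk-scale
#' experiments and tests: 6 areas (A1, PB, M1_i; V1, AT, M1_L) of 11x11
#' cells and 4 words of 10-cell patterns, keeping the 3000 learning
#' trials per word.
#'
#' @param scale `"full"` or `"miniature"`.
#' @param mode passed to [model_params()].
#' @param ... Named overrides for any configuration field (unknown names are
#'   an error). Model-parameter fields can be overridden via a `params`
#'   entry.
#' @return An object of class `spikelex_config`.
#' @export
sim_config <- function(scale = c("full", "miniature"),
                       mode = c("testing", "learning"), ...) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  cfg <- list(
    scale = scale,
    params = model_params(mode),
    # architecture
    grid = 25L,                 # cells per side of each square area
    n_exc_nb = 19L,             # excitatory projection neighbourhood (n x n)
    n_inh_nb = 5L,              # inhibitory fan-in neighbourhood
    p0 = 0.5,                   # peak connection probability
    sigma_frac = 0.5,           # Gaussian width as a fraction of n
    w_init_max = 0.1,           # initial weights ~ U[0, w_init_max]
    w_max = 22.5,               # plasticity ceiling on E->E weights
    g_ei = NULL,                # E->I weight (default 1/n_inh_nb^2)
    g_ie = 90000,               # magnitude of the I->twin-E weight
    # stimuli
    n_words = 12L,
    cells_per_pattern = 19L,
    sub_square = 5L,            # tile size for pseudoword recombination
    # training protocol
    trials_per_pattern = 3000L,
    t_on = 16L,                 # stimulus-on steps per learning trial
    isi = 30L,                  # noise-only steps between learning trials
    stim_amp = 1200,            # external drive to active pattern cells
    # testing protocol
    baseline_steps = 3000L,
    stim_steps = 1000L,
    post_steps = 2000L,
    trials_per_stimulus = 10L
  )
  if (scale == "miniature") {
    cfg$grid <- 11L
    cfg$n_exc_nb <- 9L
    cfg$n_inh_nb <- 3L
    cfg$n_words <- 4L
    cfg$cells_per_pattern <- 10L
    cfg$sub_square <- 4L       # 3x3 = 9 tiles = 2 per word + 1
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (is.null(cfg$g_ei)) cfg$g_ei <- 1 / cfg$n_inh_nb^2
  if (!inherits(cfg$params, "spikelex_params")) {
    stop("'params' must be a model_params() object")
  }
  stopifnot(cfg$grid >= 3, cfg$n_exc_nb %% 2 == 1, cfg$n_inh_nb %% 2 == 1)
  if (cfg$cells_per_pattern > cfg$grid^2) {
    stop("cells_per_pattern exceeds the number of cells in one area (",
         cfg$grid^2, ")")
  }
  if (cfg$p0 <= 0 || cfg$p0 > 1) stop("'p0' must lie in (0, 1]")
  class(cfg) <- "spikelex_config"
  cfg
}

#' @exportS3Method base::print
print.spikelex_config <- function(x, ...) {
  cat("<spikelex_config> scale =", x$scale, ", mode =", x$params$mode, "\n")
  cat(sprintf("  %d-word stimulus set, %d cells/pattern, grid %dx%d\n",
              x$n_words, x$cells_per_pattern, x$grid, x$grid))
  cat(sprintf("  training: %d trials/pattern (on %d + isi %d steps)\n",
              x$trials_per_pattern, x$t_on, x$isi))
  cat(sprintf("  testing:  %d + %d + %d steps/trial, %d trials/stimulus\n",
              x$baseline_steps, x$stim_steps, x$post_steps,
              x$trials_per_stimulus))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a plain-text YAML file whose keys mirror the configuration and
#' model-parameter field names; any key not present falls back to the
#' defaults of [sim_config()]. Model-equation constants go under a nested
#' `params:` block. An empty file yields the full defaults with a warning;
#' an unknown key is a fatal error naming the key.
#'
#' @param path Path to a YAML config file.
#' @param scale,mode defaults used unless the file overrides `scale` or
#'   `params$mode`.
#' @return A `spikelex_config` object.
#' @export
load_config <- function(path, scale = "full", mode = "testing") {
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0) {
    warning("empty config file '", path, "': using full defaults")
    return(sim_config(scale, mode))
  }
  if (!is.null(raw$scale)) scale <- raw$scale
  par_over <- raw$params
  if (!is.null(par_over$mode)) mode <- par_over$mode
  par_over$mode <- NULL
  raw$scale <- NULL
  raw$params <- NULL
  params <- do.call(model_params, c(list(mode = mode), par_over))
  do.call(sim_config, c(list(scale = scale, mode = mode), raw, list(params = params)))
}

#' Write a configuration file
#'
#' Serialises a configuration to YAML so that a run can be reproduced from
#' its config snapshot.
#'
#' @param config A `spikelex_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}
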