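#' Create a zeroed network state
#'
#' All state variables start at 0: membrane potentials of excitatory and
#' inhibitory cells, adaptation, the low-passed firing-rate estimate, the
#' per-area global-inhibition accumulators and the previous-step outputs.
#' The same function implements the global network reset performed at the
#' start of every testing trial.
#'
#' @param connectome A `spikelex_connectome`.
#' @return An object of class `spikelex_state` with fields `V_e`, `V_i`,
#'   `omega` (adaptation), `omega_E` (rate estimate), `omega_G` (per-area
#'   global inhibition), `phi_e`, `phi_i` (previous-step outputs) and `t`
#'   (step counter).
#' @export
new_state <- function(connectome) {
  Ne <- connectome$n_exc
  structure(list(
    V_e = numeric(Ne), V_i = numeric(Ne),
    omega = numeric(Ne), omega_E = numeric(Ne),
    omega_G = numeric(nrow(connectome$areas)),
    phi_e = numeric(Ne), phi_i = numeric(Ne),
    t = 0L
  ), class = "spikelex_state")
}

#' Net synaptic input to every cell
#'
#' For an excitatory cell the net input is the weighted sum of all
#' presynaptic outputs (inhibitory weights carry a negative sign), minus
#' the area's global-inhibition term `kG * omega_G`, plus any external
#' stimulus drive. Inhibitory cells receive only their local excitatory
#' fan-in: the global-inhibition term and the stimulus are absent for them.
#'
#' @param state A `spikelex_state` (previous-step outputs `phi_e`, `phi_i`
#'   are used).
#' @param connectome A `spikelex_connectome`.
#' @param ext Per-excitatory-cell external drive (`NULL` for none).
#' @param params A [model_params()] object.
#' @return A list with components `e` and `i`: net input per excitatory and
#'   per inhibitory cell.
#' @export
net_input <- function(state, connectome, ext = NULL, params = model_params()) {
  Ne <- connectome$n_exc
  if (length(state$V_e) != Ne || nrow(connectome$W_ee) != Ne) {
    stop("state/connectome dimension mismatch (", length(state$V_e),
         " state cells vs ", Ne, " connectome cells)")
  }
  vin_e <- as.numeric(connectome$W_ee %*% state$phi_e) -
    connectome$g_ie * state$phi_i -
    params$kG * state$omega_G[connectome$area_of]
  if (!is.null(ext)) vin_e <- vin_e + ext
  vin_i <- as.numeric(connectome$W_ei %*% state$phi_e)
  list(e = vin_e, i = vin_i)
}

#' One Euler step of the membrane equation
#'
#' `V <- V + (1/tau) * (-V + k1 * (vin + k2 * eta))`, with `eta` a uniform
#' noise draw on `[-0.5, 0.5]` per cell (`k2 = 0` for inhibitory cells,
#' which are noiseless). Potentials are not clipped.
#'
#' @param V Membrane potentials.
#' @param vin Net input (from [net_input()]).
#' @param tau Membrane time constant (steps).
#' @param k1 Input rescaling factor.
#' @param k2 Noise amplitude (0 for inhibitory cells).
#' @param eta Noise draws, one per cell (ignored when `k2 = 0`).
#' @return Updated potentials.
#' @export
membrane_step <- function(V, vin, tau, k1, k2 = 0, eta = numeric(length(V))) {
  V + (1 / tau) * (-V + k1 * (vin + k2 * eta))
}

#' Spike output of excitatory cells
#'
#' A cell spikes iff its membrane potential exceeds the threshold by more
#' than its current adaptation: `V - alpha * omega > thresh` (strict).
#'
#' @param V Membrane potentials.
#' @param omega Adaptation values.
#' @param params A [model_params()] object.
#' @return A 0/1 numeric vector of spikes.
#' @export
excitatory_output <- function(V, omega, params = model_params()) {
  as.numeric(V - params$alpha * omega > params$thresh)
}

#' Graded output of inhibitory cells
#'
#' Rectified-linear: 0 below 0, the membrane potential itself otherwise.
#'
#' @param V Inhibitory membrane potentials.
#' @return Non-negative graded outputs.
#' @export
inhibitory_output <- function(V) {
  pmax(V, 0)
}

#' Euler low-pass of a signal
#'
#' `x <- x + (1/tau) * (-x + input)`. With a {0,1} spike train and
#' `tau >= 1` the output stays in `[0, 1]`. This single operator implements
#' spike-rate adaptation (`tau_adapt`), the presynaptic firing-rate
#' estimate (`tau_favg`) and, fed with per-area total spike counts, the
#' global-inhibition accumulator (`tau_glob`).
#'
#' @param x Current low-pass value(s).
#' @param input Input signal (spikes, or per-area spike counts).
#' @param tau Time constant in steps.
#' @return Updated low-pass value(s).
#' @export
update_lowpass <- function(x, input, tau) {
  x + (1 / tau) * (-x + input)
}

#' @rdname update_lowpass
#' @param omega Adaptation values.
#' @param phi_e Current-step excitatory spikes.
#' @param params A [model_params()] object.
#' @export
update_adaptation <- function(omega, phi_e, params = model_params()) {
  update_lowpass(omega, phi_e, params$tau_adapt)
}

#' @rdname update_lowpass
#' @export
update_rate_estimate <- function(omega, phi_e, params = model_params()) {
  update_lowpass(omega, phi_e, params$tau_favg)
}

#' @rdname update_lowpass
#' @param omega_G Per-area global-inhibition accumulators.
#' @param area_of Area index of each excitatory cell.
#' @export
update_global_inhibition <- function(omega_G, phi_e, area_of,
                                     params = model_params()) {
  counts <- vapply(seq_along(omega_G),
                   function(a) sum(phi_e[area_of == a]), numeric(1))
  update_lowpass(omega_G, counts, params$tau_glob)
}

#' One synchronous network step (reference implementation)
#'
#' Plain-R composition of the cell equations, used as the scalar oracle
#' for the compiled engine and for small didactic runs. Within a step:
#' outputs are computed from the previous step's potentials (synchronous
#' update), then net inputs, then the membrane, adaptation, rate-estimate
#' and global-inhibition updates; if `learn = TRUE` the Hebbian rule is
#' applied last, using the step's spikes and the updated potentials. Noise
#' is drawn from R's global RNG, one uniform per excitatory cell per step,
#' in cell order — the compiled engine consumes the identical stream.
#'
#' @param state A `spikelex_state`.
#' @param connectome A `spikelex_connectome`.
#' @param params A [model_params()] object.
#' @param ext Optional per-excitatory-cell external drive.
#' @param learn Apply the plasticity rule at the end of the step.
#' @return A list with the updated `state` and (when `learn`) updated
#'   `connectome`.
#' @export
step_network <- function(state, connectome, params = model_params(),
                         ext = NULL, learn = FALSE) {
  phi_e <- excitatory_output(state$V_e, state$omega, params)
  phi_i <- inhibitory_output(state$V_i)
  st <- state
  st$phi_e <- phi_e
  st$phi_i <- phi_i
  vin <- net_input(st, connectome, ext, params)
  eta <- stats::runif(length(state$V_e)) - 0.5
  st$V_e <- membrane_step(state$V_e, vin$e, params$tau_exc, params$k1,
                          params$k2, eta)
  st$V_i <- membrane_step(state$V_i, vin$i, params$tau_inh, params$k1)
  st$omega <- update_adaptation(state$omega, phi_e, params)
  st$omega_E <- update_rate_estimate(state$omega_E, phi_e, params)
  st$omega_G <- update_global_inhibition(state$omega_G, phi_e,
                                         connectome$area_of, params)
  st$t <- state$t + 1L
  if (any(!is.finite(st$V_e)) || any(!is.finite(st$V_i))) {
    stop("non-finite membrane potential at step ", st$t)
  }
  if (learn) {
    connectome <- apply_plasticity(connectome, st, params)
  }
  list(state = st, connectome = connectome)
}

#' Run the compiled simulation engine
#'
#' Advances the network by `n_steps` synchronous steps using the C++
#' engine, which reproduces [step_network()] bit-for-bit (same equations,
#' same update order, same noise stream). Optionally applies the Hebbian
#' rule every step and records the per-area simulated event-related
#' potential (S-ERP: the sum of all excitatory membrane potentials in the
#' area) and total spike count at every step.
#'
#' @param state A `spikelex_state`.
#' @param connectome A `spikelex_connectome`.
#' @param params A [model_params()] object.
#' @param n_steps Number of steps to simulate.
#' @param ext Optional per-excitatory-cell external drive, constant over
#'   the call.
#' @param learn Apply plasticity (weights are clipped to
#'   `[0, w_max]`).
#' @param record Record S-ERP and spike counts (areas x steps matrices).
#' @return A list with `state`, `connectome` (weights updated when
#'   `learn`), `serp`, `spikes` (matrices, or `NULL` when `record =
#'   FALSE`) and `omega_E_mean` (per-cell time-average of the firing-rate
#'   estimate over the call).
#' @export
simulate_steps <- function(state, connectome, params = model_params(),
                           n_steps, ext = NULL, learn = FALSE,
                           record = TRUE) {
  Ne <- connectome$n_exc
  if (length(state$V_e) != Ne) {
    stop("state/connectome dimension mismatch")
  }
  if (is.null(ext)) ext <- numeric(Ne)
  W <- connectome$W_ee
  Wei <- connectome$W_ei
  out <- engine_run(
    state$V_e, state$V_i, state$omega, state$omega_E, state$omega_G,
    state$phi_e, state$phi_i,
    connectome$area_of, nrow(connectome$areas),
    W@i, W@p, W@x, Wei@i, Wei@p, Wei@x,
    connectome$g_ie, ext, as.integer(n_steps),
    params[c("tau_exc", "tau_inh", "k1", "k2", "kG", "thresh", "alpha",
             "tau_adapt", "tau_favg", "tau_glob", "theta_plus",
             "theta_minus", "theta_pre", "delta")],
    isTRUE(learn), connectome$settings$w_max, isTRUE(record), state$t
  )
  st <- state
  st$V_e <- out$V_e; st$V_i <- out$V_i
  st$omega <- out$omega; st$omega_E <- out$omega_E; st$omega_G <- out$omega_G
  st$phi_e <- out$phi_e; st$phi_i <- out$phi_i
  st$t <- state$t + as.integer(n_steps)
  if (learn) {
    W@x <- out$ee_x
    connectome$W_ee <- W
  }
  serp <- spikes <- NULL
  if (record) {
    serp <- out$serp
    spikes <- out$spikes
    rownames(serp) <- rownames(spikes) <- connectome$areas$name
  }
  list(state = st, connectome = connectome, serp = serp, spikes = spikes,
       omega_E_mean = out$omega_E_mean)
}
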