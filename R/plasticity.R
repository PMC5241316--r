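#' Spike-gated Hebbian weight change for one (or many) synapses
#'
#' Discretised Artola-Broecher-Singer rule on excitatory-to-excitatory
#' links. Writing `omega_E_pre` for the presynaptic firing-rate estimate
#' and `V_post` for the postsynaptic membrane potential, the change is
#'
#' * `+delta` (LTP) if `omega_E_pre >= theta_pre` and `V_post >= theta_plus`;
#' * `-delta` (homosynaptic LTD) if `omega_E_pre >= theta_pre` and
#'   `theta_minus <= V_post < theta_plus`;
#' * `-delta` (heterosynaptic LTD) if `omega_E_pre < theta_pre` and
#'   `V_post >= theta_plus`;
#' * `0` otherwise.
#'
#' The whole rule is gated by spiking: it applies only when the pre- or
#' the postsynaptic cell emitted a spike this step (inclusive OR); with no
#' spike on either side the change is 0 regardless of the potentials.
#'
#' All arguments are vectorised over synapses.
#'
#' @param omega_E_pre Presynaptic rate estimate(s).
#' @param V_post Postsynaptic membrane potential(s).
#' @param spike_pre,spike_post Binary outputs of the two cells this step.
#' @param params A [model_params()] object (uses `theta_pre`,
#'   `theta_plus`, `theta_minus`, `delta`).
#' @return Weight change(s), each exactly `+delta`, `-delta` or `0`.
#' @export
#' @examples
#' p <- model_params()
#' hebbian_delta(0.06, 0.16, 1, 0, p)   #  +0.0008 (LTP)
#' hebbian_delta(0.06, 0.145, 0, 1, p)  #  -0.0008 (homosynaptic LTD)
#' hebbian_delta(0.01, 0.20, 1, 0, p)   #  -0.0008 (heterosynaptic LTD)
#' hebbian_delta(0.5, 0.5, 0, 0, p)     #   0      (no gating spike)
hebbian_delta <- function(omega_E_pre, V_post, spike_pre, spike_post,
                          params = model_params()) {
  gate <- (spike_pre == 1) | (spike_post == 1)
  pre_on <- omega_E_pre >= params$theta_pre
  ltp <- pre_on & V_post >= params$theta_plus
  homo <- pre_on & V_post >= params$theta_minus & V_post < params$theta_plus
  hetero <- !pre_on & V_post >= params$theta_plus
  params$delta * as.numeric(gate) * (as.numeric(ltp) - as.numeric(homo) -
                                       as.numeric(hetero))
}

#' Apply the Hebbian rule to every excitatory-to-excitatory synapse
#'
#' Reference (plain-R) implementation used for oracle tests and small
#' runs; the compiled engine performs the identical update in-loop. Every
#' entry of the sparse E->E weight matrix is updated by [hebbian_delta()]
#' using the current step's spikes, the updated postsynaptic potential and
#' the updated presynaptic rate estimate, then clipped to `[0, w_max]`.
#' The inhibitory loop and the global-inhibition pathway are untouched.
#'
#' @param connectome A `spikelex_connectome`.
#' @param state A `spikelex_state` whose `phi_e`, `V_e` and `omega_E`
#'   belong to the current step.
#' @param params A [model_params()] object.
#' @return The connectome with updated `W_ee`.
#' @export
apply_plasticity <- function(connectome, state, params = model_params()) {
  W <- connectome$W_ee
  pre <- rep(seq_len(ncol(W)), diff(W@p))   # column (pre) index per entry
  post <- W@i + 1L
  dw <- hebbian_delta(state$omega_E[pre], state$V_e[post],
                      state$phi_e[pre], state$phi_e[post], params)
  W@x <- pmin(pmax(W@x + dw, 0), connectome$settings$w_max)
  connectome$W_ee <- W
  connectome
}
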