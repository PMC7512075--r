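#' Initial state of a leaky integrate-and-fire neuron
#'
#' @param v initial membrane potential (mV); default is the resting potential
#' @param g_e,g_i initial excitatory / inhibitory conductances (nS)
#' @param refractory_remaining remaining refractory time (ms)
#' @param is_excitatory population flag
#' @param params a \code{\link{neuron_params}} object (used for the default v)
#' @return a list with elements \code{v, g_e, g_i, refractory_remaining,
#'   is_excitatory}
#' @export
neuron_state <- function(v = NULL, g_e = 0, g_i = 0,
                         refractory_remaining = 0, is_excitatory = TRUE,
                         params = neuron_params()) {
  if (is.null(v)) v <- params$v_rest
  stopifnot(g_e >= 0, g_i >= 0, refractory_remaining >= 0)
  list(v = v, g_e = g_e, g_i = g_i,
       refractory_remaining = refractory_remaining,
       is_excitatory = is_excitatory)
}

#' Advance the membrane equation by one time step
#'
#' One fixed step of the conductance-based LIF membrane: forward Euler for the
#' voltage, exact exponential decay for the synaptic conductances. The
#' membrane obeys
#' \deqn{\tau_m dv/dt = (v_{rest} - v) + [g_e (v_e - v) + g_i (v_i - v) +
#'   I_{ex} + I_{syn}] / g_{leak}.}
#' \code{I_syn} is an additional injected current in pA with the depolarizing
#' direction positive; kinetic-receptor and slow-inward currents computed by
#' \code{\link{postsynaptic_currents}} / \code{\link{sic_current}} follow the
#' opposite (inward-negative) convention and must be negated before injection.
#' During the refractory period the voltage is clamped at \code{v_rest} while
#' the conductances keep decaying.
#'
#' @param state a neuron state list, see \code{\link{neuron_state}}
#' @param params a \code{\link{neuron_params}} object
#' @param I_syn injected current (pA), depolarizing positive
#' @param dt time step (ms)
#' @return the advanced state
#' @export
membrane_step <- function(state, params, I_syn = 0, dt = 0.1) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!all(is.finite(c(state$v, state$g_e, state$g_i)))) {
    stop("non-finite neuron state")
  }
  if (state$refractory_remaining > 0) {
    state$v <- params$v_rest
    rr <- state$refractory_remaining - dt
    # snap sub-half-step residue (float rounding) to zero so the refractory
    # window always spans the same whole number of steps
    state$refractory_remaining <- if (rr < dt / 2) 0 else rr
  } else {
    drive <- (params$v_rest - state$v) +
      (state$g_e * (params$v_e - state$v) +
       state$g_i * (params$v_i - state$v) +
       params$I_ex + I_syn) / params$g_leak
    state$v <- state$v + dt * drive / params$tau_m
  }
  state$g_e <- state$g_e * exp(-dt / params$tau_e)
  state$g_i <- state$g_i * exp(-dt / params$tau_i)
  state
}

#' Detect a threshold crossing and reset
#'
#' Threshold crossing is inclusive: \code{v >= v_th} fires. On a spike the
#' voltage resets to \code{v_rest} and the refractory clock is set to
#' \code{tau_ref}.
#'
#' @param state a neuron state list
#' @param params a \code{\link{neuron_params}} object
#' @param t current time (ms), recorded on the spike
#' @return a list with elements \code{state} and \code{spike} (either
#'   \code{NULL} or a list \code{(time)})
#' @export
detect_and_reset <- function(state, params, t = 0) {
  spike <- NULL
  if (state$refractory_remaining <= 0 && state$v >= params$v_th) {
    spike <- list(time = t)
    state$v <- params$v_rest
    state$refractory_remaining <- params$tau_ref
  }
  list(state = state, spike = spike)
}

#' Increment a synaptic conductance on a presynaptic spike
#'
#' Event-driven delivery: the conductance of the chosen channel is increased
#' by \code{g_max * r_open}, the maximal postsynaptic conductance scaled by
#' the receptor open fraction at the spike time. Used only in the
#' event-driven integration mode; the default kinetic mode injects currents
#' instead.
#'
#' @param state a neuron state list
#' @param g_max maximal postsynaptic conductance (nS)
#' @param r_open receptor open fraction in [0, 1]
#' @param channel \code{"excitatory"} or \code{"inhibitory"}
#' @return the updated state
#' @export
apply_conductance_increment <- function(state, g_max, r_open,
                                        channel = c("excitatory",
                                                    "inhibitory")) {
  channel <- match.arg(channel)
  if (r_open < 0 || r_open > 1) stop("r_open must lie in [0, 1]")
  stopifnot(g_max >= 0)
  if (channel == "excitatory") {
    state$g_e <- state$g_e + g_max * r_open
  } else {
    state$g_i <- state$g_i + g_max * r_open
  }
  state
}

#' Closed-form inter-spike interval under constant drive
#'
#' For a synapse-free neuron under constant suprathreshold background current
#' the inter-spike interval is
#' \deqn{ISI = \tau_{ref} + \tau_m \log\frac{v^* - v_{rest}}{v^* - v_{th}},}
#' with the drive fixed point \eqn{v^* = v_{rest} + I_{ex}/g_{leak}}.
#'
#' @param params a \code{\link{neuron_params}} object
#' @return the interval (ms); \code{Inf} if the drive is subthreshold
#' @export
lif_isi_closed_form <- function(params) {
  v_star <- params$v_rest + params$I_ex / params$g_leak
  if (v_star <= params$v_th) return(Inf)
  params$tau_ref +
    params$tau_m * log((v_star - params$v_rest) / (v_star - params$v_th))
}
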