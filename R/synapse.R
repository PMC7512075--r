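#' Initial presynaptic state
#'
#' State of one terminal: Tsodyks-Markram variables (\code{u_S}, \code{x_S}),
#' the mGluR activation \code{Gamma}, GABA-B activation \code{r_gabab}, the
#' effective release probability \code{U} and the cleft transmitter
#' concentration \code{G_S} (glutamate at excitatory terminals, GABA at
#' inhibitory ones).
#'
#' @param params a \code{\link{synapse_params}} object
#' @param glutamatergic terminal type flag; inhibitory terminals start with
#'   the fixed \code{U_inh}
#' @return a list with elements \code{u_S, x_S, Gamma, r_gabab, U, G_S,
#'   glutamatergic}
#' @export
presynaptic_state <- function(params = synapse_params(),
                              glutamatergic = TRUE) {
  list(u_S = 0, x_S = 1, Gamma = 0, r_gabab = 0,
       U = if (glutamatergic) params$U0 else params$U_inh,
       G_S = 0, glutamatergic = glutamatergic)
}

#' Advance presynaptic release-probability comodulation
#'
#' One forward-Euler step of the mGluR activation
#' \eqn{d\Gamma/dt = O_G G_A (1-\Gamma) - \Omega_G \Gamma} (driver: astrocytic
#' glutamate \code{G_A}) and the GABA-B activation
#' \eqn{dr/dt = \alpha [GABA_{ex}] (1-r) - \beta r} (driver: bath GABA), then
#' recomputes the effective release probability
#' \eqn{U = U_0 + (\xi - U_0)\Gamma - U_0 r}, clamped to [0, 1]. Inhibitory
#' terminals keep the fixed \code{U_inh} and ignore both drivers.
#'
#' @param state a presynaptic state list
#' @param params a \code{\link{synapse_params}} object
#' @param G_A astrocyte-derived glutamate concentration (uM)
#' @param GABA_ex bath GABA concentration (uM)
#' @param dt time step (s)
#' @return the advanced state
#' @export
update_release_modulation <- function(state, params, G_A, GABA_ex, dt) {
  if (G_A < 0 || GABA_ex < 0) stop("concentrations must be non-negative")
  if (!state$glutamatergic) return(state)
  og <- o_g_per_uM(params)
  state$Gamma <- state$Gamma +
    dt * (og * G_A * (1 - state$Gamma) - params$Omega_G * state$Gamma)
  state$r_gabab <- state$r_gabab +
    dt * (params$alpha_gabab * GABA_ex * (1 - state$r_gabab) -
          params$beta_gabab * state$r_gabab)
  U <- params$U0 + (params$xi - params$U0) * state$Gamma -
    params$U0 * state$r_gabab
  state$U <- min(1, max(0, U))
  state
}

#' Tsodyks-Markram jumps at a presynaptic spike
#'
#' On a spike, facilitation jumps first (\code{u_S += U * (1 - u_S)}), the
#' released fraction is evaluated with the post-jump \code{u_S} and pre-jump
#' \code{x_S} (\code{r_S = u_S * x_S}), and the resource pool is then depleted
#' by \code{r_S}. This is the standard event ordering of the model.
#'
#' @param state a presynaptic state list
#' @param params a \code{\link{synapse_params}} object
#' @return a list with elements \code{state} and \code{r_S} (released
#'   fraction, the per-spike release probability Pr)
#' @export
on_presynaptic_spike <- function(state, params) {
  state$u_S <- state$u_S + state$U * (1 - state$u_S)
  r_S <- state$u_S * state$x_S
  state$x_S <- state$x_S - r_S
  list(state = state, r_S = r_S)
}

#' Relax the Tsodyks-Markram variables between spikes
#'
#' Exact linear relaxation over \code{dt}: \code{u_S} decays to 0 with
#' \code{tau_fac}; \code{x_S} recovers to 1 with \code{tau_rec}.
#'
#' @param state a presynaptic state list
#' @param params a \code{\link{synapse_params}} object
#' @param dt time step (s)
#' @return the advanced state
#' @export
tm_relaxation_step <- function(state, params, dt) {
  state$u_S <- state$u_S * exp(-dt / params$tau_fac)
  state$x_S <- 1 - (1 - state$x_S) * exp(-dt / params$tau_rec)
  state
}

#' Advance the cleft transmitter pool
#'
#' The cleft concentration decays exponentially at the clearance rate
#' (\code{g_S_c} for glutamate, \code{g_gaba_uptake} for GABA) over the step;
#' if a release happened on this step the pool then jumps by
#' \code{r_S * rho_c * Y_T} (with \code{Y_T} in mM, so the jump is
#' \code{1000 * r_S * rho_c * Y_T} in uM).
#'
#' @param state a presynaptic state list
#' @param params a \code{\link{synapse_params}} object
#' @param release released fraction \code{r_S} for this step, or \code{NULL}
#' @param dt time step (s)
#' @return the advanced state
#' @export
transmitter_step <- function(state, params, release = NULL, dt = 1e-4) {
  stopifnot(dt > 0)
  clear <- if (state$glutamatergic) params$g_S_c else params$g_gaba_uptake
  state$G_S <- state$G_S * exp(-clear * dt)
  if (!is.null(release)) {
    state$G_S <- state$G_S + release * params$rho_c * params$Y_T * 1000
  }
  state
}

#' Advance a two-state receptor gate
#'
#' Forward-Euler step of \eqn{dr/dt = \alpha T (1 - r) - \beta r}, the open
#' fraction of a closed/open channel driven by transmitter concentration
#' \code{T_conc}.
#'
#' @param r open fraction in [0, 1] (scalar or vector)
#' @param alpha binding rate constant (uM^-1 s^-1)
#' @param beta unbinding rate constant (s^-1)
#' @param T_conc transmitter concentration (uM)
#' @param dt time step (s)
#' @return the advanced open fraction
#' @export
receptor_gating_step <- function(r, alpha, beta, T_conc, dt) {
  if (any(T_conc < 0)) stop("transmitter concentration must be non-negative")
  r + dt * (alpha * T_conc * (1 - r) - beta * r)
}

#' NMDA magnesium-block factor
#'
#' Voltage-dependent relief of the magnesium block,
#' \eqn{Mg(v) = 1 / (1 + e^{-0.062 v} [Mg^{2+}] / 3.57)} with the magnesium
#' concentration in mM.
#'
#' @param v membrane potential (mV)
#' @param Mg_conc magnesium concentration (mM)
#' @return the block factor in (0, 1)
#' @export
mg_block <- function(v, Mg_conc = 1) {
  1 / (1 + exp(-0.062 * v) * Mg_conc / 3.57)
}

#' Postsynaptic receptor currents
#'
#' AMPA, NMDA and GABA-A currents from the receptor open fractions:
#' \eqn{I = \bar g\, r\, (v - E_{rev})}, the NMDA term additionally scaled by
#' the magnesium block. Inward currents are negative in this convention
#' (negate before injecting into \code{\link{membrane_step}}).
#'
#' @param r_ampa,r_nmda,r_gabaa receptor open fractions
#' @param rp a \code{\link{receptor_params}} object
#' @param v postsynaptic membrane potential (mV)
#' @param gabaa_scale multiplier on the maximal GABA-A conductance (dose
#'   scaling), default 1
#' @return a list with elements \code{I_AMPA, I_NMDA, I_GABAA} (pA)
#' @export
postsynaptic_currents <- function(r_ampa, r_nmda, r_gabaa, rp, v,
                                  gabaa_scale = 1) {
  list(I_AMPA = rp$ampa$g_max * r_ampa * (v - rp$ampa$E_rev),
       I_NMDA = rp$nmda$g_max * mg_block(v, rp$Mg_conc) * r_nmda *
         (v - rp$nmda$E_rev),
       I_GABAA = rp$gabaa$g_max * gabaa_scale * r_gabaa *
         (v - rp$gabaa$E_rev))
}

#' Slow inward current from an extrasynaptic receptor pool
#'
#' The astrocyte-mediated slow inward current is the sum of the NMDA and AMPA
#' currents of a receptor pool gated exclusively by astrocyte-derived
#' glutamate \code{G_A} (never by synaptic glutamate); excitatory postsynaptic
#' events are tagged EPSC or SIC by this transmitter origin. Same
#' inward-negative sign convention as \code{\link{postsynaptic_currents}}.
#'
#' @param r_ampa,r_nmda open fractions of the extrasynaptic pool
#' @param rp a \code{\link{receptor_params}} object
#' @param v postsynaptic membrane potential (mV)
#' @return the current (pA)
#' @export
sic_current <- function(r_ampa, r_nmda, rp, v) {
  cur <- postsynaptic_currents(r_ampa, r_nmda, 0, rp, v)
  cur$I_NMDA + cur$I_AMPA
}
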