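#' Initial astrocyte state
#'
#' @param params an \code{\link{astrocyte_params}} object
#' @param ip3 initial IP3 concentration (uM); defaults to the equilibrium
#' @param ca initial cytosolic calcium (uM)
#' @param h_gate initial IP3R inactivation gate; defaults to its equilibrium
#'   at (\code{ip3}, \code{ca})
#' @return a list with elements \code{ip3, ca, h_gate, x_A, G_A, latch}
#' @export
astrocyte_state <- function(params = astrocyte_params(), ip3 = NULL,
                            ca = 0.1, h_gate = NULL) {
  if (is.null(ip3)) ip3 <- params$ip3_star
  if (is.null(h_gate)) {
    lr <- params$lr
    Q2 <- lr$d2 * (ip3 + lr$d1) / (ip3 + lr$d3)
    h_gate <- Q2 / (Q2 + ca)
  }
  stopifnot(ip3 >= 0, ca >= 0, h_gate >= 0, h_gate <= 1)
  list(ip3 = ip3, ca = ca, h_gate = h_gate, x_A = 1, G_A = 0, latch = FALSE)
}

#' Hill-type IP3 production fluxes
#'
#' @param params an \code{\link{astrocyte_params}} object
#' @param Glu synaptic glutamate concentration (uM)
#' @param GABA_ex bath GABA concentration (uM)
#' @return a list with elements \code{J_gaba} and \code{J_glu} (uM s^-1); the
#'   glutamate flux already carries the crosstalk amplification
#'   \code{(1 + k_amp * GABA_ex)} when enabled
#' @export
ip3_fluxes <- function(params, Glu, GABA_ex) {
  hill <- function(x, k, n) {
    if (x <= 0) return(0)
    x^n / (k^n + x^n)
  }
  J_gaba <- params$v_gaba * hill(GABA_ex, params$k_gaba, params$n1)
  J_glu <- params$v_glu * hill(Glu, params$k_glu, params$n2)
  if (params$amp_on_ip3) J_glu <- J_glu * (1 + params$k_amp * GABA_ex)
  list(J_gaba = J_gaba, J_glu = J_glu)
}

#' Advance astrocytic IP3 by one step
#'
#' Forward-Euler step of the IP3 balance: relaxation to the equilibrium
#' \code{ip3_star} with time constant \code{tau_ip3}, plus the GABA- and
#' glutamate-driven Hill production fluxes (the latter amplified by
#' \code{1 + k_amp * GABA_ex} when crosstalk amplification is on), plus the
#' externally supplied gap-junction flux \code{J_G}.
#'
#' @param state an astrocyte state list
#' @param params an \code{\link{astrocyte_params}} object
#' @param Glu synaptic glutamate driver (uM)
#' @param GABA_ex bath GABA concentration (uM)
#' @param J_G gap-junction IP3 flux (uM s^-1), see
#'   \code{\link{gap_junction_flux}}
#' @param dt time step (s)
#' @return the advanced state
#' @export
ip3_production_step <- function(state, params, Glu = 0, GABA_ex = 0,
                                J_G = 0, dt = 1e-4) {
  if (Glu < 0 || GABA_ex < 0) stop("drivers must be non-negative")
  J <- ip3_fluxes(params, Glu, GABA_ex)
  state$ip3 <- state$ip3 + dt *
    ((params$ip3_star - state$ip3) / params$tau_ip3 +
     J$J_gaba + J$J_glu + J_G)
  if (state$ip3 < 0) state$ip3 <- 0
  state
}

#' Nonlinear gap-junction IP3 flux into one astrocyte
#'
#' Sum over gap-junction neighbours of
#' \deqn{-\frac{F_{ex}}{2}\left[1 + \tanh\frac{|\Delta| - IP_3^{thr}}
#'   {\omega}\right] \mathrm{sgn}(\Delta),\qquad
#'   \Delta = IP_3^{self} - IP_3^{neighbour},}
#' i.e. IP3 flows down-gradient once the pairwise difference exceeds the
#' diffusion threshold; the flux is odd in \eqn{\Delta}.
#'
#' @param ip3_self IP3 concentration of the receiving astrocyte (uM)
#' @param ip3_neighbors IP3 concentrations of its gap-junction neighbours (uM)
#' @param params an \code{\link{astrocyte_params}} object
#' @return the total flux (uM s^-1)
#' @export
gap_junction_flux <- function(ip3_self, ip3_neighbors, params) {
  if (length(ip3_neighbors) == 0) return(0)
  stopifnot(ip3_self >= 0, all(ip3_neighbors >= 0))
  delta <- ip3_self - ip3_neighbors
  sum(-(params$F_ex / 2) *
        (1 + tanh((abs(delta) - params$ip3_thr) / params$omega)) *
        sign(delta))
}

# Li-Rinzel right-hand side: list(dca, dh) at (ca, h, ip3)
li_rinzel_rhs <- function(ca, h, ip3, lr) {
  m_inf <- ip3 / (ip3 + lr$d1)
  n_inf <- ca / (ca + lr$d5)
  gate <- (m_inf * n_inf * h)^3
  drive <- lr$c0 - (1 + lr$c1) * ca  # c1 * (ca_er - ca), closed cell
  J_channel <- lr$v1 * gate * drive
  J_leak <- lr$v2 * drive
  J_pump <- lr$v3 * ca^2 / (lr$k3^2 + ca^2)
  Q2 <- lr$d2 * (ip3 + lr$d1) / (ip3 + lr$d3)
  list(dca = J_channel + J_leak - J_pump,
       dh = lr$a2 * (Q2 * (1 - h) - ca * h))
}

#' Advance the Li-Rinzel calcium subsystem by one step
#'
#' Forward-Euler step of the reduced two-variable IP3-receptor model:
#' cytosolic calcium follows \eqn{dCa/dt = J_{channel} + J_{leak} - J_{pump}}
#' (IP3/calcium-gated ER release, ER leak, Hill-2 SERCA uptake) and the slow
#' inactivation gate \code{h_gate} relaxes with rate \code{a2}. ER calcium is
#' eliminated by closed-cell conservation.
#'
#' @param state an astrocyte state list
#' @param params an \code{\link{astrocyte_params}} object
#' @param dt time step (s)
#' @return the advanced state
#' @export
calcium_step <- function(state, params, dt = 1e-4) {
  if (!all(is.finite(c(state$ca, state$h_gate, state$ip3)))) {
    stop("non-finite astrocyte state")
  }
  d <- li_rinzel_rhs(state$ca, state$h_gate, state$ip3, params$lr)
  state$ca <- max(0, state$ca + dt * d$dca)
  state$h_gate <- min(1, max(0, state$h_gate + dt * d$dh))
  state
}

#' Calcium-threshold gliotransmitter release and pool recovery
#'
#' Implements the single-shot exocytosis rule: when cytosolic calcium crosses
#' the threshold \code{C_theta} upward and the release latch is clear, a
#' fraction \eqn{r_A = U_A x_A} of the gliotransmitter resource is released,
#' the pool is depleted by \eqn{r_A}, and the extrasynaptic glutamate jumps by
#' \eqn{r_A \varrho_e G_T (1 + k_{amp} [GABA_{ex}])} (amplification optional).
#' The latch blocks further events until calcium falls back below
#' \code{C_theta} (a refractory-like rule, so threshold conditions trigger at
#' most one event per calcium excursion). Between events \code{x_A} recovers
#' with \code{tau_G} and \code{G_A} decays at \code{g_A_c}.
#'
#' @param state an astrocyte state list (calcium already advanced this step)
#' @param params an \code{\link{astrocyte_params}} object
#' @param GABA_ex bath GABA concentration (uM)
#' @param dt time step (s)
#' @param t current time (s), recorded on a release event
#' @return a list with elements \code{state} and \code{event} (NULL, or a
#'   list \code{(time, r_A, dG_A)})
#' @export
gliotransmitter_release_step <- function(state, params, GABA_ex = 0,
                                         dt = 1e-4, t = 0) {
  state$x_A <- 1 - (1 - state$x_A) * exp(-dt / params$tau_G)
  state$G_A <- state$G_A * exp(-params$g_A_c * dt)
  event <- NULL
  if (state$ca >= params$C_theta) {
    if (!state$latch) {
      state$latch <- TRUE
      r_A <- params$U_A * state$x_A
      state$x_A <- state$x_A - r_A
      amp <- if (params$amp_on_release) 1 + params$k_amp * GABA_ex else 1
      dG_A <- r_A * params$rho_e * params$G_T * 1000 * amp  # G_T mM -> uM
      state$G_A <- state$G_A + dG_A
      event <- list(time = t, r_A = r_A, dG_A = dG_A)
    }
  } else {
    state$latch <- FALSE
  }
  list(state = state, event = event)
}
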