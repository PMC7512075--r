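#' Neuron model parameters
#'
#' Parameter set for the conductance-based leaky integrate-and-fire neuron.
#' Defaults are the standard set used throughout the package: a 20-ms membrane,
#' -50 mV firing threshold, -60 mV rest/reset, and a constant 105-pA background
#' current which by itself drives tonic firing (the subthreshold fixed point,
#' \code{v_rest + I_ex / g_leak = -49.5} mV, lies above threshold).
#'
#' @param tau_m membrane time constant (ms)
#' @param v_rest resting and reset potential (mV)
#' @param v_th firing threshold (mV); crossing is inclusive (v >= v_th fires)
#' @param v_e,v_i excitatory / inhibitory reversal potentials (mV)
#' @param g_leak leak conductance (nS)
#' @param I_ex constant background current (pA)
#' @param tau_ref absolute refractory period (ms)
#' @param tau_e,tau_i excitatory / inhibitory conductance decay constants (ms)
#' @return an object of class \code{neuron_params}
#' @export
#' @examples
#' p <- neuron_params()
#' p$v_rest + p$I_ex / p$g_leak  # tonic-drive fixed point, mV
neuron_params <- function(tau_m = 20, v_rest = -60, v_th = -50,
                          v_e = 0, v_i = -80, g_leak = 10, I_ex = 105,
                          tau_ref = 5, tau_e = 5, tau_i = 10) {
  p <- list(tau_m = tau_m, v_rest = v_rest, v_th = v_th, v_e = v_e,
            v_i = v_i, g_leak = g_leak, I_ex = I_ex, tau_ref = tau_ref,
            tau_e = tau_e, tau_i = tau_i)
  stopifnot(tau_m > 0, tau_ref >= 0, tau_e > 0, tau_i > 0, g_leak > 0,
            v_i < v_th, v_th < v_e)
  structure(p, class = "neuron_params")
}

#' Li-Rinzel calcium subsystem constants
#'
#' Constants of the reduced two-variable IP3-receptor model (channel, leak and
#' SERCA-pump fluxes plus the slow inactivation gate) in its canonical
#' parameterization. Cytosolic and ER calcium are linked by closed-cell
#' conservation: \code{ca_er = (c0 - ca) / c1}.
#'
#' @param c0 total free calcium per cytosolic volume (uM)
#' @param c1 ER-to-cytosol volume ratio (dimensionless)
#' @param v1 maximal IP3R channel flux rate (s^-1)
#' @param v2 ER leak rate (s^-1)
#' @param v3 maximal SERCA pump flux (uM s^-1)
#' @param k3 SERCA activation constant (uM)
#' @param d1,d2,d3,d5 IP3R binding constants (uM)
#' @param a2 inactivation gate rate constant (uM^-1 s^-1)
#' @return an object of class \code{li_rinzel_params}
#' @export
li_rinzel_params <- function(c0 = 2, c1 = 0.185, v1 = 6, v2 = 0.11,
                             v3 = 0.9, k3 = 0.1, d1 = 0.13, d2 = 1.049,
                             d3 = 0.9434, d5 = 0.08234, a2 = 0.2) {
  structure(list(c0 = c0, c1 = c1, v1 = v1, v2 = v2, v3 = v3, k3 = k3,
                 d1 = d1, d2 = d2, d3 = d3, d5 = d5, a2 = a2),
            class = "li_rinzel_params")
}

#' Astrocyte model parameters
#'
#' Parameters of astrocytic IP3 production (GABA- and glutamate-driven Hill
#' fluxes with GABA-dependent crosstalk amplification), nonlinear gap-junction
#' IP3 diffusion, the Li-Rinzel calcium subsystem, and calcium-threshold
#' glutamate exocytosis.
#'
#' The crosstalk factor \code{(1 + k_amp * GABA_ex)} multiplies the
#' glutamate-driven IP3 flux and, independently, the gliotransmitter release
#' increment; either site can be switched off (\code{amp_on_ip3},
#' \code{amp_on_release}).
#'
#' @param ip3_star IP3 equilibrium concentration (uM)
#' @param tau_ip3 IP3 degradation time constant (s)
#' @param v_gaba,v_glu maximal IP3 production rates via GABA / glutamate
#'   (uM s^-1)
#' @param n1,n2 Hill exponents for the GABA / glutamate fluxes
#' @param k_gaba,k_glu half-saturation concentrations (uM)
#' @param k_amp GABA-dependent crosstalk amplification coefficient (uM^-1)
#' @param ip3_thr gap-junction diffusion threshold (uM)
#' @param F_ex gap-junction IP3 permeability (uM s^-1)
#' @param omega gap-junction diffusion scaling factor (uM)
#' @param C_theta cytosolic calcium threshold for exocytosis (uM)
#' @param tau_G gliotransmitter resource reintegration time constant (s)
#' @param U_A resting gliotransmitter release probability
#' @param rho_e vesicle-to-periastrocytic-space volume ratio
#' @param g_A_c clearance rate of astrocyte-derived glutamate (s^-1)
#' @param G_T total vesicular glutamate concentration (mM)
#' @param amp_on_ip3,amp_on_release apply the crosstalk amplification to the
#'   glutamate IP3 flux / to the release increment
#' @param glu_driver how a network astrocyte reads the synaptic glutamate of
#'   its territory: \code{"mean"} (default) or \code{"sum"} over assigned
#'   excitatory synapses
#' @param lr Li-Rinzel constant set, see \code{\link{li_rinzel_params}}
#' @return an object of class \code{astrocyte_params}
#' @export
astrocyte_params <- function(ip3_star = 0.16, tau_ip3 = 7,
                             v_gaba = 0.1625, v_glu = 0.062,
                             n1 = 0.3, n2 = 0.2,
                             k_gaba = 0.6, k_glu = 0.78, k_amp = 0.3,
                             ip3_thr = 0.3, F_ex = 0.09, omega = 0.05,
                             C_theta = 0.2, tau_G = 1.66, U_A = 0.6,
                             rho_e = 6.5e-4, g_A_c = 60, G_T = 200,
                             amp_on_ip3 = TRUE, amp_on_release = TRUE,
                             glu_driver = c("mean", "sum"),
                             lr = li_rinzel_params()) {
  glu_driver <- match.arg(glu_driver)
  stopifnot(tau_ip3 > 0, tau_G > 0, k_amp >= 0, U_A >= 0, U_A <= 1,
            g_A_c >= 0, inherits(lr, "li_rinzel_params"))
  structure(list(ip3_star = ip3_star, tau_ip3 = tau_ip3, v_gaba = v_gaba,
                 v_glu = v_glu, n1 = n1, n2 = n2, k_gaba = k_gaba,
                 k_glu = k_glu, k_amp = k_amp, ip3_thr = ip3_thr,
                 F_ex = F_ex, omega = omega, C_theta = C_theta,
                 tau_G = tau_G, U_A = U_A, rho_e = rho_e, g_A_c = g_A_c,
                 G_T = G_T, amp_on_ip3 = amp_on_ip3,
                 amp_on_release = amp_on_release, glu_driver = glu_driver,
                 lr = lr),
            class = "astrocyte_params")
}

#' Presynaptic (Tsodyks-Markram) and transmitter-pool parameters
#'
#' Parameters of the short-term-plasticity release machinery at excitatory
#' terminals, its comodulation by astrocytic glutamate (presynaptic mGluRs,
#' activation variable Gamma) and bath GABA (presynaptic GABA-B receptors,
#' variable r_GABA_B), and the synaptic-cleft transmitter pools.
#'
#' The effective release probability is
#' \code{U = U0 + (xi - U0) * Gamma - U0 * r_gabab}, clamped to [0, 1].
#' Inhibitory terminals use the same release machinery with a fixed
#' \code{U = U_inh} and clearance \code{g_gaba_uptake}; their vesicle pool
#' reuses \code{rho_c} and \code{Y_T} (no separate values are established for
#' GABAergic boutons; override if needed).
#'
#' \code{O_G} is interpreted in uM^-1 s^-1 by default
#' (\code{O_G_unit = "uM"}); set \code{O_G_unit = "M"} for a literal
#' M^-1 s^-1 reading, under which the mGluR pathway is numerically inert at
#' micromolar gliotransmitter levels (see the methods vignette).
#'
#' @param U0 resting release probability of excitatory terminals
#' @param xi type/strength of astrocytic action on the terminal, in [0, 1]
#' @param O_G forward rate constant of astrocytic glutamate binding to
#'   presynaptic receptors (per \code{O_G_unit} per second)
#' @param O_G_unit \code{"uM"} (default) or \code{"M"}
#' @param Omega_G backward rate constant of presynaptic mGluR activation
#'   (s^-1)
#' @param alpha_gabab,beta_gabab GABA-B binding / unbinding rate constants
#'   (uM^-1 s^-1, s^-1)
#' @param tau_fac facilitation time constant (s)
#' @param tau_rec resource recovery time constant (s)
#' @param g_S_c synaptic glutamate clearance rate (s^-1)
#' @param rho_c vesicular-to-mixing volume ratio
#' @param Y_T total vesicular glutamate concentration (mM)
#' @param U_inh fixed release probability of inhibitory terminals
#' @param g_gaba_uptake synaptic GABA clearance rate (s^-1)
#' @return an object of class \code{synapse_params}
#' @export
synapse_params <- function(U0 = 0.3, xi = 0.8,
                           O_G = 1.5, O_G_unit = c("uM", "M"),
                           Omega_G = 0.2,
                           alpha_gabab = 16, beta_gabab = 6,
                           tau_fac = 0.3, tau_rec = 0.5,
                           g_S_c = 40, rho_c = 0.005, Y_T = 500,
                           U_inh = 0.5, g_gaba_uptake = 6) {
  O_G_unit <- match.arg(O_G_unit)
  stopifnot(U0 >= 0, U0 <= 1, xi >= 0, xi <= 1, U_inh >= 0, U_inh <= 1,
            tau_fac > 0, tau_rec > 0, O_G >= 0, Omega_G >= 0,
            alpha_gabab >= 0, beta_gabab >= 0, g_S_c >= 0,
            g_gaba_uptake >= 0)
  structure(list(U0 = U0, xi = xi, O_G = O_G, O_G_unit = O_G_unit,
                 Omega_G = Omega_G, alpha_gabab = alpha_gabab,
                 beta_gabab = beta_gabab, tau_fac = tau_fac,
                 tau_rec = tau_rec, g_S_c = g_S_c, rho_c = rho_c,
                 Y_T = Y_T, U_inh = U_inh, g_gaba_uptake = g_gaba_uptake),
            class = "synapse_params")
}

# effective O_G in uM^-1 s^-1 under the configured unit
o_g_per_uM <- function(sp) {
  if (sp$O_G_unit == "uM") sp$O_G else sp$O_G * 1e-6
}

#' Postsynaptic receptor parameters
#'
#' Two-state (closed/open) kinetic constants, maximal conductances and
#' reversal potentials of the AMPA, NMDA and GABA-A channels, the NMDA
#' magnesium block, and the dose-dependent GABA-A conductance scaling.
#'
#' \code{gabaa_dose_scaling} is a free configuration mapping from bath-GABA
#' dose (uM) to a multiplier on the maximal GABA-A conductance; it emulates
#' the experimentally motivated strengthening of GABA-A conductance with bath
#' dose and is not derived from measured values. Doses between the mapped
#' points are linearly interpolated; doses beyond the largest mapped point use
#' its multiplier.
#'
#' @param ampa,nmda,gabaa named lists with elements \code{alpha}
#'   (uM^-1 s^-1), \code{beta} (s^-1), \code{g_max} (nS), \code{E_rev} (mV)
#' @param Mg_conc extracellular magnesium concentration (mM) for the NMDA
#'   block
#' @param gabaa_dose_scaling named numeric vector, names = doses (uM),
#'   values = conductance multipliers
#' @return an object of class \code{receptor_params}
#' @export
receptor_params <- function(ampa = list(alpha = 1.1, beta = 190,
                                        g_max = 0.35, E_rev = 0),
                            nmda = list(alpha = 0.072, beta = 6.6,
                                        g_max = 0.1, E_rev = 0),
                            gabaa = list(alpha = 0.53, beta = 180,
                                         g_max = 0.62, E_rev = -80),
                            Mg_conc = 1,
                            gabaa_dose_scaling = c("0" = 1, "1" = 1.25,
                                                   "5" = 1.5, "10" = 2)) {
  for (ch in list(ampa, nmda, gabaa)) {
    stopifnot(ch$alpha >= 0, ch$beta >= 0, ch$g_max >= 0)
  }
  structure(list(ampa = ampa, nmda = nmda, gabaa = gabaa, Mg_conc = Mg_conc,
                 gabaa_dose_scaling = gabaa_dose_scaling),
            class = "receptor_params")
}

#' GABA-A conductance multiplier for a bath dose
#'
#' Looks up (with linear interpolation) the dose-dependent multiplier on the
#' maximal GABA-A conductance from \code{receptor_params()$gabaa_dose_scaling}.
#'
#' @param rp a \code{receptor_params} object
#' @param dose bath GABA dose (uM)
#' @return a scalar multiplier
#' @export
gabaa_scale_for_dose <- function(rp, dose) {
  stopifnot(dose >= 0)
  map <- rp$gabaa_dose_scaling
  x <- as.numeric(names(map))
  o <- order(x)
  x <- x[o]; y <- unname(map[o])
  if (dose <= x[1]) return(y[1])
  if (dose >= x[length(x)]) return(y[length(y)])
  stats::approx(x, y, xout = dose)$y
}
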