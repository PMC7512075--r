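#' Seeded Poisson spike train
#'
#' Homogeneous Poisson process on [0, duration), used as a prescribed
#' presynaptic drive for single-synapse harnesses.
#'
#' @param rate_hz mean rate (Hz)
#' @param duration length (s)
#' @param seed integer RNG seed
#' @return sorted spike times (s)
#' @export
poisson_spike_train <- function(rate_hz, duration, seed = 1) {
  stopifnot(rate_hz >= 0, duration > 0)
  set.seed(seed)
  n <- stats::rpois(1, rate_hz * duration)
  sort(stats::runif(n, 0, duration))
}

#' Single tripartite-synapse harness
#'
#' Minimal wired system for unit-level tests of the full signalling chain at
#' one synapse: a prescribed presynaptic spike train drives one excitatory
#' terminal; its cleft glutamate drives one astrocyte (no gap junctions);
#' the astrocyte's gliotransmitter feeds back on the terminal (mGluR) and on
#' one extrasynaptic receptor pool of a single postsynaptic LIF neuron, which
#' also receives the synaptic AMPA/NMDA currents. Bath GABA follows the given
#' protocol and reaches every receptor it does in the network model. The
#' integration scheme and update order are identical to the network engine,
#' so on a 1-synapse network the two agree to machine precision.
#'
#' @param dose bath GABA dose (uM)
#' @param spike_train presynaptic spike times (s)
#' @param duration run length (s)
#' @param dt time step (ms)
#' @param astrocyte_enabled switch for the astrocyte pathway
#' @param t_on bath onset (s)
#' @param neuron,synapse,receptor,astro parameter blocks
#' @param v0 initial membrane potential of the postsynaptic neuron (mV);
#'   defaults to the resting potential
#' @param trace_stride record every this many steps
#' @return a list with \code{traces} (data.frame: time, gaba, ip3, ca, x_A,
#'   G_A, u_S, x_S, U, Gamma, r_gabab, G_S, r_ampa, r_nmda, I_epsc, I_sic,
#'   v), \code{releases} (time, r_S), \code{glio_events} (time, r_A, dG_A),
#'   \code{post_spikes} (s)
#' @export
single_tripartite_fixture <- function(dose = 0, spike_train = numeric(0),
                                      duration = 2, dt = 0.1,
                                      astrocyte_enabled = TRUE,
                                      t_on = 0.2,
                                      neuron = neuron_params(),
                                      synapse = synapse_params(),
                                      receptor = receptor_params(),
                                      astro = astrocyte_params(),
                                      v0 = NULL,
                                      trace_stride = 10L) {
  dt_s <- dt * 1e-3
  n_steps <- round(duration / dt_s)
  protocol <- gaba_protocol(dose, t_on = t_on)
  gscale <- gabaa_scale_for_dose(receptor, dose)  # unused: no GABA_A here

  syn <- presynaptic_state(synapse, glutamatergic = TRUE)
  ast <- astrocyte_state(astro)
  neu <- neuron_state(v = v0, params = neuron)
  r_ampa <- 0; r_nmda <- 0; re_ampa <- 0; re_nmda <- 0

  spk <- sort(spike_train)
  next_spk <- 1L

  n_samp <- n_steps %/% trace_stride + 1L
  tr <- matrix(0, n_samp, 17)
  colnames(tr) <- c("time", "gaba", "ip3", "ca", "x_A", "G_A", "u_S", "x_S",
                    "U", "Gamma", "r_gabab", "G_S", "r_ampa", "r_nmda",
                    "I_epsc", "I_sic", "v")
  rel_t <- numeric(0); rel_r <- numeric(0)
  ge_t <- numeric(0); ge_r <- numeric(0); ge_d <- numeric(0)
  post_spk <- numeric(0)
  I_epsc <- 0; I_sic <- 0
  rec <- function(k, t, gaba) {
    tr[k, ] <<- c(t, gaba, ast$ip3, ast$ca, ast$x_A, ast$G_A, syn$u_S,
                  syn$x_S, syn$U, syn$Gamma, syn$r_gabab, syn$G_S,
                  r_ampa, r_nmda, I_epsc, I_sic, neu$v)
  }
  rec(1L, 0, gaba_concentration(protocol, 0))

  for (n in seq_len(n_steps)) {
    t <- (n - 1) * dt_s
    t_next <- n * dt_s
    gaba <- gaba_concentration(protocol, t)

    if (astrocyte_enabled) {
      # calcium first (old IP3), then IP3 production, then the release rule
      ast <- calcium_step(ast, astro, dt_s)
      ast <- ip3_production_step(ast, astro, Glu = syn$G_S, GABA_ex = gaba,
                                 J_G = 0, dt = dt_s)
      gr <- gliotransmitter_release_step(ast, astro, GABA_ex = gaba,
                                         dt = dt_s, t = t_next)
      ast <- gr$state
      if (!is.null(gr$event)) {
        ge_t <- c(ge_t, gr$event$time); ge_r <- c(ge_r, gr$event$r_A)
        ge_d <- c(ge_d, gr$event$dG_A)
      }
    }

    syn <- update_release_modulation(syn, synapse,
                                     G_A = if (astrocyte_enabled)
                                       ast$G_A else 0,
                                     GABA_ex = gaba, dt = dt_s)
    syn <- tm_relaxation_step(syn, synapse, dt_s)
    syn <- transmitter_step(syn, synapse, release = NULL, dt = dt_s)

    r_ampa <- receptor_gating_step(r_ampa, receptor$ampa$alpha,
                                   receptor$ampa$beta, syn$G_S, dt_s)
    r_nmda <- receptor_gating_step(r_nmda, receptor$nmda$alpha,
                                   receptor$nmda$beta, syn$G_S, dt_s)
    if (astrocyte_enabled) {
      re_ampa <- receptor_gating_step(re_ampa, receptor$ampa$alpha,
                                      receptor$ampa$beta, ast$G_A, dt_s)
      re_nmda <- receptor_gating_step(re_nmda, receptor$nmda$alpha,
                                      receptor$nmda$beta, ast$G_A, dt_s)
    }

    cur <- postsynaptic_currents(r_ampa, r_nmda, 0, receptor, neu$v)
    I_epsc <- cur$I_AMPA + cur$I_NMDA
    I_sic <- if (astrocyte_enabled) {
      sic_current(re_ampa, re_nmda, receptor, neu$v)
    } else 0

    neu <- membrane_step(neu, neuron, I_syn = -(I_epsc + I_sic), dt = dt)
    dr <- detect_and_reset(neu, neuron, t = t_next)
    neu <- dr$state
    if (!is.null(dr$spike)) post_spk <- c(post_spk, t_next)

    while (next_spk <= length(spk) && spk[next_spk] <= t_next) {
      osp <- on_presynaptic_spike(syn, synapse)
      syn <- osp$state
      syn$G_S <- syn$G_S + osp$r_S * synapse$rho_c * synapse$Y_T * 1000
      rel_t <- c(rel_t, t_next); rel_r <- c(rel_r, osp$r_S)
      next_spk <- next_spk + 1L
    }

    if (n %% trace_stride == 0) {
      rec(n %/% trace_stride + 1L, t_next, gaba)
    }
  }

  list(traces = as.data.frame(tr),
       releases = data.frame(time_s = rel_t, r_S = rel_r),
       glio_events = data.frame(time_s = ge_t, r_A = ge_r, dG_A = ge_d),
       post_spikes = post_spk)
}

#' Fine-step reference integrations
#'
#' Independent forward-Euler integrations of the elementary subsystems,
#' written directly against the model equations (no shared code with the
#' module step functions) and intended to run at a much finer step. Used as
#' oracles in convergence and equivalence tests.
#'
#' Systems:
#' \describe{
#'   \item{"lif"}{synapse-free membrane under constant background current;
#'     returns \code{time}, \code{v}, \code{spike_times}}
#'   \item{"receptor"}{two-state gate under constant transmitter
#'     concentration \code{T_conc}; returns \code{time}, \code{r}}
#'   \item{"ip3"}{IP3 balance under constant \code{Glu}/\code{GABA_ex}
#'     drivers (no gap junctions); returns \code{time}, \code{ip3}}
#'   \item{"calcium"}{Li-Rinzel subsystem at clamped IP3; returns
#'     \code{time}, \code{ca}, \code{h}}
#' }
#'
#' @param system one of \code{"lif"}, \code{"receptor"}, \code{"ip3"},
#'   \code{"calcium"}
#' @param duration run length (s)
#' @param dt time step (s); pick well below the production 1e-4 s
#' @param params a \code{neuron_params} (lif), \code{astrocyte_params}
#'   (ip3/calcium), or a list \code{(alpha, beta)} (receptor)
#' @param v0,r0,ip3_0,ca0 initial values
#' @param spiking apply threshold/reset in the \code{"lif"} system; set
#'   FALSE to integrate the free membrane equation only
#' @param T_conc constant transmitter concentration (receptor, uM)
#' @param Glu,GABA_ex constant drivers (ip3, uM)
#' @param ip3_clamp clamped IP3 (calcium, uM)
#' @param stride record every this many steps
#' @return a list of recorded series, see Systems
#' @export
reference_integrator <- function(system = c("lif", "receptor", "ip3",
                                            "calcium"),
                                 duration, dt = 1e-6, params = NULL,
                                 v0 = NULL, r0 = 0, ip3_0 = 0, ca0 = 0.1,
                                 T_conc = 0, Glu = 0, GABA_ex = 0,
                                 ip3_clamp = 0.16, stride = 1000L,
                                 spiking = TRUE) {
  system <- match.arg(system)
  n <- round(duration / dt)
  ks <- seq(0, n, by = stride)
  switch(system,
    lif = {
      p <- if (is.null(params)) neuron_params() else params
      tau <- p$tau_m * 1e-3; tref <- p$tau_ref * 1e-3
      v <- if (is.null(v0)) p$v_rest else v0
      refr <- 0
      vs <- numeric(length(ks)); vs[1] <- v; j <- 2L
      spikes <- numeric(0)
      for (i in seq_len(n)) {
        if (refr > 0) {
          v <- p$v_rest; refr <- refr - dt
        } else {
          v <- v + dt * ((p$v_rest - v) + p$I_ex / p$g_leak) / tau
          if (spiking && v >= p$v_th) {
            spikes <- c(spikes, i * dt); v <- p$v_rest; refr <- tref
          }
        }
        if (i %% stride == 0) { vs[j] <- v; j <- j + 1L }
      }
      list(time = ks * dt, v = vs, spike_times = spikes)
    },
    receptor = {
      a <- params$alpha; b <- params$beta
      r <- r0
      rs <- numeric(length(ks)); rs[1] <- r; j <- 2L
      for (i in seq_len(n)) {
        r <- r + dt * (a * T_conc * (1 - r) - b * r)
        if (i %% stride == 0) { rs[j] <- r; j <- j + 1L }
      }
      list(time = ks * dt, r = rs)
    },
    ip3 = {
      p <- if (is.null(params)) astrocyte_params() else params
      Jg <- if (GABA_ex > 0) {
        p$v_gaba * GABA_ex^p$n1 / (p$k_gaba^p$n1 + GABA_ex^p$n1)
      } else 0
      Jl <- if (Glu > 0) {
        p$v_glu * Glu^p$n2 / (p$k_glu^p$n2 + Glu^p$n2)
      } else 0
      if (p$amp_on_ip3) Jl <- Jl * (1 + p$k_amp * GABA_ex)
      x <- ip3_0
      xs <- numeric(length(ks)); xs[1] <- x; j <- 2L
      for (i in seq_len(n)) {
        x <- x + dt * ((p$ip3_star - x) / p$tau_ip3 + Jg + Jl)
        if (i %% stride == 0) { xs[j] <- x; j <- j + 1L }
      }
      list(time = ks * dt, ip3 = xs)
    },
    calcium = {
      p <- if (is.null(params)) astrocyte_params() else params
      lr <- p$lr
      Q2 <- lr$d2 * (ip3_clamp + lr$d1) / (ip3_clamp + lr$d3)
      m_inf <- ip3_clamp / (ip3_clamp + lr$d1)
      ca <- ca0; h <- Q2 / (Q2 + ca)
      cas <- numeric(length(ks)); hs <- numeric(length(ks))
      cas[1] <- ca; hs[1] <- h; j <- 2L
      for (i in seq_len(n)) {
        drive <- lr$c0 - (1 + lr$c1) * ca
        dca <- lr$v1 * (m_inf * ca / (ca + lr$d5) * h)^3 * drive +
          lr$v2 * drive - lr$v3 * ca^2 / (lr$k3^2 + ca^2)
        dh <- lr$a2 * (Q2 * (1 - h) - ca * h)
        ca <- max(0, ca + dt * dca); h <- h + dt * dh
        if (i %% stride == 0) { cas[j] <- ca; hs[j] <- h; j <- j + 1L }
      }
      list(time = ks * dt, ca = cas, h = hs)
    })
}
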