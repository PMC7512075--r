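#' Simulation configuration
#'
#' Collects every tunable of a network run: duration and step, the bath-GABA
#' protocol, the current-delivery mode, the astrocyte-pathway switch, all
#' model parameter blocks, and the recording lists.
#'
#' In the default \code{"kinetic"} mode the postsynaptic drive is delivered
#' as receptor-kinetic currents (and slow inward currents) injected into the
#' membrane equation; in \code{"event-driven"} mode presynaptic spikes
#' instead increment the postsynaptic conductances by the maximal conductance
#' scaled by the receptor open fraction, and the conductances decay with
#' their synaptic time constants (slow inward currents are injected in both
#' modes).
#'
#' @param duration run length (s)
#' @param dt time step (ms); must be at most 1 ms
#' @param seed integer seed controlling layout construction and initial
#'   membrane potentials
#' @param protocol a \code{\link{gaba_protocol}}
#' @param mode \code{"kinetic"} or \code{"event-driven"}
#' @param astrocyte_enabled master switch for the astrocyte pathway
#'   (IP3/calcium dynamics, gliotransmission, presynaptic mGluR modulation,
#'   slow inward currents)
#' @param epsc_drive deliver the synaptically driven excitatory currents to
#'   the membrane (default). Switching this off removes the excitatory
#'   effect of regular synaptic currents while release, astrocyte activation
#'   and inhibition continue, isolating the direct astrocyte-to-neuron
#'   response (the reduced protocol used for slow-inward-current analysis)
#' @param neuron,synapse,receptor,astro parameter blocks
#' @param record_neurons,record_synapses,record_astros 1-based indices of
#'   entities whose state traces are sampled
#' @param trace_dt trace sampling interval (ms); must be a multiple of
#'   \code{dt}
#' @return an object of class \code{simulation_config}
#' @export
simulation_config <- function(duration = 10, dt = 0.1, seed = 1,
                              protocol = gaba_protocol(0),
                              mode = c("kinetic", "event-driven"),
                              astrocyte_enabled = TRUE,
                              epsc_drive = TRUE,
                              neuron = neuron_params(),
                              synapse = synapse_params(),
                              receptor = receptor_params(),
                              astro = astrocyte_params(),
                              record_neurons = 1:5,
                              record_synapses = integer(0),
                              record_astros = 1:5,
                              trace_dt = 1) {
  mode <- match.arg(mode)
  stopifnot(duration > 0, dt > 0, dt <= 1,
            inherits(protocol, "gaba_protocol"),
            trace_dt >= dt)
  stride <- round(trace_dt / dt)
  if (abs(stride * dt - trace_dt) > 1e-9) {
    stop("trace_dt must be a multiple of dt")
  }
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 protocol = protocol, mode = mode,
                 astrocyte_enabled = astrocyte_enabled,
                 epsc_drive = isTRUE(epsc_drive),
                 neuron = neuron, synapse = synapse, receptor = receptor,
                 astro = astro,
                 record_neurons = as.integer(record_neurons),
                 record_synapses = as.integer(record_synapses),
                 record_astros = as.integer(record_astros),
                 trace_dt = trace_dt),
            class = "simulation_config")
}

# CSR of synapse indices grouped by presynaptic neuron (0-based, for C++)
.efferent_csr <- function(pre, n_neu) {
  o <- order(pre)
  counts <- tabulate(pre, nbins = n_neu)
  list(ptr = as.integer(c(0, cumsum(counts))), idx = as.integer(o - 1L))
}

# CSR adjacency of the astrocyte gap-junction graph (0-based)
.astro_csr <- function(edges, n_astro) {
  if (n_astro == 0) return(list(ptr = integer(0), idx = integer(0)))
  a <- c(edges[, 1], edges[, 2]); b <- c(edges[, 2], edges[, 1])
  o <- order(a, b)
  counts <- tabulate(a, nbins = n_astro)
  list(ptr = as.integer(c(0, cumsum(counts))), idx = as.integer(b[o] - 1L))
}

#' Run a network simulation
#'
#' Integrates the coupled neuron-synapse-astrocyte system with a single
#' global clock at fixed step. Per step: the bath GABA concentration is
#' updated; astrocytes advance (IP3 production with gap-junction coupling,
#' Li-Rinzel calcium, threshold-latch gliotransmitter release); presynaptic
#' modulation and transmitter pools advance; receptor gates advance; currents
#' are computed and delivered; membranes advance; spikes are processed
#' (release jumps on the spiking neuron's efferent synapses). The run is
#' deterministic given the config and seed.
#'
#' @param config a \code{\link{simulation_config}}
#' @param layout a \code{\link{build_network}} layout; built from the config
#'   seed with default geometry when omitted
#' @return an object of class \code{simulation_result}: a list with
#'   \code{spikes} (data.frame: neuron_id, time_s, population),
#'   \code{rate} (1-ms-bin population rate, see \code{\link{population_rate}}),
#'   \code{traces} (network-mean and per-entity sampled series),
#'   \code{releases} (per-synapse release events for recorded synapses),
#'   \code{release_summary} (per-synapse mean released fraction over the whole
#'   run), \code{glio_events} (astrocytic release events),
#'   \code{config} and \code{layout} echoes
#' @export
#' @examples
#' net <- build_network(n_exc = 40, n_inh = 10, n_astro = 16, seed = 1)
#' cfg <- simulation_config(duration = 0.5, seed = 1,
#'                          protocol = gaba_protocol(10, t_on = 0.1))
#' res <- run_simulation(cfg, net)
#' res
run_simulation <- function(config, layout = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(layout)) layout <- build_network(seed = config$seed)
  syn <- layout$synapses
  n_neu <- length(layout$neuron_type)
  n_astro <- nrow(layout$astro_pos)
  is_exc <- as.integer(layout$neuron_type == "E")
  syn_astro <- ifelse(is.na(syn$astro), -1L, as.integer(syn$astro) - 1L)

  # initial membrane potentials: uniform in [v_rest, v_th) for asynchrony
  set.seed(config$seed + 2L)
  v_init <- stats::runif(n_neu, config$neuron$v_rest, config$neuron$v_th)

  # slow-inward-current pools: unique (astrocyte, postsynaptic neuron) pairs
  exc <- which(syn$type == "E")
  pools <- unique(data.frame(a = syn_astro[exc], j = syn$post[exc] - 1L))
  pools <- pools[pools$a >= 0, , drop = FALSE]

  eff <- .efferent_csr(syn$pre, n_neu)
  nb <- .astro_csr(layout$astro_edges, n_astro)

  np <- config$neuron; sp <- config$synapse; rp <- config$receptor
  ap <- config$astro
  dt_s <- config$dt * 1e-3
  n_steps <- round(config$duration / dt_s)
  stride <- round(config$trace_dt / config$dt)

  cfg <- list(
    dt = dt_s, n_steps = as.integer(n_steps),
    record_stride = as.integer(stride),
    astrocyte_enabled = isTRUE(config$astrocyte_enabled),
    epsc_drive = isTRUE(config$epsc_drive),
    kinetic_mode = config$mode == "kinetic",
    neuron = np,
    synapse = c(unclass(sp), list(O_G_uM = o_g_per_uM(sp))),
    receptor = list(ampa_alpha = rp$ampa$alpha, ampa_beta = rp$ampa$beta,
                    ampa_gmax = rp$ampa$g_max, ampa_erev = rp$ampa$E_rev,
                    nmda_alpha = rp$nmda$alpha, nmda_beta = rp$nmda$beta,
                    nmda_gmax = rp$nmda$g_max, nmda_erev = rp$nmda$E_rev,
                    gabaa_alpha = rp$gabaa$alpha, gabaa_beta = rp$gabaa$beta,
                    gabaa_gmax = rp$gabaa$g_max,
                    gabaa_erev = rp$gabaa$E_rev,
                    gabaa_scale = gabaa_scale_for_dose(rp,
                                                       config$protocol$dose),
                    Mg_conc = rp$Mg_conc),
    astro = c(unclass(ap)[setdiff(names(ap), c("lr", "glu_driver"))],
              unclass(ap$lr),
              list(glu_driver_mean = ap$glu_driver == "mean")),
    protocol = unclass(config$protocol),
    is_exc = is_exc,
    syn_pre = as.integer(syn$pre - 1L), syn_post = as.integer(syn$post - 1L),
    syn_exc = as.integer(syn$type == "E"), syn_astro = syn_astro,
    eff_ptr = eff$ptr, eff_idx = eff$idx,
    astro_nb_ptr = nb$ptr, astro_nb_idx = nb$idx,
    pool_astro = as.integer(pools$a), pool_neuron = as.integer(pools$j),
    rec_neurons = config$record_neurons - 1L,
    rec_synapses = config$record_synapses - 1L,
    rec_astros = config$record_astros[config$record_astros <= n_astro] - 1L,
    v_init = v_init)

  raw <- .run_engine_cpp(cfg)

  spikes <- data.frame(neuron_id = raw$spike_id + 1L,
                       time_s = raw$spike_time)
  spikes$population <- layout$neuron_type[spikes$neuron_id]
  spikes <- spikes[order(spikes$time_s, spikes$neuron_id), , drop = FALSE]
  rownames(spikes) <- NULL

  traces <- list(
    time = raw$trace_time, gaba = raw$gaba, r_gabab = raw$r_gabab,
    mean_ca = raw$mean_ca, mean_ip3 = raw$mean_ip3, mean_GA = raw$mean_GA,
    mean_GS = raw$mean_GS, mean_U = raw$mean_U, mean_sic = raw$mean_sic,
    neuron_v = raw$neuron_v, neuron_sic = raw$neuron_sic,
    neuron_epsc = raw$neuron_epsc,
    astro_ip3 = raw$astro_ip3, astro_ca = raw$astro_ca,
    astro_h = raw$astro_h, astro_xA = raw$astro_xA, astro_GA = raw$astro_GA,
    syn_u = raw$syn_u, syn_x = raw$syn_x, syn_U = raw$syn_U,
    syn_Gamma = raw$syn_Gamma, syn_GS = raw$syn_GS)

  releases <- data.frame(synapse_id = raw$release_syn + 1L,
                         time_s = raw$release_time, r_S = raw$release_rS)
  glio <- data.frame(astro_id = raw$glio_astro + 1L,
                     time_s = raw$glio_time, r_A = raw$glio_rA,
                     dG_A = raw$glio_dGA)
  rel_summary <- data.frame(synapse_id = seq_len(nrow(syn)),
                            type = syn$type,
                            n_releases = raw$rel_n,
                            sum_r_S = raw$rel_sum)
  rel_summary$mean_r_S <- ifelse(rel_summary$n_releases > 0,
                                 rel_summary$sum_r_S /
                                   rel_summary$n_releases, NA_real_)

  structure(list(spikes = spikes,
                 rate = population_rate(spikes, n_neu,
                                        t_range = c(0, config$duration)),
                 traces = traces, releases = releases,
                 release_summary = rel_summary, glio_events = glio,
                 config = config, layout = layout),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  dur <- x$config$duration
  n_neu <- length(x$layout$neuron_type)
  exc <- x$spikes$population == "E"
  n_e <- sum(x$layout$neuron_type == "E")
  n_i <- n_neu - n_e
  cat("<simulation_result>\n",
      " duration:", dur, "s, dt:", x$config$dt, "ms, dose:",
      x$config$protocol$dose, "uM, astrocytes:",
      if (x$config$astrocyte_enabled) "on" else "off", "\n",
      " spikes:  ", nrow(x$spikes),
      sprintf("(E %.2f Hz, I %.2f Hz per neuron)\n",
              sum(exc) / n_e / dur, sum(!exc) / max(1, n_i) / dur),
      " gliotransmitter release events:", nrow(x$glio_events), "\n")
  invisible(x)
}

#' Run a bath-GABA dose series
#'
#' Repeats the same run at several bath doses. All runs share one network
#' layout and one seed so the comparison across doses is paired; only the
#' stimulus dose (and with it the dose-dependent GABA-A conductance scaling)
#' differs.
#'
#' @param config a \code{\link{simulation_config}}; its protocol supplies
#'   onset, duration and clearance
#' @param doses numeric vector of bath doses (uM)
#' @param layout optional shared layout; built once from the config seed when
#'   omitted
#' @return a named list of \code{simulation_result}, one per dose
#' @export
run_dose_series <- function(config, doses = c(0, 1, 5, 10), layout = NULL) {
  stopifnot(length(doses) >= 1, all(doses >= 0))
  if (is.null(layout)) layout <- build_network(seed = config$seed)
  out <- lapply(doses, function(d) {
    cfg <- config
    cfg$protocol$dose <- d
    run_simulation(cfg, layout)
  })
  names(out) <- as.character(doses)
  out
}

#' Write spike table to CSV
#'
#' Deterministically ordered (time, id) spike export with columns
#' \code{neuron_id}, \code{time_ms}, \code{population}.
#'
#' @param result a \code{simulation_result}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_spikes_csv <- function(result, path) {
  sp <- result$spikes
  out <- data.frame(neuron_id = sp$neuron_id,
                    time_ms = sp$time_s * 1000,
                    population = sp$population)
  out <- out[order(out$time_ms, out$neuron_id), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
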