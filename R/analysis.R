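#' Binned population firing rate
#'
#' Population rate in spikes per neuron per second:
#' \code{rate(bin) = count(bin) / (n_neurons * bin_width)}. The default 1-ms
#' bin matches the standard raster-rate display; the integral of the rate
#' over the bins times \code{n_neurons} recovers the total spike count.
#'
#' @param spikes data.frame with a \code{time_s} column (seconds)
#' @param n_neurons population size used for normalisation
#' @param t_range two-element time range (s); defaults to [0, max spike time]
#' @param bin bin width (s)
#' @return a data.frame with columns \code{t_mid} (bin centre, s) and
#'   \code{rate} (Hz per neuron), plus attribute \code{"edges"}
#' @export
population_rate <- function(spikes, n_neurons, t_range = NULL, bin = 0.001) {
  stopifnot(bin > 0, n_neurons > 0)
  if (is.null(t_range)) {
    t_range <- c(0, if (nrow(spikes) > 0) max(spikes$time_s) else bin)
  }
  edges <- seq(t_range[1], t_range[2] + bin * 1e-9, by = bin)
  if (edges[length(edges)] < t_range[2]) edges <- c(edges, t_range[2])
  counts <- if (nrow(spikes) > 0) {
    hist(spikes$time_s, breaks = edges, plot = FALSE,
         include.lowest = TRUE, right = FALSE)$counts
  } else {
    numeric(length(edges) - 1)
  }
  widths <- diff(edges)
  out <- data.frame(t_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    rate = counts / (n_neurons * widths))
  attr(out, "edges") <- edges
  out
}

#' Calcium oscillation statistics
#'
#' Locates peaks in a uniformly sampled calcium trace with a prominence
#' criterion and summarises them: peak times, mean inter-peak period, and
#' mean peak amplitude above baseline. The baseline is the pre-stimulus mean
#' of the trace (the mean over \code{t < baseline_end}); with fewer than two
#' peaks the period is undefined and reported as \code{NA}, not zero.
#'
#' @param time sample times (s), uniformly spaced
#' @param ca calcium trace (uM)
#' @param min_prominence minimal peak prominence (uM)
#' @param baseline_end end of the baseline window (s); when no samples fall
#'   before it the first sample is used as baseline
#' @return a list with \code{peak_times}, \code{peak_values},
#'   \code{peak_count}, \code{mean_period} (s or NA), \code{mean_amplitude}
#'   (uM above baseline; 0 when no peaks), \code{baseline}
#' @export
ca_oscillation_metrics <- function(time, ca, min_prominence = 0.05,
                                   baseline_end = 1.0) {
  stopifnot(length(time) == length(ca), length(ca) >= 3)
  base_idx <- which(time < baseline_end)
  baseline <- if (length(base_idx) > 0) mean(ca[base_idx]) else ca[1]
  pk <- pracma::findpeaks(ca)
  if (!is.null(pk)) {
    idx <- sort(pk[, 2])
    prom <- vapply(idx, function(i) .peak_prominence(ca, i), numeric(1))
    idx <- idx[prom >= min_prominence]
  } else {
    idx <- integer(0)
  }
  if (length(idx) == 0) {
    return(list(peak_times = numeric(0), peak_values = numeric(0),
                peak_count = 0L, mean_period = NA_real_,
                mean_amplitude = 0, baseline = baseline))
  }
  times <- time[idx]
  vals <- ca[idx]
  list(peak_times = times, peak_values = vals,
       peak_count = length(times),
       mean_period = if (length(times) >= 2) mean(diff(times)) else
         NA_real_,
       mean_amplitude = mean(vals - baseline),
       baseline = baseline)
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two key cols (lowest points separating it from higher ground)
.peak_prominence <- function(x, i) {
  h <- x[i]
  # each side is walked outward from the peak; the col is the minimum
  # between the peak and the first strictly higher sample (or the signal
  # edge when no higher ground exists on that side)
  col_side <- function(side) {
    if (length(side) == 0) return(-Inf)
    fh <- which(side > h)[1]
    if (is.na(fh)) return(min(side))
    if (fh == 1) return(h)
    min(side[seq_len(fh - 1)])
  }
  lmin <- col_side(rev(x[seq_len(i - 1)]))
  rmin <- col_side(if (i < length(x)) x[(i + 1):length(x)] else numeric(0))
  h - max(lmin, rmin)
}

#' Per-event peak amplitudes of a current trace
#'
#' Splits a current trace at the given release-event times and reports, for
#' each inter-event window, the peak magnitude of the current. Used with
#' origin-tagged traces: synaptically driven currents give EPSC amplitudes,
#' astrocyte-driven currents give SIC amplitudes.
#'
#' @param time sample times (s)
#' @param current current trace (pA, inward-negative)
#' @param event_times times of the release events that start each window (s)
#' @return a data.frame with columns \code{time} (event time) and
#'   \code{amplitude} (pA, magnitude); empty for an all-zero trace or no
#'   events
#' @export
event_amplitudes <- function(time, current, event_times) {
  stopifnot(length(time) == length(current))
  event_times <- sort(event_times)
  if (length(event_times) == 0 || all(current == 0)) {
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  }
  ends <- c(event_times[-1], Inf)
  amp <- vapply(seq_along(event_times), function(k) {
    w <- time >= event_times[k] & time < ends[k]
    if (!any(w)) return(NA_real_)
    max(abs(current[w]))
  }, numeric(1))
  keep <- !is.na(amp)
  data.frame(time = event_times[keep], amplitude = amp[keep])
}

#' Slow-inward-current amplitudes per gliotransmitter release event
#'
#' Reconstructs, for every recorded astrocyte, the slow inward current its
#' extrasynaptic glutamate would evoke in a postsynaptic neuron held at
#' \code{v_hold}: the recorded G_A trace drives an AMPA/NMDA receptor pool
#' (two-state gating) and the resulting current is split into windows at the
#' astrocyte's release events, reporting the peak magnitude per event. A
#' fixed holding potential isolates the per-event amplitude from the
#' postsynaptic neuron's own voltage excursions, the convention used when
#' SIC amplitudes are read off voltage-clamp-style traces.
#'
#' @param result a \code{simulation_result} with recorded astrocytes
#' @param v_hold holding potential (mV)
#' @param rp receptor parameters; defaults to the run's own
#' @return a data.frame with columns \code{astro_id}, \code{time},
#'   \code{amplitude} (pA)
#' @export
sic_event_amplitudes <- function(result, v_hold = -60, rp = NULL) {
  if (is.null(rp)) rp <- result$config$receptor
  tr <- result$traces
  ids <- result$config$record_astros
  out <- list()
  for (j in seq_along(ids)) {
    ev <- result$glio_events$time_s[result$glio_events$astro_id == ids[j]]
    if (length(ev) == 0) next
    ga <- tr$astro_GA[, j]
    dt <- diff(tr$time[1:2])
    ra <- rn <- numeric(length(ga))
    for (k in 2:length(ga)) {
      ra[k] <- receptor_gating_step(ra[k - 1], rp$ampa$alpha, rp$ampa$beta,
                                    ga[k - 1], dt)
      rn[k] <- receptor_gating_step(rn[k - 1], rp$nmda$alpha, rp$nmda$beta,
                                    ga[k - 1], dt)
    }
    cur <- sic_current(ra, rn, rp, v_hold)
    amp <- event_amplitudes(tr$time, cur, ev)
    if (nrow(amp) > 0) {
      out[[length(out) + 1]] <- data.frame(astro_id = ids[j],
                                           time = amp$time,
                                           amplitude = amp$amplitude)
    }
  }
  if (length(out) == 0) {
    return(data.frame(astro_id = integer(0), time = numeric(0),
                      amplitude = numeric(0)))
  }
  do.call(rbind, out)
}

#' Presynaptic release-probability series
#'
#' Extracts the per-spike released fractions r_S (the release probability Pr
#' of each event) from a release-event table and attaches a summary.
#'
#' @param release_events data.frame with columns \code{time_s} and
#'   \code{r_S} (and optionally \code{synapse_id})
#' @return a data.frame (time, r_S, sorted by time) with attribute
#'   \code{"summary"} = c(mean, min, max, n)
#' @export
pr_series <- function(release_events) {
  if (nrow(release_events) == 0) {
    out <- data.frame(time = numeric(0), r_S = numeric(0))
    attr(out, "summary") <- c(mean = NA_real_, min = NA_real_,
                              max = NA_real_, n = 0)
    return(out)
  }
  o <- order(release_events$time_s)
  out <- data.frame(time = release_events$time_s[o],
                    r_S = release_events$r_S[o])
  attr(out, "summary") <- c(mean = mean(out$r_S), min = min(out$r_S),
                            max = max(out$r_S), n = nrow(out))
  out
}

#' Mean release probability of excitatory synapses in a run
#'
#' Grand mean of the released fraction r_S over all release events at
#' excitatory synapses, the run-level "mean Pr" used in dose comparisons.
#'
#' @param result a \code{simulation_result}
#' @return a scalar (NA if no excitatory releases occurred)
#' @export
mean_release_probability <- function(result) {
  rs <- result$release_summary
  exc <- rs$type == "E"
  tot_n <- sum(rs$n_releases[exc])
  if (tot_n == 0) return(NA_real_)
  sum(rs$sum_r_S[exc]) / tot_n
}

#' Raster-plot export table
#'
#' Spike table for raster display, optionally subsampled to a fraction of
#' the population (e.g. a quarter, as in compact raster figures).
#'
#' @param result a \code{simulation_result}
#' @param fraction fraction of neurons to keep (per population, lowest ids
#'   first; default 1 = everyone)
#' @return a data.frame (neuron_id, time_s, population)
#' @export
raster_table <- function(result, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  sp <- result$spikes
  if (fraction < 1) {
    types <- result$layout$neuron_type
    keep <- unlist(lapply(c("E", "I"), function(tp) {
      ids <- which(types == tp)
      ids[seq_len(ceiling(length(ids) * fraction))]
    }))
    sp <- sp[sp$neuron_id %in% keep, , drop = FALSE]
  }
  rownames(sp) <- NULL
  sp
}
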