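# Network engine: determinism, closed-form single-neuron behaviour,
# agreement with the pure-R tripartite harness, step-size convergence,
# release bookkeeping, and both current-delivery modes.

small_config <- function(duration = 0.5, dose = 0, seed = 1, ...) {
  simulation_config(duration = duration, seed = seed,
                    protocol = gaba_protocol(dose, t_on = 0.1), ...)
}

test_that("identical config and seed reproduce the spike table exactly", {
  net <- build_network(n_exc = 40, n_inh = 10, n_astro = 16, seed = 4)
  cfg <- small_config(dose = 5)
  a <- run_simulation(cfg, net)
  b <- run_simulation(cfg, net)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$traces$mean_ca, b$traces$mean_ca)
  expect_identical(a$release_summary$sum_r_S, b$release_summary$sum_r_S)
})

test_that("an isolated tonically driven neuron fires at the closed-form ISI", {
  net <- isolated_neuron_layout()
  cfg <- small_config(duration = 1, astrocyte_enabled = FALSE)
  res <- run_simulation(cfg, net)
  isi <- diff(res$spikes$time_s) * 1000     # ms
  expect_gte(length(isi), 10)
  theory <- lif_isi_closed_form(neuron_params())   # 5 + 20 log 21 ~ 65.9 ms
  expect_true(all(abs(isi - theory) <= 2 * cfg$dt))
  # no interval violates the refractory period
  expect_true(all(isi >= neuron_params()$tau_ref))
})

test_that("engine agrees with the pure-R tripartite harness on a 1-synapse net", {
  net <- two_neuron_layout()
  cfg <- simulation_config(duration = 1.5, seed = 11,
                           protocol = gaba_protocol(10, t_on = 0.2),
                           record_neurons = 2, record_synapses = 1,
                           record_astros = 1)
  res <- run_simulation(cfg, net)
  pre_spikes <- res$spikes$time_s[res$spikes$neuron_id == 1]
  expect_gte(length(pre_spikes), 10)

  set.seed(cfg$seed + 2L)
  v_init <- runif(2, -60, -50)
  fx <- single_tripartite_fixture(dose = 10, spike_train = pre_spikes,
                                  duration = 1.5, t_on = 0.2,
                                  v0 = v_init[2])

  # presynaptic release sequence matches event-for-event
  eng_rel <- res$releases[res$releases$synapse_id == 1, ]
  expect_equal(nrow(eng_rel), nrow(fx$releases))
  expect_equal(eng_rel$time_s, fx$releases$time_s, tolerance = 1e-12)
  expect_equal(eng_rel$r_S, fx$releases$r_S, tolerance = 1e-9)

  # sampled state traces match to tight tolerance
  expect_equal(res$traces$astro_ip3[, 1], fx$traces$ip3, tolerance = 1e-9)
  expect_equal(res$traces$astro_ca[, 1], fx$traces$ca, tolerance = 1e-9)
  expect_equal(res$traces$syn_GS[, 1], fx$traces$G_S, tolerance = 1e-8)
  expect_equal(res$traces$syn_u[, 1], fx$traces$u_S, tolerance = 1e-9)
  expect_equal(res$traces$syn_U[, 1], fx$traces$U, tolerance = 1e-9)
  expect_equal(res$traces$neuron_v[, 1], fx$traces$v, tolerance = 1e-6)
  expect_equal(res$traces$neuron_sic[, 1], fx$traces$I_sic,
               tolerance = 1e-6)
  # gliotransmitter events coincide
  expect_equal(res$glio_events$time_s, fx$glio_events$time_s,
               tolerance = 1e-12)
  expect_equal(res$glio_events$dG_A, fx$glio_events$dG_A, tolerance = 1e-9)
})

test_that("release bookkeeping: one release evaluation per efferent synapse", {
  net <- build_network(n_exc = 30, n_inh = 10, n_astro = 16, seed = 8)
  res <- run_simulation(small_config(), net)
  out_deg <- tabulate(net$synapses$pre, nbins = 40)
  expected <- sum(out_deg[res$spikes$neuron_id])
  expect_equal(sum(res$release_summary$n_releases), expected)
  # all released fractions are probabilities
  rs <- res$release_summary
  ok <- rs$n_releases > 0
  expect_true(all(rs$mean_r_S[ok] >= 0 & rs$mean_r_S[ok] <= 1))
})

test_that("halving dt changes the spike count of a short run by under 2%", {
  net <- build_network(n_exc = 40, n_inh = 10, n_astro = 16, seed = 2)
  c1 <- simulation_config(duration = 2, dt = 0.1, seed = 2,
                          protocol = gaba_protocol(5, t_on = 0.2))
  c2 <- simulation_config(duration = 2, dt = 0.05, seed = 2,
                          protocol = gaba_protocol(5, t_on = 0.2))
  n1 <- nrow(run_simulation(c1, net)$spikes)
  n2 <- nrow(run_simulation(c2, net)$spikes)
  expect_lt(abs(n1 - n2) / n1, 0.02)
})

test_that("bath GABA suppresses firing when the astrocyte pathway is off", {
  net <- build_network(n_exc = 80, n_inh = 20, n_astro = 16, seed = 3)
  cfg <- simulation_config(duration = 1, seed = 3,
                           protocol = gaba_protocol(0, t_on = 0.1),
                           astrocyte_enabled = FALSE)
  rs <- run_dose_series(cfg, c(0, 10), net)
  r0 <- sum(rs[["0"]]$spikes$population == "E")
  r10 <- sum(rs[["10"]]$spikes$population == "E")
  expect_lt(r10, r0)
})

test_that("dose series shares the layout and a single dose reduces to run()", {
  net <- build_network(n_exc = 20, n_inh = 5, n_astro = 9, seed = 6)
  cfg <- small_config(duration = 0.3, seed = 6)
  series <- run_dose_series(cfg, doses = 0, net)
  single <- run_simulation(cfg, net)
  expect_identical(series[["0"]]$spikes, single$spikes)
  two <- run_dose_series(cfg, doses = c(0, 10), net)
  expect_identical(two[["0"]]$layout, two[["10"]]$layout)
})

test_that("event-driven mode runs, spikes, and differs from kinetic mode", {
  net <- build_network(n_exc = 40, n_inh = 10, n_astro = 16, seed = 5)
  ck <- small_config(duration = 0.5, dose = 5, seed = 5)
  ce <- small_config(duration = 0.5, dose = 5, seed = 5,
                     mode = "event-driven")
  rk <- run_simulation(ck, net)
  re <- run_simulation(ce, net)
  expect_gt(nrow(re$spikes), 0)
  expect_false(identical(rk$spikes, re$spikes))
})

test_that("spike export is ordered by (time, id) with population labels", {
  net <- build_network(n_exc = 20, n_inh = 5, n_astro = 9, seed = 1)
  res <- run_simulation(small_config(duration = 0.3), net)
  path <- tempfile(fileext = ".csv")
  write_spikes_csv(res, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("neuron_id", "time_ms", "population"))
  expect_true(all(diff(tab$time_ms) >= 0))
  expect_true(all(tab$population %in% c("E", "I")))
  unlink(path)
})
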