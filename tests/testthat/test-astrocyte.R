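# Astrocytic IP3 production, gap-junction diffusion, Li-Rinzel calcium and
# the calcium-threshold gliotransmitter release rule.

test_that("IP3 relaxes to its equilibrium with the analytic time course", {
  ap <- astrocyte_params()
  # from 0.30 uM with no drivers: ip3(7 s) = 0.16 + 0.14 e^-1
  st <- astrocyte_state(ap, ip3 = 0.30)
  dt <- 1e-4
  for (i in seq_len(round(7 / dt))) {
    st <- ip3_production_step(st, ap, Glu = 0, GABA_ex = 0, J_G = 0, dt = dt)
  }
  expect_equal(st$ip3, 0.16 + 0.14 * exp(-1), tolerance = 1e-4)
  expect_equal(st$ip3, 0.2115, tolerance = 1e-3)
})

test_that("IP3 converges to 0.16 uM from any start with all drivers zero", {
  ap <- astrocyte_params()
  dt <- 1e-4
  for (ip3_0 in c(0, 0.5, 1)) {
    st <- astrocyte_state(ap, ip3 = ip3_0)
    for (i in seq_len(round(60 / dt))) {
      st <- ip3_production_step(st, ap, 0, 0, 0, dt)
    }
    expect_lt(abs(st$ip3 - 0.16), 1e-3)
  }
})

test_that("module IP3 stepping matches the independent fine-step reference", {
  ap <- astrocyte_params()
  ref <- reference_integrator("ip3", duration = 5, dt = 1e-6, params = ap,
                              ip3_0 = 0.9, stride = 5e6)
  st <- astrocyte_state(ap, ip3 = 0.9)
  for (i in seq_len(5e4)) st <- ip3_production_step(st, ap, 0, 0, 0, 1e-4)
  expect_equal(st$ip3, ref$ip3[length(ref$ip3)], tolerance = 1e-5)
})

test_that("Hill production fluxes hit half-saturation and crosstalk gain", {
  ap <- astrocyte_params()
  # GABA at its dissociation constant gives half the maximal rate,
  # independent of the Hill exponent
  J <- ip3_fluxes(ap, Glu = 0, GABA_ex = ap$k_gaba)
  expect_equal(J$J_gaba, ap$v_gaba / 2)
  expect_equal(J$J_gaba, 0.08125)
  # the glutamate flux is amplified by (1 + k * GABA_ex)
  J0 <- ip3_fluxes(ap, Glu = 5, GABA_ex = 0)
  J10 <- ip3_fluxes(ap, Glu = 5, GABA_ex = 10)
  # at GABA_ex = 10 the GABA Hill term is active too, so isolate the ratio
  expect_equal(J10$J_glu / J0$J_glu, 1 + 0.3 * 10)
  # both fluxes vanish without drivers
  Jz <- ip3_fluxes(ap, 0, 0)
  expect_equal(Jz$J_gaba + Jz$J_glu, 0)
  # amplification switch
  ap_off <- astrocyte_params(amp_on_ip3 = FALSE)
  expect_equal(ip3_fluxes(ap_off, 5, 10)$J_glu, J0$J_glu)
})

test_that("gap-junction flux is thresholded, odd, and sums over neighbours", {
  ap <- astrocyte_params()
  expect_equal(gap_junction_flux(0.4, 0.4, ap), 0)  # sgn(0) = 0
  # a gradient exactly at the threshold: -(F_ex/2)(1 + tanh 0)
  expect_equal(gap_junction_flux(0.5, 0.2, ap), -0.045)
  # odd symmetry
  for (d in c(0.05, 0.2, 0.3, 0.7)) {
    expect_equal(gap_junction_flux(0.3 + d, 0.3, ap),
                 -gap_junction_flux(0.3, 0.3 + d, ap))
  }
  # additivity over neighbours
  expect_equal(gap_junction_flux(0.5, c(0.2, 0.9), ap),
               gap_junction_flux(0.5, 0.2, ap) +
                 gap_junction_flux(0.5, 0.9, ap))
  # sub-threshold differences leak almost nothing
  expect_lt(abs(gap_junction_flux(0.31, 0.3, ap)), 0.001)
})

test_that("Li-Rinzel calcium is quiescent at low IP3 and oscillates in the window", {
  ap <- astrocyte_params()
  run_ca <- function(ip3_clamp, duration = 60) {
    st <- astrocyte_state(ap, ip3 = ip3_clamp, ca = 0.1)
    n <- round(duration / 1e-3)
    ca <- numeric(n)
    for (i in seq_len(n)) {
      st <- calcium_step(st, ap, dt = 1e-3)
      st$ip3 <- ip3_clamp
      ca[i] <- st$ca
    }
    ca
  }
  # low IP3: stable fixed point, no peaks after the transient
  ca_low <- run_ca(0.1)
  tail_low <- ca_low[30000:60000]
  expect_lt(diff(range(tail_low)), 1e-3)
  m_low <- ca_oscillation_metrics(seq_along(tail_low) * 1e-3, tail_low,
                                  min_prominence = 0.05)
  expect_equal(m_low$peak_count, 0L)
  # inside the oscillatory window: sustained oscillations, period ~10 s order
  ca_mid <- run_ca(0.45, duration = 100)
  tail_mid <- ca_mid[40001:100000]
  m_mid <- ca_oscillation_metrics(seq_along(tail_mid) * 1e-3, tail_mid,
                                  min_prominence = 0.05)
  expect_gte(m_mid$peak_count, 3)
  expect_gt(m_mid$mean_period, 1); expect_lt(m_mid$mean_period, 60)
  # flux balance at the quiescent fixed point: J_channel + J_leak = J_pump
  lr <- ap$lr
  ca_fp <- tail_low[length(tail_low)]
  st_fp <- astrocyte_state(ap, ip3 = 0.1, ca = ca_fp)
  h_fp <- st_fp$h_gate
  # after long integration h is at equilibrium too; recompute the rhs
  m_inf <- 0.1 / (0.1 + lr$d1); n_inf <- ca_fp / (ca_fp + lr$d5)
  drive <- lr$c0 - (1 + lr$c1) * ca_fp
  influx <- lr$v1 * (m_inf * n_inf * h_fp)^3 * drive + lr$v2 * drive
  outflux <- lr$v3 * ca_fp^2 / (lr$k3^2 + ca_fp^2)
  expect_equal(influx, outflux, tolerance = 1e-2 * outflux)
})

test_that("gliotransmitter release fires once per excursion with the right size", {
  ap <- astrocyte_params()
  st <- astrocyte_state(ap)
  st$ca <- 0.25  # above threshold
  out <- gliotransmitter_release_step(st, ap, GABA_ex = 0, dt = 1e-4, t = 1)
  expect_false(is.null(out$event))
  expect_equal(out$event$r_A, 0.6, tolerance = 1e-4)
  expect_equal(out$event$dG_A, 0.6 * 6.5e-4 * 200 * 1000,
               tolerance = 1e-3)                      # 78 uM
  expect_equal(out$state$x_A, 1 - out$event$r_A, tolerance = 1e-4)
  # latched: staying above threshold does not release again
  out2 <- gliotransmitter_release_step(out$state, ap, 0, dt = 1e-4, t = 1.01)
  expect_null(out2$event)
  # crosstalk amplification at GABA_ex = 10 scales the jump by 4
  st2 <- astrocyte_state(ap); st2$ca <- 0.25
  out3 <- gliotransmitter_release_step(st2, ap, GABA_ex = 10, dt = 1e-4,
                                       t = 1)
  expect_equal(out3$event$dG_A, 4 * 78, tolerance = 0.1)
  # below threshold forever: no events and G_A decays to zero
  st3 <- astrocyte_state(ap); st3$ca = 0.05; st3$G_A <- 50
  for (i in 1:5000) {
    o <- gliotransmitter_release_step(st3, ap, 0, dt = 1e-3, t = i * 1e-3)
    expect_null(o$event)
    st3 <- o$state
  }
  expect_lt(st3$G_A, 1e-10)
})

test_that("release events are separated by a down-crossing (latch property)", {
  ap <- astrocyte_params()
  st <- astrocyte_state(ap)
  # drive ca through two excursions above the threshold
  ca_path <- c(seq(0.1, 0.3, length = 50), seq(0.3, 0.1, length = 50),
               seq(0.1, 0.4, length = 50))
  events <- 0
  for (ca in ca_path) {
    st$ca <- ca
    o <- gliotransmitter_release_step(st, ap, 0, dt = 1e-3, t = 0)
    st <- o$state
    if (!is.null(o$event)) events <- events + 1
  }
  expect_equal(events, 2)  # one per upward crossing, despite 100+ steps above
})

test_that("resource fraction and glutamate remain in bounds under random drive", {
  ap <- astrocyte_params()
  set.seed(7)
  st <- astrocyte_state(ap)
  for (i in 1:2000) {
    st$ca <- runif(1, 0, 0.5)
    o <- gliotransmitter_release_step(st, ap, GABA_ex = runif(1, 0, 10),
                                      dt = 1e-3, t = i * 1e-3)
    st <- o$state
    expect_true(st$x_A >= 0 && st$x_A <= 1)
    expect_gte(st$G_A, 0)
  }
})
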