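# Presynaptic comodulation, TM release machinery, transmitter pools,
# receptor gating and postsynaptic currents.

test_that("release probability follows the comodulation formula", {
  sp <- synapse_params()
  st <- presynaptic_state(sp)
  # both modulations absent -> U = U0
  st0 <- update_release_modulation(st, sp, G_A = 0, GABA_ex = 0, dt = 1e-4)
  expect_equal(st0$U, 0.3)
  # full mGluR activation -> U = xi
  st$Gamma <- 1
  st1 <- update_release_modulation(st, sp, G_A = 0, GABA_ex = 0, dt = 0)
  expect_equal(st1$U, 0.8)
  # full mGluR + full GABA-B -> U = xi - U0
  st$r_gabab <- 1
  st2 <- update_release_modulation(st, sp, G_A = 0, GABA_ex = 0, dt = 0)
  expect_equal(st2$U, 0.5)
  # clamp: xi < U0 with strong GABA-B cannot push U below 0
  sp_neg <- synapse_params(xi = 0.1)
  st$Gamma <- 0; st$r_gabab <- 1
  st3 <- update_release_modulation(st, sp_neg, G_A = 0, GABA_ex = 0, dt = 0)
  expect_gte(st3$U, 0)
  expect_error(update_release_modulation(st, sp, G_A = -1, GABA_ex = 0,
                                         dt = 1e-4), "non-negative")
})

test_that("mGluR activation settles at its analytic steady state", {
  sp <- synapse_params()
  G_A <- 50
  gamma_inf <- sp$O_G * G_A / (sp$O_G * G_A + sp$Omega_G)
  st <- presynaptic_state(sp)
  for (i in 1:20000) {
    st <- update_release_modulation(st, sp, G_A = G_A, GABA_ex = 0,
                                    dt = 1e-3)  # 20 s
  }
  expect_equal(st$Gamma, gamma_inf, tolerance = 1e-4)
})

test_that("O_G unit override makes the mGluR pathway inert at the printed unit", {
  sp_M <- synapse_params(O_G_unit = "M")
  st <- presynaptic_state(sp_M)
  for (i in 1:10000) {
    st <- update_release_modulation(st, sp_M, G_A = 78, GABA_ex = 0,
                                    dt = 1e-3)
  }
  expect_lt(st$Gamma, 1e-3)  # 78 uM binds at ~1e-4 s^-1 under M^-1 s^-1
})

test_that("TM spike jumps match the hand-stepped event sequence", {
  sp <- synapse_params()
  st <- presynaptic_state(sp)
  st$U <- 0.3
  # first spike from rest
  e1 <- on_presynaptic_spike(st, sp)
  expect_equal(e1$r_S, 0.3)
  expect_equal(e1$state$u_S, 0.3)
  expect_equal(e1$state$x_S, 0.7)
  # immediate second spike (no relaxation)
  e2 <- on_presynaptic_spike(e1$state, sp)
  expect_equal(e2$state$u_S, 0.3 + 0.3 * 0.7)      # 0.51
  expect_equal(e2$r_S, 0.51 * 0.7)                 # 0.357
  expect_equal(e2$state$x_S, 0.7 - 0.357)          # 0.343
  # full recovery: a spike after t >> tau_fac, tau_rec repeats the first
  rest <- tm_relaxation_step(e1$state, sp, dt = 100)
  e3 <- on_presynaptic_spike(rest, sp)
  expect_equal(e3$r_S, 0.3, tolerance = 1e-12)
})

test_that("single-train TM dynamics agree with an event-by-event oracle", {
  sp <- synapse_params()
  spikes <- c(0.05, 0.12, 0.16, 0.5, 0.52)
  # oracle: closed-form inter-spike relaxation + jump rules, event to event
  oracle <- function(times, U) {
    u <- 0; x <- 1; out <- numeric(length(times)); tl <- 0
    for (k in seq_along(times)) {
      el <- times[k] - tl
      u <- u * exp(-el / sp$tau_fac)
      x <- 1 - (1 - x) * exp(-el / sp$tau_rec)
      u <- u + U * (1 - u)
      out[k] <- u * x
      x <- x - out[k]
      tl <- times[k]
    }
    out
  }
  st <- presynaptic_state(sp); st$U <- 0.3
  got <- numeric(length(spikes)); tl <- 0
  for (k in seq_along(spikes)) {
    st <- tm_relaxation_step(st, sp, dt = spikes[k] - tl)
    e <- on_presynaptic_spike(st, sp)
    st <- e$state; got[k] <- e$r_S; tl <- spikes[k]
  }
  expect_equal(got, oracle(spikes, 0.3), tolerance = 1e-14)
})

test_that("cleft glutamate jumps and decays as specified", {
  sp <- synapse_params()
  st <- presynaptic_state(sp)
  st <- transmitter_step(st, sp, release = 0.3, dt = 1e-12)
  expect_equal(st$G_S, 0.3 * 0.005 * 500 * 1000, tolerance = 1e-6)  # 750 uM
  # exponential clearance, half-life ln 2 / 40 ~ 17.3 ms
  g0 <- st$G_S
  st <- transmitter_step(st, sp, release = NULL, dt = log(2) / 40)
  expect_equal(st$G_S, g0 / 2, tolerance = 1e-9)
  # zero pool stays zero without release
  st0 <- presynaptic_state(sp)
  st0 <- transmitter_step(st0, sp, release = NULL, dt = 1)
  expect_equal(st0$G_S, 0)
})

test_that("GABAergic terminals use the slower uptake clearance", {
  sp <- synapse_params()
  st <- presynaptic_state(sp, glutamatergic = FALSE)
  expect_equal(st$U, sp$U_inh)
  st <- transmitter_step(st, sp, release = 0.5, dt = 1e-12)
  g0 <- st$G_S
  st <- transmitter_step(st, sp, release = NULL, dt = log(2) / 6)
  expect_equal(st$G_S, g0 / 2, tolerance = 1e-9)
})

test_that("receptor gating reaches the two-state steady state", {
  rp <- receptor_params()
  # AMPA at a 750-uM pulse: r_inf = alpha T / (alpha T + beta)
  r <- 0
  for (i in 1:200000) {
    r <- receptor_gating_step(r, rp$ampa$alpha, rp$ampa$beta,
                              T_conc = 750, dt = 1e-5)  # 2 s
  }
  expect_equal(r, 1.1 * 750 / (1.1 * 750 + 190), tolerance = 1e-4)
  expect_equal(r, 0.813, tolerance = 1e-3)
  # GABA-A at 10 uM
  r <- 0
  for (i in 1:200000) {
    r <- receptor_gating_step(r, rp$gabaa$alpha, rp$gabaa$beta,
                              T_conc = 10, dt = 1e-5)
  }
  expect_equal(r, 5.3 / 185.3, tolerance = 1e-4)
  # pure unbinding at T = 0
  r <- receptor_gating_step(0.5, rp$ampa$alpha, rp$ampa$beta, 0, dt = 1e-5)
  expect_equal(r, 0.5 * (1 - 190 * 1e-5), tolerance = 1e-12)
})

test_that("receptor gating matches the analytic exponential under constant T", {
  # dr/dt = aT(1-r) - br has solution r(t) = r_inf (1 - exp(-(aT+b) t))
  a <- 1.1; b <- 190; T_conc <- 100
  ref <- reference_integrator("receptor", duration = 0.02, dt = 1e-7,
                              params = list(alpha = a, beta = b),
                              T_conc = T_conc, stride = 1e5)
  rate <- a * T_conc + b
  analytic <- (a * T_conc / rate) * (1 - exp(-rate * ref$time))
  expect_lt(max(abs(ref$r - analytic)), 1e-6)
})

test_that("postsynaptic currents follow the driving-force equations", {
  rp <- receptor_params()
  expect_equal(mg_block(0), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(mg_block(0), 0.781, tolerance = 1e-3)
  cur <- postsynaptic_currents(1, 0, 0, rp, v = -60)
  expect_equal(cur$I_AMPA, 0.35 * (-60 - 0))   # -21 pA, inward
  expect_equal(cur$I_NMDA, 0)
  zero <- postsynaptic_currents(0, 0, 0, rp, v = -60)
  expect_true(all(unlist(zero) == 0))
  # dose scaling multiplies only the GABA-A conductance
  c2 <- postsynaptic_currents(0, 0, 0.5, rp, v = -60, gabaa_scale = 2)
  c1 <- postsynaptic_currents(0, 0, 0.5, rp, v = -60, gabaa_scale = 1)
  expect_equal(c2$I_GABAA, 2 * c1$I_GABAA)
})

test_that("SIC matches a fine-step reference and grows with the pulse height", {
  rp <- receptor_params()
  # coarse-step pool response to a G_A pulse decaying at the glial clearance
  run_pool <- function(G0, dt) {
    n <- round(0.5 / dt)
    ra <- 0; rn <- 0; peak <- 0
    for (i in seq_len(n)) {
      G <- G0 * exp(-60 * (i - 1) * dt)
      ra <- receptor_gating_step(ra, rp$ampa$alpha, rp$ampa$beta, G, dt)
      rn <- receptor_gating_step(rn, rp$nmda$alpha, rp$nmda$beta, G, dt)
      peak <- max(peak, abs(sic_current(ra, rn, rp, v = -60)))
    }
    peak
  }
  peak_coarse <- run_pool(78, 1e-4)
  peak_fine <- run_pool(78, 1e-6)     # fine-step reference integration
  expect_equal(peak_coarse, peak_fine, tolerance = 0.01)
  # monotone in pulse height
  peaks <- vapply(c(20, 78, 150, 312), run_pool, numeric(1), dt = 1e-4)
  expect_true(all(diff(peaks) > 0))
})

test_that("presynaptic state variables stay in [0, 1] under arbitrary drive", {
  sp <- synapse_params()
  set.seed(42)
  st <- presynaptic_state(sp)
  for (i in 1:2000) {
    st <- update_release_modulation(st, sp, G_A = runif(1, 0, 500),
                                    GABA_ex = runif(1, 0, 50), dt = 1e-3)
    st <- tm_relaxation_step(st, sp, dt = runif(1, 0, 0.05))
    if (runif(1) < 0.2) st <- on_presynaptic_spike(st, sp)$state
    with(st, expect_true(all(c(u_S, x_S, Gamma, r_gabab, U) >= 0 &
                             c(u_S, x_S, Gamma, r_gabab, U) <= 1)))
    expect_gte(st$G_S, 0)
  }
})
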