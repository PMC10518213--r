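test_that("stimulus traces follow the symmetric contrast convention", {
  fs <- 1000
  # zero contrast: constant at background
  st0 <- make_stimulus(stimulus_spec(600, 0, 1, duration = 1, phase_zero = 0),
                       fs)
  expect_equal(as.numeric(st0), rep(600, 1000))

  # 80% contrast on 600: symmetric split of L_max - L_min = 480
  st <- make_stimulus(stimulus_spec(600, 80, 1, duration = 2, phase_zero = 0),
                      fs)
  expect_equal(max(st), 840)
  expect_equal(min(st), 360)
  spec <- attr(st, "spec")
  expect_equal(100 * (max(st) - min(st)) / spec$background_intensity, 80)

  # 1 Hz over 2 s: exactly 2 cycles, transitions at 0.5-s multiples,
  # first half-cycle is the On-phase
  expect_equal(as.numeric(st[1]), 840)
  tr <- which(diff(as.numeric(st)) != 0) / fs
  expect_equal(tr, c(0.5, 1.0, 1.5))
  expect_error(stimulus_spec(600, 120, 1), "contrast")
})

test_that("shot-noise conductance is reproducible and respects edge cases", {
  u <- unitary_event(0.2, 2)
  expect_equal(shot_noise_conductance(rep(0, 500), u, 10000, seed = 1),
               rep(0, 500))
  expect_error(shot_noise_conductance(rep(-5, 10), u, 10000, seed = 1),
               "rate")
  a <- shot_noise_conductance(rep(1000, 2000), u, 10000, seed = 7)
  b <- shot_noise_conductance(rep(1000, 2000), u, 10000, seed = 7)
  expect_identical(a, b)
  c2 <- shot_noise_conductance(rep(1000, 2000), u, 10000, seed = 8)
  expect_false(identical(a, c2))
  expect_true(all(a >= 0))
})

test_that("shot-noise moments agree with the Campbell-theorem oracle", {
  u <- unitary_event(0.27, 2)
  fs <- 10000
  pred <- campbell_moments(2000, u, -60)
  reps <- 40
  ms <- vs <- numeric(reps)
  for (k in seq_len(reps)) {
    i <- shot_noise_conductance(rep(2000, fs), u, fs, seed = 500 + k) * -60
    ms[k] <- mean(i)
    vs[k] <- stats::var(i)
  }
  expect_lt(abs(mean(ms) - pred$mean_pa), 3 * stats::sd(ms) / sqrt(reps))
  expect_lt(abs(mean(vs) - pred$variance_pa2), 3 * stats::sd(vs) / sqrt(reps))
})

test_that("drug conditions are factor maps with occlusion", {
  spec <- synaptic_drive_spec()

  ctrl <- apply_condition(spec, "control")
  expect_equal(ctrl$tonic_exc, spec$tonic_exc)
  expect_equal(ctrl$transient_exc, spec$transient_exc)
  expect_equal(ctrl$nmda_scale, spec$nmda_scale)

  ap5 <- apply_condition(spec, "AP5")
  expect_equal(ap5$nmda_scale, 0)
  expect_equal(ap5$tonic_exc, spec$tonic_exc)

  # IEM and MFA both zero the tonic component: composing them equals either
  iem <- apply_condition(spec, "IEM")
  both <- apply_condition(iem, "MFA")
  expect_equal(both$tonic_exc$unitary$amplitude_ns,
               iem$tonic_exc$unitary$amplitude_ns)
  expect_equal(both$transient_exc, iem$transient_exc)

  expect_error(apply_condition(spec, "unknown-drug"), "not defined")
})

test_that("build_synaptic_drive composes components under conditions", {
  fs <- 5000
  stim <- make_stimulus(midget_stimulus(duration = 1.5, phase_zero = 0.3), fs)
  spec <- synaptic_drive_spec()

  d_iem <- build_synaptic_drive(spec, stim, "IEM", seed = 3)
  expect_equal(d_iem$truth$g_tonic, rep(0, length(stim)))
  expect_gt(max(d_iem$truth$g_transient), 0)

  # control construction is condition-independent plumbing for same seed
  d_ctrl <- build_synaptic_drive(spec, stim, "control", seed = 3)
  expect_gt(max(d_ctrl$truth$g_tonic), 0)
  expect_equal(d_ctrl$truth$g_transient, d_iem$truth$g_transient)

  # Off-phase mean excitation: control exceeds a tonic-suppressed condition
  t <- (seq_along(stim) - 1) / fs
  off <- t >= 0.8 & t < 1.3
  expect_gt(mean(d_ctrl$g_ampa[off]), mean(d_iem$g_ampa[off]))

  # On-phase tonic rate rises, Off-phase falls (multiplicative modulation)
  on <- t >= 0.3 & t < 0.8
  expect_gt(mean(d_ctrl$truth$rate[on]), spec$tonic_exc$base_rate_hz)
  expect_lt(mean(d_ctrl$truth$rate[off]), spec$tonic_exc$base_rate_hz)
})

test_that("voltage-clamp currents follow the ohmic forward model", {
  fs <- 1000
  cell <- cell_model(g_leak_nS = 0)
  zero <- conductance_drive(rep(0, 100), 0, 0, fs)
  for (v in c(-110, -60, 50)) {
    expect_equal(simulate_voltage_clamp(cell, zero, v)$signal, rep(0, 100))
  }
  # constant G_exc = 1 nS at -60 mV: -60 pA
  dr <- conductance_drive(rep(1, 100), 0, 0, fs)
  expect_equal(simulate_voltage_clamp(cell, dr, -60)$signal, rep(-60, 100))
  # G_inh at its reversal contributes nothing
  dri <- conductance_drive(rep(0, 100), 0, rep(1, 100), fs)
  expect_equal(simulate_voltage_clamp(cell, dri, -70)$signal, rep(0, 100))
  # linearity in each conductance trace
  g <- abs(rnorm(100))
  i1 <- simulate_voltage_clamp(cell, conductance_drive(g, 0, 0, fs), -80)$signal
  i2 <- simulate_voltage_clamp(cell, conductance_drive(2 * g, 0, 0, fs),
                               -80)$signal
  expect_equal(i2, 2 * i1)
  # NMDA component vanishes at E_exc and is attenuated by the Mg block
  drn <- conductance_drive(rep(0, 100), rep(1, 100), 0, fs)
  expect_equal(simulate_voltage_clamp(cell, drn, 0)$signal, rep(0, 100))
  i_n <- simulate_voltage_clamp(cell, drn, -80)$signal[1]
  expect_equal(i_n, mg_block(-80) * -80)
  expect_lt(abs(i_n), 80)  # block strong at hyperpolarised potentials
  # mismatched grids are a shape error
  bad <- conductance_drive(rep(0, 100), 0, 0, fs)
  bad$g_inh <- rep(0, 50)
  expect_error(simulate_voltage_clamp(cell, bad, -60), "grid")
})

test_that("current-clamp LIF dynamics match closed-form expectations", {
  fs <- 20000
  cell <- cell_model()
  n <- fs  # 1 s

  # zero drive: relaxation to E_leak, no spikes
  sw0 <- simulate_current_clamp(cell, conductance_drive(rep(0, n), 0, 0, fs),
                                v0 = -55)
  expect_length(attr(sw0, "spike_times"), 0)
  expect_equal(tail(sw0$signal, 1), cell$e_leak_mV, tolerance = 1e-6)

  # constant suprathreshold excitation: rate matches the closed-form
  # LIF interspike interval within 2%
  g_exc <- 3
  sw <- simulate_current_clamp(cell,
                               conductance_drive(rep(g_exc, n), 0, 0, fs))
  st <- attr(sw, "spike_times")
  expect_gt(length(st), 20)
  isi_sim <- stats::median(diff(st)) * 1000  # ms
  g_tot <- cell$g_leak_nS + g_exc
  v_inf <- (cell$g_leak_nS * cell$e_leak_mV + g_exc * cell$e_exc_mV) / g_tot
  tau <- cell$capacitance_pF / g_tot
  isi_theory <- cell$spike$refractory_ms +
    tau * log((v_inf - cell$spike$reset_mV) / (v_inf - cell$spike$threshold_mV))
  expect_lt(abs(isi_sim - isi_theory) / isi_theory, 0.02)

  # too-coarse time step is a stability error
  expect_error(
    simulate_current_clamp(cell, conductance_drive(rep(3, 100), 0, 0, 100)),
    "too coarse")
})

test_that("raising drive variance at fixed mean raises near-threshold rates", {
  fs <- 10000
  n <- fs * 2
  # fixed mean conductance nu * A * tau = 1.3 nS, near-threshold
  cfgs <- list(small = c(a = 0.1, nu = 6500), large = c(a = 0.5, nu = 1300))
  counts <- vapply(names(cfgs), function(nm) {
    a <- cfgs[[nm]]["a"]; nu <- cfgs[[nm]]["nu"]
    total <- 0
    for (s in 1:5) {
      g <- shot_noise_conductance(rep(nu, n), unitary_event(a, 2), fs,
                                  seed = 40 + s)
      sw <- simulate_current_clamp(cell_model(), conductance_drive(g, 0, 0, fs))
      total <- total + length(attr(sw, "spike_times"))
    }
    total
  }, numeric(1))
  expect_gt(counts["large"], counts["small"])
})
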