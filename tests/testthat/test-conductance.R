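test_that("net light-evoked currents subtract baseline per potential", {
  fs <- 1000
  # constant sweeps: all-zero net trace
  const <- lapply(1:3, function(k) {
    sweep_record("c", "voltage_clamp", fs, rep(-120, 800), -60,
                 trial_index = k)
  })
  net <- net_light_evoked(const, baseline_window = c(0, 0.3))
  expect_equal(net$current, rep(0, 800))
  expect_equal(net$v_hold, -60)
  expect_equal(net$n_sweeps, 3L)

  # forward model: a conductance step G appears as G * (V - E) in the net
  cell <- cell_model(g_leak_nS = 2)
  g <- c(rep(0, 400), rep(1.5, 400))
  dr <- conductance_drive(g, 0, 0, fs)
  sw <- simulate_voltage_clamp(cell, dr, -60)
  net2 <- net_light_evoked(list(sw), baseline_window = c(0, 0.3))
  expect_equal(net2$current, g * (-60 - 0), tolerance = 1e-12)

  # averaging is linear: net of two trials = mean of individual nets
  s1 <- sweep_record("c", "voltage_clamp", fs, rnorm(800), -60)
  s2 <- sweep_record("c", "voltage_clamp", fs, rnorm(800), -60,
                     trial_index = 1L)
  n12 <- net_light_evoked(list(s1, s2))$current
  n1 <- net_light_evoked(list(s1))$current
  n2 <- net_light_evoked(list(s2))$current
  expect_equal(n12, (n1 + n2) / 2, tolerance = 1e-12)

  # heterogeneous holding potentials are rejected
  s3 <- sweep_record("c", "voltage_clamp", fs, rnorm(800), -80)
  expect_error(net_light_evoked(list(s1, s3)), "multiple holding potentials")
})

test_that("I-V series binning is exact for linear currents", {
  fs <- 1000
  mk_net <- function(v, cur) {
    structure(list(current = cur, v_hold = v, sampling_rate = fs,
                   n_sweeps = 1L, baseline_window = c(0, 0.1)),
              class = "net_current")
  }
  # 9 potentials spanning -110..+50 give 9 points per bin
  pots <- seq(-110, 50, by = 20)
  nets <- lapply(pots, function(v) mk_net(v, rep(v / 10, 500)))
  iv <- build_iv_series(nets, bin_ms = 10)
  expect_equal(length(iv$potentials), 9)
  expect_equal(dim(iv$currents), c(50, 9))
  expect_equal(iv$currents[1, ], pots / 10)

  # bin average of a linear-in-time current equals its midpoint value
  t <- (0:499) / fs
  lin <- mk_net(-60, 100 * t)
  iv2 <- build_iv_series(list(lin, mk_net(0, rep(0, 500))), bin_ms = 10)
  expect_equal(iv2$currents[, 1], 100 * (iv2$time_ms - 0.5) / 1000,
               tolerance = 1e-12)

  expect_error(build_iv_series(list(mk_net(-60, rep(0, 500)))), ">= 2")
})

test_that("linear I-V fits recover conductance and reversal", {
  # generative ground truth: G = 4.4 nS, E_rev = +0.9 mV at -95..+65 mV
  v <- seq(-95, 65, by = 20)
  i <- 4.4 * (v - 0.9)
  fit <- fit_linear_iv(v, i)
  expect_equal(fit$conductance_ns, 4.4, tolerance = 1e-10)
  expect_equal(fit$reversal_mv, 0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  # flat zero line: zero conductance, reversal undefined but flagged
  flat <- fit_linear_iv(c(-60, 0), c(0, 0))
  expect_equal(flat$conductance_ns, 0)
  expect_true(is.nan(flat$reversal_mv))
  expect_true(flat$degenerate)

  expect_error(fit_linear_iv(c(-60, -60), c(0, 1)), "distinct")

  # Monte-Carlo: slope estimator unbiased within 3 SE under 5-pA noise
  set.seed(1234)
  reps <- 1000
  slopes <- vapply(seq_len(reps), function(k) {
    fit_linear_iv(v, i + rnorm(length(v), sd = 5))$conductance_ns
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 4.4), 3 * stats::sd(slopes) / sqrt(reps))
})

test_that("conductance decomposition inverts the forward model", {
  fs <- 1000
  pots <- seq(-110, 50, by = 20)
  n <- 500
  t <- (0:(n - 1)) / fs
  g_exc <- 1 + 0.5 * sin(2 * pi * t)
  g_inh <- 0.5 + 0.3 * cos(2 * pi * t)
  g_nmda <- 0.4 + 0.2 * sin(4 * pi * t)
  cell <- cell_model(g_leak_nS = 0)
  nets <- lapply(pots, function(v) {
    sw <- simulate_voltage_clamp(cell,
                                 conductance_drive(g_exc, g_nmda, g_inh, fs),
                                 v)
    structure(list(current = sw$signal, v_hold = v, sampling_rate = fs,
                   n_sweeps = 1L, baseline_window = c(0, 0)),
              class = "net_current")
  })
  iv <- build_iv_series(nets, 10)
  dec <- decompose_conductances(iv, nmda = TRUE)
  bin_mean <- function(x) {
    as.numeric(tapply(x, rep(seq_len(50), each = 10), mean))
  }
  expect_lt(max(abs(dec$g_exc_ns - bin_mean(g_exc))), 1e-8)
  expect_lt(max(abs(dec$g_inh_ns - bin_mean(g_inh))), 1e-8)
  expect_lt(max(abs(dec$g_nmda_ns - bin_mean(g_nmda))), 1e-8)
  expect_true(all(dec$rmse_pa < 1e-8))
  expect_s3_class(attr(dec, "mg"), "mg_block_params")

  # all-zero currents give all-zero conductances
  iv0 <- iv
  iv0$currents[] <- 0
  dec0 <- decompose_conductances(iv0)
  expect_equal(dec0$g_exc_ns, rep(0, 50))
  expect_equal(dec0$g_nmda_ns, rep(0, 50))

  # equivariance: scaling all currents by c scales all conductances by c
  iv3 <- iv
  iv3$currents <- 3 * iv$currents
  dec3 <- decompose_conductances(iv3, nmda = TRUE)
  expect_equal(dec3$g_exc_ns, 3 * dec$g_exc_ns, tolerance = 1e-9)
  expect_equal(dec3$g_nmda_ns, 3 * dec$g_nmda_ns, tolerance = 1e-9)

  # reconstruction at supplied potentials reproduces the inputs at full rank
  for (v in c(-110, -30, 50)) {
    expect_equal(reconstruct_currents(dec, v),
                 iv$currents[, which(pots == v)], tolerance = 1e-8)
  }
  # at E_inh the inhibitory component contributes nothing
  dec_inh_only <- dec
  dec_inh_only$g_exc_ns[] <- 0
  dec_inh_only$g_nmda_ns[] <- 0
  expect_equal(reconstruct_currents(dec_inh_only, -70), rep(0, 50))
})

test_that("two-potential linear decomposition matches the closed form", {
  # with G_nmda fixed at 0 and two potentials the per-bin solution is the
  # 2x2 solve: I1 = Ge V1 + Gi (V1+70); I2 = Ge V2 + Gi (V2+70)
  fs <- 1000
  v <- c(-90, -30)
  ge_true <- 0.8
  gi_true <- 1.7
  cur <- vapply(v, function(vv) {
    rep(ge_true * vv + gi_true * (vv + 70), 100)
  }, numeric(100))
  mk_net <- function(k) structure(
    list(current = cur[, k], v_hold = v[k], sampling_rate = fs,
         n_sweeps = 1L, baseline_window = c(0, 0.1)), class = "net_current")
  iv <- build_iv_series(list(mk_net(1), mk_net(2)), 10)
  dec <- decompose_conductances(iv, nmda = FALSE)
  a <- matrix(c(v[1], v[1] + 70, v[2], v[2] + 70), 2, byrow = TRUE)
  closed <- solve(a, c(cur[1, 1], cur[1, 2]))
  expect_equal(dec$g_exc_ns[1], closed[1], tolerance = 1e-10)
  expect_equal(dec$g_inh_ns[1], closed[2], tolerance = 1e-10)
  expect_equal(dec$g_nmda_ns, rep(0, 10))
})

test_that("difference conductances isolate a blocked component", {
  fs <- 2000
  stim <- make_stimulus(midget_stimulus(duration = 1.5, phase_zero = 0.3), fs)
  spec <- synaptic_drive_spec()
  cell <- cell_model()
  pots <- seq(-110, 50, by = 40)
  iv_for <- function(cond) {
    nets <- lapply(pots, function(v) {
      sweeps <- lapply(1:4, function(k) {
        dr <- build_synaptic_drive(spec, stim, cond, seed = 600 + k)
        simulate_voltage_clamp(cell, dr, v, trial_index = k)
      })
      net_light_evoked(sweeps, baseline_window = c(0, 0.3))
    })
    build_iv_series(nets, 10)
  }
  dec_c <- decompose_conductances(iv_for("control"))
  dec_d <- decompose_conductances(iv_for("IEM"))
  diff_cd <- difference_conductance(dec_c, dec_d)

  # anti-symmetry and self-difference
  diff_dc <- difference_conductance(dec_d, dec_c)
  expect_equal(diff_cd$g_exc_ns, -diff_dc$g_exc_ns)
  self <- difference_conductance(dec_c, dec_c)
  expect_equal(self$g_exc_ns, rep(0, nrow(dec_c)))

  # the difference approximates the net tonic component suppressed by the
  # drug (baseline-subtracted, so Off-phase suppression shows as negative)
  dr <- build_synaptic_drive(spec, stim, "control", seed = 600)
  env <- dr$truth$tonic_env
  nb <- nrow(dec_c)
  tonic_net <- as.numeric(tapply(env[1:(nb * 20)], rep(1:nb, each = 20),
                                 mean)) - mean(env[1:(0.3 * fs)])
  expect_gt(stats::cor(diff_cd$g_exc_ns, tonic_net), 0.95)

  # grid mismatch is a shape error
  short <- dec_c[1:10, ]
  attr(short, "mg") <- attr(dec_c, "mg")
  class(short) <- class(dec_c)
  expect_error(difference_conductance(dec_c, short), "time grids")
})

test_that("time-course similarity recovers scale factors", {
  set.seed(77)
  b <- sin(seq(0, 3 * pi, length.out = 200)) + 1.2
  s <- timecourse_similarity(4 * b, b)
  expect_equal(s$scale, 4)
  expect_equal(s$correlation, 1)

  # orthogonal traces: zero scale
  x <- c(1, -1, 1, -1)
  y <- c(1, 1, 1, 1)
  expect_equal(timecourse_similarity(x, y)$scale, 0)

  # proportional plus noise: scale within 5% of 4, high correlation
  noisy <- 4 * b + rnorm(200, sd = 0.1)
  sn <- timecourse_similarity(noisy, b)
  expect_lt(abs(sn$scale - 4) / 4, 0.05)
  expect_gt(sn$correlation, 0.95)

  # common rescaling leaves the scale unchanged
  s2 <- timecourse_similarity(2.5 * noisy, 2.5 * b)
  expect_equal(s2$scale, sn$scale, tolerance = 1e-12)

  # identically-zero denominator trace is flagged
  z <- timecourse_similarity(b, rep(0, 200))
  expect_true(z$degenerate)
  expect_true(is.na(z$scale))
})
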