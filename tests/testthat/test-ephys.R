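# Feature extractors: parameter recovery on constructed traces and
# end-to-end checks against closed forms.

test_that("input resistance and capacitance recover the cell's constants", {
  area <- 5000
  m <- passive_model(g_pas = 0.1, e_pas = -80)
  mesh <- build_mesh(ball_area(area), m$passive)
  vc <- function(level) {
    pr <- protocol("voltage_clamp", holding = -80, pre = 150,
                   steps = data.frame(onset = 0, duration = 200,
                                      amplitude = level),
                   duration = 250, dt = 0.01)
    run_voltage_clamp(mesh, m, pr)
  }
  R_true <- 1e-6 / (0.1e-3 * area * 1e-8)
  expect_equal(input_resistance(vc(-70)), R_true, tolerance = 0.005)
  expect_equal(capacitance(vc(-90)), area * 1e-8 * 1e6, tolerance = 0.02)

  # doubling the area doubles the capacitance
  mesh2 <- build_mesh(ball_area(2 * area), m$passive)
  pr <- protocol("voltage_clamp", holding = -80, pre = 150,
                 steps = data.frame(onset = 0, duration = 200,
                                    amplitude = -90), duration = 250,
                 dt = 0.01)
  c2 <- capacitance(run_voltage_clamp(mesh2, m, pr))
  expect_equal(c2 / capacitance(vc(-90)), 2, tolerance = 0.01)

  # flat current: zero capacitance; zero step: unbounded resistance error
  t <- seq(-50, 200, by = 0.1)
  flat <- fake_vc_result(t, rep(0.5, length(t)), 0, 200, -90, -80)
  expect_equal(capacitance(flat), 0, tolerance = 1e-9)
  same <- fake_vc_result(t, rep(0.5, length(t)), 0, 200, -80, -80)
  expect_error(input_resistance(same), class = "ephys_zero_current")
})

test_that("membrane tau is recovered from planted decays", {
  t <- seq(0, 400, by = 0.1)
  v <- -90 + 10 * exp(-t / 25)
  expect_equal(membrane_tau(t, v, onset = 0, duration = 400), 25,
               tolerance = 0.001)
  # fast equalization + slow component: the slow tau is returned
  v2 <- -90 + 3 * exp(-t / 1) + 10 * exp(-t / 30)
  expect_equal(membrane_tau(t, v2, onset = 0, duration = 400), 30,
               tolerance = 0.03)
  expect_error(membrane_tau(t, rep(-80, length(t))),
               class = "ephys_tau_flat")
})

gaussian_spike <- function(sigma = 0.4, peak = 40, base = -75,
                           dt = 0.005, t0 = 20) {
  t <- seq(0, 40, by = dt)
  v <- base + (peak - base) * exp(-((t - t0) / sigma)^2 / 2)
  list(t = t, v = v)
}

test_that("AP features follow their definitions on crafted spikes", {
  # triangle spike: threshold is the first sample with dV/dt > 15 mV/ms
  dt <- 0.1
  t <- seq(0, 30, by = dt)
  v <- rep(-70, length(t))
  up <- t >= 10 & t <= 12                  # 50 mV/ms upstroke
  v[up] <- -70 + (t[up] - 10) * 50
  dn <- t > 12 & t <= 14
  v[dn] <- 30 - (t[dn] - 12) * 50
  f <- ap_features(t, v)
  expect_equal(f$amplitude + f$V_threshold, f$peak, tolerance = 1e-12)
  expect_lte(abs(f$t_threshold - 10), 2 * dt)

  # peak 50, threshold -45 -> amplitude 95 (constructed via shift)
  g <- gaussian_spike(peak = 50)
  fg <- ap_features(g$t, g$v)
  expect_equal(fg$amplitude, fg$peak - fg$V_threshold)

  # Gaussian spike: half-amplitude width ~ 2 sigma sqrt(2 ln 2); the
  # measured width is referenced to (peak+threshold)/2, slightly narrower
  sig <- 0.5
  gs <- gaussian_spike(sigma = sig, dt = 0.002)
  w <- ap_features(gs$t, gs$v)$width
  expect_lt(abs(w - 2 * sig * sqrt(2 * log(2))) / (2 * sig * sqrt(2 * log(2))),
            0.2)
  expect_error(ap_features(gs$t, rep(-70, length(gs$t))),
               class = "ephys_no_spike")
})

test_that("feature extractors are shift- and resampling-invariant", {
  gs <- gaussian_spike(sigma = 0.5, dt = 0.002)
  f0 <- ap_features(gs$t, gs$v)
  f1 <- ap_features(gs$t + 137.5, gs$v)
  expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)
  expect_equal(f1$width, f0$width, tolerance = 1e-9)
  # 2x resampling
  idx <- seq(1, length(gs$t), by = 2)
  f2 <- ap_features(gs$t[idx], gs$v[idx])
  expect_equal(f2$width, f0$width, tolerance = 0.02)

  t <- seq(0, 400, by = 0.1)
  v <- -90 + 10 * exp(-t / 25)
  expect_equal(membrane_tau(t + 55, v, onset = 55, duration = 400), 25,
               tolerance = 0.001)
})

two_spike_trace <- function(min_delay, vmin = -60) {
  # piecewise-linear trace: spike at t = 10..11 (peak 45 mV), inter-spike
  # minimum vmin at t = 10 + min_delay, second spike, return to rest
  # slow depolarizing ramp to a -48 mV threshold, fast upstroke, so the
  # detected threshold sits well above the inter-spike minimum
  tmin <- 10 + min_delay
  knots_t <- c(0, 5, 10, 11, tmin, tmin + 2, tmin + 3, 60)
  knots_v <- c(-80, -80, -48, 45, vmin, 45, -80, -80)
  t <- seq(0, 60, by = 0.05)
  list(t = t, v = approx(knots_t, knots_v, t)$y)
}

test_that("fAHP applies the 5 ms timing rule", {
  tr <- two_spike_trace(3)
  f <- ap_features(tr$t, tr$v)
  val <- fahp(tr$t, tr$v)
  expect_false(is.na(val))
  expect_equal(val, f$V_threshold - (-60), tolerance = 1e-9)
  # same minimum at 7 ms: a medium AHP, reported absent
  tr7 <- two_spike_trace(7)
  expect_true(is.na(fahp(tr7$t, tr7$v)))
  # inter-spike segment that never dips below threshold: absent
  trx <- two_spike_trace(3, vmin = -30)
  expect_true(is.na(fahp(trx$t, trx$v)))
})

test_that("rheobase respects grid semantics", {
  expect_equal(rheobase(function(a) as.integer(a >= 43)), 45)
  expect_equal(rheobase(function(a) 1L), 5)
  out <- rheobase(function(a) 0L, i_max = 50)
  expect_true(is.na(out))
  expect_identical(attr(out, "flag"), "no_spike")
  expect_error(rheobase(function(a) 1L, grid_step = 0),
               class = "ephys_bad_grid")
})

test_that("ISI features follow their definitions", {
  f <- isi_features(c(0, 10, 30))
  expect_equal(f$first_isi, 10)
  expect_equal(f$adaptation_ratio, 0.5)
  expect_equal(isi_features(c(0, 10, 20, 30))$adaptation_ratio, 0)
  f2 <- isi_features(c(0, 12))
  expect_equal(f2$first_isi, 12)
  expect_true(is.na(f2$adaptation_ratio))
})

test_that("Kir slope conductance is recovered from a constructed I-V", {
  v <- seq(-155, -60, by = 2.5)
  gl <- 2e-3; gk <- 5.5e-3                        # uS
  b <- function(v) 1 / (1 + exp((v + 100) / 5))   # steep closed-by--80 gate
  i <- gl * (v + 80) + gk * b(v) * (v + 90)       # nA
  iv <- data.frame(command_mV = v, current_nA = i)
  expect_equal(gkir_from_iv(iv), 5.5, tolerance = 0.05)
  # purely linear I-V: zero
  iv0 <- data.frame(command_mV = v, current_nA = gl * (v + 80))
  expect_lt(abs(gkir_from_iv(iv0)), 1e-9)
  # window not covered
  expect_error(gkir_from_iv(iv[iv$command_mV > -150, ]),
               class = "ephys_window_not_covered")
})

test_that("calcium transient features recover planted decays", {
  t <- seq(0, 1500, by = 1)
  y <- 0.05 + 0.7 * exp(-t / 50) + 0.3 * exp(-t / 300)
  f <- ca_transient_features(t, y)
  expect_equal(f$peak, 1.0, tolerance = 0.01)
  expect_equal(f$weighted_tau, 125, tolerance = 0.02 * 125)
  f2 <- ca_transient_features(t, 0.05 + exp(-t / 120))
  expect_equal(f2$weighted_tau, 120, tolerance = 0.02 * 120)
  expect_error(ca_transient_features(t, rep(0.05, length(t))),
               class = "ephys_ca_flat")
})

test_that("input/output ratio is a plain count ratio", {
  expect_equal(io_ratio(8, 8), 1)
  expect_equal(io_ratio(0, 8), 0)
  expect_equal(io_ratio(4, 8), 0.5)
  expect_error(io_ratio(1, 0), class = "ephys_zero_inputs")
})
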