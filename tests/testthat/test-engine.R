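# Mesh construction and the implicit cable integrator: conservation,
# closed-form checks, clamps, temperature scaling and determinism.

test_that("mesh areas are conserved and axial conductance is exact", {
  tr <- cylinder_tree(radius = 1, length = 100, step = 10)
  pas <- passive_spec(ra = 200, cm = 1)
  areas <- vapply(c(100, 25, 5), function(ms)
    sum(build_mesh(tr, pas, max_seg_um = ms)$comp$area_cm2), 0)
  expect_equal(areas[1], 2 * pi * 1e-4 * 100e-4, tolerance = 1e-12)
  expect_equal(max(areas) - min(areas), 0, tolerance = 1e-15)

  # end-to-end axial conductance of the uniform cylinder: pi r^2/(Ra L)
  m1 <- build_mesh(tr, pas, max_seg_um = 100)   # single compartment
  g_end <- 1 / (m1$comp$r_prox[1] + m1$comp$r_dist[1])   # S
  expect_equal(g_end, pi * (1e-4)^2 / (200 * 100e-4), tolerance = 1e-9)
})

test_that("sealed passive cable converges to Rall's input resistance", {
  r_um <- 1; L_um <- 1000; g_pas <- 0.04; ra <- 150
  tr <- cylinder_tree(radius = r_um, length = L_um, step = 5)
  m <- passive_model(g_pas = g_pas, e_pas = -80,
                     passive = passive_spec(ra = ra, cm = 1))
  lam <- sqrt((r_um * 1e-4) * (1 / (g_pas * 1e-3)) / (2 * ra))   # cm
  rin_theory <- ra * lam / (pi * (r_um * 1e-4)^2) / tanh(L_um * 1e-4 / lam)
  rins <- vapply(c(10, 5), function(ms) {
    mesh <- build_mesh(tr, m$passive, max_seg_um = ms)
    pr <- protocol("current_clamp", holding = NULL,
                   steps = data.frame(onset = 0, duration = 600,
                                      amplitude = 10),
                   duration = 650, record = 1, dt = 0.025)
    res <- run_current_clamp(mesh, m, pr)
    (mean(res$v[res$time > 550 & res$time < 600, 1]) + 80) / 0.01
  }, 0)
  expect_lt(abs(rins[2] - rin_theory / 1e6) / (rin_theory / 1e6), 0.005)
  # refinement changes the answer by well under half a percent
  expect_lt(abs(rins[2] - rins[1]) / rins[2], 0.005)
})

test_that("equilibrium and mirror symmetry are preserved exactly", {
  m <- passive_model(g_pas = 0.05, e_pas = -70)
  mesh <- build_mesh(ball_and_stick_tree(), m$passive)
  v <- step_state(mesh, m, v = -70, dt = 0.025, n = 200)
  expect_equal(max(abs(v + 70)), 0, tolerance = 1e-12)

  # symmetric Y under somatic stimulus: mirror sites stay equal
  ytr <- y_tree(stem = 50, arm = 60, step = 10)
  tipA <- ytr$nodes$id[which.max(ytr$nodes$x)]
  tipB <- ytr$nodes$id[which.min(ytr$nodes$x)]
  mesh2 <- build_mesh(ytr, m$passive)
  pr <- protocol("current_clamp", holding = NULL,
                 steps = data.frame(onset = 5, duration = 50, amplitude = 50),
                 duration = 80, record = c(tipA, tipB), dt = 0.025)
  res <- run_current_clamp(mesh2, m, pr)
  expect_equal(res$v[, 1], res$v[, 2], tolerance = 1e-12)
})

test_that("single-compartment RC charging matches the closed form", {
  area <- 5000
  m <- passive_model(g_pas = 0.1, e_pas = -80)
  mesh <- build_mesh(ball_area(area), m$passive)
  gA <- 0.1e-3 * area * 1e-8            # S
  R_mohm <- 1e-6 / gA
  tau <- 1e3 * 1e-6 * area * 1e-8 / gA  # ms (cm = 1 uF/cm2)
  pr <- protocol("current_clamp", holding = NULL,
                 steps = data.frame(onset = 0, duration = 100,
                                    amplitude = 10),
                 duration = 120, dt = 0.01)
  res <- run_current_clamp(mesh, m, pr)
  sel <- res$time >= 0 & res$time <= 100
  vclosed <- -80 + 0.01 * R_mohm * (1 - exp(-res$time[sel] / tau))
  expect_lt(max(abs(res$v[sel, 1] - vclosed)) * 1000, 10)   # < 10 uV
  # steady state is I * R_in exactly (linear system)
  expect_equal(max(vclosed) + 80, 0.01 * R_mohm, tolerance = 1e-3)
})

test_that("active spike counts match the adaptive ODE oracle", {
  area <- 1000
  hh <- hh_model()
  mesh <- build_mesh(ball_area(area), hh$passive)
  for (amp in c(20, 60, 120)) {
    pr <- protocol("current_clamp", holding = NULL,
                   steps = data.frame(onset = 10, duration = 200,
                                      amplitude = amp),
                   duration = 250, dt = 0.01)
    res <- run_current_clamp(mesh, hh, pr)
    orc <- hh_oracle_trace(area, amp)
    n_orc <- length(detect_spikes(orc$t, orc$v))
    expect_equal(length(res$spikes), n_orc)
  }
  # zero amplitude never spikes
  pr0 <- protocol("current_clamp", holding = NULL,
                  steps = data.frame(onset = 10, duration = 200,
                                     amplitude = 0), duration = 250)
  expect_length(run_current_clamp(mesh, hh, pr0)$spikes, 0)
})

test_that("ideal voltage clamp obeys Ohm and conserves charge", {
  area <- 5000
  m <- passive_model(g_pas = 0.1, e_pas = -80)
  mesh <- build_mesh(ball_area(area), m$passive)
  gA_us <- 0.1e-3 * area * 1e-8 * 1e6   # uS
  pr <- protocol("voltage_clamp", holding = -80, pre = 100,
                 steps = data.frame(onset = 0, duration = 100,
                                    amplitude = -70),
                 duration = 150, dt = 0.01)
  res <- run_voltage_clamp(mesh, m, pr)
  iss <- mean(res$ielec[res$time > 80 & res$time < 100])
  expect_equal(iss, gA_us * 10, tolerance = 1e-5)   # g A * 10 mV, nA

  # command = E -> zero steady current
  prE <- protocol("voltage_clamp", holding = -80, pre = 100,
                  steps = data.frame(onset = 0, duration = 100,
                                     amplitude = -80),
                  duration = 150, dt = 0.01)
  resE <- run_voltage_clamp(mesh, m, prE)
  expect_lt(abs(mean(resE$ielec[resE$time > 80])), 1e-9)

  # clamp-transient charge equals C dV within 2%
  win <- res$time >= 0 & res$time < 100
  y <- res$ielec[win] - iss
  q <- sum(diff(res$time[win]) * (y[-1] + y[-length(y)]) / 2)   # nA ms = pC
  c_pC <- area * 1e-8 * 1e6 * 1e-3 * 10   # C (nF) * 10 mV -> pC
  expect_equal(q, c_pC, tolerance = 0.02)
})

test_that("temperature rescaling follows the Q10 convention", {
  hh <- hh_model()
  expect_identical(set_temperature(hh, hh$temperature), hh)
  expect_error(set_temperature(hh, 60), class = "engine_bad_temperature")
  g <- hh$channels$na$gates[[1]]
  expect_equal(gcell:::gate_tau(g, -50, g$tref + 10),
               gcell:::gate_tau(g, -50, g$tref) / g$q10)
  # passive input resistance is temperature-independent (no conductance Q10)
  m <- passive_model()
  mesh <- build_mesh(ball_area(2000), m$passive)
  rin <- function(mod) {
    pr <- protocol("voltage_clamp", holding = -80, pre = 100,
                   steps = data.frame(onset = 0, duration = 100,
                                      amplitude = -70), duration = 150)
    input_resistance(run_voltage_clamp(mesh, mod, pr))
  }
  expect_equal(rin(m), rin(set_temperature(m, 34)), tolerance = 1e-10)
})

test_that("simulation results are bit-identical across repeated runs", {
  fx <- gc_fix()
  pr <- protocol("current_clamp", holding = -80,
                 steps = data.frame(onset = 0, duration = 100,
                                    amplitude = 60), duration = 150)
  r1 <- run_current_clamp(fx$mesh, fx$model, pr)
  r2 <- run_current_clamp(fx$mesh, fx$model, pr)
  expect_identical(r1$v, r2$v)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("halving dt leaves the subthreshold GC trace within 0.1 mV", {
  fx <- gc_fix()
  tr <- function(dt) {
    pr <- protocol("current_clamp", holding = -80,
                   steps = data.frame(onset = 0, duration = 100,
                                      amplitude = 20),
                   duration = 150, dt = dt)
    run_current_clamp(fx$mesh, fx$model, pr)
  }
  a <- tr(0.025); b <- tr(0.0125)
  vb <- b$v[match(round(a$time, 6), round(b$time, 6)), 1]
  expect_lt(max(abs(a$v[, 1] - vb), na.rm = TRUE), 0.1)
})

test_that("divergence raises a classed error with a time stamp", {
  # the implicit solve is stable for any physical input, so force an
  # overflow through a pathological injected current
  m <- passive_model()
  mesh <- build_mesh(ball_area(1000), m$passive)
  ic <- list(comp = 0L, steps = matrix(0, 0, 3), bias = 1e308)
  err <- tryCatch(
    gcell:::run_core(mesh, m, duration = 1, dt = 0.025, v0 = -80,
                     iclamp = ic),
    error = function(e) e)
  expect_s3_class(err, "engine_diverged")
  expect_match(conditionMessage(err), "t = ")
})
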