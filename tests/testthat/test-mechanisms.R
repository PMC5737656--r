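# Channel currents, gate and Markov integrators, calcium dynamics, synapses,
# spike sources, variants and the model config schema.

test_that("channel currents follow the ohmic form with table densities", {
  model <- granule_cell_model()
  k2p <- model$channels$K2P
  # K2P soma density 0.014 mS/cm2, 1e4 um2, 10 mV driving force
  i <- channel_current(k2p, v = -80, area_um2 = 1e4, region = "soma",
                       reversals = model$reversals)
  expect_equal(i, 0.014e-3 * 1e-4 * 10 * 1e6, tolerance = 1e-12)  # 0.014 nA
  # open fraction zero -> zero current
  nav <- model$channels$Nav
  expect_equal(channel_current(nav, v = 0, state = c(0, 1), area_um2 = 1e4),
               0)
  # at the reversal potential every current vanishes
  expect_equal(channel_current(nav, v = model$reversals$Na,
                               state = c(0.5, 0.5), area_um2 = 1e4), 0)
})

test_that("exponential-Euler gate updates are exact at fixed voltage", {
  g <- hh_gate(1, "inftau", vhalf = -40, k = 8,
               tau = list(amp = 5, mean = -50, sd = 25, base = 1))
  xinf <- gcell:::gate_inf(g, -30)
  expect_equal(gate_update_exact(g, 0.2, -30, dt = 1e6), xinf,
               tolerance = 1e-12)
  expect_equal(gate_update_exact(g, 0.2, -30, dt = 0), 0.2)
  # q10: tau at Tref+10 is tau at Tref divided by q10, exactly
  expect_equal(gcell:::gate_tau(g, -50, temperature = g$tref + 10),
               gcell:::gate_tau(g, -50, temperature = g$tref) / g$q10,
               tolerance = 1e-14)
})

test_that("gate trajectories match an adaptive ODE oracle under a V step", {
  g <- hh_gate(1, "alphabeta",
               alpha = rate_fn("exp", a = 0.2, v0 = -40, k = 20),
               beta = rate_fn("sigmoid", a = 1.5, v0 = -30, k = 12))
  # piecewise-constant voltage protocol
  vs <- c(-80, -20, -60)
  seg <- 20   # ms per segment
  dt <- 0.05
  x <- gcell:::gate_inf(g, vs[1])
  traj <- x
  for (v in vs) for (i in seq_len(seg / dt)) {
    x <- gate_update_exact(g, x, v, dt)
    traj <- c(traj, x)
  }
  rhs <- function(t, y, p) {
    v <- vs[pmin(length(vs), floor(t / seg) + 1)]
    a <- gcell:::eval_rate(g$alpha, v); b <- gcell:::eval_rate(g$beta, v)
    list(a * (1 - y) - b * y)
  }
  out <- deSolve::lsoda(gcell:::gate_inf(g, vs[1]),
                        seq(0, length(vs) * seg, dt), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(traj - out[, 2])), 1e-6)
})

three_state_scheme <- function() {
  markov_scheme(c("C", "O", "I"),
    list(list(from = "C", to = "O", rate = rate_fn("exp", a = 0.8, v0 = -40, k = 25)),
         list(from = "O", to = "C", rate = rate_fn("exp", a = 0.5, v0 = -40, k = -30)),
         list(from = "O", to = "I", rate = rate_fn("const", a = 0.3)),
         list(from = "I", to = "C", rate = rate_fn("const", a = 0.05))),
    open_states = "O")
}

test_that("Markov propagation matches the matrix exponential and conserves", {
  sc <- three_state_scheme()
  dt <- 0.01; v <- -30
  P <- as.matrix(Matrix::expm(gcell:::markov_q(sc, v) * dt))
  p <- c(1, 0, 0); q <- c(1, 0, 0); err <- 0
  for (i in 1:2000) {
    p <- markov_update(sc, p, v, dt = dt)
    q <- as.numeric(q %*% P)
    err <- max(err, max(abs(p - q)))
  }
  expect_lt(err, 1e-8)
  expect_true(all(p >= 0))

  # detailed balance of a 2-state scheme: open occupancy a/(a+b)
  sc2 <- markov_scheme(c("C", "O"),
    list(list(from = "C", to = "O", rate = rate_fn("const", a = 1)),
         list(from = "O", to = "C", rate = rate_fn("const", a = 3))), "O")
  p2 <- c(1, 0)
  for (i in 1:500) p2 <- markov_update(sc2, p2, 0, dt = 1)
  expect_equal(p2[2], 0.25, tolerance = 1e-10)
  expect_error(markov_update(sc2, c(0.9, 0.4), 0), class = "markov_bad_occupancy")
})

test_that("calcium shell dynamics obey their closed forms", {
  cd <- ca_dynamics(shell_depth = 0.1, kappa = 50, decay_tau = 120,
                    resting_ca = 0.05)
  expect_equal(ca_update(cd, 0.05, 0, 1000, 0.025), 0.05)

  # free decay recovers the planted time constant by log-linear fit
  ca <- 1.05; tt <- seq(0.025, 200, by = 0.025); out <- numeric(length(tt))
  for (i in seq_along(tt)) { ca <- ca_update(cd, ca, 0, 1000, 0.025)
                             out[i] <- ca }
  fitted <- -1 / coef(lm(log(out - 0.05) ~ tt))[[2]]
  expect_equal(fitted, 120, tolerance = 1e-3)

  # constant influx: steady state = resting + influx_rate * tau within 1%
  i_ca <- -0.002   # nA inward
  area <- 1000
  influx <- -i_ca * 1e9 / (2 * gcell:::FARADAY * area * cd$shell_depth * cd$kappa)
  ca <- cd$resting_ca
  for (i in 1:40000) ca <- ca_update(cd, ca, i_ca, area, 0.025)
  expect_equal(ca, cd$resting_ca + influx * cd$decay_tau, tolerance = 0.01)
  # never negative, even under absurd outward current
  expect_gte(ca_update(cd, 0.0001, 100, 10, 10), 0)
})

test_that("synaptic conductance superposes normalized double exponentials", {
  sp <- synapse_spec(rise_tau = 0.5, decay_tau = 5, peak_conductance = 2)
  t <- seq(0, 50, by = 0.001)
  expect_true(all(synapse_conductance(sp, numeric(0), t) == 0))
  g1 <- synapse_conductance(sp, 0, t)
  tp <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal(max(g1), 2, tolerance = 1e-6)
  expect_equal(t[which.max(g1)], tp, tolerance = 1e-2)
  g2 <- synapse_conductance(sp, c(0, 0), t)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  expect_error(synapse_spec(rise_tau = 5, decay_tau = 2),
               class = "synapse_invalid")
})

test_that("Poisson trains are seeded and have the right mean rate", {
  expect_length(poisson_train(0, 1000), 0)
  expect_identical(poisson_train(40, 1000, seed = 4),
                   poisson_train(40, 1000, seed = 4))
  counts <- vapply(1:1000, function(s)
    length(poisson_train(40, 1000, seed = s)), 0L)
  se <- sqrt(40 / 1000)
  expect_lt(abs(mean(counts) - 40), 3 * se)
  expect_error(poisson_train(-1, 100), class = "poisson_negative_rate")
})

test_that("variants scale densities per the published blockades", {
  model <- granule_cell_model()
  vs <- builtin_variants()

  ba <- apply_variant(model, vs$barium)
  expect_equal(ba$channels$Kir2$density[["soma"]], 0.001416, tolerance = 1e-12)
  expect_equal(ba$channels$K2P$density[["soma"]], 0.0098, tolerance = 1e-12)
  # purity: original untouched
  expect_equal(model$channels$Kir2$density[["soma"]], 0.1416)

  ep <- apply_variant(model, vs$epilepsy)
  expect_equal(ep$channels$HCN$density[["IML"]], 0.008, tolerance = 1e-12)
  expect_equal(ep$channels$Kir2$density[["OML"]], 0.2832, tolerance = 1e-12)

  expect_equal(apply_variant(model, vs$kv11_overexpression)$
                 channels$Kv11$density[["AIS"]], 0.75, tolerance = 1e-12)

  yg <- vs$young_abgc
  expect_equal(yg$scale$Kir2, 0.27)
  expect_equal(yg$scale$BK_alphabeta, 0)
  expect_equal(yg$scale$BK_alpha, 0.6)
  expect_equal(yg$scale$Kv14, 1)
  expect_equal(yg$scale$Kv34, 1)
  expect_equal(yg$scale$Nav, 0.75)
  expect_equal(yg$scale$Cav13, 0.5)
  expect_equal(yg$scale$Cav12, 1)
  expect_equal(yg$scale$Kv21, 0.5)
  expect_equal(yg$scale$Kv42, 0.5)
  expect_equal(yg$scale$Kv7, 0.5)

  # composition multiplies factors; disjoint variants commute
  ab <- apply_variant(apply_variant(model, vs$barium), vs$barium)
  expect_equal(ab$channels$Kir2$density[["soma"]], 0.1416 * 1e-4,
               tolerance = 1e-15)
  m1 <- apply_variant(apply_variant(model, vs$epilepsy),
                      vs$kv11_overexpression)
  m2 <- apply_variant(apply_variant(model, vs$kv11_overexpression),
                      vs$epilepsy)
  expect_equal(lapply(m1$channels, `[[`, "density"),
               lapply(m2$channels, `[[`, "density"))

  expect_error(apply_variant(model, model_variant("x", scale = list(Nope = 2))),
               class = "variant_unknown_channel")
  # factor 0 silences the channel's density everywhere
  z <- apply_variant(model, model_variant("z", scale = list(Nav = 0)))
  expect_true(all(z$channels$Nav$density == 0))
})

test_that("model configs round-trip and the schema rejects bad input", {
  model <- granule_cell_model()
  f <- tempfile(fileext = ".yml")
  write_model_config(model, f)
  m2 <- read_model_config(f)
  expect_equal(names(m2$channels), names(model$channels))
  for (ch in names(model$channels))
    expect_equal(m2$channels[[ch]]$density, model$channels[[ch]]$density,
                 tolerance = 1e-12)
  expect_equal(m2$passive$ra, model$passive$ra)

  cfg <- yaml::read_yaml(f)
  cfg$channels$Kv21$density$soma <- -1
  f2 <- tempfile(fileext = ".yml")
  yaml::write_yaml(cfg, f2)
  expect_error(read_model_config(f2), class = "channel_negative_density")

  cfg2 <- yaml::read_yaml(f)
  cfg2$channels$Kv21$density$hilus <- 1
  yaml::write_yaml(cfg2, f2)
  err <- tryCatch(read_model_config(f2), error = function(e) e)
  expect_s3_class(err, "channel_bad_region")
  expect_match(conditionMessage(err), "Kv21")

  cfg3 <- yaml::read_yaml(f)
  cfg3$schema <- "other"
  yaml::write_yaml(cfg3, f2)
  expect_error(read_model_config(f2), class = "config_bad_schema")
})
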