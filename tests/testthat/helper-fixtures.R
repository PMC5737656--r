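# Shared fixtures: cached granule-cell setup (built once per run), fixture
# models on a single spherical compartment, and an independent ODE oracle
# for the squid-type membrane.

.fixture_env <- new.env(parent = emptyenv())

gc_fix <- function() {
  if (is.null(.fixture_env$gc)) {
    tree <- generate_granule_cell(mst_params(seed = 3))
    model <- granule_cell_model()
    mesh <- build_mesh(tree, model$passive)
    .fixture_env$gc <- list(tree = tree, model = model, mesh = mesh)
  }
  .fixture_env$gc
}

ball_area <- function(area_um2) ball_tree(soma_radius = sqrt(area_um2 / (4 * pi)))

# classic squid-type membrane as an independent adaptive-ODE oracle
hh_oracle_trace <- function(area_um2, amp_pA, onset = 10, dur = 200,
                            total = 250, dt_out = 0.01, v0 = -65) {
  A <- area_um2 * 1e-8
  rhs <- function(t, y, p) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    al_m <- if (abs(v + 40) < 1e-7) 1 else 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
    be_m <- 4 * exp(-(v + 65) / 18)
    al_h <- 0.07 * exp(-(v + 65) / 20)
    be_h <- 1 / (1 + exp(-(v + 35) / 10))
    al_n <- if (abs(v + 55) < 1e-7) 0.1 else 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
    be_n <- 0.125 * exp(-(v + 65) / 80)
    gna <- 120e-3 * A * 1e6; gk <- 36e-3 * A * 1e6; gl <- 0.3e-3 * A * 1e6
    C <- A * 1e3
    I <- if (t >= onset && t < onset + dur) amp_pA / 1000 else 0
    i_ion <- gna * m^3 * h * (v - 50) + gk * n^4 * (v + 77) + gl * (v + 54.3)
    list(c((I - i_ion) / C,
           al_m * (1 - m) - be_m * m,
           al_h * (1 - h) - be_h * h,
           al_n * (1 - n) - be_n * n))
  }
  inf <- function(a, b) a / (a + b)
  y0 <- c(v0,
          inf(0.1 * (v0 + 40) / (1 - exp(-(v0 + 40) / 10)), 4 * exp(-(v0 + 65) / 18)),
          inf(0.07 * exp(-(v0 + 65) / 20), 1 / (1 + exp(-(v0 + 35) / 10))),
          inf(0.01 * (v0 + 55) / (1 - exp(-(v0 + 55) / 10)), 0.125 * exp(-(v0 + 65) / 80)))
  out <- deSolve::lsoda(y0, seq(0, total, dt_out), rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  list(t = out[, 1], v = out[, 2])
}

# minimal voltage-clamp sim_result for direct extractor tests
fake_vc_result <- function(t, ielec, onset, duration, level, holding) {
  structure(list(time = t, ielec = ielec,
                 protocol = list(mode = "voltage_clamp",
                                 steps = data.frame(onset = onset,
                                                    duration = duration,
                                                    amplitude = level),
                                 holding = holding)),
            class = "sim_result")
}

write_tmp_swc <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}
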