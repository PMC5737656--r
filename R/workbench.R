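# Workbench utilities: toy-tree constructors, the fixture suite, the
# Table-2-style feature table and provenance logging.

#' Toy morphology constructors
#'
#' `ball_tree()`: a single-node soma (sphere). `ball_and_stick_tree()`: soma
#' plus an unbranched dendrite. `cylinder_tree()`: an unbranched uniform
#' cable whose root carries a dendritic label (no soma sphere), for analytic
#' cable validation. `y_tree()`: soma, stem and two symmetric daughters.
#'
#' @param soma_radius,radius,length,step um.
#' @param stem,arm um (y_tree).
#' @param region dendritic label given to cable nodes.
#' @return A `morph_tree`.
#' @export
ball_tree <- function(soma_radius = 10) {
  morph_tree(data.frame(id = 1L, parent = -1L, x = 0, y = 0, z = 0,
                        radius = soma_radius, region = "soma"),
             name = "ball")
}

#' @rdname ball_tree
#' @export
ball_and_stick_tree <- function(soma_radius = 10, radius = 1, length = 200,
                                step = 10, region = "GCL") {
  ys <- seq(step, length, by = step)
  nodes <- data.frame(
    id = 1:(1 + length(ys)),
    parent = c(-1L, 1:length(ys)),
    x = 0, y = c(0, ys), z = 0,
    radius = c(soma_radius, rep(radius, length(ys))),
    region = c("soma", rep(region, length(ys))),
    stringsAsFactors = FALSE)
  morph_tree(nodes, name = "ball_and_stick")
}

#' @rdname ball_tree
#' @export
cylinder_tree <- function(radius = 1, length = 1000, step = 10,
                          region = "GCL") {
  ys <- seq(0, length, by = step)
  nodes <- data.frame(
    id = seq_along(ys), parent = c(-1L, seq_len(length(ys) - 1)),
    x = 0, y = ys, z = 0, radius = radius, region = region,
    stringsAsFactors = FALSE)
  morph_tree(nodes, name = "cylinder")
}

#' @rdname ball_tree
#' @export
y_tree <- function(soma_radius = 8, radius = 1, stem = 50, arm = 50,
                   step = 10, region = "GCL") {
  ys <- seq(step, stem, by = step)
  stem_ids <- 1L + seq_along(ys)
  mk_arm <- function(offset, dirx) {
    xs <- seq(step, arm, by = step) / sqrt(2)
    data.frame(id = offset + seq_along(xs),
               parent = c(stem_ids[length(stem_ids)],
                          offset + seq_len(length(xs) - 1)),
               x = dirx * xs, y = stem + xs, z = 0, radius = radius,
               region = region, stringsAsFactors = FALSE)
  }
  a1 <- mk_arm(1L + length(ys), 1)
  a2 <- mk_arm(1L + length(ys) + nrow(a1), -1)
  nodes <- rbind(
    data.frame(id = 1L, parent = -1L, x = 0, y = 0, z = 0,
               radius = soma_radius, region = "soma",
               stringsAsFactors = FALSE),
    data.frame(id = stem_ids, parent = c(1L, stem_ids[-length(stem_ids)]),
               x = 0, y = ys, z = 0, radius = radius, region = region,
               stringsAsFactors = FALSE),
    a1, a2)
  morph_tree(nodes, name = "y_tree")
}

#' Canonical electrophysiology feature table
#'
#' Runs the standard measurement battery on a cell and reports the canonical
#' intrinsic-property vector: input resistance (10 mV depolarizing step from
#' -92.1 mV), capacitance (-10 mV step), membrane time constant (10 pA
#' hyperpolarizing 500 ms step from -80 mV), resting potential, rheobase
#' (5 pA grid), AP threshold/amplitude/width and maximal slope plus fAHP and
#' ISI features (first AP of a 90 pA, 200 ms step), and the Kir slope
#' conductance from the I-V relation.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param dt ms.
#' @param rheo_max largest rheobase grid amplitude probed, pA.
#' @return Named list of features (units: MOhm, pF, ms, mV, pA, V/s, nS).
#' @export
ephys_feature_table <- function(mesh, model, dt = 0.025, rheo_max = 200) {
  vc <- function(level, holding) {
    pr <- protocol("voltage_clamp", holding = holding, pre = 200,
                   steps = data.frame(onset = 0, duration = 200,
                                      amplitude = level),
                   duration = 250, dt = dt)
    run_voltage_clamp(mesh, model, pr)
  }
  r_in <- input_resistance(vc(-82.1, -92.1))
  c_m <- capacitance(vc(-92.1, -82.1))          # -10 mV step
  tau_res <- run_current_clamp(mesh, model,
    protocol("current_clamp", holding = -80,
             steps = data.frame(onset = 0, duration = 500, amplitude = -10),
             duration = 550, dt = dt))
  tau <- tryCatch(membrane_tau(tau_res$time, tau_res$v[, "soma"],
                               onset = 0, duration = 500),
                  gcell_error = function(e) NA_real_)
  rest <- run_core(mesh, model, duration = 800, dt = dt, v0 = -80,
                   record_comps = resolve_site(mesh, "soma"))
  v_rest <- rest$v_final[resolve_site(mesh, "soma")]
  rheo <- rheobase(list(mesh = mesh, model = model), grid_step = 5,
                   i_max = rheo_max)
  ap_res <- run_current_clamp(mesh, model,
    protocol("current_clamp", holding = -80,
             steps = data.frame(onset = 0, duration = 200, amplitude = 90),
             duration = 250, dt = dt))
  ap <- tryCatch(ap_features(ap_res$time, ap_res$v[, "soma"]),
                 gcell_error = function(e) NULL)
  fa <- tryCatch(fahp(ap_res$time, ap_res$v[, "soma"]),
                 gcell_error = function(e) NA_real_)
  isi <- isi_features(ap_res$spikes)
  gk <- tryCatch(gkir_from_iv(run_iv(mesh, model, dt = dt)),
                 gcell_error = function(e) NA_real_)
  list(R_in_MOhm = r_in, c_m_pF = c_m, tau_ms = tau, V_rest_mV = v_rest,
       I_threshold_pA = as.numeric(rheo),
       V_threshold_mV = if (is.null(ap)) NA_real_ else ap$V_threshold,
       ap_amplitude_mV = if (is.null(ap)) NA_real_ else ap$amplitude,
       ap_width_ms = if (is.null(ap)) NA_real_ else ap$width,
       fAHP_mV = fa, isi_ms = isi$first_isi,
       isi_adaptation_ratio = isi$adaptation_ratio,
       max_spike_slope_V_s = if (is.null(ap)) NA_real_ else ap$max_slope,
       gKir_nS = gk)
}

#' Generate the reproducible fixture suite
#'
#' Writes, under `dir`: toy SWC morphologies (ball-and-stick, Y-tree),
#' passive / squid-type HH / mature-GC model configs, analytic traces with a
#' planted-feature manifest (exact exponential decay, biexponential calcium
#' decay), and `n_synthetic` seeded synthetic GC morphologies with their
#' morphometrics table. Identical seeds give byte-identical files.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param n_synthetic number of synthetic GCs (default 15).
#' @return Invisibly, a named list of the written paths.
#' @export
fixture_suite <- function(seed = 1L, dir = tempfile("fixtures"),
                          n_synthetic = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  p <- function(...) file.path(dir, ...)

  write_swc(ball_and_stick_tree(), p("ball_and_stick.swc"))
  write_swc(y_tree(), p("y_tree.swc"))
  paths$swc <- c(p("ball_and_stick.swc"), p("y_tree.swc"))

  write_model_config(passive_model(), p("passive.yml"))
  write_model_config(hh_model(), p("hh.yml"))
  write_model_config(granule_cell_model(), p("gc_mature.yml"))
  paths$models <- c(p("passive.yml"), p("hh.yml"), p("gc_mature.yml"))

  tt <- seq(0, 400, by = 0.5)
  tau_planted <- 25
  dec <- data.frame(time_ms = tt,
                    v_mV = -90 + 10 * exp(-tt / tau_planted))
  write.table(dec, p("trace_exp_decay.csv"), sep = ",", row.names = FALSE)
  tt2 <- seq(0, 1500, by = 1)
  ca <- data.frame(time_ms = tt2,
                   ca_uM = 0.05 + 0.7 * exp(-tt2 / 50) +
                           0.3 * exp(-tt2 / 300))
  write.table(ca, p("trace_biexp_ca.csv"), sep = ",", row.names = FALSE)
  manifest <- list(
    trace_exp_decay.csv = list(feature = "membrane_tau", value = tau_planted,
                               unit = "ms", tolerance_rel = 0.001),
    trace_biexp_ca.csv = list(feature = "ca_weighted_tau",
                              value = 0.7 * 50 + 0.3 * 300, unit = "ms",
                              tolerance_rel = 0.02,
                              peak = 1.0, peak_unit = "uM"))
  yaml::write_yaml(manifest, p("trace_manifest.yml"))
  paths$traces <- c(p("trace_exp_decay.csv"), p("trace_biexp_ca.csv"),
                    p("trace_manifest.yml"))

  trees <- lapply(seq_len(n_synthetic), function(i)
    generate_granule_cell(mst_params(seed = seed + i - 1L)))
  syn_paths <- vapply(seq_along(trees), function(i) {
    f <- p(sprintf("syngc_%02d.swc", i))
    write_swc(trees[[i]], f, mapping = swc_extended_mapping())
    f
  }, "")
  stats <- lapply(trees, morphometrics)
  tab <- morpho_table(stats)
  tab <- cbind(cell = basename(syn_paths), tab)
  write.table(tab, p("syngc_morphometrics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  paths$synthetic <- c(syn_paths, p("syngc_morphometrics.tsv"))
  invisible(paths)
}

#' Write a provenance sidecar for a run
#'
#' @param path output file.
#' @param seed RNG seed of the run.
#' @param config any serializable configuration list.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed, config = list()) {
  yaml::write_yaml(list(
    package = "gcell",
    version = as.character(utils::packageVersion("gcell")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config), path)
  invisible(path)
}
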