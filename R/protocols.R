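# The experiment battery: I-V and F-I families, backpropagating-AP and
# Ca-transient protocols, layer-specific synaptic drive and the
# sensitivity-analysis driver.

#' Current-voltage relation from a voltage-clamp step family
#'
#' Runs one voltage-clamp step per command from the holding potential and
#' reports the steady-state electrode current (mean over the final 10% of
#' the step window).
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param v_min,v_max,v_step command grid, mV.
#' @param holding holding potential, mV (default -82.1).
#' @param duration step length, ms (default 200).
#' @param dt time step, ms.
#' @return data.frame with `command_mV`, `current_nA`, `current_pA`.
#' @export
run_iv <- function(mesh, model, v_min = -152.1, v_max = -62.1, v_step = 10,
                   holding = -82.1, duration = 200, dt = 0.025) {
  if (v_min >= v_max) gc_error("protocol_invalid", "need v_min < v_max")
  cmds <- seq(v_min, v_max, by = v_step)
  cur <- vapply(cmds, function(cmd) {
    pr <- protocol("voltage_clamp", holding = holding, pre = 200,
                   steps = data.frame(onset = 0, duration = duration,
                                      amplitude = cmd),
                   duration = duration + 50, dt = dt)
    res <- run_voltage_clamp(mesh, model, pr)
    mean(res$ielec[steady_window(res$time, 0, duration)])
  }, 0)
  data.frame(command_mV = cmds, current_nA = cur, current_pA = cur * 1e3)
}

#' Spike counts over a current-step family (F-I relation)
#'
#' 200 ms current steps from a -80 mV holding potential by default; spike
#' counts are upward 0 mV crossings with a 2 ms refractory. Counts are not
#' forced to be monotone (adaptation may break monotonicity).
#'
#' @inheritParams run_iv
#' @param i_min,i_max,i_step amplitude grid, pA (default 0-100 by 5).
#' @param holding mV (default -80).
#' @param duration ms (default 200).
#' @return data.frame with `amplitude_pA`, `n_spikes`.
#' @export
run_fi <- function(mesh, model, i_min = 0, i_max = 100, i_step = 5,
                   holding = -80, duration = 200, dt = 0.025) {
  if (i_step <= 0) gc_error("protocol_invalid", "i_step must be > 0")
  amps <- seq(i_min, i_max, by = i_step)
  ns <- vapply(amps, function(a) {
    pr <- protocol("current_clamp", holding = holding,
                   steps = data.frame(onset = 0, duration = duration,
                                      amplitude = a),
                   duration = duration + 50, dt = dt)
    length(run_current_clamp(mesh, model, pr)$spikes)
  }, 0L)
  data.frame(amplitude_pA = amps, n_spikes = ns)
}

#' Backpropagating action potential characteristics
#'
#' Elicits a somatic AP by a brief suprathreshold current injection
#' (default 2 ms) and reports, per recording site, the maximal voltage
#' amplitude above the pre-pulse baseline, the delay of that maximum
#' relative to the somatic maximum, and the propagation velocity (path
#' distance / delay). The soma itself reports zero delay and no velocity.
#'
#' @inheritParams run_iv
#' @param sites node ids of the source morphology to record from.
#' @param pulse_pA pulse amplitude, pA (default 2000).
#' @param pulse_ms pulse duration, ms (default 2).
#' @param holding mV.
#' @param temperature C (default 33, the bAP condition).
#' @return data.frame with per-site `site`, `path_um`, `euclid_um`,
#'   `amplitude_mV`, `delay_ms`, `velocity_m_s`.
#' @export
run_bap <- function(mesh, model, sites, pulse_pA = 2000, pulse_ms = 2,
                    holding = -80, temperature = 33, dt = 0.025) {
  rec <- c("soma", sites)
  pr <- protocol("current_clamp", holding = holding,
                 steps = data.frame(onset = 20, duration = pulse_ms,
                                    amplitude = pulse_pA),
                 duration = 120, record = rec, dt = dt,
                 temperature = temperature)
  res <- run_current_clamp(mesh, model, pr)
  if (!length(res$spikes))
    gc_error("protocol_no_spike", "pulse did not elicit a somatic spike")
  post <- res$time >= 20
  t <- res$time[post]
  vm <- res$v[post, , drop = FALSE]
  base <- res$v[res$time < 20, , drop = FALSE]
  b <- apply(base, 2, mean)
  pk_i <- apply(vm, 2, which.max)
  t_soma <- t[pk_i[1]]
  out <- lapply(seq_along(rec), function(j) {
    site <- rec[j]
    pd <- if (identical(site, "soma")) 0
          else node_distances(mesh$tree, site)$path_distance
    ed <- if (identical(site, "soma")) 0
          else node_distances(mesh$tree, site)$euclidean_distance
    delay <- t[pk_i[j]] - t_soma
    data.frame(site = as.character(site), path_um = pd, euclid_um = ed,
               amplitude_mV = max(vm[, j]) - b[j],
               delay_ms = if (identical(site, "soma")) 0 else delay,
               velocity_m_s = if (identical(site, "soma") || delay <= 0)
                 NA_real_ else pd / delay * 1e-3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calcium transients following a somatic action potential
#'
#' Same pulse as [run_bap()] but at room temperature by default, recording
#' shell calcium at the sites; features are extracted with
#' [ca_transient_features()].
#'
#' @inheritParams run_bap
#' @return data.frame with per-site `site`, `peak_uM`, `weighted_tau_ms`.
#' @export
run_ca_transients <- function(mesh, model, sites, pulse_pA = 2000,
                              pulse_ms = 2, holding = -80, temperature = 24,
                              dt = 0.025, duration = 600) {
  rec <- c("soma", sites)
  pr <- protocol("current_clamp", holding = holding,
                 steps = data.frame(onset = 20, duration = pulse_ms,
                                    amplitude = pulse_pA),
                 duration = duration, record = rec, dt = dt,
                 temperature = temperature, record_ca = TRUE)
  res <- run_current_clamp(mesh, model, pr)
  out <- lapply(seq_along(rec), function(j) {
    f <- tryCatch(ca_transient_features(res$time, res$ca[, j]),
                  gcell_error = function(e) list(peak = NA_real_,
                                                 weighted_tau = NA_real_))
    data.frame(site = as.character(rec[j]), peak_uM = f$peak,
               weighted_tau_ms = f$weighted_tau, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Layer-specific synaptic drive
#'
#' Places `n_mml` synapses in the MML and `n_oml` in the OML (uniformly over
#' compartment surface area within each layer, seeded), activates all
#' synapses in regular volleys at `freq` Hz, with the OML onset shifted by
#' `-delta_t` relative to the MML (negative `delta_t` means the MML leads),
#' and reports the output-spike to input-volley ratio.
#'
#' @inheritParams run_iv
#' @param n_mml,n_oml synapse counts per layer.
#' @param freq volley frequency, Hz.
#' @param delta_t MML-vs-OML onset shift, ms (0 = synchronous).
#' @param n_volleys number of input volleys (default 8).
#' @param syn a [synapse_spec()].
#' @param holding mV.
#' @param seed placement seed.
#' @return list: `io_ratio`, `output_spikes`, `input_volleys`, `freq_Hz`,
#'   `delta_t_ms`, `placement` (compartment indices), `result`.
#' @export
run_synaptic_drive <- function(mesh, model, n_mml = 15, n_oml = 15,
                               freq = 40, delta_t = 0, n_volleys = 8,
                               syn = synapse_spec(), holding = -80,
                               seed = 1L, dt = 0.025) {
  place <- function(layer, k) {
    idx <- which(mesh$comp$region == layer)
    if (!length(idx))
      gc_error("protocol_empty_layer", "no compartments in layer %s", layer)
    with_seed(seed + match(layer, region_labels()), {
      sample(idx, k, replace = TRUE, prob = mesh$comp$area_cm2[idx])
    })
  }
  mml <- place("MML", n_mml)
  oml <- place("OML", n_oml)
  period <- 1000 / freq
  t0 <- 20
  mml_times <- t0 + (seq_len(n_volleys) - 1) * period
  oml_times <- mml_times - delta_t
  dur <- max(c(mml_times, oml_times)) + period + 50
  gmax_us <- syn$peak_conductance * 1e-3
  syns <- c(
    lapply(mml, function(cp) list(comp = cp - 1L, tau_r = syn$rise_tau,
                                  tau_d = syn$decay_tau, gmax_uS = gmax_us,
                                  erev = syn$reversal, times = mml_times)),
    lapply(oml, function(cp) list(comp = cp - 1L, tau_r = syn$rise_tau,
                                  tau_d = syn$decay_tau, gmax_uS = gmax_us,
                                  erev = syn$reversal, times = oml_times)))
  soma <- resolve_site(mesh, "soma")
  bias <- find_holding(mesh, model, holding, dt = dt)
  res <- run_core(mesh, model, duration = dur, dt = dt, v0 = holding,
                  iclamp = list(comp = soma - 1L, steps = matrix(0, 0, 3),
                                bias = bias),
                  synapses = syns, record_comps = soma)
  spikes <- detect_spikes(res$t, res$v[, 1])
  list(io_ratio = io_ratio(length(spikes), n_volleys),
       output_spikes = length(spikes), input_volleys = n_volleys,
       freq_Hz = freq, delta_t_ms = delta_t,
       placement = list(MML = mml, OML = oml),
       result = list(t = res$t, v = res$v[, 1], spikes = spikes))
}

#' Default perturbation set for the sensitivity analysis
#'
#' One 50% density reduction per channel of the model, plus parameter
#' shifts: `E_K` and `E_pas` raised by +10 mV, `E_Na` lowered by 20 mV,
#' temperature raised by 10 C and cAMP raised from 0 to 1 uM.
#'
#' @param model a [model_spec()].
#' @return Named list of [model_variant()]s.
#' @export
default_perturbations <- function(model) {
  out <- lapply(names(model$channels), function(ch) {
    v <- list(0.5); names(v) <- ch
    model_variant(paste0(ch, "_x0.5"), scale = v)
  })
  names(out) <- paste0(names(model$channels), "_x0.5")
  c(out, list(
    EK_plus10 = model_variant("EK_plus10", shifts = list(E_K = 10)),
    EPas_plus10 = model_variant("EPas_plus10", shifts = list(E_pas = 10)),
    ENa_minus20 = model_variant("ENa_minus20", shifts = list(E_Na = -20)),
    temp_plus10 = model_variant("temp_plus10",
                                shifts = list(temperature = 10)),
    camp_1uM = model_variant("camp_1uM", shifts = list(camp = 1))))
}

#' Compact feature set used by the sensitivity matrix
#'
#' Input resistance (voltage clamp), resting potential and -- when a 90 pA
#' step elicits a spike -- AP threshold, amplitude and width.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param dt ms.
#' @return Named numeric vector (`NA` for undefined features).
#' @export
sensitivity_features <- function(mesh, model, dt = 0.025) {
  rin <- tryCatch({
    pr <- protocol("voltage_clamp", holding = -92.1, pre = 200,
                   steps = data.frame(onset = 0, duration = 200,
                                      amplitude = -82.1),
                   duration = 250, dt = dt)
    input_resistance(run_voltage_clamp(mesh, model, pr))
  }, gcell_error = function(e) NA_real_)
  rest <- tryCatch({
    res <- run_core(mesh, model, duration = 800, dt = dt, v0 = -80,
                    record_comps = resolve_site(mesh, "soma"))
    res$v_final[resolve_site(mesh, "soma")]
  }, gcell_error = function(e) NA_real_)
  ap <- tryCatch({
    pr <- protocol("current_clamp", holding = -80,
                   steps = data.frame(onset = 0, duration = 200,
                                      amplitude = 90),
                   duration = 250, dt = dt)
    res <- run_current_clamp(mesh, model, pr)
    f <- ap_features(res$time, res$v[, "soma"])
    c(V_threshold = f$V_threshold, ap_amplitude = f$amplitude,
      ap_width = f$width)
  }, gcell_error = function(e)
    c(V_threshold = NA_real_, ap_amplitude = NA_real_, ap_width = NA_real_))
  c(R_in = rin, V_rest = rest, ap)
}

#' Sensitivity matrix of features to model perturbations
#'
#' Applies each perturbation, recomputes the features and reports the
#' relative change `(feature_perturbed - feature_control)/feature_control`.
#' Features undefined under a perturbation (e.g. no spike) yield `NA` cells,
#' never an error; the control column is identically zero.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param perturbations named list of [model_variant()]s (default
#'   [default_perturbations()]).
#' @param features_fn `function(mesh, model) -> named numeric` (default
#'   [sensitivity_features()]).
#' @return Matrix, features x (control + perturbations).
#' @export
sensitivity_matrix <- function(mesh, model,
                               perturbations = default_perturbations(model),
                               features_fn = sensitivity_features) {
  ctrl <- features_fn(mesh, model)
  cols <- lapply(perturbations, function(p) {
    f <- features_fn(mesh, apply_variant(model, p))
    (f - ctrl) / ctrl
  })
  out <- cbind(control = rep(0, length(ctrl)),
               matrix(unlist(cols), nrow = length(ctrl)))
  dimnames(out) <- list(names(ctrl), c("control", names(perturbations)))
  out
}
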