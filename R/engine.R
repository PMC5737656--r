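# Discretization of a morph_tree into an electrical compartment mesh and
# R-side drivers for the implicit cable integrator (sim_core, src/engine.cpp).

#' Discretize a morphology into an electrical compartment mesh
#'
#' Unbranched sections (broken at branch points and region changes) are split
#' into an odd number of compartments, either by a fixed maximum compartment
#' length or by the d_lambda rule (a fraction of the AC length constant at
#' `f_lambda` Hz). Surface areas use the conical-frustum model; axial
#' resistances integrate `Ra / (pi r^2)` exactly over the (linearly tapered)
#' frusta, and the axial conductance between adjacent compartments couples
#' their centers. Soma-labelled nodes collapse into a single compartment
#' (a sphere for a lone soma node).
#'
#' @param tree a `morph_tree` (root should be the soma if one is labelled).
#' @param passive a [passive_spec()] (axial resistivity and capacitance).
#' @param max_seg_um fixed maximum compartment length, um; overrides the
#'   d_lambda rule when given.
#' @param d_lambda fraction of the AC length constant (default 0.1).
#' @param f_lambda frequency for the length constant, Hz (default 100).
#' @return A `compartment_mesh`: compartment table (`parent`, `region`,
#'   `length_um`, `area_cm2`, `g_axial_uS`, centre coordinates) plus the
#'   node-to-compartment map.
#' @export
build_mesh <- function(tree, passive = passive_spec(), max_seg_um = NULL,
                       d_lambda = 0.1, f_lambda = 100) {
  validate_morph_tree(tree)
  n <- tree$nodes
  pi_idx <- parent_index(tree)
  len <- segment_lengths(tree)
  kids <- tabulate(pi_idx[!is.na(pi_idx)], nbins = nrow(n))
  soma_rows <- which(n$region == "soma")
  root <- which(n$parent == -1L)

  comp <- list()   # accumulated rows
  node_comp <- integer(nrow(n))
  add_comp <- function(parent, region, length_um, area_cm2, r_prox, r_dist,
                       x, y, z) {
    comp[[length(comp) + 1L]] <<- data.frame(
      parent = parent, region = region, length_um = length_um,
      area_cm2 = area_cm2, r_prox = r_prox, r_dist = r_dist,
      x = x, y = y, z = z, stringsAsFactors = FALSE)
    length(comp)
  }

  ra <- passive$ra
  frustum_area <- function(r1, r2, l)          # um^2
    pi * (r1 + r2) * sqrt(l^2 + (r1 - r2)^2)
  frustum_res <- function(r1, r2, l)           # Ohm (um inputs)
    ra * (l * 1e-4) / (pi * (r1 * 1e-4) * (r2 * 1e-4))

  have_soma <- length(soma_rows) > 0L
  if (have_soma) {
    if (!(root %in% soma_rows))
      gc_error("mesh_root_not_soma", "tree has soma nodes but a non-soma root")
    if (length(soma_rows) == 1L) {
      r <- n$radius[root]
      area <- 4 * pi * r^2 * 1e-8
      rhalf <- ra * (r * 1e-4) / (pi * (r * 1e-4)^2)
      add_comp(-1L, "soma", 2 * r, area, rhalf, rhalf,
               n$x[root], n$y[root], n$z[root])
    } else {
      segs <- soma_rows[!is.na(pi_idx[soma_rows]) &
                        pi_idx[soma_rows] %in% soma_rows]
      area <- sum(frustum_area(n$radius[pi_idx[segs]], n$radius[segs],
                               len[segs])) * 1e-8
      rtot <- sum(frustum_res(n$radius[pi_idx[segs]], n$radius[segs],
                              len[segs]))
      add_comp(-1L, "soma", sum(len[segs]), area, rtot / 2, rtot / 2,
               n$x[root], n$y[root], n$z[root])
    }
    node_comp[soma_rows] <- 1L
  }

  # section start nodes: parent is soma/root-less, a branch point, or a
  # region change
  is_soma <- n$region == "soma"
  starts <- which(!is_soma & (
    is.na(pi_idx) |
    (!is.na(pi_idx) & (is_soma[pmax(pi_idx, 1L)] |
                       kids[pmax(pi_idx, 1L)] >= 2L |
                       n$region[pmax(pi_idx, 1L)] != n$region))))
  starts <- starts[!is.na(pi_idx[starts]) | !have_soma]
  starts <- sort(starts)

  for (s0 in starts) {
    sec <- s0
    while (kids[sec[length(sec)]] == 1L) {
      ch <- which(pi_idx == sec[length(sec)])
      if (is_soma[ch] || n$region[ch] != n$region[s0]) break
      sec <- c(sec, ch)
    }
    att <- pi_idx[s0]                       # attachment node (NA if root)
    seg_from <- ifelse(is.na(att), NA, att)
    # piecewise-linear radius along the arc, starting at the attachment node
    pieces <- if (is.na(att)) sec[-1] else sec
    if (!length(pieces)) {                  # root-only degenerate chain
      node_comp[s0] <- 1L
      next
    }
    p_from <- ifelse(is.na(pi_idx[pieces]), NA, pi_idx[pieces])
    r0 <- n$radius[p_from]
    r1 <- n$radius[pieces]
    dl <- len[pieces]
    if (any(dl <= 0))
      gc_error("mesh_zero_length", "zero-length segment in section at node %d",
               n$id[pieces[which(dl <= 0)[1]]])
    L <- sum(dl)
    brk <- cumsum(c(0, dl))
    dbar <- 2 * sum((r0 + r1) / 2 * dl) / L   # length-weighted mean diameter
    if (!is.null(max_seg_um)) {
      nseg <- ceiling(L / max_seg_um)
    } else {
      lam <- 1e5 * sqrt(dbar / (4 * pi * f_lambda * ra * passive$cm))
      nseg <- floor((L / (d_lambda * lam) + 0.9) / 2) * 2 + 1
    }
    nseg <- max(1L, as.integer(nseg))
    if (nseg %% 2L == 0L) nseg <- nseg + 1L
    rad_at <- function(s) {
      i <- findInterval(s, brk, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(dl))
      w <- (s - brk[i]) / dl[i]
      r0[i] + w * (r1[i] - r0[i])
    }
    integ <- function(a, b, fn) {
      # integrate a frustum quantity over arc [a, b]
      cuts <- sort(unique(c(a, b, brk[brk > a & brk < b])))
      tot <- 0
      for (j in seq_len(length(cuts) - 1L)) {
        ca <- cuts[j]; cb <- cuts[j + 1L]
        tot <- tot + fn(rad_at(ca), rad_at(cb), cb - ca)
      }
      tot
    }
    xyz_at <- function(s) {
      i <- findInterval(s, brk, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(dl))
      w <- (s - brk[i]) / dl[i]
      from <- pieces[i]; pf <- p_from[i]
      c(n$x[pf] + w * (n$x[from] - n$x[pf]),
        n$y[pf] + w * (n$y[from] - n$y[pf]),
        n$z[pf] + w * (n$z[from] - n$z[pf]))
    }
    first_ci <- NA_integer_
    prev_ci <- if (is.na(att)) -1L
               else if (node_comp[att] > 0L) node_comp[att] else -1L
    for (j in seq_len(nseg)) {
      a <- (j - 1) * L / nseg; b <- j * L / nseg; m <- (a + b) / 2
      ctr <- xyz_at(m)
      ci <- add_comp(prev_ci, n$region[s0], b - a,
                     integ(a, b, frustum_area) * 1e-8,
                     integ(a, m, frustum_res), integ(m, b, frustum_res),
                     ctr[1], ctr[2], ctr[3])
      if (j == 1L) first_ci <- ci
      prev_ci <- ci
    }
    # map nodes to the compartment containing their arc position
    arc <- cumsum(dl)
    node_comp[pieces] <- first_ci + pmin(nseg - 1L,
                                         floor(arc / L * nseg - 1e-9))
    if (is.na(att)) node_comp[s0] <- first_ci
  }

  ctab <- do.call(rbind, comp)
  rownames(ctab) <- NULL
  # axial conductance to parent from the two half resistances (uS)
  g_ax <- numeric(nrow(ctab))
  for (i in seq_len(nrow(ctab))) {
    p <- ctab$parent[i]
    if (p < 0) next
    g_ax[i] <- 1e6 / (ctab$r_prox[i] + ctab$r_dist[p])
  }
  ctab$g_axial_uS <- g_ax
  if (any(ctab$area_cm2 <= 0))
    gc_error("mesh_zero_area", "compartment with nonpositive area")
  structure(list(comp = ctab, node_comp = node_comp, tree = tree,
                 passive = passive),
            class = "compartment_mesh")
}

#' @export
print.compartment_mesh <- function(x, ...) {
  cat(sprintf("<compartment_mesh> %d compartments, total area %.1f um^2 (%s)\n",
              nrow(x$comp), sum(x$comp$area_cm2) * 1e8,
              paste(names(table(x$comp$region)), collapse = "/")))
  invisible(x)
}

# --- model compilation -------------------------------------------------------

rate_code <- c(const = 0L, exp = 1L, linoid = 2L, sigmoid = 3L)
mode_code <- c(inftau = 0L, alphabeta = 1L, cahill = 2L)

compile_rate <- function(fn) {
  if (is.null(fn)) fn <- rate_fn("const", a = 0)
  list(type = rate_code[[fn$type]], a = fn$a, v0 = fn$v0, k = fn$k)
}

compile_gate <- function(g, temperature, vshift = 0) {
  list(mode = mode_code[[g$mode]], exponent = g$exponent,
       vhalf = g$vhalf + vshift, k = g$k,
       tau_amp = g$tau$amp, tau_mean = g$tau$mean, tau_sd = g$tau$sd,
       tau_base = g$tau$base,
       alpha = compile_rate(g$alpha), beta = compile_rate(g$beta),
       kd = g$kd, hill = g$hill, inhib = isTRUE(g$inhib),
       tauscale = g$q10^((temperature - g$tref) / 10))
}

kind_code <- c(passive = 0L, instantaneous = 1L, hh = 2L, markov = 3L)

compile_channels <- function(mesh, model) {
  ct <- mesh$comp
  out <- list()
  for (ch in model$channels) {
    dens <- channel_density(ch, ct$region)       # mS/cm2 per compartment
    idx <- which(dens > 0)
    if (!length(idx)) next
    vshift <- 0
    if (!is.null(ch$modifiers$camp_shift) && model$camp != 0)
      vshift <- ch$modifiers$camp_shift * model$camp
    mk <- NULL
    if (ch$kind == "markov") {
      sc <- ch$markov
      st <- sc$states
      q10 <- if (length(ch$gates)) ch$gates[[1]]$q10 else 1
      mk <- list(
        nstates = length(st),
        from = vapply(sc$transitions, function(tr)
          match(tr$from, st) - 1L, 0L),
        to = vapply(sc$transitions, function(tr) match(tr$to, st) - 1L, 0L),
        ca_power = vapply(sc$transitions, function(tr)
          if (is.null(tr$ca_power)) 0 else tr$ca_power, 0),
        open = match(sc$open_states, st) - 1L,
        ratescale = 1,
        rates = lapply(sc$transitions, function(tr) compile_rate(tr$rate)))
    }
    out[[length(out) + 1L]] <- list(
      kind = kind_code[[ch$kind]],
      comp = idx - 1L,
      gbar = dens[idx] * ct$area_cm2[idx] * 1e3,   # uS
      erev = resolve_reversal(ch, model$reversals),
      is_ca = isTRUE(ch$is_ca),
      gates = lapply(ch$gates, compile_gate,
                     temperature = model$temperature, vshift = vshift),
      markov = mk)
  }
  out
}

empty_iclamp <- function()
  list(comp = -1L, steps = matrix(0, 0, 3), bias = 0)
empty_vclamp <- function()
  list(enabled = FALSE, comp = 0L, gclamp_uS = 1e6,
       steps = matrix(0, 0, 3), holding = 0)

resolve_site <- function(mesh, site) {
  if (identical(site, "soma")) {
    i <- which(mesh$comp$region == "soma")
    if (!length(i)) i <- 1L
    return(i[1])
  }
  j <- match(as.integer(site), mesh$tree$nodes$id)
  if (is.na(j)) gc_error("engine_bad_site", "recording site: unknown node %s",
                         site)
  as.integer(mesh$node_comp[j])
}

run_core <- function(mesh, model, duration, dt, v0, iclamp = empty_iclamp(),
                     vclamp = empty_vclamp(), synapses = list(),
                     record_comps = 1L, record_ca = FALSE,
                     record_ielec = FALSE, theta = 1) {
  ct <- mesh$comp
  nsteps <- as.integer(round(duration / dt))
  if (length(v0) == 1L) v0 <- rep(v0, nrow(ct))
  res <- tryCatch(
    sim_core(as.integer(ct$parent - ifelse(ct$parent > 0, 1L, 0L)),
             ct$area_cm2, mesh$passive$cm * ct$area_cm2 * 1e3,
             ct$g_axial_uS,
             compile_channels(mesh, model), unclass(model$ca),
             synapses, iclamp, vclamp, v0, dt, nsteps, theta,
             as.integer(record_comps - 1L), record_ca, record_ielec,
             TRUE),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e)))
        gc_error("engine_diverged", "%s", conditionMessage(e))
      stop(e)
    })
  res
}

# --- holding-current search --------------------------------------------------

.gcell_cache <- new.env(parent = emptyenv())

holding_key <- function(mesh, model, target) {
  paste(model$name, model$temperature, model$camp, target,
        nrow(mesh$comp), signif(sum(mesh$comp$area_cm2), 10),
        signif(sum(vapply(model$channels, function(c) sum(c$density), 0)), 10),
        sep = "|")
}

#' Bias current settling the soma at a holding potential
#'
#' Bisects a constant somatic bias current until the somatic potential over
#' the final 50 ms of a 500 ms equilibration lies within 0.1 mV of the
#' target. Results are cached per (model, mesh, target) within the session.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param target holding potential, mV.
#' @param dt time step, ms.
#' @return Bias current, nA.
#' @export
find_holding <- function(mesh, model, target, dt = 0.025) {
  key <- holding_key(mesh, model, target)
  hit <- .gcell_cache[[key]]
  if (!is.null(hit)) return(hit)
  soma <- resolve_site(mesh, "soma")
  settle <- function(bias) {
    ic <- list(comp = soma - 1L, steps = matrix(0, 0, 3), bias = bias)
    res <- run_core(mesh, model, duration = 500, dt = dt, v0 = target,
                    iclamp = ic, record_comps = soma)
    tail_idx <- which(res$t >= 450)
    mean(res$v[tail_idx, 1])
  }
  lo <- -0.05; hi <- 0.05
  flo <- settle(lo) - target; fhi <- settle(hi) - target
  tries <- 0
  while (flo > 0 && tries < 12) { lo <- lo * 2; flo <- settle(lo) - target
                                  tries <- tries + 1 }
  while (fhi < 0 && tries < 24) { hi <- hi * 2; fhi <- settle(hi) - target
                                  tries <- tries + 1 }
  if (flo > 0 || fhi < 0)
    gc_error("holding_not_settled", "no bias bracket for %g mV", target)
  bias <- 0
  for (i in 1:40) {
    bias <- (lo + hi) / 2
    f <- settle(bias) - target
    if (abs(f) < 0.05) break
    if (f > 0) hi <- bias else lo <- bias
  }
  .gcell_cache[[key]] <- bias
  bias
}

# --- protocols (engine-level) ------------------------------------------------

#' Define a stimulation/recording protocol
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding holding potential, mV (implemented as a settled bias
#'   current in current clamp; as the clamp level in voltage clamp).
#' @param pre pre-equilibration time simulated before the first step, ms.
#' @param steps data.frame with `onset`, `duration` (ms) and `amplitude`
#'   (pA in current clamp, command mV in voltage clamp); onsets are relative
#'   to the end of the pre-equilibration.
#' @param duration total recorded time after pre-equilibration, ms (default:
#'   last step offset + 100).
#' @param record sites: `"soma"` and/or node ids of the source morphology.
#' @param dt time step, ms.
#' @param temperature optional override of the model temperature, C.
#' @param record_ca record calcium at the sites.
#' @param spike_threshold upward-crossing detection threshold, mV.
#' @param spike_refractory minimum inter-spike time for counting, ms.
#' @param ljp_corrected flag carried as metadata: potentials are already
#'   liquid-junction-potential corrected (LJP 12.1 mV frame); the engine
#'   performs no LJP arithmetic.
#' @param theta implicitness of the cable solve (1 backward Euler, 0.5
#'   Crank-Nicolson).
#' @return A `protocol` list.
#' @export
protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                     holding = -80, pre = 300,
                     steps = data.frame(onset = 0, duration = 200,
                                        amplitude = 0),
                     duration = NULL, record = "soma", dt = 0.025,
                     temperature = NULL, record_ca = FALSE,
                     spike_threshold = 0, spike_refractory = 2,
                     ljp_corrected = TRUE, theta = 1) {
  mode <- match.arg(mode)
  if (dt <= 0) gc_error("protocol_invalid", "dt must be > 0")
  if (is.null(duration)) duration <- max(steps$onset + steps$duration) + 100
  if (any(steps$onset < 0) || any(steps$onset + steps$duration > duration))
    gc_error("protocol_invalid", "step windows must lie within the recording")
  structure(list(mode = mode, holding = holding, pre = pre, steps = steps,
                 duration = duration, record = record, dt = dt,
                 temperature = temperature, record_ca = record_ca,
                 spike_threshold = spike_threshold,
                 spike_refractory = spike_refractory,
                 ljp_corrected = ljp_corrected, theta = theta,
                 ljp_mV = 12.1),
            class = "protocol")
}

#' Detect spike times from a voltage trace
#'
#' Upward crossings of the threshold, with a refractory time for counting.
#'
#' @param t time base, ms.
#' @param v voltage trace, mV.
#' @param threshold mV (default 0).
#' @param refractory ms (default 2).
#' @return Spike times, ms.
#' @export
detect_spikes <- function(t, v, threshold = 0, refractory = 2) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  times <- t[up] + (t[up + 1] - t[up]) *
    (threshold - v[up]) / (v[up + 1] - v[up])
  keep <- c(TRUE, diff(times) >= refractory)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= refractory)
  }
  times
}

sim_result <- function(time, v, ca, ielec, spikes, proto, sites, extra = list()) {
  structure(c(list(time = time, v = v, ca = ca, ielec = ielec,
                   spikes = spikes, protocol = proto, sites = sites),
              extra),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s, %.0f ms @ dt %g ms, %d site(s), %d spike(s)\n",
              x$protocol$mode, max(x$time), x$protocol$dt, ncol(x$v),
              length(x$spikes)))
  invisible(x)
}

#' Run a current-clamp protocol
#'
#' The holding potential is realized as a constant somatic bias current
#' found by [find_holding()]; step currents are injected at the soma. Spike
#' times are detected at the soma from upward threshold crossings. Reported
#' times are relative to the end of the pre-equilibration.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param proto a [protocol()] with `mode = "current_clamp"`.
#' @return A `sim_result`.
#' @export
run_current_clamp <- function(mesh, model, proto) {
  stopifnot(proto$mode == "current_clamp")
  if (!is.null(proto$temperature)) model <- set_temperature(model,
                                                            proto$temperature)
  soma <- resolve_site(mesh, "soma")
  bias <- if (is.null(proto$holding)) 0
          else find_holding(mesh, model, proto$holding, dt = proto$dt)
  steps <- as.matrix(cbind(proto$steps$onset + proto$pre,
                           proto$steps$duration,
                           proto$steps$amplitude / 1000))  # pA -> nA
  comps <- vapply(proto$record, resolve_site, 0L, mesh = mesh)
  res <- run_core(mesh, model, duration = proto$pre + proto$duration,
                  dt = proto$dt,
                  v0 = if (is.null(proto$holding)) -80 else proto$holding,
                  iclamp = list(comp = soma - 1L, steps = steps, bias = bias),
                  record_comps = comps, record_ca = proto$record_ca,
                  theta = proto$theta)
  tshift <- res$t - proto$pre
  keep <- tshift >= -proto$pre * 0.1   # drop most of the settling window
  v <- res$v[keep, , drop = FALSE]
  colnames(v) <- as.character(proto$record)
  somacol <- match("soma", proto$record)
  spikes <- if (!is.na(somacol))
    detect_spikes(tshift[keep], v[, somacol], proto$spike_threshold,
                  proto$spike_refractory) else numeric(0)
  ca <- if (proto$record_ca) {
    m <- res$ca[keep, , drop = FALSE]; colnames(m) <- as.character(proto$record)
    m
  } else NULL
  sim_result(tshift[keep], v, ca, NULL, spikes, proto, comps,
             extra = list(holding_bias_nA = bias, model_name = model$name))
}

#' Run a voltage-clamp protocol
#'
#' The soma is clamped through a stiff series conductance (1 Ohm series
#' resistance), pinning it to the command within microvolts; the electrode
#' current (including the capacitive transient of the implicit first step)
#' is recorded.
#'
#' @inheritParams run_current_clamp
#' @param clamp_site site to clamp (default `"soma"`).
#' @return A `sim_result` with `ielec` (nA).
#' @export
run_voltage_clamp <- function(mesh, model, proto, clamp_site = "soma") {
  stopifnot(proto$mode == "voltage_clamp")
  if (!is.null(proto$temperature)) model <- set_temperature(model,
                                                            proto$temperature)
  csite <- resolve_site(mesh, clamp_site)
  steps <- as.matrix(cbind(proto$steps$onset + proto$pre,
                           proto$steps$duration, proto$steps$amplitude))
  comps <- vapply(proto$record, resolve_site, 0L, mesh = mesh)
  res <- run_core(mesh, model, duration = proto$pre + proto$duration,
                  dt = proto$dt, v0 = proto$holding,
                  vclamp = list(enabled = TRUE, comp = csite - 1L,
                                gclamp_uS = 1e6, steps = steps,
                                holding = proto$holding),
                  record_comps = comps, record_ca = proto$record_ca,
                  record_ielec = TRUE, theta = proto$theta)
  tshift <- res$t - proto$pre
  keep <- tshift >= -proto$pre * 0.1
  v <- res$v[keep, , drop = FALSE]
  colnames(v) <- as.character(proto$record)
  sim_result(tshift[keep], v,
             if (proto$record_ca) res$ca[keep, , drop = FALSE] else NULL,
             res$ielec[keep], numeric(0), proto, comps,
             extra = list(model_name = model$name))
}

#' Re-scale a model to a new temperature
#'
#' All Q10-scaled gate and Markov time constants are re-scaled relative to
#' their reference temperatures when the model is compiled; conductances are
#' unaffected unless a channel declares a conductance Q10.
#'
#' @param model a [model_spec()].
#' @param temperature Celsius, in 0-45.
#' @return The model with the new temperature.
#' @export
set_temperature <- function(model, temperature) {
  if (temperature < 0 || temperature > 45)
    gc_error("engine_bad_temperature", "temperature %g C out of range",
             temperature)
  model$temperature <- temperature
  model
}

#' Advance the cable state by one or more fixed steps
#'
#' Low-level stepper over the assembled system: gates are initialized at
#' their steady state for the supplied voltages (the staggered convention
#' for a cold start), then `n` implicit steps of `dt` are taken. Intended
#' for equilibrium, symmetry and convergence checks; full protocols should
#' use the `run_*` drivers.
#'
#' @param mesh a `compartment_mesh`.
#' @param model a [model_spec()].
#' @param v per-compartment voltages, mV (scalar recycled).
#' @param dt step, ms.
#' @param n number of steps.
#' @param i_inj optional constant current into the soma compartment, nA.
#' @param theta implicitness (1 backward Euler, 0.5 Crank-Nicolson).
#' @return Per-compartment voltages after `n` steps.
#' @export
step_state <- function(mesh, model, v, dt, n = 1, i_inj = 0, theta = 1) {
  soma <- resolve_site(mesh, "soma")
  ic <- list(comp = soma - 1L, steps = matrix(0, 0, 3), bias = i_inj)
  res <- run_core(mesh, model, duration = n * dt, dt = dt, v0 = v,
                  iclamp = ic, record_comps = soma, theta = theta)
  res$v_final
}
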