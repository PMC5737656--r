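# Ion-channel, Ca2+-dynamics, synapse and spike-source models, the
# region-keyed density table of the mature mouse GC model, and the
# multiplicative variant machinery.
#
# Unit system (NEURON-compatible): mV, ms, nA, uS, mS/cm2, uF/cm2, uM, um.

FARADAY <- 96485.33212   # C/mol

# --- kinetic building blocks -------------------------------------------------

#' Voltage-dependent rate function
#'
#' Parametric rate forms used by gate kinetics (per ms): `const` (`a`),
#' `exp` (`a*exp((V-v0)/k)`), `linoid` (`a*(V-v0)/(1-exp(-(V-v0)/k))`) and
#' `sigmoid` (`a/(1+exp(-(V-v0)/k))`).
#'
#' @param type one of `"const"`, `"exp"`, `"linoid"`, `"sigmoid"`.
#' @param a,v0,k parameters (see forms above).
#' @return A `rate_fn` list.
#' @export
rate_fn <- function(type = c("const", "exp", "linoid", "sigmoid"),
                    a = 1, v0 = 0, k = 10) {
  structure(list(type = match.arg(type), a = a, v0 = v0, k = k),
            class = "rate_fn")
}

#' @rdname rate_fn
#' @param fn a `rate_fn`.
#' @param v membrane potential, mV.
#' @export
eval_rate <- function(fn, v) {
  switch(fn$type,
    const = rep(fn$a, length(v)),
    exp = fn$a * exp((v - fn$v0) / fn$k),
    linoid = {
      x <- (v - fn$v0) / fn$k
      out <- fn$a * fn$k * x / (1 - exp(-x))
      out[abs(x) < 1e-7] <- fn$a * fn$k   # limit x->0
      out
    },
    sigmoid = fn$a / (1 + exp(-(v - fn$v0) / fn$k))
  )
}

#' Hodgkin-Huxley style gate specification
#'
#' Three kinetic modes: `inftau` (Boltzmann steady state
#' `1/(1+exp((vhalf-V)/k))` -- `k > 0` activation, `k < 0` inactivation --
#' with a constant or Gaussian-bell voltage-dependent time constant),
#' `alphabeta` (steady state and time constant from two [rate_fn()]s) and
#' `cahill` (Hill function of local calcium,
#' `Ca^h/(Ca^h+kd^h)`, or its complement when `inhib = TRUE`, with constant
#' time constant). Time constants are divided by `q10^((T - tref)/10)`.
#'
#' @param exponent positive integer power on the gate variable.
#' @param mode `"inftau"`, `"alphabeta"` or `"cahill"`.
#' @param vhalf,k Boltzmann parameters, mV (`inftau`).
#' @param tau either a single number (ms) or
#'   `list(amp, mean, sd, base)` for a Gaussian bell in V.
#' @param alpha,beta [rate_fn()]s (`alphabeta`).
#' @param kd,hill,inhib Ca Hill parameters, uM (`cahill`).
#' @param q10,tref temperature scaling of the time constant.
#' @return An `hh_gate` list.
#' @export
hh_gate <- function(exponent = 1, mode = c("inftau", "alphabeta", "cahill"),
                    vhalf = -40, k = 10, tau = 1,
                    alpha = NULL, beta = NULL,
                    kd = 1, hill = 2, inhib = FALSE,
                    q10 = 2.3, tref = 24) {
  mode <- match.arg(mode)
  if (is.numeric(tau) && length(tau) == 1)
    tau <- list(amp = 0, mean = 0, sd = 1, base = tau)
  g <- list(exponent = as.integer(exponent), mode = mode, vhalf = vhalf,
            k = k, tau = tau, alpha = alpha, beta = beta, kd = kd,
            hill = hill, inhib = inhib, q10 = q10, tref = tref)
  if (g$exponent < 1) gc_error("gate_invalid", "exponent must be >= 1")
  structure(g, class = "hh_gate")
}

gate_tau <- function(gate, v, temperature = gate$tref) {
  sc <- gate$q10^((temperature - gate$tref) / 10)
  tau <- switch(gate$mode,
    inftau = ,
    cahill = {
      tp <- gate$tau
      tp$amp * exp(-((v - tp$mean) / tp$sd)^2) + tp$base
    },
    alphabeta = 1 / (eval_rate(gate$alpha, v) + eval_rate(gate$beta, v))
  )
  tau / sc
}

gate_inf <- function(gate, v, ca = 0) {
  switch(gate$mode,
    inftau = 1 / (1 + exp((gate$vhalf - v) / gate$k)),
    alphabeta = {
      a <- eval_rate(gate$alpha, v); b <- eval_rate(gate$beta, v)
      a / (a + b)
    },
    cahill = {
      f <- ca^gate$hill / (ca^gate$hill + gate$kd^gate$hill)
      if (gate$inhib) 1 - f else f
    }
  )
}

#' Exponential-Euler gate update
#'
#' Advances a gate variable by `x' = x_inf + (x - x_inf) * exp(-dt / tau)`,
#' exact for voltage (and calcium) held constant over the step. The time
#' constant is Q10-scaled relative to the gate's reference temperature.
#'
#' @param gate an [hh_gate()].
#' @param x current gate value in `[0, 1]`.
#' @param v membrane potential, mV.
#' @param dt time step, ms.
#' @param temperature simulation temperature, Celsius.
#' @param ca local calcium, uM (Ca-dependent gates).
#' @return Updated gate value.
#' @export
gate_update_exact <- function(gate, x, v, dt, temperature = gate$tref,
                              ca = 0) {
  xi <- gate_inf(gate, v, ca)
  xi + (x - xi) * exp(-dt / gate_tau(gate, v, temperature))
}

# --- Markov schemes ----------------------------------------------------------

#' Markov kinetic scheme
#'
#' States connected by transitions whose per-ms rates are [rate_fn()]s of V,
#' optionally multiplied by `Ca^ca_power`. Occupancy is a probability vector
#' over the states; channel open fraction is the summed occupancy of
#' `open_states`.
#'
#' @param states character vector of state labels.
#' @param transitions list of `list(from, to, rate, ca_power = 0)`.
#' @param open_states subset of `states`.
#' @return A `markov_scheme` list.
#' @export
markov_scheme <- function(states, transitions, open_states) {
  stopifnot(all(open_states %in% states))
  structure(list(states = states, transitions = transitions,
                 open_states = open_states), class = "markov_scheme")
}

markov_q <- function(scheme, v, ca = 0) {
  s <- length(scheme$states)
  Q <- matrix(0, s, s, dimnames = list(scheme$states, scheme$states))
  for (tr in scheme$transitions) {
    r <- eval_rate(tr$rate, v)
    cp <- if (is.null(tr$ca_power)) 0 else tr$ca_power
    if (cp > 0) r <- r * ca^cp
    if (r < 0) gc_error("markov_negative_rate", "negative transition rate")
    Q[tr$from, tr$to] <- Q[tr$from, tr$to] + r
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Advance a Markov occupancy vector by one step
#'
#' Propagates the master equation over `dt` with rates frozen at the current
#' voltage and calcium (the staggering convention of the integrator), using
#' uniformization of the matrix exponential: the propagator is evaluated as
#' a Poisson-weighted power series of the stochastic matrix `I + Q/lambda`,
#' which is unconditionally stable, keeps every entry nonnegative and
#' conserves total occupancy to round-off (the result is renormalized to sum
#' exactly to one).
#'
#' @param scheme a [markov_scheme()].
#' @param occupancy probability vector over the states (sums to 1).
#' @param v membrane potential, mV.
#' @param ca local calcium, uM.
#' @param dt time step, ms.
#' @return Updated occupancy vector.
#' @export
markov_update <- function(scheme, occupancy, v, ca = 0, dt = 0.025) {
  if (abs(sum(occupancy) - 1) > 1e-6)
    gc_error("markov_bad_occupancy", "occupancy must sum to 1")
  Q <- markov_q(scheme, v, ca)
  lam <- max(-diag(Q), .Machine$double.eps)
  P <- diag(nrow(Q)) + Q / lam
  mu <- lam * dt
  # p' = p expm(Q dt) = sum_k pois(k; mu) * p P^k
  term <- occupancy
  out <- term * exp(-mu)
  w <- exp(-mu)
  cum <- w
  k <- 0
  while (cum < 1 - 1e-16 && k < 10000) {
    k <- k + 1
    term <- as.numeric(term %*% P)
    w <- w * mu / k
    out <- out + w * term
    cum <- cum + w
  }
  out <- pmax(out, 0)
  out / sum(out)
}

# --- calcium, synapses, spike sources ---------------------------------------

#' Phenomenological single-shell calcium dynamics
#'
#' Calcium in a submembrane shell of depth `shell_depth` receives influx
#' `-I_Ca / (2 F V_shell kappa)` (inward Ca current positive contribution,
#' instantaneous buffering factor `kappa`) and relaxes toward `resting_ca`
#' with time constant `decay_tau`.
#'
#' @param shell_depth um.
#' @param kappa dimensionless buffering factor.
#' @param decay_tau ms.
#' @param resting_ca uM.
#' @return A `ca_dynamics` list.
#' @export
ca_dynamics <- function(shell_depth = 0.1, kappa = 100, decay_tau = 150,
                        resting_ca = 0.05) {
  stopifnot(shell_depth > 0, kappa > 0, decay_tau > 0, resting_ca >= 0)
  structure(list(shell_depth = shell_depth, kappa = kappa,
                 decay_tau = decay_tau, resting_ca = resting_ca),
            class = "ca_dynamics")
}

#' Advance shell calcium by one step
#'
#' Implicit update of the single-shell balance; never produces a negative
#' concentration. Influx only counts inward (negative) Ca current.
#'
#' @param cadyn a [ca_dynamics()].
#' @param ca current concentration, uM.
#' @param i_ca calcium current, nA (outward positive).
#' @param area_um2 membrane area of the compartment, um^2.
#' @param dt ms.
#' @return Updated concentration, uM.
#' @export
ca_update <- function(cadyn, ca, i_ca, area_um2, dt) {
  vol_um3 <- area_um2 * cadyn$shell_depth
  influx <- max(0, -i_ca) * 1e9 / (2 * FARADAY * vol_um3 * cadyn$kappa)  # uM/ms
  out <- (ca + dt * (influx + cadyn$resting_ca / cadyn$decay_tau)) /
         (1 + dt / cadyn$decay_tau)
  max(out, 0)
}

#' AMPA-type synapse specification
#'
#' Conductance rises and decays exponentially upon each presynaptic spike;
#' the waveform is normalized so a single spike peaks at `peak_conductance`.
#'
#' @param rise_tau,decay_tau ms, `decay_tau > rise_tau > 0`.
#' @param peak_conductance nS.
#' @param reversal mV.
#' @param target_regions regions eligible for placement.
#' @return A `synapse_spec` list.
#' @export
synapse_spec <- function(rise_tau = 0.2, decay_tau = 2.5,
                         peak_conductance = 1, reversal = 0,
                         target_regions = c("MML", "OML")) {
  if (!(decay_tau > rise_tau && rise_tau > 0))
    gc_error("synapse_invalid", "need decay_tau > rise_tau > 0")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 peak_conductance = peak_conductance, reversal = reversal,
                 target_regions = target_regions), class = "synapse_spec")
}

#' Synaptic conductance waveform
#'
#' Linear superposition over spikes of the normalized double exponential;
#' each spike contributes a waveform peaking at `peak_conductance` at
#' `t_peak = (tr*td/(td-tr)) * log(td/tr)` after the spike.
#'
#' @param spec a [synapse_spec()].
#' @param spike_times sorted spike times, ms.
#' @param t evaluation times, ms.
#' @return Conductance, nS, same length as `t`.
#' @export
synapse_conductance <- function(spec, spike_times, t) {
  tr <- spec$rise_tau; td <- spec$decay_tau
  tp <- tr * td / (td - tr) * log(td / tr)
  norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
  g <- numeric(length(t))
  for (t0 in spike_times) {
    dtv <- t - t0
    on <- dtv >= 0
    g[on] <- g[on] + spec$peak_conductance * norm *
      (exp(-dtv[on] / td) - exp(-dtv[on] / tr))
  }
  g
}

#' Homogeneous Poisson spike train
#'
#' @param rate Hz, `>= 0`.
#' @param duration ms.
#' @param seed RNG seed.
#' @return Sorted spike times in `[0, duration)`, ms.
#' @export
poisson_train <- function(rate, duration, seed = 1L) {
  if (rate < 0) gc_error("poisson_negative_rate", "rate must be >= 0")
  if (rate == 0) return(numeric(0))
  with_seed(seed, {
    t <- cumsum(rexp(ceiling(rate * duration / 1000 * 3) + 20,
                     rate = rate / 1000))
    while (length(t) && t[length(t)] < duration)
      t <- c(t, t[length(t)] + cumsum(rexp(50, rate = rate / 1000)))
    t[t < duration]
  })
}

# --- channel specs and model -------------------------------------------------

#' Ion channel specification
#'
#' A channel has a `kind` (`passive`: ohmic leak; `instantaneous`: open
#' fraction follows V with no dynamics; `hh`: product of [hh_gate()]s;
#' `markov`: a [markov_scheme()]), a per-region conductance density map in
#' mS/cm^2, and a reversal potential given either in mV or as an ion tag
#' (`"K"`, `"Na"`, `"Ca"`, `"pas"`) resolved against the model's reversal
#' table.
#'
#' @param name channel name (e.g. `"Kir2"`, `"Nav"`, `"BK_alphabeta"`).
#' @param kind see above.
#' @param density named numeric vector, region label -> mS/cm^2 (missing
#'   regions mean zero density).
#' @param reversal mV, or ion tag string.
#' @param gates list of [hh_gate()] (hh/instantaneous kinds).
#' @param markov a [markov_scheme()] (markov kind).
#' @param is_ca logical; current feeds the calcium shell.
#' @param modifiers optional list, e.g. `camp_shift` (mV per uM cAMP added
#'   to activation vhalf, HCN).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, kind = c("passive", "instantaneous", "hh",
                                        "markov"),
                         density, reversal, gates = list(), markov = NULL,
                         is_ca = FALSE, modifiers = list()) {
  kind <- match.arg(kind)
  if (any(density < 0))
    gc_error("channel_negative_density", "%s: densities must be >= 0", name)
  bad <- setdiff(names(density), region_labels())
  if (length(bad))
    gc_error("channel_bad_region", "%s: unknown region(s) %s", name,
             paste(bad, collapse = ", "))
  structure(list(name = name, kind = kind, density = density,
                 reversal = reversal, gates = gates, markov = markov,
                 is_ca = is_ca, modifiers = modifiers),
            class = "channel_spec")
}

resolve_reversal <- function(spec, reversals) {
  if (is.numeric(spec$reversal)) return(spec$reversal)
  e <- reversals[[spec$reversal]]
  if (is.null(e)) gc_error("channel_bad_reversal",
                           "%s: unknown ion tag %s", spec$name, spec$reversal)
  e
}

channel_density <- function(spec, region) {
  d <- unname(spec$density[region])
  d[is.na(d)] <- 0
  d
}

channel_open_fraction <- function(spec, v, state = NULL, ca = 0) {
  switch(spec$kind,
    passive = 1,
    instantaneous = {
      o <- 1
      for (g in spec$gates) o <- o * gate_inf(g, v, ca)^g$exponent
      o
    },
    hh = {
      if (length(state) != length(spec$gates))
        gc_error("channel_state_mismatch", "%s: expected %d gate values",
                 spec$name, length(spec$gates))
      o <- 1
      for (i in seq_along(spec$gates))
        o <- o * state[[i]]^spec$gates[[i]]$exponent
      o
    },
    markov = {
      if (length(state) != length(spec$markov$states))
        gc_error("channel_state_mismatch", "%s: expected %d occupancies",
                 spec$name, length(spec$markov$states))
      sum(state[match(spec$markov$open_states, spec$markov$states)])
    }
  )
}

#' Ohmic channel current
#'
#' `I = gbar * open_fraction * (V - E) * area`, outward positive, in nA.
#'
#' @param spec a [channel_spec()].
#' @param v membrane potential, mV.
#' @param state gate values (hh), occupancy vector (markov) or `NULL`.
#' @param ca local calcium, uM.
#' @param area_um2 membrane area, um^2.
#' @param region region whose density applies (default `"soma"`).
#' @param reversals named list of ionic reversal potentials, mV.
#' @return Current in nA.
#' @export
channel_current <- function(spec, v, state = NULL, ca = 0, area_um2 = 1,
                            region = "soma",
                            reversals = list(K = -90, Na = 60, Ca = 130,
                                             pas = -90)) {
  g_ms <- channel_density(spec, region)          # mS/cm2
  g_us <- g_ms * (area_um2 * 1e-8) * 1e3         # uS
  e <- resolve_reversal(spec, reversals)
  g_us * channel_open_fraction(spec, v, state, ca) * (v - e)
}

#' Passive membrane and axial parameters
#'
#' @param ra axial resistivity, Ohm cm.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @return A `passive_spec` list.
#' @export
passive_spec <- function(ra = 200, cm = 1) {
  stopifnot(ra > 0, cm > 0)
  structure(list(ra = ra, cm = cm), class = "passive_spec")
}

#' Assemble a model specification
#'
#' @param name model name.
#' @param channels list of [channel_spec()].
#' @param passive a [passive_spec()].
#' @param reversals named list: `K`, `Na`, `Ca`, `pas` reversal potentials, mV.
#' @param ca a [ca_dynamics()].
#' @param temperature simulation temperature, Celsius.
#' @param camp cAMP concentration, uM (shifts HCN activation).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, channels, passive = passive_spec(),
                       reversals = list(K = -90, Na = 60, Ca = 130,
                                        pas = -90),
                       ca = ca_dynamics(), temperature = 24, camp = 0) {
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm))
    gc_error("model_duplicate_channel", "duplicated channel names")
  structure(list(name = name, channels = stats::setNames(channels, nm),
                 passive = passive, reversals = reversals, ca = ca,
                 temperature = temperature, camp = camp),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d channels, Ra %g Ohm cm, cm %g uF/cm2, %g C\n",
              x$name, length(x$channels), x$passive$ra, x$passive$cm,
              x$temperature))
  invisible(x)
}

# --- variants ---------------------------------------------------------------

#' Multiplicative model variant
#'
#' @param name variant name.
#' @param scale named list: channel name -> factor (`>= 0`), or
#'   `list(factor =, regions =)` to restrict the scaling to regions.
#' @param shifts optional named list of offsets applied to the model:
#'   `E_K`, `E_Na`, `E_pas` (mV), `temperature` (C), `camp` (uM).
#' @return A `model_variant` list.
#' @export
model_variant <- function(name, scale = list(), shifts = list()) {
  for (s in scale) {
    f <- if (is.list(s)) s$factor else s
    if (f < 0) gc_error("variant_negative_factor", "factors must be >= 0")
  }
  structure(list(name = name, scale = scale, shifts = shifts),
            class = "model_variant")
}

#' Apply a variant to a model
#'
#' Returns a new model with the variant's channel densities multiplied
#' (region-restricted if specified) and any reversal/temperature/cAMP shifts
#' applied; the input model is untouched. Composing variants multiplies
#' factors.
#'
#' @param model a [model_spec()].
#' @param variant a [model_variant()].
#' @return A new `model_spec`.
#' @export
apply_variant <- function(model, variant) {
  unknown <- setdiff(names(variant$scale), names(model$channels))
  if (length(unknown))
    gc_error("variant_unknown_channel", "unknown channel(s): %s",
             paste(unknown, collapse = ", "))
  for (ch in names(variant$scale)) {
    s <- variant$scale[[ch]]
    f <- if (is.list(s)) s$factor else s
    regs <- if (is.list(s) && !is.null(s$regions)) s$regions
            else names(model$channels[[ch]]$density)
    d <- model$channels[[ch]]$density
    hit <- names(d) %in% regs
    d[hit] <- d[hit] * f
    model$channels[[ch]]$density <- d
  }
  sh <- variant$shifts
  if (!is.null(sh$E_K)) model$reversals$K <- model$reversals$K + sh$E_K
  if (!is.null(sh$E_Na)) model$reversals$Na <- model$reversals$Na + sh$E_Na
  if (!is.null(sh$E_pas)) model$reversals$pas <- model$reversals$pas + sh$E_pas
  if (!is.null(sh$temperature))
    model$temperature <- model$temperature + sh$temperature
  if (!is.null(sh$camp)) model$camp <- model$camp + sh$camp
  model$name <- paste0(model$name, "+", variant$name)
  model
}

#' Built-in named model variants
#'
#' Ships the variants used throughout the granule-cell work: `barium`
#' (200 uM Ba2+: 99% Kir2 and 30% K2P blockade), `epilepsy` (doubled Kir2
#' and HCN conductance), `kv11_overexpression` (three-fold Kv1.1),
#' `young_abgc` (channel downregulation of young adult-born GCs: Kir2 -73%,
#' Kv2.1 -50%, Kv4.2/3 -50%, Kv7 -50%, Nav -25%, Cav1.3 -50%, BK-alpha -40%,
#' BK-alpha/beta4 -100%; Kv1.4, Kv3.4 and Cav1.2 unchanged) and
#' `rat_mature` (increased Kir2 conductance; the scaling factor is
#' config-exposed as it is fitted per dataset).
#'
#' @param rat_kir_factor Kir2 scaling for the rat variant (default 2).
#' @return Named list of [model_variant()]s.
#' @export
builtin_variants <- function(rat_kir_factor = 2) {
  list(
    barium = model_variant("barium", scale = list(Kir2 = 0.01, K2P = 0.7)),
    epilepsy = model_variant("epilepsy", scale = list(Kir2 = 2, HCN = 2)),
    kv11_overexpression = model_variant("kv11_overexpression",
                                        scale = list(Kv11 = 3)),
    young_abgc = model_variant("young_abgc", scale = list(
      Kir2 = 1 - 0.73, Kv14 = 1, Kv21 = 0.5, Kv34 = 1, Kv42 = 0.5,
      Kv7 = 0.5, Nav = 0.75, Cav12 = 1, Cav13 = 0.5,
      BK_alpha = 1 - 0.4, BK_alphabeta = 0)),
    rat_mature = model_variant("rat_mature",
                               scale = list(Kir2 = rat_kir_factor))
  )
}
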