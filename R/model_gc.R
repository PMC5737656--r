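# The shipped mature mouse granule-cell model: region-keyed conductance
# densities with generic kinetic templates, plus small fixture models.
#
# The density table is the model's channel inventory (mS/cm2 per region).
# The kinetic parameterizations shipped here are generic templates (Boltzmann
# steady states with constant or bell-shaped time constants, Hill-type
# Ca-dependence for BK/SK, instantaneous Boltzmann rectification for Kir)
# chosen to make the full protocol battery runnable and qualitatively
# GC-like; quantitative reproduction of measured feature tables requires the
# experimentally fitted kinetic parameter sets, which can be loaded through
# the same config schema.

gc_density <- function(soma = 0, axon = 0, AIS = 0, GCL = 0, IML = 0,
                       MML = 0, OML = 0) {
  c(soma = soma, axon = axon, AIS = AIS, GCL = GCL, IML = IML, MML = MML,
    OML = OML)
}

#' The mature mouse granule-cell model
#'
#' Builds the full region-specific channel inventory of the mature mouse GC:
#' Nav (somatic and axonal, peaking in the AIS), K2P leak, inwardly
#' rectifying Kir2, dendritic HCN, axonal Kv1.1/Kv1.4/Kv3.4/Kv7, somatic
#' Kv2.1, dendritic A-type Kv4.2/3, L-/N-/T-type Cav with Ca-dependent
#' inactivation of the L-types, Ca-activated BK (alpha and alpha+beta4) and
#' SK2, with single-shell calcium dynamics. Densities are in mS/cm^2 per
#' region; kinetics are the package's generic templates (see the package
#' vignette).
#'
#' @param passive a [passive_spec()].
#' @param temperature Celsius (default 24; protocols may override).
#' @return A [model_spec()].
#' @export
granule_cell_model <- function(passive = passive_spec(ra = 200, cm = 1),
                               temperature = 24) {
  tau_m_nav <- list(amp = 0.10, mean = -40, sd = 25, base = 0.04)
  tau_h_nav <- list(amp = 5, mean = -60, sd = 20, base = 0.4)
  ch <- list(
    channel_spec("Nav", "hh",
      density = gc_density(soma = 88.128, axon = 88.128, AIS = 518.400),
      reversal = "Na",
      gates = list(
        hh_gate(3, "inftau", vhalf = -40, k = 6, tau = tau_m_nav),
        hh_gate(1, "inftau", vhalf = -52, k = -6, tau = tau_h_nav))),
    channel_spec("K2P", "passive",
      density = gc_density(soma = 0.014, axon = 0.007, AIS = 0.007,
                           GCL = 0.014, IML = 0.014, MML = 0.014,
                           OML = 0.014),
      reversal = "pas"),
    channel_spec("Kir2", "instantaneous",
      density = gc_density(soma = 0.1416, axon = 0.0674, AIS = 0.0674,
                           GCL = 0.1416, IML = 0.1416, MML = 0.1416,
                           OML = 0.1416),
      reversal = "K",
      gates = list(hh_gate(1, "inftau", vhalf = -102, k = -9))),
    channel_spec("HCN", "hh",
      density = gc_density(IML = 0.004, MML = 0.004, OML = 0.004),
      reversal = -30,
      gates = list(hh_gate(1, "inftau", vhalf = -95, k = -8, tau = 50)),
      modifiers = list(camp_shift = 8)),   # mV per uM cAMP
    channel_spec("Kv11", "hh",
      density = gc_density(axon = 0.25, AIS = 0.25),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = -35, k = 10,
                tau = list(amp = 8, mean = -40, sd = 30, base = 1)),
        hh_gate(1, "inftau", vhalf = -55, k = -8, tau = 8000))),
    channel_spec("Kv14", "hh",
      density = gc_density(axon = 1, AIS = 1),
      reversal = "K",
      gates = list(
        hh_gate(4, "inftau", vhalf = -40, k = 12,
                tau = list(amp = 2, mean = -50, sd = 30, base = 0.5)),
        hh_gate(1, "inftau", vhalf = -60, k = -7, tau = 30))),
    channel_spec("Kv21", "hh",
      density = gc_density(soma = 7.09),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = -15, k = 8,
                tau = list(amp = 3, mean = -30, sd = 30, base = 1)),
        hh_gate(1, "inftau", vhalf = -55, k = -12, tau = 4000))),
    channel_spec("Kv34", "hh",
      density = gc_density(axon = 7.6562, AIS = 30.7813),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = -15, k = 10,
                tau = list(amp = 1, mean = -20, sd = 30, base = 0.3)),
        hh_gate(1, "inftau", vhalf = -45, k = -10, tau = 1000))),
    channel_spec("Kv42", "hh",
      density = gc_density(GCL = 2.1750, IML = 4.35, MML = 4.35,
                           OML = 4.35),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = -25, k = 9,
                tau = list(amp = 1.5, mean = -50, sd = 30, base = 0.4)),
        hh_gate(1, "inftau", vhalf = -75, k = -6, tau = 25))),
    channel_spec("Kv7", "hh",
      density = gc_density(axon = 1.34, AIS = 6.70),
      reversal = "K",
      gates = list(hh_gate(1, "inftau", vhalf = -35, k = 9, tau = 100))),
    channel_spec("Cav12", "hh", is_ca = TRUE,
      density = gc_density(soma = 0.02, AIS = 0.01, GCL = 0.01, IML = 0.04,
                           MML = 0.04, OML = 0.04),
      reversal = "Ca",
      gates = list(
        hh_gate(1, "inftau", vhalf = -20, k = 7, tau = 1),
        hh_gate(1, "inftau", vhalf = -55, k = -10, tau = 80),
        hh_gate(1, "cahill", kd = 1, hill = 2, inhib = TRUE, tau = 10))),
    channel_spec("Cav13", "hh", is_ca = TRUE,
      density = gc_density(soma = 0.016, axon = 0.004, AIS = 0.008,
                           GCL = 0.004, IML = 0.008, MML = 0.008,
                           OML = 0.008),
      reversal = "Ca",
      gates = list(
        hh_gate(1, "inftau", vhalf = -30, k = 7, tau = 1),
        hh_gate(1, "inftau", vhalf = -60, k = -10, tau = 80),
        hh_gate(1, "cahill", kd = 1, hill = 2, inhib = TRUE, tau = 10))),
    channel_spec("CavN", "hh", is_ca = TRUE,
      density = gc_density(soma = 0.3, axon = 0.05, AIS = 0.05, GCL = 0.05,
                           IML = 0.05, MML = 0.05, OML = 0.05),
      reversal = "Ca",
      gates = list(
        hh_gate(2, "inftau", vhalf = -25, k = 8, tau = 0.8),
        hh_gate(1, "inftau", vhalf = -60, k = -10, tau = 100))),
    channel_spec("CavT", "hh", is_ca = TRUE,
      density = gc_density(soma = 0.022, axon = 0.008, AIS = 0.008,
                           GCL = 0.022, IML = 0.022, MML = 0.022,
                           OML = 0.022),
      reversal = "Ca",
      gates = list(
        hh_gate(1, "inftau", vhalf = -50, k = 6, tau = 2),
        hh_gate(1, "inftau", vhalf = -75, k = -6, tau = 30))),
    channel_spec("BK_alpha", "hh",
      density = gc_density(soma = 15.6, axon = 62.4, AIS = 62.4),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = 0, k = 12, tau = 1),
        hh_gate(1, "cahill", kd = 4, hill = 2, tau = 1))),
    channel_spec("BK_alphabeta", "hh",
      density = gc_density(soma = 3.9, axon = 15.6, AIS = 15.6),
      reversal = "K",
      gates = list(
        hh_gate(1, "inftau", vhalf = -20, k = 12, tau = 5),
        hh_gate(1, "cahill", kd = 2, hill = 2, tau = 5))),
    channel_spec("SK2", "hh",
      density = gc_density(soma = 0.001, axon = 0.013, AIS = 0.083,
                           GCL = 0.002, IML = 0.004, MML = 0.004,
                           OML = 0.004),
      reversal = "K",
      gates = list(hh_gate(1, "cahill", kd = 0.4, hill = 4, tau = 10)))
  )
  model_spec("gc_mature_mouse", ch, passive = passive,
             reversals = list(K = -90, Na = 60, Ca = 130, pas = -90),
             ca = ca_dynamics(), temperature = temperature)
}

#' Single-compartment fixture models
#'
#' `passive_model()` is a pure leak membrane; `hh_model()` is the classic
#' squid-type Na/K/leak membrane (rates in their original form, 6.3 C
#' reference), used as an integration fixture against independent ODE
#' solutions.
#'
#' @param g_pas leak density, mS/cm^2.
#' @param e_pas leak reversal, mV.
#' @param passive a [passive_spec()].
#' @return A [model_spec()].
#' @export
passive_model <- function(g_pas = 0.04, e_pas = -80,
                          passive = passive_spec(ra = 150, cm = 1)) {
  model_spec("passive",
             list(channel_spec("pas", "passive",
                               density = gc_density(soma = g_pas, axon = g_pas,
                                                    AIS = g_pas, GCL = g_pas,
                                                    IML = g_pas, MML = g_pas,
                                                    OML = g_pas),
                               reversal = e_pas)),
             passive = passive,
             ca = ca_dynamics(), temperature = 24)
}

#' @rdname passive_model
#' @export
hh_model <- function(passive = passive_spec(ra = 150, cm = 1)) {
  all_reg <- function(v) gc_density(soma = v, axon = v, AIS = v, GCL = v,
                                    IML = v, MML = v, OML = v)
  # classic squid parameterization, voltages in the modern (mV) convention
  m <- hh_gate(3, "alphabeta",
               alpha = rate_fn("linoid", a = 0.1, v0 = -40, k = 10),
               beta = rate_fn("exp", a = 4, v0 = -65, k = -18),
               q10 = 3, tref = 6.3)
  h <- hh_gate(1, "alphabeta",
               alpha = rate_fn("exp", a = 0.07, v0 = -65, k = -20),
               beta = rate_fn("sigmoid", a = 1, v0 = -35, k = 10),
               q10 = 3, tref = 6.3)
  n <- hh_gate(4, "alphabeta",
               alpha = rate_fn("linoid", a = 0.01, v0 = -55, k = 10),
               beta = rate_fn("exp", a = 0.125, v0 = -65, k = -80),
               q10 = 3, tref = 6.3)
  model_spec("hh_squid",
             list(
               channel_spec("na", "hh", density = all_reg(120),
                            reversal = 50, gates = list(m, h)),
               channel_spec("k", "hh", density = all_reg(36),
                            reversal = -77, gates = list(n)),
               channel_spec("leak", "passive", density = all_reg(0.3),
                            reversal = -54.3)),
             passive = passive, ca = ca_dynamics(), temperature = 6.3)
}

# --- config I/O --------------------------------------------------------------

#' Write / read a model configuration
#'
#' Serializes a [model_spec()] to a structured YAML config with one block
#' per channel mirroring the seven region columns of the density table, and
#' reads it back with strict schema validation: negative densities, unknown
#' regions, unknown kinds or malformed gates are rejected with messages
#' naming the offending channel and field.
#'
#' @param model a [model_spec()].
#' @param path file path.
#' @return `read_model_config` returns a [model_spec()];
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  ser_gate <- function(g) {
    out <- list(exponent = g$exponent, mode = g$mode, q10 = g$q10,
                tref = g$tref)
    if (g$mode == "inftau")
      out <- c(out, list(vhalf = g$vhalf, k = g$k, tau = g$tau))
    if (g$mode == "alphabeta")
      out <- c(out, list(alpha = unclass(g$alpha), beta = unclass(g$beta)))
    if (g$mode == "cahill")
      out <- c(out, list(kd = g$kd, hill = g$hill, inhib = g$inhib,
                         tau = g$tau))
    out
  }
  ser_ch <- function(ch) {
    list(kind = ch$kind, reversal = ch$reversal,
         density = as.list(ch$density), is_ca = ch$is_ca,
         modifiers = ch$modifiers,
         gates = lapply(ch$gates, ser_gate),
         markov = if (!is.null(ch$markov)) list(
           states = ch$markov$states,
           open_states = ch$markov$open_states,
           transitions = lapply(ch$markov$transitions, function(tr)
             list(from = tr$from, to = tr$to,
                  ca_power = if (is.null(tr$ca_power)) 0 else tr$ca_power,
                  rate = unclass(tr$rate)))))
  }
  cfg <- list(
    schema = "gcell-model-1",
    name = model$name,
    units = list(density = "mS/cm2", voltage = "mV", time = "ms",
                 concentration = "uM", ra = "Ohm cm", cm = "uF/cm2"),
    passive = unclass(model$passive),
    reversals = model$reversals,
    ca = unclass(model$ca),
    temperature = model$temperature,
    camp = model$camp,
    channels = lapply(model$channels, ser_ch))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, "gcell-model-1"))
    gc_error("config_bad_schema", "%s: unknown or missing schema tag", path)
  de_gate <- function(g, ch) {
    ok <- tryCatch({
      if (g$mode == "alphabeta")
        hh_gate(g$exponent, "alphabeta",
                alpha = do.call(rate_fn, g$alpha),
                beta = do.call(rate_fn, g$beta),
                q10 = g$q10, tref = g$tref)
      else if (g$mode == "cahill")
        hh_gate(g$exponent, "cahill", kd = g$kd, hill = g$hill,
                inhib = isTRUE(g$inhib), tau = g$tau$base,
                q10 = g$q10, tref = g$tref)
      else hh_gate(g$exponent, "inftau", vhalf = g$vhalf, k = g$k,
                   tau = g$tau, q10 = g$q10, tref = g$tref)
    }, error = function(e)
      gc_error("config_bad_gate", "channel %s: bad gate (%s)", ch,
               conditionMessage(e)))
    if (ok$mode %in% c("inftau", "cahill") && is.list(g$tau) &&
        !is.null(g$tau$amp))
      ok$tau <- g$tau
    ok
  }
  de_ch <- function(ch, nm) {
    d <- unlist(ch$density)
    if (is.null(d)) gc_error("config_bad_density",
                             "channel %s: missing density block", nm)
    mk <- NULL
    if (!is.null(ch$markov))
      mk <- markov_scheme(unlist(ch$markov$states),
                          lapply(ch$markov$transitions, function(tr)
                            list(from = tr$from, to = tr$to,
                                 ca_power = tr$ca_power,
                                 rate = do.call(rate_fn, tr$rate))),
                          unlist(ch$markov$open_states))
    channel_spec(nm, ch$kind, density = d,
                 reversal = if (is.character(ch$reversal)) ch$reversal
                            else as.numeric(ch$reversal),
                 gates = lapply(ch$gates, de_gate, ch = nm),
                 markov = mk, is_ca = isTRUE(ch$is_ca),
                 modifiers = if (length(ch$modifiers)) ch$modifiers
                             else list())
  }
  channels <- mapply(de_ch, cfg$channels, names(cfg$channels),
                     SIMPLIFY = FALSE)
  model_spec(cfg$name, unname(channels),
             passive = passive_spec(cfg$passive$ra, cfg$passive$cm),
             reversals = cfg$reversals,
             ca = ca_dynamics(cfg$ca$shell_depth, cfg$ca$kappa,
                              cfg$ca$decay_tau, cfg$ca$resting_ca),
             temperature = cfg$temperature, camp = cfg$camp)
}
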