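# Electrophysiology feature extraction: input resistance, capacitance,
# membrane time constant, AP features, fAHP, rheobase, ISI adaptation, Kir
# slope conductance, Ca-transient features and input/output ratios.
# Extractors work on plain (time, signal) vectors or on sim_result objects
# carrying their protocol metadata.

steady_window <- function(t, onset, duration, frac = 0.1) {
  t >= onset + duration * (1 - frac) & t < onset + duration
}

vc_step_meta <- function(x) {
  if (!inherits(x, "sim_result") || x$protocol$mode != "voltage_clamp")
    gc_error("ephys_no_step", "need a voltage-clamp sim_result with a step")
  s <- x$protocol$steps
  if (nrow(s) < 1) gc_error("ephys_no_step", "trace has no step metadata")
  list(onset = s$onset[1], duration = s$duration[1],
       level = s$amplitude[1], holding = x$protocol$holding)
}

#' Input resistance from a voltage-clamp step
#'
#' `R_in = dV / dI` with the current change taken as the mean electrode
#' current over the final 10% of the step window minus the pre-step steady
#' current (the canonical measurement uses a depolarizing 10 mV step, 200 ms
#' long, from a holding potential of -92.1 mV).
#'
#' @param x a voltage-clamp `sim_result` (see [run_voltage_clamp()]).
#' @return Input resistance, MOhm.
#' @export
input_resistance <- function(x) {
  m <- vc_step_meta(x)
  dv <- m$level - m$holding
  base <- mean(x$ielec[x$time >= m$onset - 20 & x$time < m$onset])
  ss <- mean(x$ielec[steady_window(x$time, m$onset, m$duration)])
  di <- ss - base
  if (abs(di) < 1e-12)
    gc_error("ephys_zero_current", "zero steady-state current change")
  dv / di   # mV / nA = MOhm
}

#' Membrane capacitance from a voltage-clamp step transient
#'
#' `c_m = integral(I - I_ss) dt / |dV|` over the step window, with `I_ss`
#' the steady current in the final 10% of the step (canonically a -10 mV
#' step).
#'
#' @param x a voltage-clamp `sim_result` including the transient.
#' @return Capacitance, pF.
#' @export
capacitance <- function(x) {
  m <- vc_step_meta(x)
  dv <- m$level - m$holding
  win <- x$time >= m$onset & x$time < m$onset + m$duration
  t <- x$time[win]; i <- x$ielec[win]
  base <- mean(x$ielec[x$time >= m$onset - 20 & x$time < m$onset])
  iss <- mean(x$ielec[steady_window(x$time, m$onset, m$duration)]) - base
  y <- (i - base) - iss
  q <- sum(diff(t) * (y[-1] + y[-length(y)]) / 2)   # nA ms = pC
  abs(q) / abs(dv) * 1e3                            # pC/mV -> pF
}

#' Membrane time constant from a current-clamp step
#'
#' Fits a single exponential `V = V_inf + a exp(-(t - t0)/tau)` to the
#' voltage relaxation following the step onset (canonically a 10 pA
#' hyperpolarizing 500 ms step from -80 mV); the fit window starts after a
#' latency that skips the fast equalization between compartments.
#'
#' @param t,v time (ms) and voltage (mV) vectors.
#' @param onset step onset, ms.
#' @param duration step duration, ms.
#' @param latency fit-window start after onset, ms (default 2).
#' @return Time constant, ms.
#' @export
membrane_tau <- function(t, v, onset = 0, duration = max(t) - onset,
                         latency = 2) {
  win <- t >= onset + latency & t < onset + duration
  tt <- t[win] - (onset + latency); vv <- v[win]
  if (length(tt) < 10 || diff(range(vv)) < 1e-9)
    gc_error("ephys_tau_flat", "no relaxation to fit")
  vinf0 <- mean(vv[tt > max(tt) * 0.9])
  a0 <- vv[1] - vinf0
  if (abs(a0) < 1e-9) gc_error("ephys_tau_flat", "no relaxation to fit")
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ vinf + a * exp(-tt / tau),
                      start = list(vinf = vinf0, a = a0, tau = max(tt) / 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) gc_error("ephys_tau_fit_failed", "%s",
                                 conditionMessage(e)))
  tau <- coef(fit)[["tau"]]
  if (tau <= 0) gc_error("ephys_tau_fit_failed", "nonpositive tau")
  tau
}

central_slope <- function(t, v) {
  n <- length(v)
  s <- numeric(n)
  s[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  s[1] <- s[2]; s[n] <- s[n - 1]
  s
}

spike_peaks <- function(t, v, threshold = 0) {
  n <- length(v)
  loc <- which(v[2:(n - 1)] >= threshold &
               v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  # one peak per threshold excursion
  if (!length(loc)) return(integer(0))
  keep <- c(TRUE, diff(t[loc]) > 1)
  loc[keep]
}

#' Action-potential features of the first spike
#'
#' The voltage threshold is the first sample in the 10 ms window preceding
#' the peak at which the slope `dV/dt` (central differences) exceeds
#' `slope_threshold`; the amplitude is peak minus threshold; the width is
#' measured at half that amplitude with linear interpolation at both
#' crossings; the maximal spike slope is the global `dV/dt` maximum.
#'
#' @param t,v time (ms) and voltage (mV) vectors containing at least one
#'   spike.
#' @param slope_threshold mV/ms (default 15).
#' @param peak_threshold minimum peak voltage to count as a spike, mV.
#' @return list: `V_threshold` (mV), `amplitude` (mV), `width` (ms),
#'   `max_slope` (V/s), `peak` (mV), `t_threshold`, `t_peak` (ms).
#' @export
ap_features <- function(t, v, slope_threshold = 15, peak_threshold = 0) {
  pk <- spike_peaks(t, v, peak_threshold)
  if (!length(pk)) gc_error("ephys_no_spike", "trace contains no spike")
  p <- pk[1]
  slope <- central_slope(t, v)
  pre <- which(t >= t[p] - 10 & t <= t[p])
  hit <- pre[slope[pre] > slope_threshold]
  if (!length(hit)) gc_error("ephys_no_spike", "no threshold crossing found")
  th <- hit[1]
  vthr <- v[th]; amp <- v[p] - vthr
  half <- vthr + amp / 2
  iu <- th + which(v[(th + 1):p] >= half)[1]        # upstroke crossing
  tu <- t[iu - 1] + (t[iu] - t[iu - 1]) * (half - v[iu - 1]) /
        (v[iu] - v[iu - 1])
  after <- p + which(v[(p + 1):length(v)] < half)[1]
  if (is.na(after)) gc_error("ephys_no_spike", "spike not repolarized")
  td <- t[after - 1] + (t[after] - t[after - 1]) * (half - v[after - 1]) /
        (v[after] - v[after - 1])
  list(V_threshold = vthr, amplitude = amp, width = td - tu,
       max_slope = max(slope), peak = v[p], t_threshold = t[th], t_peak = t[p])
}

#' Fast afterhyperpolarization
#'
#' Difference between the AP voltage threshold and the minimum voltage
#' between two consecutive APs (or after a lone AP), counted only when the
#' minimum occurs within `window` ms of the threshold; later minima are
#' medium AHPs and the feature is reported as absent (`NA`).
#'
#' @inheritParams ap_features
#' @param window ms (default 5).
#' @return fAHP in mV, or `NA` when the timing rule fails.
#' @export
fahp <- function(t, v, slope_threshold = 15, peak_threshold = 0, window = 5) {
  pk <- spike_peaks(t, v, peak_threshold)
  if (!length(pk)) gc_error("ephys_no_spike", "trace contains no spike")
  f <- ap_features(t, v, slope_threshold, peak_threshold)
  to <- if (length(pk) >= 2) pk[2] else length(v)
  seg <- (pk[1]):to
  rel <- which.min(v[seg])
  if (rel == length(seg) && length(pk) < 2) return(NA_real_)  # no minimum
  tmin <- t[seg[rel]]; vmin <- v[seg[rel]]
  if (tmin - f$t_threshold >= window) return(NA_real_)
  if (vmin >= f$V_threshold) return(NA_real_)   # no hyperpolarizing minimum
  f$V_threshold - vmin
}

#' Rheobase on a current grid
#'
#' Smallest amplitude on the grid (`grid_step`, `2*grid_step`, ...) that
#' elicits at least one spike during a 200 ms step from the holding
#' potential. `x` is either a spike-counting function `f(amplitude_pA)` or
#' a list `list(mesh =, model =)` simulated via [run_current_clamp()].
#'
#' @param x spike counter or `list(mesh, model)`.
#' @param grid_step pA (default 5).
#' @param i_max largest amplitude probed, pA.
#' @param holding mV.
#' @param duration step length, ms.
#' @return Rheobase in pA, or `NA` (attribute `flag = "no_spike"`) when the
#'   grid maximum elicits no spike.
#' @export
rheobase <- function(x, grid_step = 5, i_max = 200, holding = -80,
                     duration = 200) {
  if (grid_step <= 0) gc_error("ephys_bad_grid", "grid_step must be > 0")
  counter <- if (is.function(x)) x else function(amp) {
    pr <- protocol("current_clamp", holding = holding,
                   steps = data.frame(onset = 0, duration = duration,
                                      amplitude = amp))
    length(run_current_clamp(x$mesh, x$model, pr)$spikes)
  }
  for (amp in seq(grid_step, i_max, by = grid_step))
    if (counter(amp) >= 1) return(amp)
  structure(NA_real_, flag = "no_spike")
}

#' Interspike-interval features
#'
#' First ISI (delay between the first two AP maxima) and the adaptation
#' ratio `1 - first ISI / last ISI` (requires at least three spikes).
#'
#' @param spike_times sorted spike times, ms.
#' @return list: `first_isi` (ms, `NA` if < 2 spikes), `adaptation_ratio`
#'   (`NA` if < 3 spikes).
#' @export
isi_features <- function(spike_times) {
  isi <- diff(spike_times)
  list(first_isi = if (length(isi) >= 1) isi[1] else NA_real_,
       adaptation_ratio = if (length(isi) >= 2)
         1 - isi[1] / isi[length(isi)] else NA_real_)
}

#' Kir slope conductance from an I-V table
#'
#' Least-squares slope of the I-V relation over the hyperpolarized window
#' (-152.1 to -122.1 mV) minus the slope over the window where Kir channels
#' are largely closed (-82.1 to -62.1 mV).
#'
#' @param iv data.frame with `command_mV` and `current_nA`.
#' @param hyper,depol the two voltage windows, mV.
#' @return Slope-conductance difference, nS.
#' @export
gkir_from_iv <- function(iv, hyper = c(-152.1, -122.1),
                         depol = c(-82.1, -62.1)) {
  slope <- function(win) {
    sel <- iv$command_mV >= win[1] - 1e-9 & iv$command_mV <= win[2] + 1e-9
    if (sum(sel) < 2 || min(iv$command_mV) > win[1] + 1e-9 ||
        max(iv$command_mV) < win[2] - 1e-9)
      gc_error("ephys_window_not_covered",
               "I-V table does not cover [%g, %g] mV", win[1], win[2])
    coef(lm(current_nA ~ command_mV, data = iv[sel, ]))[[2]]   # uS
  }
  (slope(hyper) - slope(depol)) * 1e3   # nS
}

#' Calcium transient features
#'
#' Peak amplitude above the pre-event baseline, and the weighted decay time
#' constant from a biexponential fit to the decay
#' (`tau_w = (a1 tau1 + a2 tau2)/(a1 + a2)`).
#'
#' @param t,ca time (ms) and concentration (uM) vectors.
#' @return list: `peak` (uM above baseline), `weighted_tau` (ms).
#' @export
ca_transient_features <- function(t, ca) {
  p <- which.max(ca)
  # pre-event baseline; traces that start at the peak fall back to the
  # decayed tail
  base <- if (p > 5) min(ca[1:p]) else min(ca)
  peak <- ca[p] - base
  if (peak < 1e-9 || p >= length(ca) - 10)
    gc_error("ephys_ca_flat", "no identifiable transient")
  tt <- t[p:length(t)] - t[p]
  yy <- ca[p:length(ca)] - base
  th_i <- which(yy <= peak / 2)[1]
  tau0 <- if (!is.na(th_i)) tt[th_i] / log(2) else max(tt) / 3
  span <- max(tt)
  # free offset absorbs any un-decayed residual; time constants are bounded
  # by a multiple of the observation window to keep the fit identified
  resid_fn <- function(p)
    yy - (p[1] + p[2] * exp(-tt / p[3]) + p[4] * exp(-tt / p[5]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(c0 = 0, a1 = 0.7 * peak, tau1 = min(tau0, span / 2),
              a2 = 0.3 * peak, tau2 = min(4 * tau0, span)),
      fn = resid_fn,
      lower = c(-Inf, 0, 1e-3, 0, 1e-3),
      upper = c(Inf, Inf, 3 * span, Inf, 3 * span),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) gc_error("ephys_ca_fit_failed", "%s",
                                 conditionMessage(e)))
  if (!fit$info %in% 1:4)
    gc_error("ephys_ca_fit_failed", "fit did not converge (%s)", fit$message)
  cf <- fit$par
  if (cf[["a1"]] + cf[["a2"]] <= 0)
    gc_error("ephys_ca_fit_failed", "degenerate amplitudes")
  wt <- (cf[["a1"]] * cf[["tau1"]] + cf[["a2"]] * cf[["tau2"]]) /
        (cf[["a1"]] + cf[["a2"]])
  list(peak = peak, weighted_tau = wt)
}

#' Input/output spike ratio
#'
#' @param output_spikes number of postsynaptic spikes.
#' @param input_events number of presynaptic volleys (> 0).
#' @return Dimensionless ratio.
#' @export
io_ratio <- function(output_spikes, input_events) {
  if (input_events <= 0) gc_error("ephys_zero_inputs", "no input events")
  output_spikes / input_events
}
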