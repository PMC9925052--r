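#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Constructs the parameter set of the conductance-based adaptive exponential
#' integrate-and-fire (AdEx) neuron used throughout the package. The defaults
#' are the membrane, adaptation and synapse constants fitted to turtle-cortex
#' whole-cell recordings: capacitance and leak conductance from least-squares
#' fits of current-clamp traces, adaptation constants reproducing the median
#' experimental adaptation index, and the synaptic conductance decay constant
#' fitted to EPSP rise times.
#'
#' The membrane potential evolves as
#' \deqn{C \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T
#'   e^{(V - V_T)/\Delta_T} - g_e (V - E_e) - g_i (V - E_i) - w + I_e}
#' with adaptation current
#' \deqn{\tau_w \frac{dw}{dt} = a (V - E_L) - w,}
#' and exponentially decaying synaptic conductances \eqn{g_e, g_i} (time
#' constant `tau_syn`). A spike is detected when \eqn{V \ge} `V_detect`;
#' the membrane is then reset to `V_reset`, clamped there for `t_ref`
#' milliseconds, and \eqn{w} is incremented by `b`.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param V_T spike-initiation threshold (mV).
#' @param Delta_T slope factor (mV).
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param tau_w adaptation time constant (ms).
#' @param E_e,E_i excitatory / inhibitory reversal potentials (mV).
#' @param tau_syn synaptic conductance decay time constant (ms).
#' @param V_detect spike detection threshold (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' p$C
#' @export
neuron_params <- function(C = 239.8, g_L = 4.2, E_L = -70.6, V_T = -50.4,
                          Delta_T = 2, a = 4, b = 80.5, tau_w = 144,
                          E_e = 10, E_i = -75, tau_syn = 1.103681,
                          V_detect = 0, V_reset = -60, t_ref = 2) {
  p <- list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
            a = a, b = b, tau_w = tau_w, E_e = E_e, E_i = E_i,
            tau_syn = tau_syn, V_detect = V_detect, V_reset = V_reset,
            t_ref = t_ref)
  for (nm in names(p)) stop_if_not_scalar(p[[nm]], nm)
  if (C <= 0 || g_L <= 0 || tau_w <= 0 || tau_syn <= 0 || Delta_T <= 0)
    stop("C, g_L, tau_w, tau_syn and Delta_T must be positive")
  if (!(E_i < E_L && E_L < V_T && V_T < V_detect))
    stop("potentials must satisfy E_i < E_L < V_T < V_detect")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("AdEx neuron parameters\n")
  cat(sprintf("  C = %.4g pF, g_L = %.4g nS, E_L = %.4g mV (tau_m = %.3g ms)\n",
              x$C, x$g_L, x$E_L, x$C / x$g_L))
  cat(sprintf("  V_T = %.4g mV, Delta_T = %.4g mV, detect %.4g mV, reset %.4g mV\n",
              x$V_T, x$Delta_T, x$V_detect, x$V_reset))
  cat(sprintf("  a = %.4g nS, b = %.4g pA, tau_w = %.4g ms, t_ref = %.4g ms\n",
              x$a, x$b, x$tau_w, x$t_ref))
  cat(sprintf("  E_e = %.4g mV, E_i = %.4g mV, tau_syn = %.6g ms\n",
              x$E_e, x$E_i, x$tau_syn))
  invisible(x)
}

.adex_par <- function(p) {
  as.numeric(c(p$C, p$g_L, p$E_L, p$V_T, p$Delta_T, p$a, p$b, p$tau_w,
               p$E_e, p$E_i, p$tau_syn, p$V_detect, p$V_reset, p$t_ref))
}

#' Integrate a single AdEx neuron
#'
#' Fixed-step explicit integration (default dt = 0.1 ms) of one isolated
#' neuron under a piecewise-constant injected current and a list of synaptic
#' conductance events. The exponential term's argument is clamped at
#' `(V_detect - V_T) / Delta_T` to prevent overflow during the spike upswing.
#'
#' @param params a [neuron_params()] object.
#' @param drive injected current: a single number (constant, pA) or a
#'   data.frame with columns `time` (ms, first must be 0) and `current` (pA)
#'   interpreted as a step function.
#' @param events synaptic events: `NULL` or a data.frame with columns `time`
#'   (ms), `peak_conductance` (nS, > 0) and `sign` ("excitatory" or
#'   "inhibitory").
#' @param duration total simulated time (ms).
#' @param dt integration step (ms).
#' @param V0,w0 initial state; defaults to the leak reversal and the
#'   corresponding adaptation steady state.
#' @return A `voltage_trace`: list with `times`, `V`, `w` (each of length
#'   `duration/dt + 1`) and `spike_times`.
#' @examples
#' tr <- integrate_neuron(neuron_params(), drive = 200, duration = 500)
#' length(tr$spike_times)
#' @export
integrate_neuron <- function(params, drive = 0, events = NULL,
                             duration = 1000, dt = 0.1,
                             V0 = NULL, w0 = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  if (dt <= 0) stop("dt must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (is.numeric(drive) && length(drive) == 1L) {
    drive <- data.frame(time = 0, current = drive)
  }
  stopifnot(is.data.frame(drive), all(c("time", "current") %in% names(drive)))
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), peak_conductance = numeric(0),
                         sign = character(0))
  }
  stopifnot(all(c("time", "peak_conductance", "sign") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$peak_conductance < 0)) stop("peak_conductance must be >= 0")
    if (any(events$time < 0 | events$time > duration))
      stop("event times must lie within [0, duration]")
    events <- events[events$peak_conductance > 0, , drop = FALSE]
    events <- events[order(events$time), , drop = FALSE]
  }
  if (is.null(V0)) V0 <- params$E_L
  if (is.null(w0)) w0 <- params$a * (V0 - params$E_L)
  out <- .integrate_neuron_cpp(.adex_par(params), duration, dt,
                               drive$time, drive$current,
                               events$time, events$peak_conductance,
                               events$sign == "inhibitory", V0, w0)
  structure(list(times = out$times, V = out$V, w = out$w,
                 spike_times = out$spike_times, dt = dt),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage trace: %.4g ms at dt = %g ms, %d spike(s)\n",
              max(x$times), x$dt, length(x$spike_times)))
  invisible(x)
}

#' Rheobase of an isolated model neuron
#'
#' Minimal constant current eliciting at least one spike within
#' `trial_duration`, found to within `resolution` by bisection after a coarse
#' bracketing scan. Each probe is a fresh constant-current trial from rest.
#'
#' @param params a [neuron_params()] object.
#' @param trial_duration trial length (ms).
#' @param resolution required precision (pA).
#' @param lower,upper search bounds (pA).
#' @param dt integration step (ms).
#' @return The rheobase current (pA), the smallest multiple of `resolution`
#'   above `lower` that spikes.
#' @export
rheobase <- function(params, trial_duration = 1000, resolution = 1,
                     lower = 0, upper = 300, dt = 0.1) {
  stopifnot(inherits(params, "neuron_params"))
  if (resolution <= 0) stop("resolution must be positive")
  spikes_at <- function(I) {
    tr <- integrate_neuron(params, drive = I, duration = trial_duration, dt = dt)
    length(tr$spike_times) > 0
  }
  if (!spikes_at(upper))
    stop(sprintf("no spike at the upper search bound (%g pA)", upper))
  # coarse scan to bracket, then bisection
  coarse <- seq(lower, upper, length.out = 13)
  lo <- lower; hi <- upper
  for (k in seq_along(coarse)) {
    if (spikes_at(coarse[k])) {
      hi <- coarse[k]
      lo <- if (k > 1) coarse[k - 1] else lower
      break
    }
  }
  while (hi - lo > resolution) {
    mid <- (hi + lo) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  # snap up to the resolution grid anchored at `lower`
  lower + ceiling((hi - lower) / resolution - 1e-9) * resolution
}

#' Steady-state holding current for a target membrane potential
#'
#' Solves the joint steady state of the (V, w) subsystem: with
#' \eqn{w^\ast = a (V_h - E_L)}, the current that cancels leak, exponential
#' and adaptation terms at \eqn{V_h}.
#'
#' @param params a [neuron_params()] object.
#' @param V_hold target potential (mV), below `V_detect`.
#' @return Holding current (pA).
#' @export
holding_current <- function(params, V_hold) {
  stopifnot(inherits(params, "neuron_params"))
  if (V_hold >= params$V_detect) stop("holding potential must be below V_detect")
  ex <- params$g_L * params$Delta_T *
    exp(min((V_hold - params$V_T) / params$Delta_T,
            (params$V_detect - params$V_T) / params$Delta_T))
  params$g_L * (V_hold - params$E_L) - ex + params$a * (V_hold - params$E_L)
}

#' Postsynaptic potential amplitude of a single synaptic event
#'
#' Simulates an isolated neuron held at `holding_potential` by the
#' steady-state holding current, delivers a single synaptic conductance event
#' after an equilibration period, and returns the signed peak deflection of V
#' from the holding potential within `window` ms of the event. If the event
#' elicits a spike, the pre-spike extremum is returned and flagged via the
#' `"spike"` attribute.
#'
#' @param params a [neuron_params()] object.
#' @param peak_conductance event peak conductance (nS, >= 0).
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param holding_potential membrane potential at which the cell is held
#'   (mV); defaults to the leak reversal (rest).
#' @param window read-out window after the event (ms); PSPs decay well inside
#'   200 ms given tau_syn of ~1.1 ms and a ~57 ms membrane time constant.
#' @param dt integration step (ms).
#' @return Signed peak deflection (mV) with attribute `spike` (logical).
#' @examples
#' psp_amplitude(neuron_params(), 67.8, "excitatory")
#' @export
psp_amplitude <- function(params, peak_conductance,
                          sign = c("excitatory", "inhibitory"),
                          holding_potential = params$E_L,
                          window = 200, dt = 0.1) {
  stopifnot(inherits(params, "neuron_params"))
  sign <- match.arg(sign)
  if (peak_conductance < 0) stop("peak_conductance must be >= 0")
  if (holding_potential >= params$V_detect)
    stop("holding potential must be below V_detect")
  if (peak_conductance == 0) {
    return(structure(0, spike = FALSE))
  }
  equil <- 20
  Ih <- holding_current(params, holding_potential)
  tr <- integrate_neuron(
    params, drive = Ih,
    events = data.frame(time = equil, peak_conductance = peak_conductance,
                        sign = sign),
    duration = equil + window, dt = dt,
    V0 = holding_potential,
    w0 = params$a * (holding_potential - params$E_L))
  sel <- tr$times >= equil
  spiked <- length(tr$spike_times) > 0
  if (spiked) sel <- sel & tr$times < tr$spike_times[1]
  dv <- tr$V[sel] - holding_potential
  amp <- if (sign == "excitatory") max(dv) else min(dv)
  structure(amp, spike = spiked)
}

#' Adaptation index of a spike train
#'
#' Ratio of the last inter-spike interval to the first. For adapting cells
#' this ratio is >= 1; the reciprocal (first/last) is also reported because
#' both orientations are in experimental use.
#'
#' @param spike_times numeric vector of spike times (ms), at least 3 spikes.
#' @return Named vector with `last_over_first` and `first_over_last`.
#' @examples
#' adaptation_index(c(0, 10, 30, 70))
#' @export
adaptation_index <- function(spike_times) {
  if (length(spike_times) < 3)
    stop("insufficient data: at least 3 spikes are required")
  st <- sort(spike_times)
  isi <- diff(st)
  c(last_over_first = isi[length(isi)] / isi[1],
    first_over_last = isi[1] / isi[length(isi)])
}
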