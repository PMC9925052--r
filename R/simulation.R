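#' Background noise current specification
#'
#' Every neuron receives an independent current redrawn every
#' `refresh_interval` ms from a Gaussian \eqn{N(\mu_{in}, \sigma_{in})} and
#' held constant across the interval (piecewise-constant noise).
#'
#' @param mu_in mean current (pA); the explored regime spans roughly 50-110.
#' @param sigma_in current standard deviation (pA), 0-110.
#' @param refresh_interval redraw interval (ms).
#' @return A `background_noise` object.
#' @export
background_noise <- function(mu_in, sigma_in, refresh_interval = 1) {
  stopifnot(sigma_in >= 0, refresh_interval > 0)
  structure(list(mu_in = mu_in, sigma_in = sigma_in,
                 refresh_interval = refresh_interval),
            class = "background_noise")
}

#' Single-spike trigger protocol
#'
#' Defines the trial structure: after a kick-start volley (forced spikes in
#' `kickstart_count` random excitatory neurons within the first
#' `kickstart_window` ms) and a discarded settling period, the trigger
#' neuron(s) are forced to spike every `inter_trial` ms for `n_trials`
#' trials. Each trial has a baseline window (`before_window` ms before the
#' trigger spike) and a response window (`after_window` ms after it).
#' Multiple trigger ids are coactivated in the same integration step.
#'
#' @param trigger_ids neuron id(s) forced to spike at each trial onset; must
#'   be excitatory.
#' @param n_trials number of trials.
#' @param inter_trial trial spacing (ms).
#' @param kickstart_count,kickstart_window size and window (ms) of the
#'   kick-start volley.
#' @param discard initial period removed from the record (ms).
#' @param before_window,after_window analysis windows (ms);
#'   their sum must not exceed `inter_trial`.
#' @return A `trigger_protocol` object.
#' @export
trigger_protocol <- function(trigger_ids, n_trials = 100, inter_trial = 400,
                             kickstart_count = 500, kickstart_window = 100,
                             discard = 1000, before_window = 100,
                             after_window = 300) {
  stopifnot(length(trigger_ids) >= 0, n_trials >= 1, inter_trial > 0,
            before_window > 0, after_window > 0,
            before_window + after_window <= inter_trial,
            kickstart_count >= 0, kickstart_window > 0, discard >= 0)
  structure(list(trigger_ids = as.integer(trigger_ids), n_trials = n_trials,
                 inter_trial = inter_trial, kickstart_count = kickstart_count,
                 kickstart_window = kickstart_window, discard = discard,
                 before_window = before_window, after_window = after_window),
            class = "trigger_protocol")
}

#' External synaptic input specification
#'
#' A single extra conductance event from a virtual external source, applied
#' once per trial at `delta_t` ms relative to the trigger spike.
#'
#' @param target target neuron id.
#' @param peak_conductance conductance jump (nS).
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param delta_t delay from trigger spike to the input (ms; may be
#'   negative).
#' @return An `external_input` object.
#' @export
external_input <- function(target, peak_conductance,
                           sign = c("excitatory", "inhibitory"), delta_t) {
  sign <- match.arg(sign)
  stopifnot(peak_conductance >= 0)
  structure(list(target = as.integer(target),
                 peak_conductance = peak_conductance, sign = sign,
                 delta_t = delta_t),
            class = "external_input")
}

.trial_onsets <- function(protocol) {
  protocol$discard + (seq_len(protocol$n_trials) - 1) * protocol$inter_trial +
    protocol$before_window
}

#' Run the trigger-trial protocol on a network
#'
#' Clock-driven integration of the whole network (fixed step, default
#' 0.1 ms): presynaptic spikes are delivered to their targets as conductance
#' jumps after the per-edge delay (rounded to the grid); trigger neurons are
#' forced to spike at each trial onset (a forced spike runs the full spike
#' lifecycle: recorded spike, reset, refractory clamp and adaptation
#' increment); a kick-start volley seeds activity and the initial `discard`
#' ms are dropped from the record.
#'
#' @param net a `network_model`.
#' @param noise a [background_noise()].
#' @param protocol a [trigger_protocol()].
#' @param externals list of [external_input()] objects.
#' @param params neuron parameters shared by all neurons.
#' @param seed optional RNG seed.
#' @param dt integration step (ms).
#' @param runaway_frac fraction of neurons spiking in a single step above
#'   which the record is flagged as runaway (the simulation continues).
#' @return A `spike_record`: `spikes` is a data.frame with `trial`,
#'   `neuron`, and `time` in ms relative to the trigger spike (negative in
#'   the baseline window).
#' @export
run_protocol <- function(net, noise, protocol, externals = list(),
                         params = neuron_params(), seed = NULL, dt = 0.1,
                         runaway_frac = 0.1) {
  stopifnot(inherits(net, "network_model"),
            inherits(noise, "background_noise"),
            inherits(protocol, "trigger_protocol"))
  if (length(protocol$trigger_ids) > 0) {
    if (any(protocol$trigger_ids < 1 | protocol$trigger_ids > net$n_neurons))
      stop("trigger ids outside the network")
    if (any(net$neurons$population[protocol$trigger_ids] != "E"))
      stop("trigger neurons must be excitatory")
  }
  for (ex in externals) {
    stopifnot(inherits(ex, "external_input"))
    if (ex$target < 1 || ex$target > net$n_neurons)
      stop("external input target outside the network")
  }
  with_seed(seed, {
    is_exc <- net$neurons$population == "E"
    syn <- net$synapses
    ord <- order(syn$pre)
    ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = net$n_neurons)))
    dstep <- pmax(1L, as.integer(round(syn$delay[ord] / dt)))
    onsets <- .trial_onsets(protocol)
    total <- protocol$discard + protocol$n_trials * protocol$inter_trial
    n_steps <- as.integer(round(total / dt))
    # forced spikes: kick-start volley + trigger coactivations
    ks_ids <- integer(0); ks_t <- numeric(0)
    if (protocol$kickstart_count > 0) {
      ks_ids <- sample(which(is_exc), protocol$kickstart_count)
      ks_t <- runif(protocol$kickstart_count, 0, protocol$kickstart_window)
    }
    f_n <- c(ks_ids, rep(protocol$trigger_ids, times = protocol$n_trials))
    f_t <- c(ks_t, rep(onsets, each = length(protocol$trigger_ids)))
    f_s <- as.integer(round(f_t / dt))
    o <- order(f_s)
    # external inputs, expanded per trial
    e_s <- integer(0); e_tg <- integer(0); e_g <- numeric(0); e_i <- logical(0)
    for (ex in externals) {
      st <- as.integer(round((onsets + ex$delta_t) / dt))
      ok <- st >= 0 & st < n_steps
      e_s <- c(e_s, st[ok])
      e_tg <- c(e_tg, rep(ex$target - 1L, sum(ok)))
      e_g <- c(e_g, rep(ex$peak_conductance, sum(ok)))
      e_i <- c(e_i, rep(ex$sign == "inhibitory", sum(ok)))
    }
    eo <- order(e_s)
    out <- .simulate_network_cpp(
      .adex_par(params),
      net$n_neurons, is_exc,
      ptr, syn$post[ord] - 1L, syn$weight[ord], dstep,
      dt, n_steps, noise$mu_in, noise$sigma_in,
      max(1L, as.integer(round(noise$refresh_interval / dt))),
      f_s[o], f_n[o] - 1L,
      e_s[eo], e_tg[eo], e_g[eo], e_i[eo],
      record_from = as.integer(round(protocol$discard / dt)),
      runaway_frac = runaway_frac)
    t_abs <- out$step * dt
    trial <- pmin(protocol$n_trials,
                  floor((t_abs - protocol$discard) / protocol$inter_trial) + 1L)
    time <- t_abs - onsets[trial]
    if (out$runaway)
      warning(sprintf("runaway activity flagged at t = %.1f ms",
                      out$runaway_step * dt))
    structure(list(
      spikes = data.frame(trial = as.integer(trial), neuron = out$neuron,
                          time = time),
      n_neurons = net$n_neurons, population = net$neurons$population,
      protocol = protocol, noise = noise, externals = externals,
      dt = dt, runaway = out$runaway, seed = seed,
      fingerprint = network_fingerprint(net)),
      class = "spike_record")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike record: %d spikes, %d neurons, %d trials of %g ms\n",
              nrow(x$spikes), x$n_neurons, x$protocol$n_trials,
              x$protocol$inter_trial))
  if (isTRUE(x$runaway)) cat("  (runaway activity flagged)\n")
  invisible(x)
}

#' Mean baseline firing rate
#'
#' Mean firing rate over neurons during the baseline windows (the
#' `before_window` ms preceding each trigger spike).
#'
#' @param rec a `spike_record`.
#' @param protocol trial structure; defaults to the one stored in `rec`.
#' @param population `NULL` for all neurons, or `"E"` / `"I"`.
#' @return Rate in spikes per second.
#' @export
mean_firing_rate <- function(rec, protocol = rec$protocol, population = NULL) {
  stopifnot(inherits(rec, "spike_record"))
  if (protocol$n_trials < 1) stop("record contains no trials")
  sel <- rec$spikes$time >= -protocol$before_window & rec$spikes$time < 0
  n_pop <- rec$n_neurons
  if (!is.null(population)) {
    sel <- sel & rec$population[rec$spikes$neuron] == population
    n_pop <- sum(rec$population == population)
  }
  total_s <- n_pop * protocol$n_trials * protocol$before_window / 1000
  sum(sel) / total_s
}

#' Instantaneous firing-rate estimate
#'
#' Gaussian-kernel rate estimate per neuron over the recorded span. The time
#' integral of each neuron's rate equals its spike count up to kernel mass
#' lost at the record edges.
#'
#' @param rec a `spike_record`.
#' @param window_sd Gaussian kernel standard deviation (ms).
#' @param neurons neuron ids to estimate (default: neurons with spikes).
#' @param resolution output grid step (ms).
#' @return List with `times` (ms, absolute within the recorded span) and
#'   `rate` (neurons x times matrix, spikes/s).
#' @export
instantaneous_rate <- function(rec, window_sd = 250, neurons = NULL,
                               resolution = 10) {
  stopifnot(inherits(rec, "spike_record"), window_sd > 0)
  p <- rec$protocol
  t_abs <- (rec$spikes$trial - 1) * p$inter_trial + p$before_window +
    rec$spikes$time
  span <- p$n_trials * p$inter_trial
  grid <- seq(0, span, by = resolution)
  if (is.null(neurons)) neurons <- sort(unique(rec$spikes$neuron))
  rate <- matrix(0, nrow = length(neurons), ncol = length(grid),
                 dimnames = list(neurons, NULL))
  for (k in seq_along(neurons)) {
    st <- t_abs[rec$spikes$neuron == neurons[k]]
    if (length(st) == 0) next
    for (s in st) rate[k, ] <- rate[k, ] + dnorm(grid, s, window_sd)
  }
  list(times = grid, rate = rate * 1000) # per ms -> per s
}
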