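#' Synthetic current-clamp traces for membrane-fit recovery
#'
#' Generates subthreshold voltage responses of the passive membrane (leak
#' only) to constant current steps, plus additive Gaussian noise. The ground
#' truth is recorded alongside, so recovery tests never read it during
#' estimation.
#'
#' @param g_L,C true leak conductance (nS) and capacitance (pF).
#' @param currents step amplitudes (pA); each must keep the passive steady
#'   state below the spike threshold.
#' @param noise_sd additive voltage noise SD (mV).
#' @param t_on step onset (ms).
#' @param duration trace duration (ms).
#' @param dt sample interval (ms).
#' @param params parameters supplying the resting potential and threshold.
#' @param seed RNG seed.
#' @return List of `voltage_trace`s (fields `times`, `V`) with attributes
#'   `truth` (g_L, C) and `currents`.
#' @export
make_patch_traces <- function(g_L = 4.2, C = 239.8, currents = c(-50, 25, 50),
                              noise_sd = 0.5, t_on = 100, duration = 1000,
                              dt = 0.1, params = neuron_params(), seed = NULL) {
  stopifnot(length(currents) > 0, noise_sd >= 0, t_on > 0, duration > t_on)
  tau <- C / g_L
  for (I in currents)
    if (params$E_L + I / g_L >= params$V_T)
      stop(sprintf("current %g pA drives the passive trace above threshold", I))
  with_seed(seed, {
    times <- seq(0, duration, by = dt)
    traces <- lapply(currents, function(I) {
      V <- rep(params$E_L, length(times))
      on <- times >= t_on
      V[on] <- params$E_L + (I / g_L) * (1 - exp(-(times[on] - t_on) / tau))
      if (noise_sd > 0) V <- V + rnorm(length(V), 0, noise_sd)
      structure(list(times = times, V = V), class = "voltage_trace")
    })
    attr(traces, "truth") <- c(g_L = g_L, C = C)
    attr(traces, "currents") <- currents
    attr(traces, "t_on") <- t_on
    traces
  })
}

#' Synthetic EPSP amplitude set
#'
#' Draws peak conductances from the truncated lognormal and maps them to
#' EPSP amplitudes at the resting potential, emulating an experimentally
#' obtained amplitude set. Amplitudes are bounded by the PSP of the
#' truncation conductance (about 21 mV).
#'
#' @param n number of amplitudes (the emulated sets have 122 or 382).
#' @param dist a [weight_distribution()].
#' @param params neuron parameters.
#' @param seed RNG seed.
#' @return Amplitudes (mV) with attribute `conductances` (ground truth, nS).
#' @export
make_amplitude_set <- function(n = 122, dist = weight_distribution(),
                               params = neuron_params(), seed = NULL) {
  stopifnot(n > 0)
  g <- sample_weights(n, dist, "E", seed = seed)
  grid_g <- seq(0, dist$truncation_max, length.out = 200)
  grid_a <- vapply(grid_g, function(x)
    as.numeric(psp_amplitude(params, x, "excitatory")), numeric(1))
  amps <- splinefun(grid_g, grid_a, method = "hyman")(g)
  attr(amps, "conductances") <- g
  amps
}

#' Scaled-down fixture network
#'
#' Builds a reduced network that preserves the full model's neuron density
#' (side scales with the square root of the neuron count) and its absolute
#' out-degree targets, so the expected number of strong (top 0.3%) E-to-E
#' connections per neuron stays near 2 -- the regime sequence propagation
#' depends on -- rather than shrinking with network size.
#'
#' @param n_neurons fixture size.
#' @param targets out-degree targets per pair.
#' @param sigma connection-profile widths (um).
#' @param full_n,full_side the full-scale geometry that sets the density.
#' @param fraction_excitatory excitatory fraction.
#' @param weights weight distribution.
#' @param seed RNG seed.
#' @return A `network_model` with attribute `fixture_spec`.
#' @export
make_fixture_network <- function(n_neurons = 10000,
                                 targets = c(ee = 750, ei = 190,
                                             ie = 2690, ii = 110),
                                 sigma = c(ee = 150, ei = 150,
                                           ie = 150, ii = 120),
                                 full_n = 1e5, full_side = 2000,
                                 fraction_excitatory = 0.93,
                                 weights = weight_distribution(),
                                 seed = NULL) {
  stopifnot(n_neurons > 1)
  side <- full_side * sqrt(n_neurons / full_n)
  profile <- calibrate_profile(sigma = sigma, targets = targets,
                               n_neurons = n_neurons, side = side,
                               fraction_excitatory = fraction_excitatory)
  net <- build_network(n_neurons, side,
                       fraction_excitatory = fraction_excitatory,
                       profile = profile, weights = weights, seed = seed)
  attr(net, "fixture_spec") <- list(n_neurons = n_neurons, side = side,
                                    scale = n_neurons / full_n,
                                    targets = targets, sigma = sigma,
                                    seed = seed)
  net
}

#' Trial-structured Poisson spike record with optional planted followers
#'
#' Generates homogeneous Poisson spiking per neuron over the baseline and
#' response window of every trial, mimicking the `spike_record` layout.
#' Planted followers additionally emit one deterministic response spike per
#' trial with a given probability, at a fixed latency plus Gaussian jitter,
#' providing ground truth for follower-detection calibration.
#'
#' @param n_neurons number of neurons (all excitatory unless
#'   `fraction_excitatory < 1`).
#' @param rate baseline Poisson rate (spikes/s), `>= 0`.
#' @param protocol a [trigger_protocol()].
#' @param planted data.frame with columns `neuron`, `prob`, `latency`,
#'   `jitter` describing planted followers (optional).
#' @param fraction_excitatory excitatory fraction.
#' @param seed RNG seed.
#' @return A `spike_record` with attribute `planted`.
#' @export
make_poisson_record <- function(n_neurons, rate, protocol, planted = NULL,
                                fraction_excitatory = 1, seed = NULL) {
  stopifnot(rate >= 0, inherits(protocol, "trigger_protocol"))
  with_seed(seed, {
    span <- protocol$before_window + protocol$after_window
    lam <- rate * span / 1000
    n_sp <- rpois(n_neurons * protocol$n_trials, lam)
    tot <- sum(n_sp)
    trial <- rep(rep(seq_len(protocol$n_trials), each = n_neurons), n_sp)
    neuron <- rep(rep(seq_len(n_neurons), protocol$n_trials), n_sp)
    time <- runif(tot, -protocol$before_window, protocol$after_window)
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        hit <- runif(protocol$n_trials) < planted$prob[i]
        if (!any(hit)) next
        t_resp <- planted$latency[i] +
          rnorm(sum(hit), 0, planted$jitter[i] %||% 0)
        t_resp <- pmin(pmax(t_resp, 1e-3), protocol$after_window)
        trial <- c(trial, which(hit))
        neuron <- c(neuron, rep(planted$neuron[i], sum(hit)))
        time <- c(time, t_resp)
      }
    }
    n_e <- round(n_neurons * fraction_excitatory)
    rec <- structure(list(
      spikes = data.frame(trial = as.integer(trial),
                          neuron = as.integer(neuron), time = time),
      n_neurons = n_neurons,
      population = rep(c("E", "I"), c(n_e, n_neurons - n_e)),
      protocol = protocol, noise = NULL, externals = list(),
      dt = NA_real_, runaway = FALSE, seed = seed, fingerprint = NULL),
      class = "spike_record")
    attr(rec, "planted") <- planted
    rec
  })
}
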