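# Independent single-neuron AdEx oracle: a deliberately plain forward-Euler
# integrator written separately from the package's C++ kernel, used to
# validate the engine. Events are conductance jumps applied at the start of
# the step containing their time; refractory pins V at the reset value while
# w and the conductances keep evolving; the exponential argument is clamped
# at its value for V = V_detect.
oracle_adex <- function(dur, dt, I = function(t) 0, events = NULL,
                        V0 = -70.6, w0 = NULL,
                        C = 239.8, gL = 4.2, EL = -70.6, VT = -50.4, DT = 2,
                        a = 4, b = 80.5, tw = 144, Ee = 10, Ei = -75,
                        ts = 1.103681, Vdet = 0, Vres = -60, tref = 2) {
  n <- round(dur / dt)
  V <- V0
  w <- if (is.null(w0)) a * (V0 - EL) else w0
  ge <- 0; gi <- 0; refu <- -Inf
  dec <- exp(-dt / ts)
  spk <- c(); Vtr <- numeric(n); tt <- (1:n) * dt
  evt <- if (!is.null(events)) events$t else numeric(0)
  evg <- if (!is.null(events)) events$g else numeric(0)
  evs <- if (!is.null(events)) events$sign else character(0)
  ei <- 1
  clampexp <- (Vdet - VT) / DT
  for (k in 1:n) {
    t <- k * dt
    while (ei <= length(evt) && evt[ei] <= t - dt + 1e-12) {
      if (evs[ei] == "e") ge <- ge + evg[ei] else gi <- gi + evg[ei]
      ei <- ei + 1
    }
    if (t <= refu) {
      Vn <- Vres
    } else {
      ex <- gL * DT * exp(min((V - VT) / DT, clampexp))
      Vn <- V + dt / C *
        (-gL * (V - EL) + ex - ge * (V - Ee) - gi * (V - Ei) - w + I(t))
    }
    wn <- w + dt / tw * (a * (V - EL) - w)
    ge <- ge * dec; gi <- gi * dec
    V <- Vn; w <- wn
    if (V >= Vdet && t > refu) {
      spk <- c(spk, t); V <- Vres; w <- w + b; refu <- t + tref
    }
    Vtr[k] <- V
  }
  list(t = tt, V = Vtr, spikes = spk)
}

# Hand-built network_model for engine and analysis tests: explicit synapse
# table on a small set of neurons with given positions.
toy_network <- function(pre, post, weight, delay, population,
                        x = NULL, y = NULL, side = 100) {
  n <- length(population)
  neurons <- data.frame(
    x = x %||% seq(10, 90, length.out = n),
    y = y %||% rep(50, n),
    population = factor(population, levels = c("E", "I")))
  structure(list(n_neurons = n, side = side, neurons = neurons,
                 synapses = data.frame(pre = as.integer(pre),
                                       post = as.integer(post),
                                       weight = weight, delay = delay),
                 profile = NULL, weights = NULL, seed = NULL),
            class = "network_model")
}

# Hand-built spike_record for analysis tests.
toy_record <- function(spikes, n_neurons, protocol,
                       population = rep("E", n_neurons),
                       fingerprint = NULL) {
  structure(list(spikes = spikes, n_neurons = n_neurons,
                 population = population, protocol = protocol,
                 noise = NULL, externals = list(), dt = NA_real_,
                 runaway = FALSE, seed = NULL, fingerprint = fingerprint),
            class = "spike_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixture network and low-noise record, built once per test run and
# reused by the simulation, follower, transfer, subnetwork and acceptance
# suites (building is the expensive part).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- make_fixture_network(seed = 11)
      trig <- which(net$neurons$population == "E")[1]
      protocol <- trigger_protocol(trig, n_trials = 10)
      rec <- run_protocol(net, background_noise(90, 30), protocol, seed = 21)
      cache <<- list(net = net, protocol = protocol, rec = rec,
                     report = detect_followers(rec))
    }
    cache
  }
})
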