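test_that("protocol construction validates its trial structure", {
  expect_error(trigger_protocol(1, before_window = 200, after_window = 300,
                                inter_trial = 400))
  expect_error(trigger_protocol(1, n_trials = 0))
  p <- trigger_protocol(5L)
  expect_equal(p$n_trials, 100)
  expect_equal(p$inter_trial, 400)
  expect_equal(p$before_window, 100)
  expect_equal(p$after_window, 300)
  expect_equal(p$kickstart_count, 500)
  expect_equal(p$discard, 1000)
})

test_that("forced trigger spikes appear at time zero in every trial", {
  net <- toy_network(pre = 1, post = 2, weight = 1, delay = 1,
                     population = c("E", "E"))
  pro <- trigger_protocol(1, n_trials = 5, kickstart_count = 0)
  rec <- run_protocol(net, background_noise(0, 0), pro, seed = 1)
  trig <- rec$spikes[rec$spikes$neuron == 1, ]
  expect_equal(nrow(trig), 5)
  expect_setequal(trig$trial, 1:5)
  expect_true(all(abs(trig$time) < 1e-9))
})

test_that("trigger neurons must be excitatory and inside the network", {
  net <- toy_network(pre = 1, post = 2, weight = 1, delay = 1,
                     population = c("E", "I"))
  expect_error(run_protocol(net, background_noise(0, 0),
                            trigger_protocol(2, n_trials = 1)),
               "excitatory")
  expect_error(run_protocol(net, background_noise(0, 0),
                            trigger_protocol(7, n_trials = 1)),
               "outside")
})

test_that("synaptic propagation through a chain matches the oracle", {
  # 1 -> 2 -> 3 chain with a conductance strong enough to fire the target
  # from rest; delays 1.5 ms each.
  g <- 150
  net <- toy_network(pre = c(1, 2), post = c(2, 3), weight = c(g, g),
                     delay = c(1.5, 1.5), population = c("E", "E", "E"))
  pro <- trigger_protocol(1, n_trials = 3, kickstart_count = 0,
                          discard = 100)
  rec <- run_protocol(net, background_noise(0, 0), pro, seed = 2,
                      runaway_frac = 1.01)
  sp <- rec$spikes
  expect_setequal(unique(sp$neuron), 1:3)
  # oracle: single neuron at rest receiving g at t = 1.5 ms
  or <- oracle_adex(60, 0.1, events = list(t = 1.5, g = g, sign = "e"))
  expect_equal(length(or$spikes), 1)
  lat2 <- sp$time[sp$neuron == 2 & sp$trial == 1]
  expect_equal(lat2, or$spikes[1], tolerance = 1e-9)
  # neuron 3 receives its event one spike latency + delay later
  lat3 <- sp$time[sp$neuron == 3 & sp$trial == 1]
  or3 <- oracle_adex(60, 0.1, events = list(t = lat2 + 1.5, g = g,
                                            sign = "e"))
  expect_equal(lat3, or3$spikes[1], tolerance = 1e-9)
})

test_that("noise-driven spiking matches the oracle for one isolated neuron", {
  # one neuron, no synapses: the engine's piecewise-constant noise can be
  # replayed through the oracle by extracting the same current sequence from
  # a deterministic strong drive alternative -- instead, check the
  # statistics: supra-rheobase constant noise (sigma = 0) must reproduce the
  # deterministic oracle exactly.
  net <- toy_network(pre = integer(0), post = integer(0), weight = numeric(0),
                     delay = numeric(0), population = c("E", "E"))
  pro <- trigger_protocol(integer(0), n_trials = 2, kickstart_count = 0,
                          discard = 0)
  rec <- run_protocol(net, background_noise(200, 0), pro, seed = 3,
                      runaway_frac = 1.01)
  or <- oracle_adex(800, 0.1, I = function(t) 200)
  sp <- rec$spikes
  t_abs <- (sp$trial - 1) * 400 + 100 + sp$time
  for (n in 1:2)
    expect_equal(sort(t_abs[sp$neuron == n]), or$spikes, tolerance = 1e-9)
})

test_that("simulation is deterministic under a fixed seed", {
  net <- shared_fixture()$net
  pro <- trigger_protocol(which(net$neurons$population == "E")[1],
                          n_trials = 2, discard = 200)
  r1 <- run_protocol(net, background_noise(90, 30), pro, seed = 7)
  r2 <- run_protocol(net, background_noise(90, 30), pro, seed = 7)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_protocol(net, background_noise(90, 30), pro, seed = 8)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("external inputs are delivered at the configured trial offset", {
  net <- toy_network(pre = integer(0), post = integer(0), weight = numeric(0),
                     delay = numeric(0), population = c("E", "E"))
  pro <- trigger_protocol(1, n_trials = 4, kickstart_count = 0, discard = 100)
  ext <- external_input(2, 150, "excitatory", delta_t = 50)
  rec <- run_protocol(net, background_noise(0, 0), pro, externals = list(ext),
                      seed = 4, runaway_frac = 1.01)
  sp <- rec$spikes[rec$spikes$neuron == 2, ]
  expect_equal(nrow(sp), 4)
  # oracle latency of a 150 nS event
  or <- oracle_adex(60, 0.1, events = list(t = 0.1, g = 150, sign = "e"))
  expect_equal(sp$time, rep(50 - 0.1 + or$spikes[1], 4), tolerance = 1e-9)
})

test_that("runaway activity is flagged but the record is returned", {
  net <- toy_network(pre = c(1, 2), post = c(2, 3), weight = c(150, 150),
                     delay = c(1, 1), population = c("E", "E", "E"))
  pro <- trigger_protocol(1, n_trials = 1, kickstart_count = 0, discard = 0)
  expect_warning(
    rec <- run_protocol(net, background_noise(0, 0), pro, seed = 5,
                        runaway_frac = 0.2),
    "runaway")
  expect_true(rec$runaway)
})

test_that("baseline firing rate matches a hand count", {
  pro <- trigger_protocol(1L, n_trials = 2)
  sp <- data.frame(trial = c(1, 1, 2, 2, 2),
                   neuron = c(2, 3, 2, 2, 4),
                   time = c(-50, -10, -99, 20, 150))
  rec <- toy_record(sp, 4, pro, population = c("E", "E", "E", "I"))
  # 3 baseline spikes (time < 0) over 4 neurons x 2 trials x 0.1 s
  expect_equal(mean_firing_rate(rec), 3 / (4 * 2 * 0.1))
  # E only: spikes from neurons 2, 3 -> all 3 baseline spikes, 3 E neurons
  expect_equal(mean_firing_rate(rec, population = "E"), 3 / (3 * 2 * 0.1))
  expect_equal(mean_firing_rate(rec, population = "I"), 0)
})

test_that("instantaneous rate integrates to the spike count", {
  pro <- trigger_protocol(1L, n_trials = 3)
  sp <- data.frame(trial = c(1, 2, 3), neuron = 2, time = c(10, 15, 12))
  rec <- toy_record(sp, 2, pro)
  ir <- instantaneous_rate(rec, window_sd = 40, neurons = 2, resolution = 1)
  integral <- sum(ir$rate[1, ]) * 1 / 1000 # rate in spk/s, grid 1 ms
  expect_equal(integral, 3, tolerance = 0.01)
})
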