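# brute-force O(spikes^2 x synapses) transfer-edge oracle
oracle_edges <- function(spikes, synapses, window = 100) {
  out <- list()
  for (a in seq_len(nrow(spikes))) for (b in seq_len(nrow(spikes))) {
    if (spikes$trial[a] != spikes$trial[b]) next
    dt <- spikes$time[b] - spikes$time[a]
    if (dt <= 0 || dt > window) next
    hit <- synapses$pre == spikes$neuron[a] & synapses$post == spikes$neuron[b]
    for (s in which(hit))
      out[[length(out) + 1]] <- c(a, b, synapses$weight[s])
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}

make_graph_fixture <- function(seed = 1, n = 8, n_spikes = 20, window = 100) {
  set.seed(seed)
  net <- toy_network(pre = sample(n, 12, TRUE), post = sample(n, 12, TRUE),
                     weight = runif(12, 1, 60), delay = runif(12, 0.5, 2),
                     population = sample(c("E", "I"), n, TRUE, c(0.7, 0.3)))
  net$synapses <- net$synapses[net$synapses$pre != net$synapses$post, ]
  pro <- trigger_protocol(which(net$neurons$population == "E")[1],
                          n_trials = 3)
  sp <- data.frame(trial = sample(3, n_spikes, TRUE),
                   neuron = sample(n, n_spikes, TRUE),
                   time = round(runif(n_spikes, -90, 290), 1))
  rec <- toy_record(sp, n, pro, population = as.character(net$neurons$population),
                    fingerprint = spikeroute:::network_fingerprint(net))
  list(net = net, rec = rec)
}

test_that("no synapses means no transfer edges", {
  net <- toy_network(integer(0), integer(0), numeric(0), numeric(0),
                     population = c("E", "E"))
  pro <- trigger_protocol(1L, n_trials = 1)
  rec <- toy_record(data.frame(trial = c(1, 1), neuron = c(1, 2),
                               time = c(0, 5)),
                    2, pro, fingerprint = spikeroute:::network_fingerprint(net))
  g <- build_transfer_graph(rec, net)
  expect_equal(nrow(g$edges), 0)
})

test_that("convergent spikes create one edge per presynaptic spike", {
  net <- toy_network(pre = c(1, 2), post = c(3, 3), weight = c(10, 20),
                     delay = c(1, 1), population = c("E", "E", "E"))
  pro <- trigger_protocol(1L, n_trials = 1)
  rec <- toy_record(data.frame(trial = 1, neuron = c(1, 2, 3),
                               time = c(0, 2, 5)),
                    3, pro, fingerprint = spikeroute:::network_fingerprint(net))
  g <- build_transfer_graph(rec, net)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$post_neuron == 3))
  expect_setequal(g$edges$delay, c(5, 3))
  # acyclic by construction: all delays positive
  expect_true(all(g$edges$delay > 0 & g$edges$delay <= 100))
})

test_that("random rasters match the brute-force all-pairs oracle", {
  for (seed in 1:3) {
    fx <- make_graph_fixture(seed)
    g <- build_transfer_graph(fx$rec, fx$net)
    ref <- oracle_edges(g$nodes[order(g$nodes$id), c("trial", "neuron", "time")],
                        fx$net$synapses)
    got <- g$edges[order(g$edges$pre, g$edges$post, g$edges$weight), ]
    ref <- ref[order(ref[, 1], ref[, 2], ref[, 3]), , drop = FALSE]
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$pre, as.integer(ref[, 1]))
    expect_equal(got$post, as.integer(ref[, 2]))
    expect_equal(got$weight, ref[, 3])
  }
})

test_that("fingerprint mismatch raises a consistency error", {
  fx <- make_graph_fixture(1)
  other <- fx$net
  other$synapses$weight[1] <- other$synapses$weight[1] + 1
  expect_error(build_transfer_graph(fx$rec, other), "fingerprint")
})

test_that("delay distribution reports mode and matches direct tabulation", {
  net <- toy_network(pre = c(1, 1), post = c(2, 3), weight = c(5, 5),
                     delay = c(1, 1), population = c("E", "E", "E"))
  pro <- trigger_protocol(1L, n_trials = 2)
  sp <- data.frame(trial = c(1, 1, 1, 2, 2),
                   neuron = c(1, 2, 3, 1, 2),
                   time = c(0, 7.4, 12.2, 0, 7.2))
  rec <- toy_record(sp, 3, pro,
                    fingerprint = spikeroute:::network_fingerprint(net))
  g <- build_transfer_graph(rec, net)
  h <- transfer_delay_distribution(g, by = "EE")
  expect_equal(h$n, 3)
  expect_equal(h$mode, 7.5) # two delays in the (7, 8] bin
  expect_equal(sum(h$counts), 3)
  expect_error(transfer_delay_distribution(g, by = "IE"),
               "insufficient data")
})

test_that("motif census matches canonical hand-built examples", {
  # chain 1 -> 2 -> 3, one spike each
  net <- toy_network(pre = c(1, 2), post = c(2, 3), weight = c(5, 5),
                     delay = c(1, 1), population = c("E", "E", "E"))
  pro <- trigger_protocol(1L, n_trials = 1)
  rec <- toy_record(data.frame(trial = 1, neuron = 1:3, time = c(0, 5, 10)),
                    3, pro, fingerprint = spikeroute:::network_fingerprint(net))
  cen <- motif_census(build_transfer_graph(rec, net))
  ps <- cen$per_spike
  expect_equal(sum(ps$single), 2) # spikes of neurons 2 and 3
  expect_equal(sum(ps$chain_depth_2), 1) # only neuron 3's spike
  expect_equal(sum(ps$convergence_2), 0)
  # convergence: 1, 2 -> 3
  net2 <- toy_network(pre = c(1, 2), post = c(3, 3), weight = c(5, 5),
                      delay = c(1, 1), population = c("E", "E", "E"))
  rec2 <- toy_record(data.frame(trial = 1, neuron = 1:3, time = c(0, 2, 5)),
                     3, pro,
                     fingerprint = spikeroute:::network_fingerprint(net2))
  cen2 <- motif_census(build_transfer_graph(rec2, net2))
  expect_equal(sum(cen2$per_spike$convergence_2), 1)
  expect_equal(sum(cen2$per_spike$single), 0)
})

test_that("motif census matches exhaustive enumeration on random graphs", {
  for (seed in 4:6) {
    fx <- make_graph_fixture(seed)
    g <- build_transfer_graph(fx$rec, fx$net)
    cen <- motif_census(g)
    # independent enumeration from the edge list
    ind <- vapply(g$nodes$id, function(s) sum(g$edges$post == s), numeric(1))
    outd <- vapply(g$nodes$id, function(s) sum(g$edges$pre == s), numeric(1))
    chain <- vapply(g$nodes$id, function(s)
      any(ind[g$edges$pre[g$edges$post == s]] > 0), logical(1))
    fan_t <- vapply(g$nodes$id, function(s)
      any(outd[g$edges$pre[g$edges$post == s]] >= 2), logical(1))
    expect_equal(cen$per_spike$single, ind == 1)
    expect_equal(cen$per_spike$convergence_2, ind == 2)
    expect_equal(cen$per_spike$convergence_3plus, ind >= 3)
    expect_equal(cen$per_spike$chain_depth_2, chain)
    expect_equal(cen$per_spike$fan_source, outd >= 2)
    expect_equal(cen$per_spike$fan_target, fan_t)
  }
})

test_that("census is invariant to relabeling trials", {
  fx <- make_graph_fixture(7)
  g1 <- build_transfer_graph(fx$rec, fx$net)
  rec2 <- fx$rec
  rec2$spikes$trial <- c(2L, 3L, 1L)[rec2$spikes$trial]
  g2 <- build_transfer_graph(rec2, fx$net)
  expect_equal(motif_census(g1)$totals, motif_census(g2)$totals)
})

test_that("strength histogram separates weak and strong mass", {
  net <- toy_network(pre = c(1, 1), post = c(2, 3), weight = c(5, 60),
                     delay = c(1, 1), population = c("E", "E", "E"))
  pro <- trigger_protocol(1L, n_trials = 1)
  rec <- toy_record(data.frame(trial = 1, neuron = 1:3, time = c(0, 4, 6)),
                    3, pro, fingerprint = spikeroute:::network_fingerprint(net))
  g <- build_transfer_graph(rec, net)
  h <- transfer_strength_histogram(g)
  expect_equal(h$strong_fraction, 0.5)
  expect_equal(sum(h$counts), 2)
  # weak-only edges: no strong mass
  net$synapses$weight <- c(5, 7)
  rec$fingerprint <- spikeroute:::network_fingerprint(net)
  h2 <- transfer_strength_histogram(build_transfer_graph(rec, net))
  expect_equal(h2$strong_fraction, 0)
})

test_that("transfer edges are a subset of the synapse table", {
  fx <- shared_fixture()
  g <- build_transfer_graph(fx$rec, fx$net)
  expect_gt(nrow(g$edges), 0)
  key_syn <- paste(fx$net$synapses$pre, fx$net$synapses$post)
  smp <- g$edges[sample(nrow(g$edges), min(200, nrow(g$edges))), ]
  expect_true(all(paste(smp$pre_neuron, smp$post_neuron) %in% key_syn))
  expect_true(all(smp$delay > 0 & smp$delay <= 100))
})
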