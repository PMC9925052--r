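# exhaustive k-modes cost oracle for K = 2: minimum total Hamming distance
# to cluster modes over all assignments of rows to two non-empty clusters
oracle_kmodes2_cost <- function(m) {
  n <- nrow(m)
  best <- Inf
  mode_cost <- function(rows) {
    if (length(rows) == 0) return(0)
    sub <- m[rows, , drop = FALSE]
    md <- as.integer(colMeans(sub) >= 0.5)
    # per column, the majority mode minimizes Hamming distance; ties equal
    sum(vapply(seq_len(ncol(sub)), function(j)
      min(sum(sub[, j] != 0), sum(sub[, j] != 1)), numeric(1)))
  }
  for (mask in 1:(2^(n - 1) - 1)) { # row 1 fixed in cluster 1, both non-empty
    g1 <- c(1, which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0) + 1)
    g2 <- setdiff(seq_len(n), g1)
    best <- min(best, mode_cost(g1) + mode_cost(g2))
  }
  best
}

test_that("anti-correlated blocks are recovered exactly", {
  m <- rbind(matrix(rep(c(1, 0), c(5, 5)), 4, 10, byrow = TRUE),
             matrix(rep(c(0, 1), c(5, 5)), 4, 10, byrow = TRUE))
  rownames(m) <- 1:8
  part <- kmodes_partition(m, seed = 1, K = 2)
  expect_equal(part$cost, 0)
  expect_equal(length(unique(part$cluster[1:4])), 1)
  expect_equal(length(unique(part$cluster[5:8])), 1)
  expect_false(part$cluster[1] == part$cluster[5])
})

test_that("the cluster-count rule is K = max(1, round(n/6))", {
  m <- matrix(rbinom(25 * 30, 1, 0.5), 25, 30)
  part <- kmodes_partition(m, seed = 2)
  expect_equal(part$K, 4)
  m2 <- matrix(rbinom(3 * 10, 1, 0.5), 3, 10)
  expect_equal(kmodes_partition(m2, seed = 2)$K, 1)
})

test_that("k-modes reaches the exhaustive optimum on a toy matrix", {
  set.seed(5)
  m <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6)
  part <- kmodes_partition(m, seed = 3, K = 2, n_init = 20)
  expect_equal(part$cost, oracle_kmodes2_cost(m))
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(9)
  m <- matrix(rbinom(20 * 40, 1, 0.3), 20, 40)
  p1 <- kmodes_partition(m, seed = 4)
  p2 <- kmodes_partition(m, seed = 4)
  expect_identical(p1$cluster, p2$cluster)
  expect_identical(p1$cost, p2$cost)
})

test_that("activation fraction matches hand counts", {
  # cluster of 5 followers: trial active iff >= 40% (2 of 5) fire
  m <- matrix(0, 5, 4, dimnames = list(1:5, NULL))
  m[1:5, 1] <- 1        # 100% -> active
  m[1:2, 2] <- 1        # 40%  -> active (boundary)
  m[1, 3] <- 1          # 20%  -> inactive
  part <- structure(list(cluster = setNames(rep(1L, 5), 1:5), K = 1L,
                         members = list(`1` = as.character(1:5))),
                    class = "subnetwork_partition")
  a <- subnetwork_activation(m, part, 1)
  expect_equal(a$a, 2 / 4)
  expect_equal(a$active_trials, c(1, 2))
  # all active every trial
  a2 <- subnetwork_activation(matrix(1, 5, 4, dimnames = list(1:5, NULL)),
                              part, 1)
  expect_equal(a2$a, 1)
  # fold change against a supplied baseline
  a3 <- subnetwork_activation(m, part, 1, a0 = 0.25)
  expect_equal(a3$fold_change, 100 * (0.5 - 0.25) / 0.25)
})

test_that("gates are the members with minimal median first-spike delay", {
  pro <- trigger_protocol(1L, n_trials = 3)
  # neuron 2 fires at 10 each trial, neuron 3 at 5 (but second spikes later),
  # neuron 4 in another cluster at 20
  sp <- data.frame(
    trial = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1),
    neuron = c(2, 3, 4, 2, 3, 4, 2, 3, 4, 3),
    time = c(10, 5, 20, 10, 6, 20, 10, 5, 20, 80))
  rec <- toy_record(sp, 4, pro)
  part <- structure(list(cluster = setNames(c(1L, 1L, 2L), c("2", "3", "4")),
                         K = 2L, members = list(`1` = c("2", "3"),
                                                `2` = "4")),
                    class = "subnetwork_partition")
  g <- identify_gates(rec, part)
  expect_equal(g$gate[g$cluster == 1], 3) # median first-spike 5 < 10
  expect_equal(g$median_delay[g$cluster == 1], 5)
  expect_equal(g$gate[g$cluster == 2], 4)
  # permuting trials leaves gates unchanged
  rec2 <- rec
  rec2$spikes$trial <- c(3L, 1L, 2L)[rec2$spikes$trial]
  expect_equal(identify_gates(rec2, part), g)
})

test_that("clusters without spikes are flagged with no gate", {
  pro <- trigger_protocol(1L, n_trials = 2)
  rec <- toy_record(data.frame(trial = 1, neuron = 2, time = 10), 3, pro)
  part <- structure(list(cluster = setNames(c(1L, 2L), c("2", "3")), K = 2L,
                         members = list(`1` = "2", `2` = "3")),
                    class = "subnetwork_partition")
  g <- identify_gates(rec, part)
  expect_true(is.na(g$gate[g$cluster == 2]))
})

test_that("outcome entropy spans its trivial and maximal cases", {
  part <- structure(list(cluster = setNames(c(1L, 1L, 2L, 2L), 1:4), K = 2L,
                         members = list(`1` = c("1", "2"), `2` = c("3", "4"))),
                    class = "subnetwork_partition")
  # both clusters active in all 4 trials -> 0 bits
  m <- matrix(1, 4, 4, dimnames = list(1:4, NULL))
  expect_equal(outcome_entropy(m, part)$entropy, 0)
  # uniform over the 4 outcomes -> 2 bits
  m2 <- cbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  rownames(m2) <- 1:4
  oe <- outcome_entropy(m2, part)
  expect_equal(oe$entropy, 2)
  expect_equal(as.numeric(oe$frequencies), rep(0.25, 4))
})

test_that("outcome entropy matches a hand-computed distribution", {
  part <- structure(list(cluster = setNames(c(1L, 2L), 1:2), K = 2L,
                         members = list(`1` = "1", `2` = "2")),
                    class = "subnetwork_partition")
  # counts over 25 trials: a&b 10, a alone 10, b alone 5, failure 0
  m <- rbind(c(rep(1, 10), rep(1, 10), rep(0, 5)),
             c(rep(1, 10), rep(0, 10), rep(1, 5)))
  rownames(m) <- 1:2
  oe <- outcome_entropy(m, part)
  p <- c(10, 10, 5) / 25
  expect_equal(oe$entropy, -sum(p * log2(p)))
  expect_error(outcome_entropy(m, structure(list(
    cluster = setNames(1L, "1"), K = 1L, members = list(`1` = "1")),
    class = "subnetwork_partition")), "at least 2 clusters")
})

test_that("multi-trigger classes follow set algebra", {
  mk_report <- function(followers, all_ids = 1:10) {
    tab <- data.frame(neuron = all_ids, population = "E",
                      delta_fr = 0, p_value = 1,
                      follower = all_ids %in% followers)
    structure(list(table = tab, activation = matrix(0, 0, 0),
                   rates = c(E = 1, I = 0), threshold = 1e-7,
                   protocol = trigger_protocol(99L, n_trials = 2),
                   fingerprint = c(net = 1)),
              class = "follower_report")
  }
  cls <- classify_multi_trigger(mk_report(c(1, 4, 5, 7)),
                                mk_report(c(2, 4, 6, 7)),
                                mk_report(c(3, 5, 6, 7)))
  tab <- cls$table
  lab <- setNames(tab$class, tab$neuron)
  expect_equal(unname(lab[as.character(1:7)]),
               c("a only", "b only", "ab only", "a&b", "a&ab", "b&ab",
                 "a&b&ab"))
  expect_true(tab$core[tab$neuron == 5])
  expect_true(tab$combination_specific[tab$neuron == 3])
  expect_false(tab$core[tab$neuron == 1])
  # classes partition the union
  expect_equal(sort(tab$neuron), 1:7)
  bad <- mk_report(1)
  bad$fingerprint <- c(net = 2)
  expect_error(classify_multi_trigger(mk_report(1), mk_report(2), bad),
               "fingerprint")
})

test_that("a null gate perturbation leaves activation unchanged", {
  # deterministic chain: trigger 1 -> gate 2 -> members 3, 4
  g <- 150
  net <- toy_network(pre = c(1, 2, 2), post = c(2, 3, 4),
                     weight = c(g, g, g), delay = c(1, 1, 1),
                     population = rep("E", 4))
  pro <- trigger_protocol(1, n_trials = 5, kickstart_count = 0, discard = 100)
  rec <- run_protocol(net, background_noise(0, 0), pro, seed = 6,
                      runaway_frac = 1.01)
  rep <- detect_followers(rec)
  followers <- rep$table$neuron[rep$table$follower]
  expect_setequal(followers, 2:4)
  part <- kmodes_partition(rep$activation, seed = 7, K = 1)
  gate <- identify_gates(rec, part)$gate[1]
  expect_equal(gate, 2)
  gm <- gating_map(net, background_noise(0, 0), pro, gate, part, 1, rep,
                   grid = data.frame(sign = "excitatory",
                                     peak_conductance = 0, delta_t = 0),
                   seed = 8, runaway_frac = 1.01)
  expect_equal(gm$grid$fold_change, 0)
  expect_equal(gm$a0, 1)
})

test_that("a strong inhibitory input on the gate halts the sub-network", {
  g <- 150
  net <- toy_network(pre = c(1, 2, 2), post = c(2, 3, 4),
                     weight = c(g, g, g), delay = c(1, 1, 1),
                     population = rep("E", 4))
  pro <- trigger_protocol(1, n_trials = 5, kickstart_count = 0, discard = 100)
  rec <- run_protocol(net, background_noise(0, 0), pro, seed = 6,
                      runaway_frac = 1.01)
  rep <- detect_followers(rec)
  part <- kmodes_partition(rep$activation, seed = 7, K = 1)
  # the inhibitory event lands 0.5 ms after the trigger spike, 0.5 ms before
  # the gate's excitatory input arrives
  gm <- gating_map(net, background_noise(0, 0), pro, 2, part, 1, rep,
                   grid = data.frame(sign = "inhibitory",
                                     peak_conductance = 542.4, delta_t = 0.5),
                   seed = 9, runaway_frac = 1.01)
  expect_lt(gm$grid$fold_change, -50)
  expect_true(gm$halting)
})
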