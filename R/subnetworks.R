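#' K-modes clustering of the follower-by-trial activation matrix
#'
#' Partitions followers into sub-networks by trial-wise coactivation:
#' k-modes clustering with Hamming dissimilarity on the binary follower x
#' trial matrix, K = max(1, round(n/6)), Huang-style density-based seeding,
#' and the best of `n_init` restarts by total within-cluster Hamming cost.
#'
#' @param m binary matrix (followers x trials), e.g. the `activation` field
#'   of a `follower_report`.
#' @param seed RNG seed for the restarts.
#' @param K number of clusters; default is the n/6 rule.
#' @param n_init number of random restarts.
#' @param max_iter iteration cap per restart.
#' @return A `subnetwork_partition`: `cluster` (label per follower), `K`,
#'   `modes`, `cost`, `members` (list of row names per cluster).
#' @export
kmodes_partition <- function(m, seed = NULL, K = NULL, n_init = 10,
                             max_iter = 100) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1, all(m %in% c(0, 1)))
  storage.mode(m) <- "integer"
  n <- nrow(m)
  if (is.null(K)) K <- max(1L, as.integer(round(n / 6)))
  stopifnot(K >= 1, K <= n)
  dist_to_modes <- function(modes) {
    # n x K Hamming distances
    sapply(seq_len(nrow(modes)), function(k)
      rowSums(m != matrix(modes[k, ], n, ncol(m), byrow = TRUE)))
  }
  one_run <- function() {
    # Huang density-based seeding: sample initial modes weighted by how
    # common each row's pattern of attribute values is.
    freq1 <- colMeans(m)
    dens <- as.vector(m %*% log(pmax(freq1, 1e-12)) +
                        (1 - m) %*% log(pmax(1 - freq1, 1e-12)))
    prob <- exp(dens - max(dens))
    init <- sample.int(n, K, prob = prob, replace = FALSE)
    modes <- m[init, , drop = FALSE]
    cl <- max.col(-dist_to_modes(modes), ties.method = "first")
    for (it in seq_len(max_iter)) {
      for (k in seq_len(K)) {
        rows <- which(cl == k)
        if (length(rows) == 0) {
          # re-seed an empty cluster with the worst-fitting row
          d <- dist_to_modes(modes)
          rows <- which.max(d[cbind(seq_len(n), cl)])
          cl[rows] <- k
        }
        modes[k, ] <- as.integer(colMeans(m[rows, , drop = FALSE]) >= 0.5)
      }
      new_cl <- max.col(-dist_to_modes(modes), ties.method = "first")
      if (all(new_cl == cl)) break
      cl <- new_cl
    }
    cost <- sum(dist_to_modes(modes)[cbind(seq_len(n), cl)])
    list(cluster = cl, modes = modes, cost = cost)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      run <- one_run()
      if (is.null(best) || run$cost < best$cost) best <- run
    }
    ids <- rownames(m) %||% as.character(seq_len(n))
    structure(list(cluster = setNames(best$cluster, ids), K = K,
                   modes = best$modes, cost = best$cost, seed = seed,
                   members = split(ids, best$cluster)),
              class = "subnetwork_partition")
  })
}

#' @export
print.subnetwork_partition <- function(x, ...) {
  cat(sprintf("subnetwork partition: %d followers in %d cluster(s), cost %d\n",
              length(x$cluster), x$K, x$cost))
  cat("  sizes:", paste(lengths(x$members), collapse = ", "), "\n")
  invisible(x)
}

#' Sub-network activation fraction
#'
#' A sub-network counts as activated in a trial if at least
#' `threshold` (default 40%) of its followers fire at least once in that
#' trial's response window.
#'
#' @param m binary follower x trial matrix.
#' @param partition a [kmodes_partition()] result.
#' @param cluster cluster label.
#' @param threshold minimal active-member fraction.
#' @param a0 optional baseline activation for the fold change.
#' @return An `activation_summary` list: `a`, `a0`, `fold_change` (%),
#'   `active_trials`, `threshold`.
#' @export
subnetwork_activation <- function(m, partition, cluster, threshold = 0.40,
                                  a0 = NULL) {
  stopifnot(inherits(partition, "subnetwork_partition"))
  rows <- which(partition$cluster == cluster)
  if (length(rows) == 0) stop("cluster is empty")
  frac <- colMeans(m[rows, , drop = FALSE])
  active <- frac >= threshold
  a <- mean(active)
  fold <- if (!is.null(a0) && a0 > 0) 100 * (a - a0) / a0 else NA_real_
  structure(list(a = a, a0 = a0 %||% NA_real_, fold_change = fold,
                 active_trials = which(active), threshold = threshold,
                 n_members = length(rows)),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("activation: a = %.3f over %d members (threshold %.0f%%)",
              x$a, x$n_members, 100 * x$threshold))
  if (!is.na(x$fold_change))
    cat(sprintf(", fold change %.1f%% vs a0 = %.3f", x$fold_change, x$a0))
  cat("\n")
  invisible(x)
}

#' Identify gate neurons
#'
#' The gate of a sub-network is the member with the shortest median
#' first-spike delay from the trigger, across trials in which it fired
#' (response window only). Ties are broken by the lower neuron id; clusters
#' with no spikes are flagged with an NA gate.
#'
#' @param rec a `spike_record`.
#' @param partition a [kmodes_partition()] whose follower ids are neuron ids
#'   of `rec`.
#' @return data.frame (`cluster`, `gate`, `median_delay`).
#' @export
identify_gates <- function(rec, partition) {
  stopifnot(inherits(rec, "spike_record"),
            inherits(partition, "subnetwork_partition"))
  sp <- rec$spikes
  sp <- sp[sp$time > 0 & sp$time <= rec$protocol$after_window, ]
  sp <- sp[order(sp$trial, sp$neuron, sp$time), ]
  first <- sp[!duplicated(sp[c("trial", "neuron")]), ]
  med <- tapply(first$time, first$neuron, median)
  out <- data.frame(cluster = sort(unique(partition$cluster)),
                    gate = NA_integer_, median_delay = NA_real_)
  for (i in seq_len(nrow(out))) {
    ids <- as.integer(names(partition$cluster)[
      partition$cluster == out$cluster[i]])
    d <- med[as.character(ids)]
    if (all(is.na(d))) next
    best <- min(d, na.rm = TRUE)
    out$gate[i] <- min(ids[!is.na(d) & d == best])
    out$median_delay[i] <- best
  }
  out
}

#' Trial-outcome distribution and entropy for the two largest sub-networks
#'
#' Classifies every trial as one of four outcomes -- full failure, a and b
#' together, a alone, b alone -- for the two largest sub-networks (a, b) and
#' reports the Shannon entropy of the empirical distribution in bits
#' (maximum 2 bits).
#'
#' @param m binary follower x trial matrix.
#' @param partition a [kmodes_partition()] with at least 2 clusters.
#' @param threshold activation threshold per trial.
#' @return An `outcome_distribution`: `frequencies` (named, summing to 1),
#'   `entropy` (bits), `clusters` (the two labels used).
#' @export
outcome_entropy <- function(m, partition, threshold = 0.40) {
  stopifnot(inherits(partition, "subnetwork_partition"))
  if (length(partition$members) < 2)
    stop("insufficient data: at least 2 clusters are required")
  sizes <- lengths(partition$members)
  labs <- as.integer(names(partition$members))
  o <- order(-sizes, labs)
  ca <- labs[o[1]]; cb <- labs[o[2]]
  act <- function(cl) {
    rows <- which(partition$cluster == cl)
    colMeans(m[rows, , drop = FALSE]) >= threshold
  }
  a <- act(ca); b <- act(cb)
  outcome <- ifelse(a & b, "a&b", ifelse(a, "a alone",
                                         ifelse(b, "b alone", "full failure")))
  lev <- c("full failure", "a&b", "a alone", "b alone")
  freq <- table(factor(outcome, lev)) / length(outcome)
  p <- freq[freq > 0]
  structure(list(frequencies = freq, entropy = -sum(p * log2(p)),
                 clusters = c(a = ca, b = cb)),
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf("trial outcomes (clusters %d vs %d), entropy %.3f bits\n",
              x$clusters[["a"]], x$clusters[["b"]], x$entropy))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Gating map: fold change of sub-network activation under gate manipulation
#'
#' Reruns the trigger protocol once per grid point, each time adding a
#' single external synaptic input to the gate neuron, and reports the fold
#' change of the target sub-network's activation fraction relative to the
#' unperturbed baseline, plus +/-50% contour masks.
#'
#' @param net,noise,protocol,params,seed,dt as in [run_protocol()].
#' @param gate gate neuron id.
#' @param partition the baseline partition defining the sub-network.
#' @param cluster cluster label of the targeted sub-network.
#' @param report baseline `follower_report` (defines the follower set and
#'   baseline activation a0).
#' @param grid data.frame with columns `sign`, `peak_conductance`,
#'   `delta_t`; defaults to log-spaced conductances up to the population
#'   maxima and delays -50..150 ms in 10 ms steps.
#' @param threshold activation threshold.
#' @return A `gating_map`: the grid with `a` and `fold_change` columns plus
#'   `halting`/`facilitating` masks at -50%/+50%.
#' @export
gating_map <- function(net, noise, protocol, gate, partition, cluster, report,
                       grid = NULL, threshold = 0.40,
                       params = neuron_params(), seed = NULL, dt = 0.1,
                       runaway_frac = 0.1) {
  stopifnot(inherits(report, "follower_report"))
  followers <- report$table$neuron[report$table$follower]
  base <- subnetwork_activation(report$activation, partition, cluster,
                                threshold)
  if (base$a == 0) stop("baseline activation a0 is zero; fold change undefined")
  if (is.null(grid)) {
    g_exc <- exp(seq(log(1), log(67.8), length.out = 5))
    g_inh <- exp(seq(log(1), log(542.4), length.out = 5))
    dts <- seq(-50, 150, by = 10)
    grid <- rbind(
      expand.grid(sign = "excitatory", peak_conductance = g_exc,
                  delta_t = dts, stringsAsFactors = FALSE),
      expand.grid(sign = "inhibitory", peak_conductance = g_inh,
                  delta_t = dts, stringsAsFactors = FALSE))
  }
  rows <- which(partition$cluster == cluster)
  member_ids <- as.integer(names(partition$cluster)[rows])
  grid$a <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ext <- external_input(gate, grid$peak_conductance[i], grid$sign[i],
                          grid$delta_t[i])
    rec <- run_protocol(net, noise, protocol, externals = list(ext),
                        params = params,
                        seed = if (is.null(seed)) NULL
                        else child_seed(seed, i), dt = dt,
                        runaway_frac = runaway_frac)
    sp <- rec$spikes
    resp <- sp[sp$time > 0 & sp$time <= protocol$after_window &
                 sp$neuron %in% member_ids, ]
    act <- matrix(0L, length(member_ids), protocol$n_trials)
    if (nrow(resp) > 0)
      act[cbind(match(resp$neuron, member_ids), resp$trial)] <- 1L
    grid$a[i] <- mean(colMeans(act) >= threshold)
  }
  grid$fold_change <- 100 * (grid$a - base$a) / base$a
  structure(list(grid = grid, a0 = base$a, gate = gate, cluster = cluster,
                 halting = grid$fold_change <= -50,
                 facilitating = grid$fold_change >= 50),
            class = "gating_map")
}

#' @export
print.gating_map <- function(x, ...) {
  cat(sprintf("gating map: gate %d, cluster %d, a0 = %.3f, %d grid points\n",
              x$gate, x$cluster, x$a0, nrow(x$grid)))
  cat(sprintf("  halting (<= -50%%): %d, facilitating (>= +50%%): %d\n",
              sum(x$halting), sum(x$facilitating)))
  invisible(x)
}

#' Classify followers across trigger combinations
#'
#' Compares follower sets from three records of the same network and noise:
#' single triggers a and b, and their coactivation ab. Every follower in the
#' union is labeled with one of six classes by set membership; classes
#' `a&ab` and `b&ab` are core followers, classes `a only`, `b only` and
#' `ab only` are combination-specific.
#'
#' @param report_a,report_b,report_ab `follower_report`s from the same
#'   network.
#' @return A `trigger_classes`: data.frame (`neuron`, `class`, `core`,
#'   `combination_specific`) plus the three follower sets.
#' @export
classify_multi_trigger <- function(report_a, report_b, report_ab) {
  reps <- list(report_a, report_b, report_ab)
  for (r in reps) stopifnot(inherits(r, "follower_report"))
  fp <- lapply(reps, `[[`, "fingerprint")
  if (!identical(fp[[1]], fp[[2]]) || !identical(fp[[1]], fp[[3]]))
    stop("reports come from different networks (fingerprint mismatch)")
  set <- lapply(reps, function(r) r$table$neuron[r$table$follower])
  names(set) <- c("a", "b", "ab")
  all_ids <- sort(unique(unlist(set)))
  ina <- all_ids %in% set$a; inb <- all_ids %in% set$b
  inab <- all_ids %in% set$ab
  class <- character(length(all_ids))
  class[ina & !inb & !inab] <- "a only"
  class[!ina & inb & !inab] <- "b only"
  class[!ina & !inb & inab] <- "ab only"
  class[ina & !inb & inab] <- "a&ab"
  class[!ina & inb & inab] <- "b&ab"
  class[ina & inb & inab] <- "a&b&ab"
  class[ina & inb & !inab] <- "a&b"
  core <- class %in% c("a&ab", "b&ab", "a&b&ab")
  spec <- class %in% c("a only", "b only", "ab only")
  structure(list(table = data.frame(neuron = all_ids, class = class,
                                    core = core,
                                    combination_specific = spec),
                 sets = set),
            class = "trigger_classes")
}

#' @export
print.trigger_classes <- function(x, ...) {
  cat("multi-trigger follower classes:\n")
  print(table(x$table$class))
  cat(sprintf("  core: %d, combination-specific: %d\n",
              sum(x$table$core), sum(x$table$combination_specific)))
  invisible(x)
}
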