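#' Directed acyclic graph of spike transfers
#'
#' A spike transfer is a presynaptic spike followed, within the same trial
#' and within `window` ms, by a spike of a synaptically connected
#' postsynaptic neuron. Edges point forward in time, so the graph is acyclic
#' by construction. Multiple presynaptic spikes of the same neuron within
#' the window each create their own edge.
#'
#' @param rec a `spike_record`.
#' @param net the `network_model` the record was simulated on.
#' @param window maximal pre-to-post spike delay (ms).
#' @return A `transfer_graph`: `nodes` (spike table with a spike id) and
#'   `edges` (`trial`, `pre`, `post` spike ids, `pre_neuron`, `post_neuron`,
#'   `delay` ms, `weight` nS).
#' @export
build_transfer_graph <- function(rec, net, window = 100) {
  stopifnot(inherits(rec, "spike_record"), inherits(net, "network_model"))
  if (!identical(rec$fingerprint, network_fingerprint(net)))
    stop("record and network are inconsistent (fingerprint mismatch)")
  nodes <- rec$spikes
  nodes$id <- seq_len(nrow(nodes))
  nodes$population <- rec$population[nodes$neuron]
  syn <- net$synapses
  # synapse lookup keyed by presynaptic neuron
  ord <- order(syn$pre)
  ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = net$n_neurons)))
  tgt <- syn$post[ord]; wgt <- syn$weight[ord]
  # spikes per (trial, neuron), scanned trial by trial
  e_pre <- integer(0); e_post <- integer(0); e_w <- numeric(0)
  sp <- nodes[order(nodes$trial, nodes$time, nodes$neuron), ]
  for (tr in unique(sp$trial)) {
    s <- sp[sp$trial == tr, ]
    # spike ids per neuron in this trial
    by_neuron <- split(seq_len(nrow(s)), s$neuron)
    for (i in seq_len(nrow(s))) {
      pre_n <- s$neuron[i]
      lo <- ptr[pre_n] + 1L; hi <- ptr[pre_n + 1L]
      if (hi < lo) next
      for (j in lo:hi) {
        rows <- by_neuron[[as.character(tgt[j])]]
        if (is.null(rows)) next
        dt <- s$time[rows] - s$time[i]
        ok <- dt > 0 & dt <= window
        if (any(ok)) {
          e_pre <- c(e_pre, rep(s$id[i], sum(ok)))
          e_post <- c(e_post, s$id[rows[ok]])
          e_w <- c(e_w, rep(wgt[j], sum(ok)))
        }
      }
    }
  }
  edges <- data.frame(pre = e_pre, post = e_post)
  edges$trial <- nodes$trial[e_pre]
  edges$pre_neuron <- nodes$neuron[e_pre]
  edges$post_neuron <- nodes$neuron[e_post]
  edges$delay <- nodes$time[e_post] - nodes$time[e_pre]
  edges$weight <- e_w
  structure(list(nodes = nodes, edges = edges, window = window,
                 population = rec$population,
                 fingerprint = rec$fingerprint),
            class = "transfer_graph")
}

#' @export
print.transfer_graph <- function(x, ...) {
  cat(sprintf("transfer graph: %d spikes, %d transfer edges (window %g ms)\n",
              nrow(x$nodes), nrow(x$edges), x$window))
  invisible(x)
}

.edge_pair_mask <- function(g, by) {
  if (is.null(by)) return(rep(TRUE, nrow(g$edges)))
  stopifnot(nchar(by) == 2)
  pre_pop <- g$population[g$edges$pre_neuron]
  post_pop <- g$population[g$edges$post_neuron]
  pre_pop == substr(by, 1, 1) & post_pop == substr(by, 2, 2)
}

#' Distribution of spike-transfer delays
#'
#' Histogram of pre-to-post spike time differences for transfer edges of a
#' given population pair, with the modal bin reported.
#'
#' @param g a `transfer_graph`.
#' @param by population pair (`"EE"`, `"EI"`, `"IE"`, `"II"`) or `NULL` for
#'   all edges.
#' @param bin histogram bin width (ms).
#' @return List with `breaks`, `counts`, `mode` (centre of the modal bin,
#'   ms) and `n`.
#' @export
transfer_delay_distribution <- function(g, by = NULL, bin = 1) {
  stopifnot(inherits(g, "transfer_graph"), bin > 0)
  d <- g$edges$delay[.edge_pair_mask(g, by)]
  if (length(d) == 0) stop("insufficient data: no transfer edges selected")
  breaks <- seq(0, ceiling(g$window / bin) * bin, by = bin)
  counts <- tabulate(findInterval(d, breaks, left.open = TRUE),
                     nbins = length(breaks) - 1)
  centers <- breaks[-length(breaks)] + bin / 2
  list(breaks = breaks, counts = counts,
       mode = centers[which.max(counts)], n = length(d))
}

#' Low-order motif census of the transfer graph
#'
#' Counts, per postsynaptic spike, the motif classes restricted to depths of
#' at most two spike transfers and at most four spikes: `single` (exactly one
#' in-edge), `convergence_2` (two in-edges), `convergence_3plus` (three or
#' more), `chain_depth_2` (an in-edge whose source spike itself has an
#' in-edge), and fan (divergence). Because it is ambiguous whether a fan is
#' attributed to the diverging source spike or to its targets, both tallies
#' are returned: `fan_source` counts spikes with two or more out-edges and
#' `fan_target` counts spikes that share their source with another target.
#'
#' @param g a `transfer_graph`.
#' @return A `motif_census`: `per_spike` logical data.frame and `totals`, a
#'   count table split by population.
#' @export
motif_census <- function(g) {
  stopifnot(inherits(g, "transfer_graph"))
  n <- nrow(g$nodes)
  indeg <- tabulate(g$edges$post, nbins = n)
  outdeg <- tabulate(g$edges$pre, nbins = n)
  # chain: spike with an in-edge from a spike that itself has an in-edge
  has_in <- indeg > 0
  chain <- rep(FALSE, n)
  if (nrow(g$edges) > 0)
    chain[unique(g$edges$post[has_in[g$edges$pre]])] <- TRUE
  fan_target <- rep(FALSE, n)
  if (nrow(g$edges) > 0)
    fan_target[unique(g$edges$post[outdeg[g$edges$pre] >= 2])] <- TRUE
  per_spike <- data.frame(
    id = g$nodes$id,
    population = g$nodes$population,
    single = indeg == 1,
    convergence_2 = indeg == 2,
    convergence_3plus = indeg >= 3,
    chain_depth_2 = chain,
    fan_source = outdeg >= 2,
    fan_target = fan_target)
  classes <- c("single", "convergence_2", "convergence_3plus",
               "chain_depth_2", "fan_source", "fan_target")
  totals <- sapply(classes, function(cl)
    tapply(per_spike[[cl]], factor(per_spike$population, c("E", "I")), sum,
           default = 0L))
  structure(list(per_spike = per_spike, totals = totals),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("motif census (spikes per class, by population):\n")
  print(x$totals)
  invisible(x)
}

#' Conductance histogram of traversed synapses
#'
#' Histogram of the conductances of synapses underlying spike transfers,
#' with the fraction of edge mass above the strong-connection threshold as a
#' bimodality score.
#'
#' @param g a `transfer_graph`.
#' @param by population pair or `NULL`.
#' @param strong_threshold conductance (nS) separating strong connections.
#' @param bin histogram bin width (nS).
#' @return List with `breaks`, `counts`, `strong_fraction` and `n`.
#' @export
transfer_strength_histogram <- function(g, by = NULL, strong_threshold = 50.6,
                                        bin = 1) {
  stopifnot(inherits(g, "transfer_graph"))
  w <- g$edges$weight[.edge_pair_mask(g, by)]
  if (length(w) == 0) stop("insufficient data: no transfer edges selected")
  breaks <- seq(0, ceiling(max(w) / bin) * bin + bin, by = bin)
  counts <- tabulate(findInterval(w, breaks, left.open = TRUE),
                     nbins = length(breaks) - 1)
  list(breaks = breaks, counts = counts,
       strong_fraction = mean(w > strong_threshold), n = length(w))
}

#' Export a transfer graph as a delimited edge list
#'
#' @param g a `transfer_graph`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
export_transfer_graph <- function(g, path) {
  stopifnot(inherits(g, "transfer_graph"))
  e <- g$edges
  out <- data.frame(trial = e$trial,
                    pre_id = e$pre_neuron,
                    pre_time = g$nodes$time[e$pre],
                    post_id = e$post_neuron,
                    post_time = g$nodes$time[e$post],
                    weight = e$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
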