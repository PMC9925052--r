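#' Truncated-lognormal synaptic weight distribution
#'
#' Excitatory conductances are drawn from a lognormal distribution truncated
#' at the conductance corresponding to the largest recorded EPSP amplitude;
#' draws above the truncation are discarded and re-sampled. `mean` and `sd`
#' are interpreted as the moments of the *truncated* distribution and the
#' underlying log-scale parameters are obtained by two-dimensional moment
#' matching, which also reproduces the 50.6 nS lower bound of the top 0.3% of
#' conductances. Inhibitory conductances are the same truncated draws scaled
#' by `inhibitory_scale`.
#'
#' @param mean,sd target mean and standard deviation of the truncated
#'   distribution (nS).
#' @param truncation_max upper truncation (nS).
#' @param inhibitory_scale multiplicative scale applied to draws for
#'   inhibitory source neurons (applied after truncation).
#' @return A `weight_distribution` with the underlying `mu`, `sigma`
#'   (log-nS) and the inputs.
#' @examples
#' wd <- weight_distribution()
#' weight_quantile(wd, 0.997)
#' @export
weight_distribution <- function(mean = 3.73, sd = 6.51, truncation_max = 67.8,
                                inhibitory_scale = 8) {
  stopifnot(mean > 0, sd > 0, truncation_max > mean, inhibitory_scale > 0)
  mom <- function(mu, sig, k) {
    exp(k * mu + k^2 * sig^2 / 2) *
      pnorm((log(truncation_max) - mu - k * sig^2) / sig) /
      pnorm((log(truncation_max) - mu) / sig)
  }
  obj <- function(p) {
    m1 <- mom(p[1], exp(p[2]), 1)
    m2 <- mom(p[1], exp(p[2]), 2)
    c(m1 - mean, sqrt(pmax(m2 - m1^2, 0)) - sd)
  }
  sol <- pracma::fsolve(obj, c(log(mean), 0))
  mu <- sol$x[1]; sigma <- exp(sol$x[2])
  res <- obj(sol$x)
  if (max(abs(res)) > 1e-6 * mean)
    stop("moment matching did not converge")
  structure(list(mean = mean, sd = sd, truncation_max = truncation_max,
                 mu = mu, sigma = sigma, inhibitory_scale = inhibitory_scale),
            class = "weight_distribution")
}

#' @export
print.weight_distribution <- function(x, ...) {
  cat(sprintf(paste0("truncated lognormal weights: mean %.3g nS, sd %.3g nS, ",
                     "max %.3g nS\n  underlying mu = %.5g, sigma = %.5g; ",
                     "inhibitory scale %g\n"),
              x$mean, x$sd, x$truncation_max, x$mu, x$sigma, x$inhibitory_scale))
  invisible(x)
}

#' Quantile of the truncated weight distribution
#'
#' @param dist a [weight_distribution()].
#' @param p probability (e.g. 0.997 for the strong-connection threshold).
#' @return Conductance (nS).
#' @export
weight_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "weight_distribution"), p >= 0, p <= 1)
  Z <- pnorm((log(dist$truncation_max) - dist$mu) / dist$sigma)
  exp(dist$mu + dist$sigma * qnorm(p * Z))
}

#' Sample synaptic conductances
#'
#' Rejection-samples the lognormal above `truncation_max`; draws for
#' inhibitory source neurons are multiplied by the inhibitory scale after
#' truncation.
#'
#' @param n number of draws.
#' @param dist a [weight_distribution()].
#' @param source_population `"E"` or `"I"`.
#' @param seed optional RNG seed.
#' @return Numeric vector of conductances (nS).
#' @export
sample_weights <- function(n, dist = weight_distribution(),
                           source_population = c("E", "I"), seed = NULL) {
  stopifnot(inherits(dist, "weight_distribution"), n >= 0)
  source_population <- match.arg(source_population)
  with_seed(seed, {
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      out[todo] <- exp(rnorm(length(todo), dist$mu, dist$sigma))
      todo <- todo[out[todo] > dist$truncation_max]
    }
    if (source_population == "I") out <- out * dist$inhibitory_scale
    out
  })
}

#' Place neurons uniformly on a square with periodic boundaries
#'
#' @param n number of neurons.
#' @param side square side (micrometres).
#' @param fraction_excitatory proportion of excitatory neurons; exactly
#'   `round(n * fraction_excitatory)` neurons are labelled "E".
#' @param seed optional RNG seed.
#' @return data.frame with columns `x`, `y` and `population` (factor E/I).
#' @export
place_neurons <- function(n, side = 2000, fraction_excitatory = 0.93,
                          seed = NULL) {
  stopifnot(n > 0, side > 0,
            fraction_excitatory > 0, fraction_excitatory < 1)
  with_seed(seed, {
    n_e <- round(n * fraction_excitatory)
    data.frame(x = runif(n, 0, side), y = runif(n, 0, side),
               population = factor(rep(c("E", "I"), c(n_e, n - n_e)),
                                   levels = c("E", "I")))
  })
}

#' Torus (periodic boundary) distance
#'
#' Euclidean distance between points on a square with per-axis wrap-around.
#'
#' @param p1,p2 two-column matrices (or length-2 vectors) of coordinates in
#'   `[0, side)`.
#' @param side square side.
#' @return Numeric vector of distances (at most `side / sqrt(2)`).
#' @export
torus_distance <- function(p1, p2, side) {
  p1 <- matrix(p1, ncol = 2); p2 <- matrix(p2, ncol = 2)
  dx <- abs(p1[, 1] - p2[, 1]); dx <- pmin(dx, side - dx)
  dy <- abs(p1[, 2] - p2[, 2]); dy <- pmin(dy, side - dy)
  sqrt(dx^2 + dy^2)
}

# Mean over a uniform point pair on the torus of exp(-d^2 / (2 sigma^2));
# separable per axis, closed form via the normal CDF.
.torus_gauss_mean <- function(sigma, side) {
  m1 <- sqrt(2 * pi) * sigma / side * (2 * pnorm(side / (2 * sigma)) - 1)
  m1^2
}

#' Calibrate the distance-dependent connectivity profile
#'
#' Connection probability between two neurons decays with torus distance as
#' a Gaussian, \eqn{p(d) = A \, e^{-d^2 / 2\sigma^2}}, per ordered population
#' pair. The zero-distance amplitude A of each pair is set analytically so
#' that the expected out-degree (target density times the Gaussian integrated
#' over the torus) equals the calibration target. Also reports the implied
#' mean connection probability within a 200 um disc.
#'
#' @param sigma named numeric vector of Gaussian widths (um) for pairs
#'   `ee`, `ei`, `ie`, `ii` (source population first).
#' @param targets named numeric vector of mean outgoing connections per
#'   source cell for the same pairs.
#' @param n_neurons,side,fraction_excitatory network geometry.
#' @param disc_radius radius (um) for the reported disc probability.
#' @return A `connectivity_profile` with per-pair `amplitude`, `sigma`,
#'   `target` and `disc_probability`.
#' @examples
#' calibrate_profile()
#' @export
calibrate_profile <- function(sigma = c(ee = 150, ei = 150, ie = 150, ii = 120),
                              targets = c(ee = 750, ei = 190, ie = 2690, ii = 110),
                              n_neurons = 1e5, side = 2000,
                              fraction_excitatory = 0.93,
                              disc_radius = 200) {
  pairs <- c("ee", "ei", "ie", "ii")
  stopifnot(all(pairs %in% names(sigma)), all(pairs %in% names(targets)),
            all(sigma[pairs] > 0), all(targets[pairs] >= 0))
  n_e <- round(n_neurons * fraction_excitatory)
  n_i <- n_neurons - n_e
  # effective number of candidate targets (no autapses within a population)
  n_tgt <- c(ee = n_e - 1, ei = n_i, ie = n_e, ii = n_i - 1)
  amp <- disc <- setNames(numeric(4), pairs)
  for (p in pairs) {
    mbar <- .torus_gauss_mean(sigma[[p]], side)
    amp[p] <- if (targets[[p]] == 0) 0 else targets[[p]] / (n_tgt[[p]] * mbar)
    if (amp[p] > 1)
      stop(sprintf(
        "infeasible profile: pair %s needs amplitude %.3f > 1 for target %g",
        p, amp[p], targets[[p]]))
    s2 <- sigma[[p]]^2
    disc[p] <- amp[p] * 2 * s2 * (1 - exp(-disc_radius^2 / (2 * s2))) /
      disc_radius^2
  }
  structure(list(sigma = sigma[pairs], amplitude = amp, targets = targets[pairs],
                 disc_probability = disc, disc_radius = disc_radius,
                 n_neurons = n_neurons, side = side,
                 fraction_excitatory = fraction_excitatory),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("distance-dependent connectivity profile (torus)\n")
  for (p in names(x$amplitude))
    cat(sprintf("  %s: sigma = %g um, amplitude = %.4f, target out-degree = %g, p(disc %g um) = %.4f\n",
                p, x$sigma[[p]], x$amplitude[[p]], x$targets[[p]],
                x$disc_radius, x$disc_probability[[p]]))
  invisible(x)
}

#' Generate a spatially embedded random network
#'
#' Places neurons uniformly on a torus, draws one independent Bernoulli edge
#' per ordered pair with the calibrated distance-dependent probability, and
#' assigns each edge an independent truncated-lognormal conductance and a
#' uniform conduction delay. No autapses; at most one synapse per ordered
#' pair. Degrees are not fixed.
#'
#' @param n_neurons network size (default 100,000).
#' @param side square side (um); 2000 um corresponds to the modelled slab.
#' @param fraction_excitatory proportion of excitatory neurons.
#' @param profile a [calibrate_profile()] result; by default calibrated for
#'   the requested geometry with the default widths and out-degree targets.
#' @param weights a [weight_distribution()].
#' @param delay_range conduction delay bounds (ms), uniform per edge.
#' @param seed optional RNG seed.
#' @param max_neurons memory guard; building more neurons than this requires
#'   raising the cap explicitly.
#' @return A `network_model`: list with `n_neurons`, `side`, `neurons`
#'   (positions + population) and `synapses` (data.frame `pre`, `post`,
#'   `weight`, `delay`).
#' @examples
#' net <- build_network(n_neurons = 300, side = 110,
#'                      profile = calibrate_profile(
#'                        targets = c(ee = 20, ei = 4, ie = 40, ii = 3),
#'                        n_neurons = 300, side = 110),
#'                      seed = 1)
#' nrow(net$synapses)
#' @export
build_network <- function(n_neurons = 1e5, side = 2000,
                          fraction_excitatory = 0.93, profile = NULL,
                          weights = weight_distribution(),
                          delay_range = c(0.5, 2), seed = NULL,
                          max_neurons = 150000) {
  stopifnot(inherits(weights, "weight_distribution"),
            length(delay_range) == 2, delay_range[1] > 0,
            delay_range[2] >= delay_range[1])
  if (n_neurons > max_neurons)
    stop(sprintf("n_neurons = %g exceeds the memory guard (%g); raise max_neurons to override",
                 n_neurons, max_neurons))
  if (is.null(profile))
    profile <- calibrate_profile(n_neurons = n_neurons, side = side,
                                 fraction_excitatory = fraction_excitatory)
  stopifnot(inherits(profile, "connectivity_profile"))
  with_seed(seed, {
    neurons <- place_neurons(n_neurons, side, fraction_excitatory)
    is_exc <- neurons$population == "E"
    expect_m <- sum(profile$targets * c(sum(is_exc), sum(is_exc),
                                        sum(!is_exc), sum(!is_exc)))
    syn <- .build_network_cpp(neurons$x, neurons$y, is_exc,
                              as.numeric(profile$amplitude),
                              as.numeric(profile$sigma), side,
                              weights$mu, weights$sigma,
                              weights$truncation_max,
                              weights$inhibitory_scale,
                              delay_range[1], delay_range[2],
                              reserve_n = expect_m * 1.02 + 1000)
    structure(list(n_neurons = n_neurons, side = side,
                   neurons = neurons,
                   synapses = structure(syn, class = "data.frame",
                                        row.names = seq_along(syn$pre)),
                   profile = profile, weights = weights,
                   delay_range = delay_range, truncation = "full"),
              class = "network_model")
  })
}

#' @export
print.network_model <- function(x, ...) {
  tab <- table(x$neurons$population)
  cat(sprintf("network model: %d neurons (%d E, %d I) on a %g um torus; %d synapses (%s)\n",
              x$n_neurons, tab[["E"]], tab[["I"]], x$side,
              nrow(x$synapses), x$truncation))
  invisible(x)
}

# logical masks for the four ordered population pairs of a synapse table
.pair_mask <- function(net, pair) {
  is_e <- net$neurons$population == "E"
  pre_e <- is_e[net$synapses$pre]
  post_e <- is_e[net$synapses$post]
  switch(pair,
         ee = pre_e & post_e, ei = pre_e & !post_e,
         ie = !pre_e & post_e, ii = !pre_e & !post_e,
         stop("unknown pair: ", pair))
}

#' Degree summaries per population pair
#'
#' Mean and standard deviation of per-neuron out- and in-degrees for a given
#' ordered population pair. Both orientations are reported because incoming
#' and outgoing counts answer different calibration questions.
#'
#' @param net a `network_model`.
#' @param pair one of `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#' @return List with `out_mean`, `out_sd`, `in_mean`, `in_sd` and the raw
#'   per-neuron counts `out_degree`, `in_degree` (over source / target
#'   population respectively).
#' @export
degree_summary <- function(net, pair = "ee") {
  stopifnot(inherits(net, "network_model"))
  m <- .pair_mask(net, pair)
  src_pop <- if (substr(pair, 1, 1) == "e") "E" else "I"
  tgt_pop <- if (substr(pair, 2, 2) == "e") "E" else "I"
  src <- which(net$neurons$population == src_pop)
  tgt <- which(net$neurons$population == tgt_pop)
  outd <- tabulate(net$synapses$pre[m], nbins = net$n_neurons)[src]
  ind <- tabulate(net$synapses$post[m], nbins = net$n_neurons)[tgt]
  list(out_mean = mean(outd), out_sd = sd(outd),
       in_mean = mean(ind), in_sd = sd(ind),
       out_degree = outd, in_degree = ind)
}

#' Strong-only / weak-only network variants
#'
#' Removes excitatory-to-excitatory synapses by conductance: `strong_only`
#' keeps only E-to-E synapses above the `strong_quantile` of the E-to-E
#' conductance distribution, `weak_only` keeps only those below the
#' `weak_quantile`. Connectivity involving inhibitory neurons is untouched.
#'
#' @param net a `network_model` with at least one E-to-E synapse.
#' @param mode `"full"`, `"strong_only"` or `"weak_only"`.
#' @param strong_quantile,weak_quantile conductance quantiles defining the
#'   strong (top 0.3%) and weak (bottom 90%) connection classes.
#' @return A `network_model` with the reduced synapse table.
#' @export
truncate_network <- function(net, mode = c("full", "strong_only", "weak_only"),
                             strong_quantile = 0.997, weak_quantile = 0.90) {
  stopifnot(inherits(net, "network_model"))
  mode <- match.arg(mode)
  if (mode == "full") return(net)
  ee <- .pair_mask(net, "ee")
  if (!any(ee)) stop("network has no E-to-E synapses")
  w_ee <- net$synapses$weight[ee]
  keep <- !ee
  if (mode == "strong_only") {
    thr <- quantile(w_ee, strong_quantile, names = FALSE, type = 7)
    keep[ee] <- w_ee > thr
  } else {
    thr <- quantile(w_ee, weak_quantile, names = FALSE, type = 7)
    keep[ee] <- w_ee < thr
  }
  net$synapses <- net$synapses[keep, , drop = FALSE]
  row.names(net$synapses) <- NULL
  net$truncation <- mode
  net
}

#' Export the synapse table as a plain-text edge list
#'
#' One synapse per line: `pre TAB post TAB conductance_nS TAB delay_ms`.
#'
#' @param net a `network_model`.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
export_edges <- function(net, file) {
  stopifnot(inherits(net, "network_model"))
  write.table(net$synapses, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(file)
}
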