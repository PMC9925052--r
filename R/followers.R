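#' Per-neuron firing-rate modulation
#'
#' The firing-rate modulation of a neuron is the difference between its mean
#' rate in the response windows and its mean rate in the baseline windows,
#' normalized by the modulation expected from a perfect follower: a neuron
#' that never spikes before the trigger and spikes exactly once per trial
#' after it. A perfect follower therefore scores 1 and a silent or
#' unmodulated neuron 0. Trigger neurons are excluded.
#'
#' @param rec a `spike_record`.
#' @param protocol trial structure; defaults to the one stored in `rec`.
#' @return data.frame with `neuron`, `population`, `n_before`, `n_after`,
#'   `delta_fr` for every non-trigger neuron.
#' @export
compute_delta_fr <- function(rec, protocol = rec$protocol) {
  stopifnot(inherits(rec, "spike_record"))
  sp <- rec$spikes
  before <- sp$time >= -protocol$before_window & sp$time < 0
  after <- sp$time > 0 & sp$time <= protocol$after_window
  nb <- tabulate(sp$neuron[before], nbins = rec$n_neurons)
  na_ <- tabulate(sp$neuron[after], nbins = rec$n_neurons)
  keep <- setdiff(seq_len(rec$n_neurons), protocol$trigger_ids)
  ratio <- protocol$after_window / protocol$before_window
  data.frame(neuron = keep,
             population = rec$population[keep],
             n_before = nb[keep], n_after = na_[keep],
             delta_fr = (na_[keep] - ratio * nb[keep]) / protocol$n_trials)
}

#' Exact Poisson-difference null for the firing-rate modulation
#'
#' Under the null, a neuron's spike counts in the pooled baseline and
#' response windows are independent Poisson variables with the same
#' underlying rate, adjusted for the different window durations. The exact
#' probability mass function of the normalized modulation is computed by
#' enumerating both counts up to a tail cutoff with mass below 1e-12.
#' Separate nulls are built per population because excitatory and inhibitory
#' baseline rates differ strongly.
#'
#' @param rate underlying rate (spikes/s), typically the population mean
#'   baseline rate of the record.
#' @param protocol a [trigger_protocol()] giving windows and trial count.
#' @return A `null_model` with the support `values`, `pmf` and upper-tail
#'   probabilities `tail` (P(X >= value)). A zero rate yields a flagged
#'   degenerate point mass at 0.
#' @export
build_null <- function(rate, protocol) {
  stopifnot(rate >= 0, inherits(protocol, "trigger_protocol"))
  n <- protocol$n_trials
  ta <- protocol$after_window / 1000
  tb <- protocol$before_window / 1000
  if (rate == 0) {
    return(structure(list(values = 0, pmf = 1, tail = 1, rate = 0,
                          degenerate = TRUE, n_trials = n),
                     class = "null_model"))
  }
  la <- rate * n * ta
  lb <- rate * n * tb
  amax <- qpois(1e-13, la, lower.tail = FALSE) + 1
  bmax <- qpois(1e-13, lb, lower.tail = FALSE) + 1
  A <- 0:amax; B <- 0:bmax
  # normalized modulation for count pair (A, B)
  v <- outer(A, B, function(a, b) (a - (ta / tb) * b) / n)
  p <- outer(dpois(A, la), dpois(B, lb))
  key <- round(v, 10)
  agg <- tapply(as.vector(p), as.vector(key), sum)
  values <- as.numeric(names(agg))
  o <- order(values)
  values <- values[o]; pmf <- as.numeric(agg)[o]
  pmf <- pmf / sum(pmf)
  structure(list(values = values, pmf = pmf,
                 tail = rev(cumsum(rev(pmf))), rate = rate,
                 degenerate = FALSE, n_trials = n),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Poisson-difference null: rate %.4g spk/s over %d trials, %d support points%s\n",
              x$rate, x$n_trials, length(x$values),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Upper-tail p-value under a modulation null
#'
#' @param null a [build_null()] result.
#' @param x observed normalized modulation(s).
#' @return P(null >= x) for each x.
#' @export
null_p_value <- function(null, x) {
  stopifnot(inherits(null, "null_model"))
  idx <- findInterval(x - 1e-9, null$values) + 1
  out <- numeric(length(x))
  out[idx <= length(null$values)] <- null$tail[idx[idx <= length(null$values)]]
  out
}

#' Expected simulations per false positive
#'
#' With `n_tested` neurons tested per simulation at a per-neuron threshold
#' `threshold`, the expected number of simulations per false positive is
#' `1 / (n_tested * threshold)`.
#'
#' @param n_tested number of neurons tested per simulation.
#' @param threshold per-test p-value threshold.
#' @return Expected number of simulations per false positive.
#' @export
expected_simulations_per_false_positive <- function(n_tested, threshold = 1e-7) {
  stopifnot(n_tested > 0, threshold > 0)
  1 / (n_tested * threshold)
}

#' Detect follower neurons
#'
#' Flags neurons whose normalized firing-rate modulation is statistically
#' incompatible with the population's Poisson-difference null (one-sided
#' upper tail, strictly: a neuron is a follower iff P(null >= modulation) <
#' `threshold`). The null rate of each population is the mean baseline rate
#' of all its neurons in this record. Also returns the follower-by-trial
#' binary activation matrix (at least one spike in the trial's response
#' window).
#'
#' @param rec a `spike_record` with at least 2 trials.
#' @param threshold per-neuron p-value threshold.
#' @param nulls optional named list with elements `E` and `I` of
#'   [build_null()] objects; built from the record's baseline rates by
#'   default.
#' @return A `follower_report`: data.frame `table` (`neuron`, `population`,
#'   `delta_fr`, `p_value`, `follower`), binary `activation` matrix
#'   (followers x trials), baseline `rates`, `threshold` and protocol.
#' @export
detect_followers <- function(rec, threshold = 1e-7, nulls = NULL) {
  stopifnot(inherits(rec, "spike_record"))
  protocol <- rec$protocol
  if (protocol$n_trials < 2)
    stop("insufficient data: at least 2 trials are required")
  pops <- intersect(c("E", "I"), unique(rec$population))
  rates <- setNames(vapply(pops, function(p)
    mean_firing_rate(rec, protocol, p), numeric(1)), pops)
  rates <- c(rates, setNames(rep(0, 2 - length(pops)),
                             setdiff(c("E", "I"), pops)))[c("E", "I")]
  if (is.null(nulls))
    nulls <- setNames(lapply(pops, function(p)
      build_null(rates[[p]], protocol)), pops)
  dfr <- compute_delta_fr(rec, protocol)
  dfr$p_value <- NA_real_
  for (pop in pops) {
    m <- dfr$population == pop
    dfr$p_value[m] <- null_p_value(nulls[[pop]], dfr$delta_fr[m])
  }
  dfr$follower <- dfr$p_value < threshold
  followers <- dfr$neuron[dfr$follower]
  act <- matrix(0L, nrow = length(followers), ncol = protocol$n_trials,
                dimnames = list(followers, NULL))
  if (length(followers) > 0) {
    sp <- rec$spikes
    resp <- sp[sp$time > 0 & sp$time <= protocol$after_window &
                 sp$neuron %in% followers, ]
    if (nrow(resp) > 0) {
      act[cbind(match(resp$neuron, followers), resp$trial)] <- 1L
    }
  }
  structure(list(table = dfr, activation = act, rates = rates,
                 nulls = nulls, threshold = threshold, protocol = protocol,
                 fingerprint = rec$fingerprint),
            class = "follower_report")
}

#' @export
print.follower_report <- function(x, ...) {
  nf <- sum(x$table$follower)
  cat(sprintf("follower report: %d follower(s) of %d tested (threshold %g)\n",
              nf, nrow(x$table), x$threshold))
  cat(sprintf("  baseline rates: E %.4g spk/s, I %.4g spk/s\n",
              x$rates[["E"]], x$rates[["I"]]))
  invisible(x)
}

#' Entropy of follower identity per sequence rank
#'
#' In each qualifying trial, followers are ordered by the time of their first
#' spike in the response window; \eqn{H_k} is the Shannon entropy of follower
#' identity at rank k across trials, normalized by the entropy of a uniform
#' distribution over the n followers. Estimates are restricted to records
#' with at least as many trials as followers and to trials where at least
#' `min_present` of the followers are present.
#'
#' @param rec a `spike_record`.
#' @param report a `follower_report` from the same record.
#' @param min_present minimum fraction of followers present for a trial to
#'   qualify.
#' @return A data.frame (`rank`, `n_trials`, `H`, `H_norm`) with attributes
#'   `n_followers` and `H_u`.
#' @export
rank_entropy <- function(rec, report, min_present = 0.25) {
  stopifnot(inherits(rec, "spike_record"), inherits(report, "follower_report"))
  followers <- report$table$neuron[report$table$follower]
  n <- length(followers)
  if (n < 2) stop("insufficient data: need at least 2 followers")
  if (rec$protocol$n_trials < n)
    stop("insufficient data: fewer trials than followers")
  sp <- rec$spikes
  sp <- sp[sp$neuron %in% followers & sp$time > 0 &
             sp$time <= rec$protocol$after_window, ]
  # first spike per (trial, neuron), ranked within trial (ties by neuron id)
  sp <- sp[order(sp$trial, sp$time, sp$neuron), ]
  first <- sp[!duplicated(sp[c("trial", "neuron")]), ]
  present <- table(factor(first$trial, levels = seq_len(rec$protocol$n_trials)))
  qualify <- as.integer(names(present))[present >= min_present * n]
  if (length(qualify) == 0) stop("insufficient data: no qualifying trials")
  first <- first[first$trial %in% qualify, ]
  first$rank <- ave(first$time, first$trial, FUN = seq_along)
  H_u <- log2(n)
  ranks <- sort(unique(first$rank))
  out <- data.frame(rank = ranks, n_trials = NA_integer_,
                    H = NA_real_, H_norm = NA_real_)
  for (i in seq_along(ranks)) {
    ids <- first$neuron[first$rank == ranks[i]]
    p <- table(ids) / length(ids)
    H <- -sum(p * log2(p))
    out$n_trials[i] <- length(ids)
    out$H[i] <- H
    out$H_norm[i] <- H / H_u
  }
  attr(out, "n_followers") <- n
  attr(out, "H_u") <- H_u
  attr(out, "qualifying_trials") <- qualify
  out
}

#' Spatial centre of mass of follower activations
#'
#' For one trial, the average XY position of the followers spiking inside a
#' sliding window, then Gaussian-smoothed over time. Windows with no active
#' follower yield explicit gaps (NA).
#'
#' @param rec a `spike_record`.
#' @param report a `follower_report` from the same record.
#' @param positions data.frame with `x`, `y` per neuron id (e.g.
#'   `net$neurons`).
#' @param trial trial index.
#' @param window sliding-window width (ms).
#' @param smoothing Gaussian smoothing SD (ms).
#' @return A data.frame (`time`, `x`, `y`, `x_smooth`, `y_smooth`).
#' @export
center_of_mass <- function(rec, report, positions, trial = 1,
                           window = 5, smoothing = 15) {
  stopifnot(inherits(rec, "spike_record"), inherits(report, "follower_report"))
  followers <- report$table$neuron[report$table$follower]
  sp <- rec$spikes
  sp <- sp[sp$trial == trial & sp$neuron %in% followers & sp$time > 0 &
             sp$time <= rec$protocol$after_window, ]
  if (nrow(sp) == 0) stop("no follower spikes in this trial")
  grid <- seq(0, rec$protocol$after_window, by = 1)
  x <- y <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    act <- unique(sp$neuron[abs(sp$time - grid[i]) <= window / 2])
    if (length(act) > 0) {
      x[i] <- mean(positions$x[act])
      y[i] <- mean(positions$y[act])
    }
  }
  smooth_na <- function(v) {
    out <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    if (!any(ok)) return(out)
    for (i in seq_along(v)) {
      wgt <- dnorm(grid - grid[i], 0, smoothing) * ok
      if (sum(wgt) > 0) out[i] <- sum(wgt * ifelse(ok, v, 0)) / sum(wgt)
    }
    out
  }
  data.frame(time = grid, x = x, y = y,
             x_smooth = smooth_na(x), y_smooth = smooth_na(y))
}
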