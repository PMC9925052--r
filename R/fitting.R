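#' Two-stage membrane fit from a current-step voltage trace
#'
#' Stage 1 estimates the leak conductance from the steady-state deflection
#' after current onset (g_L = I / delta_V_ss). Stage 2 fixes g_L and fits
#' the membrane capacitance by least squares on the onset transient, where
#' the passive response is exponential with time constant C / g_L.
#'
#' @param trace a `voltage_trace` (fields `times` ms, `V` mV) spanning a
#'   pre-onset baseline and a post-onset steady state.
#' @param injected_current step amplitude (pA); must be nonzero.
#' @param t_on onset time (ms).
#' @param onset_window transient window after onset used for the C fit (ms).
#' @param ss_window window at the end of the trace averaged for the steady
#'   state (ms).
#' @param slope_tol maximal residual slope (mV/ms) in the steady-state
#'   window before the fit is rejected.
#' @return A `membrane_fit`: `g_L_hat` (nS), `C_hat` (pF), `tau_hat` (ms),
#'   residual summaries per stage.
#' @export
fit_membrane <- function(trace, injected_current, t_on,
                         onset_window = 100, ss_window = 100,
                         slope_tol = 0.005) {
  stopifnot(!is.null(trace$times), !is.null(trace$V))
  if (injected_current == 0)
    stop("zero injected current: membrane parameters are unidentifiable")
  t <- trace$times; V <- trace$V
  if (t_on <= min(t) || t_on >= max(t) - ss_window)
    stop("trace must span a baseline before t_on and a steady state after it")
  base <- mean(V[t < t_on])
  ss_sel <- t >= max(t) - ss_window
  slope <- lm.fit(cbind(1, t[ss_sel]), V[ss_sel])$coefficients[2]
  if (abs(slope) > slope_tol)
    stop(sprintf("no steady state reached (residual slope %.4g mV/ms)", slope))
  ss <- mean(V[ss_sel])
  dv <- ss - base
  if (abs(dv) < 1e-9) stop("no measurable deflection; fit is unidentifiable")
  g_L_hat <- injected_current / dv # pA / mV = nS
  # stage 2: V(t) = base + dv * (1 - exp(-(t - t_on) / tau))
  on_sel <- t >= t_on & t <= t_on + onset_window
  tt <- t[on_sel] - t_on; vv <- V[on_sel]
  sse <- function(tau) sum((vv - (base + dv * (1 - exp(-tt / tau))))^2)
  opt <- optimize(sse, c(1e-3, 10 * diff(range(t))))
  tau_hat <- opt$minimum
  structure(list(g_L_hat = g_L_hat, C_hat = g_L_hat * tau_hat,
                 tau_hat = tau_hat, baseline = base, steady_state = ss,
                 residuals = list(
                   stage1_slope = unname(slope),
                   stage2_rmse = sqrt(opt$objective / length(vv)))),
            class = "membrane_fit")
}

#' @export
print.membrane_fit <- function(x, ...) {
  cat(sprintf("membrane fit: g_L = %.4g nS, C = %.4g pF (tau = %.4g ms)\n",
              x$g_L_hat, x$C_hat, x$tau_hat))
  invisible(x)
}

#' Convert an EPSP amplitude to a synaptic peak conductance
#'
#' Numerically inverts [psp_amplitude()] at the resting potential by
#' monotone bisection: finds the excitatory peak conductance whose single
#' synaptic event depolarizes the default (or given) neuron by the requested
#' amplitude.
#'
#' @param amplitude EPSP amplitude (mV), nonnegative and below the range
#'   where the PSP triggers a spike.
#' @param params neuron parameters.
#' @param tol conductance tolerance (nS).
#' @param g_max upper search bound (nS).
#' @return Peak conductance (nS).
#' @export
epsp_to_conductance <- function(amplitude, params = neuron_params(),
                                tol = 1e-3, g_max = 200) {
  stopifnot(inherits(params, "neuron_params"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(0)
  amp_at <- function(g) {
    a <- psp_amplitude(params, g, "excitatory")
    if (isTRUE(attr(a, "spike"))) NA_real_ else as.numeric(a)
  }
  lo <- 0; hi <- g_max
  a_hi <- amp_at(hi)
  if (!is.na(a_hi) && a_hi < amplitude)
    stop("amplitude outside the invertible (subthreshold) range")
  # treat spiking responses as "too large": bisection then converges either
  # to the requested amplitude or to the spiking boundary
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    a <- amp_at(mid)
    if (is.na(a) || a >= amplitude) hi <- mid else lo <- mid
  }
  a_lo <- amp_at(lo)
  if (is.na(a_lo) || amplitude - a_lo > 0.05)
    stop("amplitude outside the invertible (subthreshold) range")
  (lo + hi) / 2
}

#' Maximum-likelihood fit of a (truncated) lognormal
#'
#' Fits the underlying lognormal parameters to conductance samples. With
#' `truncated = TRUE` (default) the likelihood is normalized by the
#' lognormal CDF at the truncation bound, i.e. a proper truncated-lognormal
#' MLE; with `truncated = FALSE` the plain lognormal likelihood is used.
#'
#' @param samples positive conductances (nS), all at or below `truncation`.
#' @param truncation truncation bound (nS).
#' @param truncated whether the likelihood accounts for truncation.
#' @return A `lognormal_fit`: `underlying_mu`, `underlying_sigma` (log-nS),
#'   `truncation`, implied truncated `mean` and `sd` (nS), `loglik`.
#' @export
fit_truncated_lognormal <- function(samples, truncation = 67.8,
                                    truncated = TRUE) {
  samples <- as.numeric(samples)
  if (length(samples) < 10) stop("insufficient data: need at least 10 samples")
  if (any(samples <= 0)) stop("samples must be positive")
  if (any(samples > truncation)) stop("samples must not exceed the truncation")
  if (sd(samples) == 0) stop("degenerate samples: zero variance")
  ls <- log(samples)
  nll <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    ll <- sum(dlnorm(samples, mu, sg, log = TRUE))
    if (truncated) ll <- ll - length(samples) *
        plnorm(truncation, mu, sg, log.p = TRUE)
    -ll
  }
  fit <- optim(c(mean(ls), log(sd(ls))), nll, method = "BFGS")
  mu <- fit$par[1]; sg <- exp(fit$par[2])
  mom <- .truncated_lognormal_moments(mu, sg, truncation)
  structure(list(underlying_mu = mu, underlying_sigma = sg,
                 truncation = truncation, mean = mom[["mean"]],
                 sd = mom[["sd"]], loglik = -fit$value,
                 truncated = truncated, n = length(samples)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(paste0("lognormal fit (%s): mu = %.4f, sigma = %.4f; ",
                     "truncated mean %.3f nS, sd %.3f nS\n"),
              if (x$truncated) "truncation-aware" else "untruncated",
              x$underlying_mu, x$underlying_sigma, x$mean, x$sd))
  invisible(x)
}

#' Bootstrap of the probability of receiving a strong connection
#'
#' Per bootstrap rep: resample the amplitude set with replacement, convert
#' to conductances, refit the truncated lognormal, compute the probability
#' p_j that one connection falls in the strong range, draw 1000 in-degrees
#' n_i from a discretized Gaussian (truncated at >= 1), sample s_ij ~
#' Binomial(n_i, p_j) and record the fraction of draws with at least one
#' strong connection.
#'
#' @param amplitude_samples EPSP amplitudes (mV).
#' @param reps bootstrap repetitions.
#' @param seed RNG seed.
#' @param strong_range strong-conductance interval (nS).
#' @param degree_mean,degree_sd in-degree Gaussian parameters.
#' @param n_degree degree draws per rep.
#' @param truncation conductance truncation bound (nS).
#' @param params neuron parameters for the amplitude-to-conductance map.
#' @return A `bootstrap_result`: vectors `p_j` and `estimate` (length
#'   `reps`) plus the configuration.
#' @export
bootstrap_strong_probability <- function(amplitude_samples, reps = 50000,
                                         seed = NULL,
                                         strong_range = c(50.6, 67.8),
                                         degree_mean = 745, degree_sd = 27,
                                         n_degree = 1000, truncation = 67.8,
                                         params = neuron_params()) {
  amplitude_samples <- as.numeric(amplitude_samples)
  if (length(amplitude_samples) == 0) stop("amplitude_samples is empty")
  n <- length(amplitude_samples)
  # amplitude -> conductance via a monotone spline over the inversion grid,
  # so each rep avoids thousands of bisection integrations
  grid_g <- seq(0, truncation, length.out = 200)
  grid_a <- vapply(grid_g, function(g)
    as.numeric(psp_amplitude(params, g, "excitatory")), numeric(1))
  to_g <- splinefun(grid_a, grid_g, method = "hyman")
  cond <- to_g(amplitude_samples)
  with_seed(seed, {
    p_j <- numeric(reps); est <- numeric(reps)
    for (j in seq_len(reps)) {
      s <- cond[sample.int(n, n, replace = TRUE)]
      if (sd(s) == 0) s <- s + rnorm(n, 0, 1e-6) # guard pathological resample
      f <- fit_truncated_lognormal(s, truncation)
      cdf <- function(q) plnorm(q, f$underlying_mu, f$underlying_sigma) /
        plnorm(truncation, f$underlying_mu, f$underlying_sigma)
      p_j[j] <- max(0, min(1, cdf(min(strong_range[2], truncation)) -
                             cdf(strong_range[1])))
      n_i <- pmax(1L, as.integer(round(rnorm(n_degree, degree_mean,
                                             degree_sd))))
      s_ij <- rbinom(n_degree, n_i, p_j[j])
      est[j] <- mean(s_ij >= 1)
    }
    structure(list(p_j = p_j, estimate = est, reps = reps,
                   strong_range = strong_range,
                   degree_mean = degree_mean, degree_sd = degree_sd,
                   seed = seed),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("bootstrap (%d reps): P(>=1 strong connection) ",
                     "median %.3f [%.3f, %.3f]\n"),
              x$reps, median(x$estimate),
              quantile(x$estimate, 0.025), quantile(x$estimate, 0.975)))
  invisible(x)
}

#' Synaptic time-constant fit from a PSP trace
#'
#' Least-squares fit of the exponential synaptic decay constant on a
#' subthreshold PSP trace, for use on synthetic traces.
#'
#' @param trace a `voltage_trace` containing a single subthreshold PSP.
#' @param event_time onset of the synaptic event (ms).
#' @param peak_conductance known event conductance (nS).
#' @param params neuron parameters (tau_syn is the fitted quantity).
#' @return Fitted tau_syn (ms).
#' @export
fit_synaptic_tau <- function(trace, event_time, peak_conductance,
                             params = neuron_params()) {
  stopifnot(!is.null(trace$times), !is.null(trace$V))
  sel <- trace$times >= event_time
  tt <- trace$times[sel]; vv <- trace$V[sel]
  sse <- function(tau) {
    p <- params; p$tau_syn <- tau
    tr <- integrate_neuron(p, events = data.frame(
      time = event_time, peak_conductance = peak_conductance,
      sign = "excitatory"), duration = max(trace$times),
      dt = diff(trace$times[1:2]), V0 = trace$V[1])
    sum((approx(tr$times, tr$V, tt)$y - vv)^2)
  }
  # the objective can be multimodal (large tau can push the trace over
  # threshold), so bracket the global minimum by a coarse scan first
  grid <- exp(seq(log(0.05), log(20), length.out = 40))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  optimize(sse, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]))$minimum
}
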