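#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so that callers' random streams are unaffected. If
#' `seed` is `NULL` the expression is evaluated as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based expansion used by the orchestration layer so
#' that every pipeline stage has its own reproducible stream. Results stay
#' below 2^31.
#'
#' @param master integer master seed.
#' @param k stage counter (1, 2, ...).
#' @return An integer seed.
#' @export
child_seed <- function(master, k) {
  stopifnot(is.numeric(master), is.numeric(k))
  as.integer((as.double(master) * 1009 + as.double(k) * 9973) %% 2147483647)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# Cheap structural fingerprint used to check that analyses that must share a
# network actually do (not a cryptographic hash).
network_fingerprint <- function(net) {
  s <- net$synapses
  c(n = net$n_neurons, m = length(s$pre),
    w = round(sum(s$weight), 3), d = round(sum(s$delay), 3))
}

# truncated-lognormal mean and sd (truncation from above at `truncation`)
.truncated_lognormal_moments <- function(mu, sigma, truncation) {
  mom <- function(k) {
    exp(k * mu + k^2 * sigma^2 / 2) *
      pnorm((log(truncation) - mu - k * sigma^2) / sigma) /
      pnorm((log(truncation) - mu) / sigma)
  }
  m1 <- mom(1); m2 <- mom(2)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}
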