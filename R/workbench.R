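#' Load and validate an experiment configuration
#'
#' Configurations are YAML files (or equivalent named lists) with the
#' sections `seed`, `output_dir`, `network`, `noise`, `protocol` and
#' optional `analyses`. Validation errors name the offending field.
#'
#' @param config path to a YAML file, or a named list.
#' @return The validated configuration list, with defaults filled in.
#' @export
load_config <- function(config) {
  src <- "<list>"
  if (is.character(config)) {
    src <- config
    if (!file.exists(config)) stop(sprintf("config file not found: %s", src))
    config <- yaml::read_yaml(config)
  }
  fail <- function(field, why)
    stop(sprintf("invalid config (%s): field '%s' %s", src, field, why))
  if (!is.list(config)) fail("<root>", "must be a mapping")
  for (f in c("seed", "output_dir", "network", "noise", "protocol"))
    if (is.null(config[[f]])) fail(f, "is required")
  if (!is.numeric(config$seed)) fail("seed", "must be numeric")
  nw <- config$network
  nw$n_neurons <- nw$n_neurons %||% 10000
  if (nw$n_neurons < 2) fail("network.n_neurons", "must be >= 2")
  config$network <- nw
  no <- config$noise
  if (is.null(no$mu_in) || is.null(no$sigma_in))
    fail("noise", "needs mu_in and sigma_in")
  pr <- config$protocol
  pr$n_trials <- pr$n_trials %||% 100
  pr$n_triggers <- pr$n_triggers %||% 1
  config$protocol <- pr
  config$analyses <- config$analyses %||% list()
  config$analyses$followers <- config$analyses$followers %||% TRUE
  config$analyses$motifs <- isTRUE(config$analyses$motifs)
  config$analyses$subnetworks <- isTRUE(config$analyses$subnetworks)
  config
}

#' Run a configured experiment end to end
#'
#' Executes build, simulate and analyze stages from a configuration,
#' writing every artifact plus a manifest with the child seeds and network
#' fingerprint to the configured output directory. Stages already present
#' on disk are reloaded instead of recomputed when `resume = TRUE`, so a
#' partially failed run can be restarted.
#'
#' The master seed expands deterministically into per-stage child seeds
#' (network = 1, simulation = 2, clustering = 3), all recorded in the
#' manifest.
#'
#' @param config path to a YAML configuration or a named list
#'   (see [load_config()]).
#' @param resume reload stages whose artifacts already exist.
#' @return An `experiment_bundle`: `config`, `net`, `rec`, `report`, and the
#'   optional `census`/`partition`, plus the `manifest`.
#' @export
run_experiment <- function(config, resume = FALSE) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(network = child_seed(cfg$seed, 1),
                simulation = child_seed(cfg$seed, 2),
                clustering = child_seed(cfg$seed, 3))
  stage <- function(name, build) {
    path <- file.path(cfg$output_dir, paste0(name, ".rds"))
    if (resume && file.exists(path)) {
      message("resuming stage '", name, "' from ", path)
      return(readRDS(path))
    }
    obj <- build()
    saveRDS(obj, path)
    obj
  }
  net <- stage("network", function()
    make_fixture_network(n_neurons = cfg$network$n_neurons,
                         seed = seeds$network))
  # deterministic trigger choice: first excitatory neurons
  trig <- cfg$protocol$trigger_ids %||%
    which(net$neurons$population == "E")[seq_len(cfg$protocol$n_triggers)]
  protocol <- trigger_protocol(
    trigger_ids = trig, n_trials = cfg$protocol$n_trials,
    kickstart_count = cfg$protocol$kickstart_count %||% 500)
  noise <- background_noise(cfg$noise$mu_in, cfg$noise$sigma_in)
  rec <- stage("record", function()
    run_protocol(net, noise, protocol, seed = seeds$simulation))
  report <- census <- partition <- NULL
  if (isTRUE(cfg$analyses$followers))
    report <- stage("followers", function() detect_followers(rec))
  if (isTRUE(cfg$analyses$motifs))
    census <- stage("motifs", function()
      motif_census(build_transfer_graph(rec, net)))
  if (isTRUE(cfg$analyses$subnetworks) && !is.null(report) &&
      sum(report$table$follower) >= 2)
    partition <- stage("subnetworks", function()
      kmodes_partition(report$activation, seed = seeds$clustering))
  manifest <- list(
    seed = cfg$seed, child_seeds = seeds,
    network_fingerprint = as.list(network_fingerprint(net)),
    n_neurons = net$n_neurons, n_synapses = nrow(net$synapses),
    n_spikes = nrow(rec$spikes),
    n_followers = if (is.null(report)) NA else sum(report$table$follower),
    package_version = as.character(utils::packageVersion("spikeroute")))
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  if (!is.null(report))
    write.table(report$table, file.path(cfg$output_dir, "followers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(config = cfg, net = net, rec = rec, report = report,
                 census = census, partition = partition,
                 manifest = manifest),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment bundle: %d neurons, %d spikes, %s follower(s)\n",
              x$net$n_neurons, nrow(x$rec$spikes),
              if (is.null(x$report)) "?" else sum(x$report$table$follower)))
  invisible(x)
}

#' Summarize a batch of experiment bundles
#'
#' One row per simulation with the headline statistics: baseline rates,
#' follower counts, outcome entropy (when a partition with >= 2 clusters is
#' present) and motif totals (when a census is present).
#'
#' @param bundles list of `experiment_bundle`s.
#' @return data.frame with one row per bundle.
#' @export
summarize_batch <- function(bundles) {
  if (length(bundles) == 0) stop("no bundles to summarize")
  vers <- vapply(bundles, function(b)
    b$manifest$package_version %||% NA_character_, character(1))
  if (length(unique(vers)) > 1)
    stop("bundles come from incompatible package versions")
  rows <- lapply(bundles, function(b) {
    stopifnot(inherits(b, "experiment_bundle"))
    ent <- NA_real_
    if (!is.null(b$partition) && length(b$partition$members) >= 2)
      ent <- outcome_entropy(b$report$activation, b$partition)$entropy
    data.frame(
      seed = b$config$seed,
      mu_in = b$rec$noise$mu_in, sigma_in = b$rec$noise$sigma_in,
      rate_E = mean_firing_rate(b$rec, population = "E"),
      rate_I = mean_firing_rate(b$rec, population = "I"),
      n_spikes = nrow(b$rec$spikes),
      n_followers = if (is.null(b$report)) NA_integer_
      else sum(b$report$table$follower),
      outcome_entropy = ent,
      motif_spikes = if (is.null(b$census)) NA_integer_
      else sum(b$census$totals))
  })
  do.call(rbind, rows)
}
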