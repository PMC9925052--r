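---
title: "Methods: models, generators and statistics in spikeroute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and statistics in spikeroute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
# This vignette is distributed as source and is not knitted at build time:
# several chunks build full-scale networks or run minutes-long simulations.
knitr::opts_chunk$set(eval = FALSE)
```

`spikeroute` simulates and analyzes how a *single extra spike* of one
excitatory neuron is routed through a biologically constrained recurrent
network, a regime documented in the three-layered visual cortex of turtles,
where one evoked spike reliably activates specific "follower" neurons over
tens of milliseconds. This vignette records the modelling conventions,
numerical choices and statistical procedures, so that every number produced
by the package can be traced to a definition.

## 1. Neuron and synapse model

Neurons are adaptive exponential integrate-and-fire (AdEx) units with
conductance-based synapses:

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - g_e (V - E_e) - g_i (V - E_i) - w + I,$$
$$\tau_w\,\dot w = a (V - E_L) - w,$$

with exponential synaptic conductance decay
$\dot g_{e,i} = -g_{e,i}/\tau_{\mathrm{syn}}$. A spike is detected when
$V \ge V_{\mathrm{detect}} = 0$ mV; then $V$ is reset to $-60$ mV, the
adaptation current is incremented by $b$, and $V$ is clamped for a 2 ms
refractory period during which $w$ and the synaptic conductances keep
evolving. The exponential term's argument is clamped at
$(V_{\mathrm{detect}} - V_T)/\Delta_T$ for numerical stability.

```{r}
library(spikeroute)
neuron_params()
```

Default parameters: $C = 239.8$ pF, $g_L = 4.2$ nS, $E_L = -70.6$ mV,
$V_T = -50.4$ mV, $\Delta_T = 2$ mV, $a = 4$ nS, $b = 80.5$ pA,
$\tau_w = 144$ ms, $E_e = 10$ mV, $E_i = -75$ mV,
$\tau_{\mathrm{syn}} = 1.103681$ ms.

Integration is forward Euler at $dt = 0.1$ ms. Natural threshold crossings
are stamped at the end of the step in which they are detected; externally
forced (trigger) spikes are stamped at the step start. The single-neuron
kernel (`integrate_neuron()`) and the network engine share these
conventions exactly, and the test suite holds them to a plain-R oracle at
$10^{-10}$ tolerance.

Two consequences worth knowing:

* At 1 pA resolution the model's rheobase (1 s constant-current trial) is
  120 pA (`rheobase(neuron_params())`). A coarser, experimental-style
  search in 50 pA increments returns 150 pA
  (`rheobase(neuron_params(), resolution = 50)`): the value quoted for
  this class of model depends on the search resolution.
* The maximal single-synapse EPSP at rest (peak conductance 67.8 nS) is
  21.09 mV; the corresponding maximal IPSP ($8 \times 67.8$ nS, neuron held
  at $-50$ mV) is $-22.58$ mV.

## 2. Network generator

`build_network()` places `n` neurons (93% excitatory) uniformly at random
on a square torus (2000 μm side at full scale) and connects them with
distance-dependent Gaussian probability
$p(d) = A \exp(-d^2 / 2\sigma^2)$ per ordered pair. The amplitude $A$ of
each of the four pair types (E→E, E→I, I→E, I→I) is calibrated
analytically so that the *expected out-degree* matches the targets
750 / 190 / 2690 / 110, using the exact first moment of the Gaussian
profile on the torus. Gaussian widths default to
$\sigma = 150$ μm (E→E, E→I, I→E) and 120 μm (I→I); narrower inhibitory
widths are infeasible on this geometry because the I→E amplitude would
have to exceed 1. Profiles that cannot reach their target raise an error
rather than silently saturating.

Synaptic conductances are drawn from a lognormal distribution truncated at
67.8 nS whose *truncated* moments are matched to mean 3.73 nS and SD
6.51 nS (`weight_distribution()` solves the underlying
$\mu = 0.4192$, $\sigma = 1.4154$). Inhibitory source weights are scaled
by 8 after truncation. Conduction delays are uniform on [0.5, 2] ms.
"Strong" connections are the top 0.3% of E→E conductances; the
moment-matched threshold is `weight_quantile(weight_distribution(),
0.997)` = 50.61 nS.

Sampling $10^{10}$ candidate pairs individually is infeasible, so the C++
builder uses geometric skip-sampling (thinning): within each (source,
target-population) scan, candidate indices advance by
$1 + \lfloor \log U / \log(1 - p_{\max}) \rfloor$ and survivors are
accepted with probability $p(d)/p_{\max}$ — distributionally identical to
per-pair Bernoulli draws. A full 100,000-neuron network (~107 million
synapses) builds in about 3 minutes and 5 GB. Builds are deterministic
given `set.seed()`/the `seed` argument.

```{r}
net <- build_network(1e5, 2000, seed = 1)     # full scale, ~3 min
fx  <- make_fixture_network(seed = 1)          # 10,000 neurons, ~3 s
```

`make_fixture_network()` shrinks the side with $\sqrt{n/10^5}$ so that
neuron *density* and the absolute out-degree targets are preserved; the
expected number of strong E→E outputs per neuron (~2.25) — the quantity
propagation depends on — is therefore scale-invariant. Below roughly
6,500 neurons the full targets become infeasible and the builder errors.

## 3. Simulation protocol

`run_protocol()` runs repeated trials. Background drive is an
Ornstein–Uhlenbeck-free simplification: each neuron receives independent
Gaussian current noise with mean `mu_in` and SD `sigma_in` per step
(`background_noise()`). Each trial forces the trigger neuron(s) to spike
once at $t = 0$; a kickstart transient and discard window precede the
analysis windows (100 ms baseline before the trigger, 300 ms response
after). The engine flags runaway trials (population spike fraction above
`runaway_frac`). At the default fixture drive (`mu_in = 90`,
`sigma_in = 30`) baseline firing is near zero and single triggers evoke
reliable, sparse propagation — the low-rate regime under study.

## 4. Follower statistics

For each neuron, `detect_followers()` computes the trigger-locked rate
change per trial,
$\Delta FR_i = (A_i - (t_a/t_b) B_i)/n_{\mathrm{trials}}$, where $A_i$ and
$B_i$ count response- and baseline-window spikes and $t_a/t_b$ corrects
the window lengths. The null distribution of $\Delta FR$ under
trigger-independent Poisson firing at the population baseline rate is
computed by *exact enumeration* of the Poisson difference (tails cut at
$10^{-13}$), separately per population; a neuron is a follower when
$P(\Delta FR_{\mathrm{null}} \ge \Delta FR_i) < 10^{-7}$. At $10^5$
neurons tested per simulation this threshold yields one false positive per
100 simulations (`expected_simulations_per_false_positive(1e-7, 1e5)`).
When the baseline rate is exactly zero the null is a point mass at zero
and is flagged as degenerate: any response spiking is then significant.

Sequencing is quantified by `rank_entropy()` — the Shannon entropy of
follower identity at each rank of the trial's first-spike order,
normalized by $\log_2 n$ — and by `center_of_mass()`, the spatial mean of
follower activity in 5 ms windows after 15 ms Gaussian smoothing.

## 5. Transfer graph and motifs

`build_transfer_graph()` connects spike $a$ to spike $b$ within a trial
when a synapse from $a$'s neuron to $b$'s neuron exists and
$0 < t_b - t_a \le 100$ ms. The graph is acyclic by construction (edges
point forward in time). `motif_census()` classifies each spike by its
presynaptic in-edges: `single` (exactly one), `convergence_2`,
`convergence_3plus`, `chain_depth_2` (an in-edge whose source itself has
an in-edge) and fan motifs on both sides (`fan_source`: a spike with ≥ 2
out-edges; `fan_target`: a spike fed by such a source).
`transfer_delay_distribution()` histograms edge delays per population
pair; in the low-rate fixture regime the E→E mode falls in the 6–8 ms
range and E→I transfer is no slower.

## 6. Sub-networks, gates and gating

Follower-by-trial binary activation matrices are clustered with a
hand-rolled k-modes algorithm (`kmodes_partition()`: Hamming
dissimilarity, Huang density seeding, `n_init = 10` restarts,
$K = \max(1, \mathrm{round}(n/6))$, empty clusters reseeded with the
worst-fitting row). A cluster is *active* in a trial when ≥ 40% of its
members fire (`subnetwork_activation()`). The *gate* of a cluster is its
member with the smallest median first-spike delay (`identify_gates()`).
`outcome_entropy()` measures the 4-outcome entropy (both / first-only /
second-only / neither active) of the two largest clusters, ≤ 2 bits;
it grows with the background drive. `gating_map()` reruns the protocol
over a grid of single external inputs (sign × conductance × timing) on a
gate neuron and reports the fold change of cluster activation, flagging
halting and facilitating inputs (|fold| ≥ 50%). `classify_multi_trigger()`
intersects follower sets of two triggers and their joint condition into
the seven set-algebra classes and marks the combination-specific core.

## 7. Fitting procedures

* `fit_membrane()`: two-stage passive fit — $g_L = I/\Delta V_{ss}$ from
  the steady-state deflection, then least-squares $\tau$ on the onset
  transient gives $C = g_L \tau$. It rejects traces without a settled
  steady state and zero-current (unidentifiable) inputs.
* `epsp_to_conductance()`: monotone bisection of the simulated PSP
  amplitude; inverse of `psp_amplitude()` on the subthreshold range.
* `fit_truncated_lognormal()`: MLE with the likelihood normalized by the
  lognormal CDF at the truncation bound (set `truncated = FALSE` for the
  naive variant, which underestimates the tail).
* `bootstrap_strong_probability()`: resamples an EPSP amplitude set,
  refits the truncated lognormal, computes the strong-range probability
  $p_j$, and propagates it through in-degrees
  $n_i \sim \mathcal{N}(745, 27)$ (discretized, ≥ 1) and
  $s_{ij} \sim \mathrm{Binomial}(n_i, p_j)$ to estimate the probability
  that a neuron receives at least one strong connection.

## 8. Synthetic data and the workbench

`make_patch_traces()`, `make_amplitude_set()` and `make_poisson_record()`
generate ground-truth-tagged inputs for the fitting and detection
procedures (the generators' defaults are the study conditions, not tuned
conveniences). `make_poisson_record()` plants followers with known
probability/latency/jitter for null-calibration checks.
`run_experiment()` drives a YAML-configured build → simulate → analyze
pipeline with per-stage child seeds, on-disk artifacts, a manifest and
`resume` support; `summarize_batch()` condenses bundles into one row per
simulation.

```{r}
cfg <- list(seed = 5, output_dir = "out",
            network = list(n_neurons = 10000),
            noise = list(mu_in = 90, sigma_in = 30),
            protocol = list(n_trials = 30))
bundle <- run_experiment(cfg)
summarize_batch(list(bundle))
```

## 9. Numerical and design notes

* All stochastic entry points accept a `seed` and restore the caller's RNG
  state; internal child seeds stay below $2^{31}$.
* Exact-enumeration nulls avoid Monte-Carlo error at the $10^{-7}$
  threshold, where simulation-based nulls would need $\gtrsim 10^9$ draws.
* The k-modes objective is verified in tests against exhaustive
  enumeration of all two-cluster partitions of toy matrices; the
  simulation engine is verified against an independent plain-R AdEx
  integrator; the network calibration against direct degree counts.
* Known limitation: the fixture cannot shrink below ~6,500 neurons with
  the default degree targets, and fixture-scale statistics (follower
  counts, entropies) are qualitative stand-ins for full-scale sweeps.
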