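#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared by all kernels (see .adex_par() on the R side):
// 0 C, 1 g_L, 2 E_L, 3 V_T, 4 Delta_T, 5 a, 6 b, 7 tau_w,
// 8 E_e, 9 E_i, 10 tau_syn, 11 V_detect, 12 V_reset, 13 t_ref

struct AdexPar {
  double C, gL, EL, VT, DT, a, b, tw, Ee, Ei, ts, Vdet, Vres, tref;
  double clamp_arg; // exponential-term argument clamp
  explicit AdexPar(const NumericVector& p)
    : C(p[0]), gL(p[1]), EL(p[2]), VT(p[3]), DT(p[4]), a(p[5]), b(p[6]),
      tw(p[7]), Ee(p[8]), Ei(p[9]), ts(p[10]), Vdet(p[11]), Vres(p[12]),
      tref(p[13]) {
    clamp_arg = (Vdet - VT) / DT;
  }
};

static inline double adex_dV(const AdexPar& P, double V, double w,
                             double ge, double gi, double I) {
  double arg = (V - P.VT) / P.DT;
  if (arg > P.clamp_arg) arg = P.clamp_arg;
  // skip the exponential where it contributes < 1e-3 pA
  double ex = (arg > -18.0) ? P.gL * P.DT * std::exp(arg) : 0.0;
  return (-P.gL * (V - P.EL) + ex - ge * (V - P.Ee) - gi * (V - P.Ei) - w + I) / P.C;
}

// [[Rcpp::export(name = ".integrate_neuron_cpp")]]
List integrate_neuron_cpp(NumericVector par, double duration, double dt,
                          NumericVector drive_t, NumericVector drive_I,
                          NumericVector ev_t, NumericVector ev_g,
                          LogicalVector ev_inh, double V0, double w0) {
  AdexPar P(par);
  const int n = (int)std::lround(duration / dt);
  NumericVector times(n + 1), Vtr(n + 1), wtr(n + 1);
  std::vector<double> spikes;
  double V = V0, w = w0, ge = 0.0, gi = 0.0, refu = -1.0;
  const double dec = std::exp(-dt / P.ts);
  int di = 0, ei = 0;
  const int nd = drive_t.size(), ne = ev_t.size();
  times[0] = 0.0; Vtr[0] = V; wtr[0] = w;
  for (int k = 0; k < n; ++k) {
    const double t = k * dt;
    while (ei < ne && ev_t[ei] <= t + 1e-9) {
      if (ev_inh[ei]) gi += ev_g[ei]; else ge += ev_g[ei];
      ++ei;
    }
    while (di + 1 < nd && drive_t[di + 1] <= t + 1e-9) ++di;
    const double I = nd > 0 ? drive_I[di] : 0.0;
    double Vn, wn = w + dt / P.tw * (P.a * (V - P.EL) - w);
    if (t < refu - 1e-9) {
      Vn = P.Vres; // pinned during refractory; w and conductances evolve
    } else {
      Vn = V + dt * adex_dV(P, V, w, ge, gi, I);
    }
    ge *= dec; gi *= dec;
    V = Vn; w = wn;
    if (!std::isfinite(V) || !std::isfinite(w))
      stop("integration failure: non-finite state at t = %f ms", t + dt);
    if (V >= P.Vdet && t >= refu - 1e-9) {
      spikes.push_back(t + dt);
      V = P.Vres; w += P.b; refu = (t + dt) + P.tref;
    }
    times[k + 1] = t + dt; Vtr[k + 1] = V; wtr[k + 1] = w;
  }
  return List::create(_["times"] = times, _["V"] = Vtr, _["w"] = wtr,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}

// ---------------------------------------------------------------------------
// Spatial network generation: independent Bernoulli edge per ordered pair,
// p = amplitude[type] * exp(-d^2 / (2 sigma[type]^2)) with torus distance d.
// Pair types: 0 E->E, 1 E->I, 2 I->E, 3 I->I.

// Fast internal RNG (xoshiro256++) for the O(n^2) pair scan; seeded from
// R's RNG stream so generation stays reproducible under set.seed().
static inline uint64_t splitmix64(uint64_t& z) {
  z += 0x9e3779b97f4a7c15ULL;
  uint64_t r = z;
  r = (r ^ (r >> 30)) * 0xbf58476d1ce4e5b9ULL;
  r = (r ^ (r >> 27)) * 0x94d049bb133111ebULL;
  return r ^ (r >> 31);
}
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]: never 0, so log() is finite
  inline double u01() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

// [[Rcpp::export(name = ".build_network_cpp")]]
List build_network_cpp(NumericVector x, NumericVector y, LogicalVector is_exc,
                       NumericVector amp, NumericVector sigma, double side,
                       double w_mu, double w_sigma, double w_max,
                       double inh_scale, double delay_min, double delay_max,
                       double reserve_n) {
  const int n = x.size();
  const double half = side / 2.0;
  const int NT = 1 << 14;
  // per-type probability lookup over d^2, linear interpolation
  std::vector<std::vector<double>> tab(4);
  double d2max[4], step[4];
  for (int t = 0; t < 4; ++t) {
    if (amp[t] <= 0) { d2max[t] = -1.0; step[t] = 1.0; continue; }
    // skip pairs where p < 1e-8 (expected missed edges ~ O(10) out of ~1e8)
    double lim = 2.0 * sigma[t] * sigma[t] * (std::log(amp[t]) + 8.0 * std::log(10.0));
    if (lim <= 0) lim = 1e-6;
    const double maxd2 = 2.0 * half * half;
    if (lim > maxd2) lim = maxd2;
    d2max[t] = lim; step[t] = lim / NT;
    tab[t].resize(NT + 2);
    for (int k = 0; k <= NT + 1; ++k)
      tab[t][k] = amp[t] * std::exp(-(k * step[t]) / (2.0 * sigma[t] * sigma[t]));
  }
  std::vector<int> pre, post;
  std::vector<double> wt, dl;
  const size_t rsv = (size_t)reserve_n;
  pre.reserve(rsv); post.reserve(rsv); wt.reserve(rsv); dl.reserve(rsv);
  const double dspan = delay_max - delay_min;
  uint64_t seed64 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                    (uint64_t)(unif_rand() * 4294967296.0);
  FastRng rng(seed64);
  // split targets by population so the pair type is constant per inner loop
  std::vector<double> tx[2], ty_[2];
  std::vector<int> tid[2];
  for (int j = 0; j < n; ++j) {
    const int pj = is_exc[j] ? 0 : 1;
    tx[pj].push_back(x[j]); ty_[pj].push_back(y[j]); tid[pj].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    const int base = is_exc[i] ? 0 : 2;
    for (int pj = 0; pj < 2; ++pj) {
      const int ty = base + pj;
      const double lim = d2max[ty];
      if (lim < 0) continue;
      const double dlim = std::sqrt(lim);
      const double istep = 1.0 / step[ty];
      const double* t0 = tab[ty].data();
      const double* px = tx[pj].data();
      const double* py = ty_[pj].data();
      const int* pid = tid[pj].data();
      const int m = (int)tx[pj].size();
      // Geometric skip-sampling (thinning): visit only candidate targets,
      // each index an independent Bernoulli(pmax) hit, then accept with
      // p(d)/pmax -- exactly an independent Bernoulli(p(d)) per pair.
      const double pmax = amp[ty];
      const double ilog1mp = 1.0 / std::log1p(-pmax);
      long k = -1;
      for (;;) {
        k += 1 + (long)(std::log(rng.u01()) * ilog1mp);
        if (k >= m) break;
        double dx = std::fabs(xi - px[k]); if (dx > half) dx = side - dx;
        if (dx >= dlim) continue;
        double dy = std::fabs(yi - py[k]); if (dy > half) dy = side - dy;
        const double d2 = dx * dx + dy * dy;
        if (d2 >= lim) continue;
        const int j = pid[k];
        if (j == i) continue;
        const double u = d2 * istep;
        const int k0 = (int)u;
        const double p = t0[k0] + (u - k0) * (t0[k0 + 1] - t0[k0]);
        if (rng.u01() * pmax < p) {
          double g;
          do { g = std::exp(w_mu + w_sigma * norm_rand()); } while (g > w_max);
          if (!is_exc[i]) g *= inh_scale;
          pre.push_back(i + 1);
          post.push_back(j + 1);
          wt.push_back(g);
          dl.push_back(delay_min + dspan * rng.u01());
        }
      }
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // hand the columns over one at a time to limit peak memory
  IntegerVector rpre(pre.begin(), pre.end()); std::vector<int>().swap(pre);
  IntegerVector rpost(post.begin(), post.end()); std::vector<int>().swap(post);
  NumericVector rwt(wt.begin(), wt.end()); std::vector<double>().swap(wt);
  NumericVector rdl(dl.begin(), dl.end()); std::vector<double>().swap(dl);
  return List::create(_["pre"] = rpre, _["post"] = rpost,
                      _["weight"] = rwt, _["delay"] = rdl);
}

// ---------------------------------------------------------------------------
// Clock-driven network simulation. Synapses in CSR layout sorted by
// presynaptic id; spike deliveries via a ring buffer of conductance jumps.

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(NumericVector par, int n, LogicalVector is_exc,
                          IntegerVector adj_ptr, IntegerVector adj_tgt,
                          NumericVector adj_w, IntegerVector adj_dstep,
                          double dt, int n_steps,
                          double noise_mu, double noise_sigma,
                          int noise_refresh,
                          IntegerVector force_step, IntegerVector force_neuron,
                          IntegerVector ext_step, IntegerVector ext_target,
                          NumericVector ext_g, LogicalVector ext_inh,
                          int record_from, double runaway_frac) {
  AdexPar P(par);
  std::vector<double> V(n, P.EL), w(n, 0.0), ge(n, 0.0), gi(n, 0.0), Inoise(n, noise_mu);
  std::vector<int> refu(n, -1);
  const double dec = std::exp(-dt / P.ts);
  const double dt_C = dt / P.C, dt_tw = dt / P.tw;
  const double skipV = P.VT - 18.0 * P.DT;
  int maxd = 1;
  for (int e = 0; e < adj_dstep.size(); ++e) if (adj_dstep[e] > maxd) maxd = adj_dstep[e];
  const int L = maxd + 2;
  std::vector<std::vector<std::pair<int, double>>> ring_e(L), ring_i(L);
  std::vector<int> sp_neuron; std::vector<int> sp_step;
  int fi = 0, xi = 0;
  const int nf = force_step.size(), nx = ext_step.size();
  bool runaway = false; int runaway_step = -1;
  const int runaway_n = (int)std::ceil(runaway_frac * n);
  std::vector<int> fired; fired.reserve(256);

  for (int s = 0; s < n_steps; ++s) {
    // scheduled synaptic deliveries for this step
    {
      auto& de = ring_e[s % L];
      for (auto& pr : de) ge[pr.first] += pr.second;
      de.clear();
      auto& di = ring_i[s % L];
      for (auto& pr : di) gi[pr.first] += pr.second;
      di.clear();
    }
    // external conductance injections
    while (xi < nx && ext_step[xi] == s) {
      if (ext_inh[xi]) gi[ext_target[xi]] += ext_g[xi];
      else ge[ext_target[xi]] += ext_g[xi];
      ++xi;
    }
    // background noise current, redrawn every noise_refresh steps
    if (noise_sigma > 0 && s % noise_refresh == 0)
      for (int i = 0; i < n; ++i) Inoise[i] = noise_mu + noise_sigma * norm_rand();

    fired.clear();
    // forced spikes (trigger / kick-start volley): full spike lifecycle
    while (fi < nf && force_step[fi] == s) {
      const int i = force_neuron[fi];
      fired.push_back(i);
      V[i] = P.Vres; w[i] += P.b; refu[i] = s + (int)std::lround(P.tref / dt);
      ++fi;
    }
    const size_t n_forced = fired.size();

    for (int i = 0; i < n; ++i) {
      const double Vi = V[i], wi = w[i];
      double Vn;
      if (s < refu[i]) {
        Vn = P.Vres;
      } else {
        double arg = (Vi - P.VT) / P.DT;
        if (arg > P.clamp_arg) arg = P.clamp_arg;
        const double ex = (Vi > skipV) ? P.gL * P.DT * std::exp(arg) : 0.0;
        Vn = Vi + dt_C * (-P.gL * (Vi - P.EL) + ex - ge[i] * (Vi - P.Ee)
                          - gi[i] * (Vi - P.Ei) - wi + Inoise[i]);
      }
      w[i] = wi + dt_tw * (P.a * (Vi - P.EL) - wi);
      ge[i] *= dec; gi[i] *= dec;
      if (Vn >= P.Vdet && s >= refu[i]) {
        fired.push_back(i);
        V[i] = P.Vres; w[i] += P.b; refu[i] = s + 1 + (int)std::lround(P.tref / dt);
      } else {
        V[i] = Vn;
      }
      if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
        stop("integration failure: non-finite state, neuron %d, t = %f ms", i + 1, s * dt);
    }
    if ((int)(fired.size() - n_forced) >= runaway_n && !runaway) {
      runaway = true; runaway_step = s;
    }
    // record and deliver; forced spikes happen at the start of step s
    // (time s*dt), threshold crossings at its end (time (s+1)*dt)
    for (size_t k = 0; k < fired.size(); ++k) {
      const int i = fired[k];
      const int st = (k < n_forced) ? s : s + 1;
      if (st >= record_from) { sp_neuron.push_back(i + 1); sp_step.push_back(st); }
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
        const int slot = (st + adj_dstep[e]) % L;
        if (is_exc[i]) ring_e[slot].emplace_back(adj_tgt[e], adj_w[e]);
        else ring_i[slot].emplace_back(adj_tgt[e], adj_w[e]);
      }
    }
    if ((s & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
                      _["step"] = IntegerVector(sp_step.begin(), sp_step.end()),
                      _["runaway"] = runaway,
                      _["runaway_step"] = runaway_step);
}
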