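#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Self-contained RNG primitives so that per-neuron streams are fully
// reproducible from (seed, stream_id) and independent of R's RNG state.

static inline double u01(std::mt19937_64 &g) {
  // 53-bit uniform in [0, 1)
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline double gauss(std::mt19937_64 &g) {
  double u1 = u01(g), u2 = u01(g);
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) *
         std::cos(6.283185307179586476925286766559 * u2);
}

// Knuth multiplicative Poisson; per-step means here are at most a few.
static inline int rpois_small(std::mt19937_64 &g, double expmlam) {
  int k = 0;
  double p = u01(g);
  while (p > expmlam) {
    ++k;
    p *= u01(g);
  }
  return k;
}

static std::mt19937_64 make_stream(int seed, int stream_id, int tag) {
  std::seed_seq ss{seed, stream_id, tag};
  return std::mt19937_64(ss);
}

// Synchronous step-based simulation of a population of modified
// integrate-and-fire neurons with cumulative post-spike potentials and
// delayed, unreliable excitatory network transmission.
//
// Parameter matrix columns (one row per neuron):
//  0 I_re    1 I_ratio  2 e_h      3 i_h       4 lambda_syn
//  5 k_HAP   6 lambda_HAP  7 k_AHP  8 lambda_AHP  9 k_DAP  10 lambda_DAP
// 11 V_rest 12 V_thresh 13 t_refabs 14 synweight
//
// Edges are 0-based (src, tgt) with integer delays in steps (>= 1).
// ou_spec: list(use, mu, tau_ms, k_per_sqrt_ms) - global OU process that
// replaces I_re for all neurons when active.
// pert: matrix with columns onset_ms, dur_ms, delta_hz added to the
// effective external EPSP rate of every neuron.
// [[Rcpp::export]]
List sim_network_cpp(NumericMatrix pm, IntegerVector edge_src,
                     IntegerVector edge_tgt, IntegerVector edge_delay,
                     double syntrans, double n_h, double dt, int n_steps,
                     int seed, IntegerVector stream_ids,
                     IntegerVector record_idx, bool init_at_k, List ou_spec,
                     NumericMatrix pert, bool record_rate, bool euler_decay) {
  const int n = pm.nrow();
  const int n_edges = edge_src.size();

  // per-neuron constants
  std::vector<double> I_re(n), I_ratio(n), e_h(n), i_h(n), k_HAP(n), k_AHP(n),
      k_DAP(n), V_rest(n), V_thresh(n), t_refabs(n), synweight(n), d_syn(n),
      d_hap(n), d_ahp(n), d_dap(n);
  for (int i = 0; i < n; ++i) {
    I_re[i] = pm(i, 0);
    I_ratio[i] = pm(i, 1);
    e_h[i] = pm(i, 2);
    i_h[i] = pm(i, 3);
    k_HAP[i] = pm(i, 5);
    k_AHP[i] = pm(i, 7);
    k_DAP[i] = pm(i, 9);
    V_rest[i] = pm(i, 11);
    V_thresh[i] = pm(i, 12);
    t_refabs[i] = pm(i, 13);
    synweight[i] = pm(i, 14);
    // per-step decay factor: forward-Euler (1 - dt/tau), the direct
    // discretisation of the model equations, or exact exp(-dt/tau)
    if (euler_decay) {
      const double ln2 = std::log(2.0);
      d_syn[i] = 1.0 - dt * ln2 / pm(i, 4);
      d_hap[i] = 1.0 - dt * ln2 / pm(i, 6);
      d_ahp[i] = 1.0 - dt * ln2 / pm(i, 8);
      d_dap[i] = 1.0 - dt * ln2 / pm(i, 10);
      for (double *d : {&d_syn[i], &d_hap[i], &d_ahp[i], &d_dap[i]}) {
        if (*d < 0.0) *d = 0.0;
      }
    } else {
      d_syn[i] = std::pow(2.0, -dt / pm(i, 4));
      d_hap[i] = std::pow(2.0, -dt / pm(i, 6));
      d_ahp[i] = std::pow(2.0, -dt / pm(i, 8));
      d_dap[i] = std::pow(2.0, -dt / pm(i, 10));
    }
  }

  // per-neuron RNG streams: tag 1 external input, tag 2 inbound transmission
  std::vector<std::mt19937_64> rng_ext, rng_trans;
  rng_ext.reserve(n);
  rng_trans.reserve(n);
  for (int i = 0; i < n; ++i) {
    rng_ext.push_back(make_stream(seed, stream_ids[i], 1));
    rng_trans.push_back(make_stream(seed, stream_ids[i], 2));
  }

  // OU noise on the shared external input rate
  bool ou_use = as<bool>(ou_spec["use"]);
  double ou_mu = 0.0, ou_tau = 1.0, ou_k = 0.0, ou_rate = 0.0;
  std::mt19937_64 rng_ou = make_stream(seed, -1, 3);
  if (ou_use) {
    ou_mu = as<double>(ou_spec["mu"]);
    ou_tau = as<double>(ou_spec["tau_ms"]);
    ou_k = as<double>(ou_spec["k_per_sqrt_ms"]);
    ou_rate = ou_mu;
  }
  const double sqdt = std::sqrt(dt);

  const int n_pert = pert.nrow();
  const bool rate_varies = ou_use || n_pert > 0;

  // cached exp(-lambda) for the twin Poisson draws (constant-rate case)
  std::vector<double> exml_e(n), exml_i(n);
  if (!rate_varies) {
    for (int i = 0; i < n; ++i) {
      exml_e[i] = std::exp(-I_re[i] * dt / 1000.0);
      exml_i[i] = std::exp(-I_ratio[i] * I_re[i] * dt / 1000.0);
    }
  }

  // adjacency in CSR form by source neuron
  std::vector<int> off(n + 1, 0), adj_tgt(n_edges), adj_del(n_edges);
  {
    for (int e = 0; e < n_edges; ++e) off[edge_src[e] + 1]++;
    for (int i = 0; i < n; ++i) off[i + 1] += off[i];
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int s = edge_src[e];
      adj_tgt[pos[s]] = edge_tgt[e];
      adj_del[pos[s]] = edge_delay[e];
      pos[s]++;
    }
  }
  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];

  // per-neuron delay queues as one flat ring buffer
  const int H = max_delay + 2;
  std::vector<int> queue((size_t)n * H, 0);

  // dynamic state
  std::vector<double> V_syn(n, 0.0), HAP(n), AHP(n), DAP(n),
      t_last(n, -1e18);
  for (int i = 0; i < n; ++i) {
    HAP[i] = init_at_k ? k_HAP[i] : 0.0;
    AHP[i] = init_at_k ? k_AHP[i] : 0.0;
    DAP[i] = init_at_k ? k_DAP[i] : 0.0;
  }

  std::vector<std::vector<double>> spikes(n);
  std::vector<int> spiked;
  spiked.reserve(n);

  const int n_rec = record_idx.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps : 0, n_rec);
  std::vector<int> rec_col(n, -1);
  for (int r = 0; r < n_rec; ++r) rec_col[record_idx[r]] = r;

  NumericVector rate_trace(record_rate ? n_steps : 0);

  double attempts = 0.0, delivered = 0.0;

  for (int t = 1; t <= n_steps; ++t) {
    const double now = t * dt;
    const int slot = t % H;

    double delta = 0.0;
    if (ou_use) {
      ou_rate += (ou_mu - ou_rate) / ou_tau * dt + ou_k * sqdt * gauss(rng_ou);
      if (ou_rate < 0.0) ou_rate = 0.0;  // Poisson rates cannot go negative
    }
    for (int p = 0; p < n_pert; ++p) {
      if (now > pert(p, 0) && now <= pert(p, 0) + pert(p, 1)) delta += pert(p, 2);
    }
    if (record_rate && ou_use) rate_trace[t - 1] = ou_rate;

    spiked.clear();
    for (int i = 0; i < n; ++i) {
      // external Poisson EPSP/IPSP counts
      int en, in;
      if (!rate_varies) {
        en = rpois_small(rng_ext[i], exml_e[i]);
        in = rpois_small(rng_ext[i], exml_i[i]);
      } else {
        double r = (ou_use ? ou_rate : I_re[i]) + delta;
        if (r < 0.0) r = 0.0;
        en = rpois_small(rng_ext[i], std::exp(-r * dt / 1000.0));
        in = rpois_small(rng_ext[i], std::exp(-I_ratio[i] * r * dt / 1000.0));
      }
      const double I_ext = e_h[i] * en + i_h[i] * in;

      // delayed network EPSPs arriving this step
      int &head = queue[(size_t)i * H + slot];
      const double I_net = synweight[i] * n_h * head;
      head = 0;

      // decay, then integrate this step's input
      V_syn[i] = V_syn[i] * d_syn[i] + I_ext + I_net;
      HAP[i] *= d_hap[i];
      AHP[i] *= d_ahp[i];
      DAP[i] *= d_dap[i];

      const double V = V_rest[i] + V_syn[i] - HAP[i] - AHP[i] + DAP[i];
      if (rec_col[i] >= 0) vtrace(t - 1, rec_col[i]) = V;

      if (V >= V_thresh[i] && now - t_last[i] > t_refabs[i]) {
        spikes[i].push_back(now);
        t_last[i] = now;
        // cumulative post-spike potentials: no reset, increments act from
        // the next step
        HAP[i] += k_HAP[i];
        AHP[i] += k_AHP[i];
        DAP[i] += k_DAP[i];
        if (n_edges > 0) spiked.push_back(i);
      }
    }

    // transmission: spikes from step t are eligible for delivery from t + d
    for (size_t s = 0; s < spiked.size(); ++s) {
      const int i = spiked[s];
      for (int e = off[i]; e < off[i + 1]; ++e) {
        const int j = adj_tgt[e];
        attempts += 1.0;
        if (u01(rng_trans[j]) < syntrans) {
          delivered += 1.0;
          queue[(size_t)j * H + (t + adj_del[e]) % H] += 1;
        }
      }
    }

    if (t % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  return List::create(
      _["spikes"] = sp, _["v"] = vtrace, _["rate"] = rate_trace,
      _["diag"] = List::create(_["attempts"] = attempts,
                               _["delivered"] = delivered));
}
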