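// Compiled settling / training core. Mirrors the reference R engine
// (R/dynamics.R, R/engine.R) exactly: synchronous conductance updates,
// pool-wise kWTA inhibition, explicit membrane integration, saturating
// rate function, and the phase-contrast weight updates. All randomness
// (weights, connectivity, presentation orders) is drawn in R; this code is
// fully deterministic.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Proj {
  int from, to, rule, gate;   // rule: 1 hebb, 2 msp(TT), 3 tsp(TP)
  double scale, lmix, lr;
  NumericMatrix W;                       // senders x receivers (cloned)
  std::vector<std::vector<int>> adj;     // per sender: connected receivers
  std::vector<double> fanin;             // per receiver: connected senders
};

struct Net {
  int n_layers;
  std::vector<int> n;
  std::vector<std::vector<std::vector<int>>> pools;  // layer -> pool -> units
  std::vector<std::vector<int>> pool_k;
  std::vector<Proj> proj;
  double g_l, gain, threshold, e_exc, e_inh, e_leak, dt, kwta_pt, eps;
  int n_steps;
  bool soft_bound;
  // state
  std::vector<std::vector<double>> y, vm;

  void reset() {
    for (int l = 0; l < n_layers; ++l) {
      std::fill(y[l].begin(), y[l].end(), 0.0);
      std::fill(vm[l].begin(), vm[l].end(), e_leak);
    }
  }

  double gtheta(double ge) const {
    return (ge * (e_exc - threshold) + g_l * (e_leak - threshold)) /
           (threshold - e_inh);
  }

  // gate ids: 0 always open, 1 ec_in->ca1, 2 ca3->ca1, 3 ec_in->ec_out.
  // TT: 2 and 3 closed; TP: 1 and 3 closed; PLUS: only 2 closed.
  static bool gate_closed(int gate, int phase) {
    switch (phase) {
      case 0: return gate == 2 || gate == 3;
      case 1: return gate == 1 || gate == 3;
      default: return gate == 2;
    }
  }

  // phase: 0 TT, 1 TP, 2 PLUS. clamped: layer -> clamp vector or empty.
  void settle_phase(int phase, const std::vector<std::vector<double>>& clamp) {
    for (int l = 0; l < n_layers; ++l)
      if (!clamp[l].empty()) y[l] = clamp[l];
    std::vector<std::vector<double>> ge(n_layers);
    std::vector<std::vector<double>> contrib(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      ge[l].resize(n[l]);
      contrib[l].resize(n[l]);
    }
    std::vector<int> nproj(n_layers);
    std::vector<double> gt;
    for (int step = 0; step < n_steps; ++step) {
      for (int l = 0; l < n_layers; ++l) {
        std::fill(ge[l].begin(), ge[l].end(), 0.0);
        nproj[l] = 0;
      }
      for (const Proj& p : proj) {
        if (gate_closed(p.gate, phase)) continue;
        if (!clamp[p.to].empty()) continue;
        const int nt = n[p.to];
        std::fill(contrib[p.to].begin(), contrib[p.to].begin() + nt, 0.0);
        const double* w = REAL(p.W);
        const int nf = n[p.from];
        const std::vector<double>& x = y[p.from];
        double* c = contrib[p.to].data();
        for (int i = 0; i < nf; ++i) {
          const double xi = x[i];
          if (xi == 0.0) continue;
          for (int r : p.adj[i]) c[r] += xi * w[i + (size_t)r * nf];
        }
        double* g = ge[p.to].data();
        for (int r = 0; r < nt; ++r) g[r] += p.scale * c[r] / p.fanin[r];
        ++nproj[p.to];
      }
      for (int l = 0; l < n_layers; ++l) {
        if (!clamp[l].empty()) continue;
        double* g = ge[l].data();
        if (nproj[l] > 1)
          for (int u = 0; u < n[l]; ++u) g[u] /= nproj[l];
        // pool-wise kWTA inhibitory conductance, then membrane + rate
        for (size_t pi = 0; pi < pools[l].size(); ++pi) {
          const std::vector<int>& members = pools[l][pi];
          const int k = pool_k[l][pi];
          const int np = (int)members.size();
          gt.resize(np);
          for (int m = 0; m < np; ++m) gt[m] = gtheta(g[members[m]]);
          std::vector<double> srt(gt);
          std::nth_element(srt.begin(), srt.begin() + (k - 1), srt.end(),
                           std::greater<double>());
          const double upper = srt[k - 1];
          double lower;
          if (k < np) {
            std::nth_element(srt.begin(), srt.begin() + k, srt.end(),
                             std::greater<double>());
            lower = srt[k];
          } else {
            lower = std::min(*std::min_element(gt.begin(), gt.end()), 0.0);
          }
          double gi = lower + kwta_pt * (upper - lower);
          if (gi < 0.0) gi = 0.0;
          for (int m = 0; m < np; ++m) {
            const int u = members[m];
            double v = vm[l][u];
            v += dt * (g[u] * (e_exc - v) + gi * (e_inh - v) +
                       g_l * (e_leak - v));
            vm[l][u] = v;
            const double d = v - threshold;
            y[l][u] = (d > 0.0) ? gain * d / (gain * d + 1.0) : 0.0;
          }
        }
      }
    }
  }

  // one full cycle; snapshots filled with per-phase y copies
  void run_cycle(const std::vector<double>& input, bool train, bool msp_only,
                 std::vector<std::vector<std::vector<double>>>& snaps) {
    reset();
    std::vector<std::vector<double>> clamp(n_layers);
    clamp[0] = input;  // ec_in
    if (msp_only) {
      clamp[1].assign(n[1], 0.0);  // dg
      clamp[2].assign(n[2], 0.0);  // ca3
    }
    const int n_phases = train ? 3 : 2;
    snaps.assign(n_phases, {});
    for (int ph = 0; ph < n_phases; ++ph) {
      settle_phase(ph, clamp);
      snaps[ph] = y;
    }
  }

  void learn(const std::vector<std::vector<std::vector<double>>>& snaps,
             bool msp_only) {
    const std::vector<std::vector<double>>& plus = snaps[2];
    for (Proj& p : proj) {
      if (p.rule == 0) continue;
      if (msp_only && p.rule != 2) continue;
      const int nf = n[p.from];
      const std::vector<double>& xp = plus[p.from];
      const std::vector<double>& yp = plus[p.to];
      const std::vector<std::vector<double>>& minus =
          snaps[p.rule == 2 ? 0 : 1];
      const std::vector<double>& xm = minus[p.from];
      const std::vector<double>& ym = minus[p.to];
      const double eps_p = eps * p.lr;
      double* w = REAL(p.W);
      for (int i = 0; i < nf; ++i) {
        for (int r : p.adj[i]) {
          double& wij = w[i + (size_t)r * nf];
          const double hebb = yp[r] * (xp[i] - wij);
          double delta;
          if (p.rule == 1) {
            delta = eps_p * hebb;
          } else {
            const double err = xp[i] * yp[r] - xm[i] * ym[r];
            delta = eps_p * (p.lmix * hebb + (1.0 - p.lmix) * err);
          }
          if (soft_bound) {
            wij += (delta > 0.0) ? delta * (1.0 - wij) : delta * wij;
          } else {
            wij += delta;
            if (wij < 0.0) wij = 0.0;
            else if (wij > 1.0) wij = 1.0;
          }
        }
      }
    }
  }
};

Net build_net(const List& nl) {
  Net net;
  IntegerVector layer_n = nl["layer_n"];
  net.n_layers = layer_n.size();
  net.n = as<std::vector<int>>(layer_n);
  List pool = nl["pool"], pool_k = nl["pool_k"];
  net.pools.resize(net.n_layers);
  net.pool_k.resize(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    IntegerVector pl = pool[l];
    IntegerVector kk = pool_k[l];
    net.pool_k[l] = as<std::vector<int>>(kk);
    net.pools[l].resize(kk.size());
    for (int u = 0; u < pl.size(); ++u) net.pools[l][pl[u]].push_back(u);
  }
  IntegerVector pf = nl["proj_from"], pt = nl["proj_to"],
                rule = nl["proj_rule"], gate = nl["proj_gate"];
  NumericVector scale = nl["proj_scale"], lmix = nl["proj_lmix"],
                lr = nl["proj_lr"];
  List Ws = nl["proj_W"], Ms = nl["proj_mask"];
  for (int j = 0; j < pf.size(); ++j) {
    Proj p;
    p.from = pf[j]; p.to = pt[j]; p.rule = rule[j]; p.gate = gate[j];
    p.scale = scale[j]; p.lmix = lmix[j]; p.lr = lr[j];
    p.W = clone(as<NumericMatrix>(Ws[j]));
    IntegerMatrix m = Ms[j];
    const int nf = m.nrow(), nt = m.ncol();
    p.adj.resize(nf);
    p.fanin.assign(nt, 0.0);
    for (int i = 0; i < nf; ++i)
      for (int r = 0; r < nt; ++r)
        if (m(i, r) != 0) {
          p.adj[i].push_back(r);
          p.fanin[r] += 1.0;
        }
    for (int r = 0; r < nt; ++r)
      if (p.fanin[r] < 1.0) p.fanin[r] = 1.0;
    net.proj.push_back(std::move(p));
  }
  net.g_l = nl["g_l"]; net.gain = nl["gain"]; net.threshold = nl["threshold"];
  net.e_exc = nl["e_rev_exc"]; net.e_inh = nl["e_rev_inh"];
  net.e_leak = nl["e_rev_leak"]; net.dt = nl["dt_vm"];
  net.kwta_pt = nl["kwta_pt"]; net.eps = nl["eps"];
  net.n_steps = nl["n_settle_steps"];
  net.soft_bound = nl["soft_bound"];
  net.y.resize(net.n_layers);
  net.vm.resize(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    net.y[l].assign(net.n[l], 0.0);
    net.vm[l].assign(net.n[l], 0.0);
  }
  return net;
}

List snaps_to_list(const std::vector<std::vector<std::vector<double>>>& s) {
  List out(s.size());
  for (size_t ph = 0; ph < s.size(); ++ph) {
    List lay(s[ph].size());
    for (size_t l = 0; l < s[ph].size(); ++l) lay[l] = wrap(s[ph][l]);
    out[ph] = lay;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_cycle(List net_list, NumericVector input, bool train,
                   bool msp_only) {
  Net net = build_net(net_list);
  std::vector<std::vector<std::vector<double>>> snaps;
  net.run_cycle(as<std::vector<double>>(input), train, msp_only, snaps);
  return snaps_to_list(snaps);
}

// [[Rcpp::export]]
List cpp_train(List net_list, NumericMatrix patterns, IntegerMatrix orders,
               bool msp_only) {
  Net net = build_net(net_list);
  const int n_epochs = orders.nrow(), n_pat = orders.ncol();
  const int n_ec = patterns.ncol();
  std::vector<std::vector<std::vector<double>>> snaps;
  std::vector<double> input(n_ec);
  for (int e = 0; e < n_epochs; ++e) {
    for (int t = 0; t < n_pat; ++t) {
      const int idx = orders(e, t) - 1;
      for (int u = 0; u < n_ec; ++u) input[u] = patterns(idx, u);
      net.run_cycle(input, true, msp_only, snaps);
      net.learn(snaps, msp_only);
    }
  }
  List w(net.proj.size());
  for (size_t j = 0; j < net.proj.size(); ++j) w[j] = net.proj[j].W;
  return w;
}

// [[Rcpp::export]]
NumericMatrix cpp_recall(List net_list, NumericMatrix cues, bool readout_tp) {
  Net net = build_net(net_list);
  const int n_cue = cues.nrow(), n_ec = cues.ncol();
  const int ec_out = net.n_layers - 1;
  NumericMatrix out(n_cue, net.n[ec_out]);
  std::vector<std::vector<std::vector<double>>> snaps;
  std::vector<double> input(n_ec);
  for (int c = 0; c < n_cue; ++c) {
    for (int u = 0; u < n_ec; ++u) input[u] = cues(c, u);
    net.run_cycle(input, false, false, snaps);
    const std::vector<double>& s = snaps[readout_tp ? 1 : 0][ec_out];
    for (int u = 0; u < (int)s.size(); ++u) out(c, u) = s[u];
  }
  return out;
}
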