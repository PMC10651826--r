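// Compiled core: directed Watts-Strogatz generation, HSP rewiring steps,
// and the RK4 integrator for the delayed memristive FHN network with
// event-driven (or per-step) multiplicative nearest-spike-pair STDP.
//
// All randomness is drawn from R's RNG (unif_rand via RNGScope), so every
// exported entry point is reproducible under set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct ModelParams {
  double a, eps, d, lam, beta_mem, k1, k2, k3, phi_ext, v_shp, v_syn, v_th;
};

ModelParams read_model(const List& p) {
  ModelParams m;
  m.a = p["a"]; m.eps = p["eps"]; m.d = p["d"];
  m.lam = p["lam"]; m.beta_mem = p["beta_mem"];
  m.k1 = p["k1"]; m.k2 = p["k2"]; m.k3 = p["k3"];
  m.phi_ext = p["phi_ext"]; m.v_shp = p["v_shp"];
  m.v_syn = p["v_syn"]; m.v_th = p["v_th"];
  return m;
}

struct StdpParams {
  double P, D, tau_p, tau_d, g_min, g_max;
  bool per_step;    // true: weight update applied every dt; false: at spike events
  double step_scale; // factor on M in per-step mode (1 or dt)
};

StdpParams read_stdp(const List& p) {
  StdpParams s;
  s.P = p["P"]; s.D = p["D"];
  s.tau_p = p["tau_p"]; s.tau_d = p["tau_d"];
  s.g_min = p["g_min"]; s.g_max = p["g_max"];
  std::string sched = as<std::string>(p["schedule"]);
  s.per_step = sched != "spike";
  s.step_scale = sched == "step_dt" ? -1.0 : 1.0;  // -1: replace by dt below
  return s;
}

// saturating logistic; v_shp = 0.05 makes |x| large routinely
inline double sigmoid_sat(double x) {
  if (x > 40.0) return 1.0;
  if (x < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

inline double clipw(double g, const StdpParams& sp) {
  if (g < sp.g_min) return sp.g_min;
  if (g > sp.g_max) return sp.g_max;
  return g;
}

// STDP modification factor, Dt = t_post - t_pre (nearest spikes)
inline double stdp_M(double Dt, const StdpParams& sp) {
  if (Dt > 0) return sp.P * std::exp(-Dt / sp.tau_p);
  if (Dt < 0) return -sp.D * std::exp(Dt / sp.tau_d);
  return 0.0;
}

inline int ring_dist(int i, int j, int n) {
  int d = i > j ? i - j : j - i;
  return std::min(d, n - d);
}

// uniform integer in [0, m)
inline int runif_int(int m) {
  int r = (int)(unif_rand() * m);
  return r >= m ? m - 1 : r;
}

// Directed network with fixed postsynaptic endpoints: edge e is src[e] -> dst[e],
// edges stay grouped by dst for the whole run (rewiring only changes src).
struct Net {
  int n;
  int k_ring;                       // <k> of the original ring (distance cutoff)
  std::vector<int> src, dst;
  std::vector<double> g;
  std::vector<int> in_ptr;          // size n+1; edges [in_ptr[i], in_ptr[i+1]) have dst i
  std::vector<int> kin;             // in-degree
  std::vector<unsigned char> adj;   // adj[dst*n + src]
  std::vector<std::vector<int> > out; // edge ids by current src
  std::vector<int> outpos;          // position of edge e within out[src[e]]
  long n_rewires = 0, n_skips = 0;

  void build(IntegerVector s0, IntegerVector d0, NumericVector g0,
             int n_, int k_ring_) {
    n = n_; k_ring = k_ring_;
    int E = s0.size();
    // counting sort by dst (stable)
    kin.assign(n, 0);
    for (int e = 0; e < E; ++e) kin[d0[e]]++;
    in_ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) in_ptr[i + 1] = in_ptr[i] + kin[i];
    std::vector<int> fill(in_ptr.begin(), in_ptr.end() - 1);
    src.assign(E, 0); dst.assign(E, 0); g.assign(E, 0.0);
    for (int e = 0; e < E; ++e) {
      int pos = fill[d0[e]]++;
      src[pos] = s0[e]; dst[pos] = d0[e]; g[pos] = g0[e];
    }
    adj.assign((size_t)n * n, 0);
    out.assign(n, std::vector<int>());
    outpos.assign(E, 0);
    for (int e = 0; e < E; ++e) {
      if (src[e] == dst[e]) stop("self-loop in edge list");
      size_t a = (size_t)dst[e] * n + src[e];
      if (adj[a]) stop("duplicate edge in edge list");
      adj[a] = 1;
      outpos[e] = (int)out[src[e]].size();
      out[src[e]].push_back(e);
    }
  }

  void apply_rewire(int e, int new_src) {
    int old = src[e];
    adj[(size_t)dst[e] * n + old] = 0;
    adj[(size_t)dst[e] * n + new_src] = 1;
    // swap-remove from out[old]
    std::vector<int>& vo = out[old];
    int pos = outpos[e];
    int last = vo.back();
    vo[pos] = last; outpos[last] = pos; vo.pop_back();
    outpos[e] = (int)out[new_src].size();
    out[new_src].push_back(e);
    src[e] = new_src;
    ++n_rewires;
  }

  // new presynaptic source at ring distance <= k_ring from dst of e (near set)
  bool draw_src_near(int e, int& ns) {
    int d = dst[e];
    for (int t = 0; t < 30; ++t) {
      int u = 1 + runif_int(k_ring);
      int cand = unif_rand() < 0.5 ? (d + u) % n : (d - u + n) % n;
      if (cand != d && !adj[(size_t)d * n + cand]) { ns = cand; return true; }
    }
    std::vector<int> el;
    for (int u = 1; u <= k_ring; ++u) {
      int c1 = (d + u) % n, c2 = (d - u + n) % n;
      if (c1 != d && !adj[(size_t)d * n + c1]) el.push_back(c1);
      if (c2 != c1 && c2 != d && !adj[(size_t)d * n + c2]) el.push_back(c2);
    }
    if (el.empty()) return false;
    ns = el[runif_int((int)el.size())];
    return true;
  }

  // new source at ring distance > k_ring from dst (distant set)
  bool draw_src_distant(int e, int& ns) {
    int d = dst[e];
    if (2 * k_ring + 1 >= n) return false;  // distant set empty by geometry
    for (int t = 0; t < 60; ++t) {
      int cand = runif_int(n);
      if (cand != d && ring_dist(cand, d, n) > k_ring &&
          !adj[(size_t)d * n + cand]) { ns = cand; return true; }
    }
    std::vector<int> el;
    for (int c = 0; c < n; ++c)
      if (c != d && ring_dist(c, d, n) > k_ring && !adj[(size_t)d * n + c])
        el.push_back(c);
    if (el.empty()) return false;
    ns = el[runif_int((int)el.size())];
    return true;
  }

  // any new source != dst, not already a source of dst (random-network rule)
  bool draw_src_any(int e, int& ns) {
    int d = dst[e];
    for (int t = 0; t < 60; ++t) {
      int cand = runif_int(n);
      if (cand != d && !adj[(size_t)d * n + cand]) { ns = cand; return true; }
    }
    std::vector<int> el;
    for (int c = 0; c < n; ++c)
      if (c != d && !adj[(size_t)d * n + c]) el.push_back(c);
    if (el.empty()) return false;
    ns = el[runif_int((int)el.size())];
    return true;
  }
};

// One HSP step for the small-world rule: near-pair edges jump to a distant
// source with prob beta*F*dt, distant-pair edges jump to a near source with
// prob (1-beta)*F*dt (probabilities clamped to 1). Thinning with p_max keeps
// the per-edge draw count low when F*dt is small.
void hsp_smallworld_step(Net& net, double beta, double Fdt,
                         std::vector<int>* touched) {
  double p_far = std::min(1.0, (1.0 - beta) * Fdt);
  double p_near = std::min(1.0, beta * Fdt);
  double p_max = std::max(p_far, p_near);
  if (p_max <= 0.0) return;
  int E = (int)net.src.size();
  int e = -1;
  double lq = p_max >= 1.0 ? 0.0 : std::log1p(-p_max);
  while (true) {
    if (p_max >= 1.0) { ++e; } else {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      e += 1 + (int)(std::log(u) / lq);
    }
    if (e >= E) break;
    bool far = ring_dist(net.src[e], net.dst[e], net.n) > net.k_ring;
    double p = far ? p_far : p_near;
    if (p < p_max && unif_rand() * p_max >= p) continue;
    int ns;
    bool ok = far ? net.draw_src_near(e, ns) : net.draw_src_distant(e, ns);
    if (ok) {
      net.apply_rewire(e, ns);
      if (touched) touched->push_back(e);
    } else ++net.n_skips;
  }
}

// One HSP step for the random-network rule: every edge redraws its source
// uniformly (excluding self, current and existing sources) with prob
// (1 - <k>/(N-1))*F*dt.
void hsp_random_step(Net& net, double Fdt, std::vector<int>* touched) {
  int n = net.n, E = (int)net.src.size();
  double p = std::min(1.0, (1.0 - (double)net.k_ring / (n - 1)) * Fdt);
  if (p <= 0.0) return;
  int e = -1;
  double lq = p >= 1.0 ? 0.0 : std::log1p(-p);
  while (true) {
    if (p >= 1.0) { ++e; } else {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      e += 1 + (int)(std::log(u) / lq);
    }
    if (e >= E) break;
    int ns;
    if (net.draw_src_any(e, ns)) {
      net.apply_rewire(e, ns);
      if (touched) touched->push_back(e);
    } else ++net.n_skips;
  }
}

} // namespace

// [[Rcpp::export]]
List ws_generate_cpp(int n, int k_avg, double beta) {
  if (k_avg < 2 || k_avg % 2 != 0 || k_avg >= n)
    stop("k_avg must be even, >= 2 and < n");
  RNGScope scope;
  int half = k_avg / 2, E = n * k_avg;
  std::vector<int> src(E), dst(E);
  std::vector<unsigned char> adj((size_t)n * n, 0);
  int e = 0;
  for (int i = 0; i < n; ++i)
    for (int u = 1; u <= half; ++u) {
      src[e] = (i + u) % n; dst[e] = i; adj[(size_t)i * n + src[e]] = 1; ++e;
      src[e] = (i - u + n) % n; dst[e] = i; adj[(size_t)i * n + src[e]] = 1; ++e;
    }
  // WS rewiring of the presynaptic endpoint with probability beta
  for (e = 0; e < E; ++e) {
    if (unif_rand() >= beta) continue;
    int d = dst[e];
    int cand = -1;
    for (int t = 0; t < 200; ++t) {
      int c = runif_int(n);
      if (c != d && !adj[(size_t)d * n + c]) { cand = c; break; }
    }
    if (cand < 0) continue;   // saturated in-neighborhood; keep edge
    adj[(size_t)d * n + src[e]] = 0;
    adj[(size_t)d * n + cand] = 1;
    src[e] = cand;
  }
  return List::create(_["src"] = wrap(src), _["dst"] = wrap(dst));
}

// [[Rcpp::export]]
List hsp_step_cpp(IntegerVector src, IntegerVector dst, NumericVector g,
                  int n, int k_ring, std::string kind,
                  double beta, double F, double dt, int n_steps) {
  RNGScope scope;
  Net net;
  net.build(src, dst, g, n, k_ring);
  bool sw = kind == "small-world";
  for (int s = 0; s < n_steps; ++s) {
    if (sw) hsp_smallworld_step(net, beta, F * dt, nullptr);
    else hsp_random_step(net, F * dt, nullptr);
  }
  return List::create(_["src"] = wrap(net.src), _["dst"] = wrap(net.dst),
                      _["g"] = wrap(net.g),
                      _["n_rewires"] = (double)net.n_rewires,
                      _["n_skips"] = (double)net.n_skips);
}

// [[Rcpp::export]]
List sim_engine_cpp(NumericVector v0, NumericVector w0, NumericVector phi0,
                    NumericVector s0,
                    IntegerVector esrc, IntegerVector edst, NumericVector eg,
                    List model, List stdp, List hsp, List cfg) {
  RNGScope scope;
  const ModelParams mp = read_model(model);
  StdpParams sp = read_stdp(stdp);
  if (sp.step_scale < 0) sp.step_scale = as<double>(cfg["dt"]);
  const double F = as<double>(hsp["F"]);
  const double ws_beta = as<double>(hsp["beta"]);
  const std::string kind = as<std::string>(hsp["kind"]);
  const bool sw = kind == "small-world";

  const double dt = as<double>(cfg["dt"]);
  const double t_total = as<double>(cfg["t_total"]);
  const double t_trans = as<double>(cfg["t_transient"]);
  const int tau_steps = as<int>(cfg["tau_steps"]);
  const int stride = as<int>(cfg["record_stride"]);
  const bool rec_states = as<bool>(cfg["record_states"]);
  const int k_ring = as<int>(cfg["k_ring"]);

  const int n = v0.size();
  const int n_steps = (int)std::lround(t_total / dt);
  const int step0_rec = (int)std::lround(t_trans / dt);

  Net net;
  net.build(esrc, edst, eg, n, k_ring);
  const int E = (int)net.src.size();

  std::vector<double> v(v0.begin(), v0.end()), w(w0.begin(), w0.end()),
      phi(phi0.begin(), phi0.end()), s(s0.begin(), s0.end());

  // delay ring buffer of membrane potentials, pre-filled with v(0)
  const int blen = tau_steps + 1;
  std::vector<double> buf((size_t)blen * n);
  for (int b = 0; b < blen; ++b)
    std::copy(v.begin(), v.end(), buf.begin() + (size_t)b * n);
  int head = 0;

  std::vector<double> sig(n), cacc(n);
  std::vector<double> k1v(n), k1w(n), k1p(n), k1s(n),
      k2v(n), k2w(n), k2p(n), k2s(n),
      k3v(n), k3w(n), k3p(n), k3s(n),
      k4v(n), k4w(n), k4p(n), k4s(n),
      tv(n), tw(n), tp(n), ts(n), vprev(n);

  std::vector<double> last_spike(n, -1e18);
  std::vector<std::vector<double> > spikes(n);
  std::vector<double> fac;                 // per-step STDP factors
  const bool stdp_on = sp.P != 0.0 || sp.D != 0.0;
  if (sp.per_step) fac.assign(E, 1.0);

  auto refresh_fac = [&](int e) {
    double ti = last_spike[net.dst[e]], tj = last_spike[net.src[e]];
    fac[e] = (ti < -1e17 || tj < -1e17)
                 ? 1.0
                 : 1.0 + sp.step_scale * stdp_M(ti - tj, sp);
  };

  // stage derivative: reads (xv,xw,xp,xs), writes (dv,dw,dp,ds); sig fixed per step
  auto deriv = [&](const std::vector<double>& xv, const std::vector<double>& xw,
                   const std::vector<double>& xp, const std::vector<double>& xs,
                   std::vector<double>& dv, std::vector<double>& dw,
                   std::vector<double>& dp, std::vector<double>& ds) {
    std::fill(cacc.begin(), cacc.end(), 0.0);
    for (int e = 0; e < E; ++e) cacc[net.dst[e]] += net.g[e] * xs[net.src[e]];
    for (int i = 0; i < n; ++i) {
      double vi = xv[i], wi = xw[i], pi = xp[i];
      double isyn = net.kin[i] ? (cacc[i] / net.kin[i]) * (vi - mp.v_syn) : 0.0;
      dv[i] = vi * (vi - mp.a) * (1.0 - vi) - wi
              + mp.k3 * vi * (mp.lam + 3.0 * mp.beta_mem * pi * pi) - isyn;
      dw[i] = mp.eps * (vi - mp.d * wi);
      dp[i] = mp.k1 * vi - mp.k2 * pi + mp.phi_ext;
      ds[i] = 2.0 * (1.0 - xs[i]) * sig[i] - xs[i];
    }
  };

  // recording
  int n_rec = 0;
  for (int m = 1; m <= n_steps; ++m)
    if (m >= step0_rec && (m - step0_rec) % stride == 0) ++n_rec;
  NumericMatrix rv, rw, rp;
  if (rec_states) { rv = NumericMatrix(n_rec, n); rw = NumericMatrix(n_rec, n); rp = NumericMatrix(n_rec, n); }
  NumericVector rt(n_rec);
  int n_tr = n_steps / stride + 1;
  NumericVector gbar_t(n_tr), gbar_v(n_tr);
  int irec = 0, itr = 0;
  {
    double gs = 0; for (int e = 0; e < E; ++e) gs += net.g[e];
    gbar_t[itr] = 0.0; gbar_v[itr] = E ? gs / E : NA_REAL; ++itr;
  }

  std::vector<int> spikers;
  std::vector<int> touched;
  const double hdt = 0.5 * dt, dt6 = dt / 6.0;

  for (int m = 1; m <= n_steps; ++m) {
    if ((m & 2047) == 0) Rcpp::checkUserInterrupt();
    // delayed presynaptic potentials (held constant across the 4 stages)
    const double* vd = &buf[(size_t)((head - tau_steps + blen) % blen) * n];
    for (int i = 0; i < n; ++i) sig[i] = sigmoid_sat(vd[i] / mp.v_shp);

    std::copy(v.begin(), v.end(), vprev.begin());
    deriv(v, w, phi, s, k1v, k1w, k1p, k1s);
    for (int i = 0; i < n; ++i) {
      tv[i] = v[i] + hdt * k1v[i]; tw[i] = w[i] + hdt * k1w[i];
      tp[i] = phi[i] + hdt * k1p[i]; ts[i] = s[i] + hdt * k1s[i];
    }
    deriv(tv, tw, tp, ts, k2v, k2w, k2p, k2s);
    for (int i = 0; i < n; ++i) {
      tv[i] = v[i] + hdt * k2v[i]; tw[i] = w[i] + hdt * k2w[i];
      tp[i] = phi[i] + hdt * k2p[i]; ts[i] = s[i] + hdt * k2s[i];
    }
    deriv(tv, tw, tp, ts, k3v, k3w, k3p, k3s);
    for (int i = 0; i < n; ++i) {
      tv[i] = v[i] + dt * k3v[i]; tw[i] = w[i] + dt * k3w[i];
      tp[i] = phi[i] + dt * k3p[i]; ts[i] = s[i] + dt * k3s[i];
    }
    deriv(tv, tw, tp, ts, k4v, k4w, k4p, k4s);
    for (int i = 0; i < n; ++i) {
      v[i] += dt6 * (k1v[i] + 2 * k2v[i] + 2 * k3v[i] + k4v[i]);
      w[i] += dt6 * (k1w[i] + 2 * k2w[i] + 2 * k3w[i] + k4w[i]);
      phi[i] += dt6 * (k1p[i] + 2 * k2p[i] + 2 * k3p[i] + k4p[i]);
      s[i] += dt6 * (k1s[i] + 2 * k2s[i] + 2 * k3s[i] + k4s[i]);
      // closed gates decay like e^{-t}; flush to zero before the value
      // underflows into (slow) denormal range
      if (s[i] < 1e-30) s[i] = 0.0;
    }
    const double t_new = m * dt;
    double chk = 0.0;
    for (int i = 0; i < n; ++i) chk += v[i] + w[i] + phi[i];
    if (!std::isfinite(chk))
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(v[i]) || !std::isfinite(w[i]) || !std::isfinite(phi[i]))
          stop("state diverged (non-finite) at t = %f, neuron %d", t_new, i + 1);

    // spike detection: upward crossing of v_th, spike time = post-step time
    spikers.clear();
    for (int i = 0; i < n; ++i)
      if (vprev[i] < mp.v_th && v[i] >= mp.v_th) spikers.push_back(i);

    if (!spikers.empty()) {
      // stamp all simultaneous spikers first so coincident pairs get dt = 0
      for (int i : spikers) { last_spike[i] = t_new; spikes[i].push_back(t_new); }
      if (stdp_on) {
        if (!sp.per_step) {
          for (int i : spikers) {
            for (int e = net.in_ptr[i]; e < net.in_ptr[i + 1]; ++e) {
              double tj = last_spike[net.src[e]];
              if (tj > -1e17)
                net.g[e] = clipw(net.g[e] * (1.0 + stdp_M(t_new - tj, sp)), sp);
            }
            for (int e : net.out[i]) {
              double tm = last_spike[net.dst[e]];
              if (tm > -1e17)
                net.g[e] = clipw(net.g[e] * (1.0 + stdp_M(tm - t_new, sp)), sp);
            }
          }
        } else {
          for (int i : spikers) {
            for (int e = net.in_ptr[i]; e < net.in_ptr[i + 1]; ++e) refresh_fac(e);
            for (int e : net.out[i]) refresh_fac(e);
          }
        }
      }
    }
    if (stdp_on && sp.per_step)
      for (int e = 0; e < E; ++e)
        if (fac[e] != 1.0) net.g[e] = clipw(net.g[e] * fac[e], sp);

    // HSP rewiring (each existing edge tested once; new sources not re-tested)
    if (F > 0.0) {
      if (sp.per_step) {
        touched.clear();
        if (sw) hsp_smallworld_step(net, ws_beta, F * dt, &touched);
        else hsp_random_step(net, F * dt, &touched);
        for (int e : touched) refresh_fac(e);
      } else {
        if (sw) hsp_smallworld_step(net, ws_beta, F * dt, nullptr);
        else hsp_random_step(net, F * dt, nullptr);
      }
    }

    // push new v into the delay buffer
    head = (head + 1) % blen;
    std::copy(v.begin(), v.end(), buf.begin() + (size_t)head * n);

    if (m % stride == 0 && itr < n_tr) {
      double gs = 0; for (int e = 0; e < E; ++e) gs += net.g[e];
      gbar_t[itr] = t_new; gbar_v[itr] = E ? gs / E : NA_REAL; ++itr;
    }
    if (m >= step0_rec && (m - step0_rec) % stride == 0) {
      rt[irec] = t_new;
      if (rec_states)
        for (int i = 0; i < n; ++i) { rv(irec, i) = v[i]; rw(irec, i) = w[i]; rp(irec, i) = phi[i]; }
      ++irec;
    }
  }

  List sp_out(n);
  for (int i = 0; i < n; ++i) sp_out[i] = wrap(spikes[i]);
  List res = List::create(
      _["t"] = rt, _["spikes"] = sp_out,
      _["gbar_t"] = gbar_t, _["gbar"] = gbar_v,
      _["src"] = wrap(net.src), _["dst"] = wrap(net.dst), _["g"] = wrap(net.g),
      _["n_rewires"] = (double)net.n_rewires,
      _["n_rewire_skips"] = (double)net.n_skips,
      _["final_state"] = List::create(_["v"] = wrap(v), _["w"] = wrap(w),
                                      _["phi"] = wrap(phi), _["s"] = wrap(s)));
  if (rec_states) { res["v"] = rv; res["w"] = rw; res["phi"] = rp; }
  return res;
}
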