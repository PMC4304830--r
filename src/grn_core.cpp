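// Core numerics: Hill-kinetics ODE right-hand side, adaptive Dormand-Prince
// 5(4) integration onto a regular output grid, oscillation/bistability scoring
// and the Monte Carlo robustness loop. Hot paths avoid R allocations; random
// parameter draws use R's RNG stream so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

// integer power; Hill coefficients are small positive integers
inline double ipow(double x, int n) {
  double r = 1.0;
  while (n > 0) {
    if (n & 1) r *= x;
    x *= x;
    n >>= 1;
  }
  return r;
}

struct Edge {
  int target;   // regulated gene i
  int source;   // regulator gene j
  int sign;     // +1 activation, -1 inhibition
  double K;     // half-saturation threshold (nM)
};

struct Model {
  int N;
  int hill;
  std::vector<Edge> edges;    // row-major over nonzero entries of M
  std::vector<double> a, b;   // basal production, degradation

  // dG_i/dt = a_i * prod_j K^n/(G_j^n + K^n) * prod_k G_k^n/(G_k^n + Ka^n) - b_i G_i
  void rhs(const double* G, double* dG) const {
    for (int i = 0; i < N; ++i) dG[i] = a[i];
    for (size_t e = 0; e < edges.size(); ++e) {
      const Edge& ed = edges[e];
      double g = G[ed.source] > 0.0 ? G[ed.source] : 0.0;
      double gn = ipow(g, hill);
      double kn = ipow(ed.K, hill);
      double f = (ed.sign > 0) ? gn / (gn + kn) : kn / (gn + kn);
      dG[ed.target] *= f;
    }
    for (int i = 0; i < N; ++i) dG[i] -= b[i] * G[i];
  }
};

// collect signed edges row-major; thresholds (if given) aligned to that order
std::vector<Edge> edges_from_matrix(const IntegerMatrix& M,
                                    const double* K, int nK) {
  const int N = M.nrow();
  std::vector<Edge> edges;
  int idx = 0;
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      int s = M(i, j);
      if (s != 0) {
        Edge e;
        e.target = i;
        e.source = j;
        e.sign = s;
        e.K = (K != nullptr && idx < nK) ? K[idx] : 0.0;
        edges.push_back(e);
        ++idx;
      }
    }
  }
  return edges;
}

// Dormand-Prince 5(4) coefficients
const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 4.0 / 5.0, C5 = 8.0 / 9.0;
const double A21 = 1.0 / 5.0;
const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
             A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
             A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
             A65 = -5103.0 / 18656.0;
const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
             B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
// error = y5 - y4 expressed on k1..k7 (k7 = f(t+h, y5))
const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0, E4 = 71.0 / 1920.0,
             E5 = -17253.0 / 339200.0, E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;

struct Integrator {
  const Model* m;
  double rtol, atol;
  double h;  // persisted step size across output segments
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp, ynew;

  void init(const Model* model, double rtol_, double atol_, double h0) {
    m = model;
    rtol = rtol_;
    atol = atol_;
    h = h0;
    int N = m->N;
    k1.resize(N); k2.resize(N); k3.resize(N); k4.resize(N);
    k5.resize(N); k6.resize(N); k7.resize(N);
    ytmp.resize(N); ynew.resize(N);
  }

  // advance y from t0 to t1 (t1 > t0); returns false on failure
  bool advance(std::vector<double>& y, double t0, double t1) {
    const int N = m->N;
    double t = t0;
    const double hmin = 1e-10;
    int guard = 0;
    while (t < t1) {
      if (++guard > 2000000) return false;
      if (h < hmin) return false;
      double hs = h;
      bool clipped = false;
      if (t + hs > t1) { hs = t1 - t; clipped = true; }

      m->rhs(y.data(), k1.data());
      for (int i = 0; i < N; ++i) ytmp[i] = y[i] + hs * A21 * k1[i];
      m->rhs(ytmp.data(), k2.data());
      for (int i = 0; i < N; ++i)
        ytmp[i] = y[i] + hs * (A31 * k1[i] + A32 * k2[i]);
      m->rhs(ytmp.data(), k3.data());
      for (int i = 0; i < N; ++i)
        ytmp[i] = y[i] + hs * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
      m->rhs(ytmp.data(), k4.data());
      for (int i = 0; i < N; ++i)
        ytmp[i] = y[i] + hs * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                               A54 * k4[i]);
      m->rhs(ytmp.data(), k5.data());
      for (int i = 0; i < N; ++i)
        ytmp[i] = y[i] + hs * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                               A64 * k4[i] + A65 * k5[i]);
      m->rhs(ytmp.data(), k6.data());
      for (int i = 0; i < N; ++i)
        ynew[i] = y[i] + hs * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                               B5 * k5[i] + B6 * k6[i]);
      m->rhs(ynew.data(), k7.data());

      double errnorm = 0.0;
      bool finite = true;
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(ynew[i]) || std::fabs(ynew[i]) > 1e12) {
          finite = false;
          break;
        }
        double err = hs * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                           E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
        double ay = std::fabs(y[i]), an = std::fabs(ynew[i]);
        double sc = atol + rtol * (ay > an ? ay : an);
        double r = err / sc;
        errnorm += r * r;
      }
      if (finite) errnorm = std::sqrt(errnorm / N);

      if (finite && errnorm <= 1.0) {
        t += hs;
        y = ynew;
        double fac = errnorm > 1e-12 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (!clipped) h = hs * fac;
        else if (fac > 1.0) h = h * ((fac < 2.0) ? fac : 2.0);
      } else {
        double fac = finite ? 0.9 * std::pow(errnorm, -0.2) : 0.1;
        if (fac < 0.1) fac = 0.1;
        if (fac > 0.9) fac = 0.9;
        h = hs * fac;
      }
    }
    return true;
  }
};

// integrate onto a regular grid 0..t_end step dt_out; out is (ngrid x N)
// column-major buffer. Returns false on integrator failure.
bool simulate_grid(const Model& m, const std::vector<double>& init,
                   double t_end, double dt_out, double rtol, double atol,
                   std::vector<double>& out, int& ngrid) {
  const int N = m.N;
  ngrid = (int)std::floor(t_end / dt_out + 1e-9) + 1;
  out.resize((size_t)ngrid * N);
  std::vector<double> y = init;
  Integrator integ;
  integ.init(&m, rtol, atol, dt_out < 0.1 ? dt_out : 0.1);
  for (int i = 0; i < N; ++i) out[(size_t)i * ngrid] = y[i] > 0 ? y[i] : 0;
  for (int g = 1; g < ngrid; ++g) {
    double t0 = (g - 1) * dt_out, t1 = g * dt_out;
    if (!integ.advance(y, t0, t1)) return false;
    for (int i = 0; i < N; ++i) {
      double v = y[i];
      out[(size_t)i * ngrid + g] = v > 0 ? v : 0;  // clip integrator ripple
    }
  }
  return true;
}

// ---- oscillation scoring ------------------------------------------------

struct PeakSet {
  std::vector<int> idx;          // retained peak indices (into window)
  std::vector<double> height;    // series value at the peak
  std::vector<double> amplitude; // height minus mean of adjacent troughs
};

// strict local maxima filtered by prominence; amplitudes from adjacent
// segment minima (window edges fall back to the edge-segment minimum)
PeakSet find_peaks(const double* y, int nw, double prominence) {
  PeakSet out;
  std::vector<int> raw;
  for (int i = 1; i + 1 < nw; ++i) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) raw.push_back(i);
  }
  if (raw.empty()) return out;

  // prominence: height above the higher of the two adjacent segment minima
  std::vector<int> kept;
  for (size_t p = 0; p < raw.size(); ++p) {
    int lo = (p == 0) ? 0 : raw[p - 1];
    int hi = (p + 1 == raw.size()) ? nw - 1 : raw[p + 1];
    double lmin = y[raw[p]], rmin = y[raw[p]];
    for (int i = lo; i < raw[p]; ++i) lmin = std::min(lmin, y[i]);
    for (int i = raw[p] + 1; i <= hi; ++i) rmin = std::min(rmin, y[i]);
    double prom = y[raw[p]] - std::max(lmin, rmin);
    if (prom >= prominence) kept.push_back(raw[p]);
  }
  if (kept.empty()) return out;

  // amplitudes against troughs BETWEEN retained peaks; edge peaks use their
  // single inter-peak trough, a lone peak falls back to the window minimum
  size_t np = kept.size();
  if (np == 1) {
    double mn = y[0];
    for (int i = 0; i < nw; ++i) mn = std::min(mn, y[i]);
    out.idx.push_back(kept[0]);
    out.height.push_back(y[kept[0]]);
    out.amplitude.push_back(y[kept[0]] - mn);
    return out;
  }
  std::vector<double> trough(np - 1);
  for (size_t s = 0; s + 1 < np; ++s) {
    double mn = y[kept[s]];
    for (int i = kept[s]; i <= kept[s + 1]; ++i) mn = std::min(mn, y[i]);
    trough[s] = mn;
  }
  for (size_t p = 0; p < np; ++p) {
    double tl = trough[p == 0 ? 0 : p - 1];
    double tr = trough[p + 1 >= np ? np - 2 : p];
    out.idx.push_back(kept[p]);
    out.height.push_back(y[kept[p]]);
    out.amplitude.push_back(y[kept[p]] - 0.5 * (tl + tr));
  }
  return out;
}

struct OscSpecC {
  double skip;            // stabilization window to drop (min)
  double sd_max;          // cap on the standard deviation term (nM)
  double prominence;      // peak prominence threshold (nM)
  double damping_penalty; // PN when damped
  double damping_drop;    // relative first->last amplitude drop deemed damped
  double threshold;       // satisfaction threshold on the mean score
};

struct OscResult {
  double mean_score;
  bool satisfied;
  bool all_oscillating;           // every gene has >= 2 retained peaks
  std::vector<double> per_gene;
  std::vector<int> n_peaks;
};

// score one trajectory (column-major ngrid x N, regular grid step dt_out)
OscResult osc_score(const std::vector<double>& conc, int ngrid, int N,
                    double dt_out, const OscSpecC& sp) {
  OscResult res;
  res.per_gene.assign(N, 0.0);
  res.n_peaks.assign(N, 0);
  int i0 = (int)std::ceil(sp.skip / dt_out - 1e-9);
  if (i0 < 0) i0 = 0;
  int nw = ngrid - i0;
  double total = 0.0;
  bool all_osc = true;
  for (int gidx = 0; gidx < N; ++gidx) {
    const double* y = conc.data() + (size_t)gidx * ngrid + i0;
    double mean = 0.0;
    for (int i = 0; i < nw; ++i) mean += y[i];
    mean /= nw;
    double var = 0.0;
    for (int i = 0; i < nw; ++i) var += (y[i] - mean) * (y[i] - mean);
    double sd = std::sqrt(var / (nw - 1));
    double sdc = sd < sp.sd_max ? sd : sp.sd_max;

    PeakSet pk = find_peaks(y, nw, sp.prominence);
    int np = (int)pk.idx.size();
    res.n_peaks[gidx] = np;
    double lc = 0.0, pn = 1.0;
    if (np >= 2) {
      double a1 = pk.amplitude.front(), a2 = pk.amplitude.back();
      double mx = std::max(a1, a2);
      lc = mx > 0 ? std::min(a1, a2) / mx : 0.0;
      // damped: amplitudes monotone non-increasing with a material drop
      bool mono = true;
      for (int p = 1; p < np; ++p) {
        if (pk.amplitude[p] > pk.amplitude[p - 1] + 1e-9) {
          mono = false;
          break;
        }
      }
      if (mono && a1 > 0 && (a1 - a2) / a1 > sp.damping_drop)
        pn = sp.damping_penalty;
    } else {
      all_osc = false;
    }
    double f = sdc * lc * pn;
    res.per_gene[gidx] = f;
    total += f;
  }
  res.mean_score = total / N;
  res.all_oscillating = all_osc;
  res.satisfied = all_osc && res.mean_score >= sp.threshold;
  return res;
}

// ---- bistability check --------------------------------------------------

struct BistSpecC {
  double t_end, w0, w1;   // horizon and check window (min)
  double high, low, other; // initial concentrations (nM)
  double tol;              // fluctuation tolerance (nM)
};

struct BistResult {
  bool satisfied;
  bool evaluable;
  double fluct_max;  // worst probe-gene fluctuation across both runs
};

BistResult bistable_check(const Model& m, double dt_out, double rtol,
                          double atol, const BistSpecC& sp) {
  BistResult res;
  res.satisfied = false;
  res.evaluable = true;
  res.fluct_max = 0.0;
  const int N = m.N;
  std::vector<double> out;
  int ngrid = 0;
  int j0 = (int)std::ceil(sp.w0 / dt_out - 1e-9);
  for (int run = 0; run < 2; ++run) {
    std::vector<double> init(N, sp.other);
    int hi_gene = (run == 0) ? 1 : 0;   // run 1: G0=low, G1=high; run 2 swapped
    int lo_gene = 1 - hi_gene;
    init[hi_gene] = sp.high;
    init[lo_gene] = sp.low;
    if (!simulate_grid(m, init, sp.t_end, dt_out, rtol, atol, out, ngrid)) {
      res.evaluable = false;
      return res;
    }
    double means[2];
    for (int g = 0; g < 2; ++g) {
      const double* y = out.data() + (size_t)g * ngrid;
      double mn = y[j0], mx = y[j0], sum = 0.0;
      int cnt = 0;
      for (int i = j0; i < ngrid; ++i) {
        mn = std::min(mn, y[i]);
        mx = std::max(mx, y[i]);
        sum += y[i];
        ++cnt;
      }
      double fl = mx - mn;
      res.fluct_max = std::max(res.fluct_max, fl);
      if (fl > sp.tol) return res;  // condition (i) fails
      means[g] = sum / cnt;
    }
    if (!(means[hi_gene] > means[lo_gene])) return res;  // condition (ii)
  }
  res.satisfied = true;
  return res;
}

OscSpecC osc_spec_from_list(const List& spec) {
  OscSpecC sp;
  sp.skip = as<double>(spec["stabilization_skip"]);
  sp.sd_max = as<double>(spec["sd_max"]);
  sp.prominence = as<double>(spec["peak_prominence"]);
  sp.damping_penalty = as<double>(spec["damping_penalty_factor"]);
  sp.damping_drop = as<double>(spec["damping_rel_drop"]);
  sp.threshold = as<double>(spec["satisfaction_threshold"]);
  return sp;
}

BistSpecC bist_spec_from_list(const List& spec) {
  BistSpecC sp;
  sp.t_end = as<double>(spec["t_end"]);
  NumericVector w = spec["check_window"];
  sp.w0 = w[0];
  sp.w1 = w[1];
  sp.high = as<double>(spec["high_init"]);
  sp.low = as<double>(spec["low_init"]);
  sp.other = as<double>(spec["other_init"]);
  sp.tol = as<double>(spec["fluctuation_tolerance"]);
  return sp;
}

}  // namespace

// [[Rcpp::export(name = ".derivative_cpp")]]
NumericVector derivative_cpp(IntegerMatrix M, NumericVector a, NumericVector b,
                             NumericVector K, int hill, NumericVector state) {
  Model m;
  m.N = M.nrow();
  m.hill = hill;
  m.a = as<std::vector<double> >(a);
  m.b = as<std::vector<double> >(b);
  m.edges = edges_from_matrix(M, K.begin(), K.size());
  NumericVector dG(m.N);
  std::vector<double> y = as<std::vector<double> >(state);
  std::vector<double> d(m.N);
  m.rhs(y.data(), d.data());
  for (int i = 0; i < m.N; ++i) dG[i] = d[i];
  return dG;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(IntegerMatrix M, NumericVector a, NumericVector b,
                  NumericVector K, int hill, NumericVector init, double t_end,
                  double dt_out, double rtol, double atol) {
  Model m;
  m.N = M.nrow();
  m.hill = hill;
  m.a = as<std::vector<double> >(a);
  m.b = as<std::vector<double> >(b);
  m.edges = edges_from_matrix(M, K.begin(), K.size());
  std::vector<double> y0 = as<std::vector<double> >(init);
  std::vector<double> out;
  int ngrid = 0;
  bool ok = simulate_grid(m, y0, t_end, dt_out, rtol, atol, out, ngrid);
  NumericVector times(ngrid);
  for (int g = 0; g < ngrid; ++g) times[g] = g * dt_out;
  NumericMatrix conc(ngrid, m.N);
  if (ok) {
    for (int i = 0; i < m.N; ++i)
      for (int g = 0; g < ngrid; ++g) conc(g, i) = out[(size_t)i * ngrid + g];
  } else {
    std::fill(conc.begin(), conc.end(), NA_REAL);
  }
  return List::create(_["times"] = times, _["concentrations"] = conc,
                      _["ok"] = ok);
}

// [[Rcpp::export(name = ".detect_peaks_cpp")]]
List detect_peaks_cpp(NumericVector series, NumericVector times,
                      double prominence) {
  int nw = series.size();
  PeakSet pk = find_peaks(series.begin(), nw, prominence);
  int np = (int)pk.idx.size();
  NumericVector pt(np), ph(np), pa(np);
  for (int p = 0; p < np; ++p) {
    pt[p] = times[pk.idx[p]];
    ph[p] = pk.height[p];
    pa[p] = pk.amplitude[p];
  }
  return List::create(_["time"] = pt, _["height"] = ph, _["amplitude"] = pa);
}

// [[Rcpp::export(name = ".osc_score_cpp")]]
List osc_score_cpp(NumericMatrix conc, double dt_out, List spec) {
  OscSpecC sp = osc_spec_from_list(spec);
  int ngrid = conc.nrow(), N = conc.ncol();
  std::vector<double> buf((size_t)ngrid * N);
  for (int i = 0; i < N; ++i)
    for (int g = 0; g < ngrid; ++g) buf[(size_t)i * ngrid + g] = conc(g, i);
  OscResult r = osc_score(buf, ngrid, N, dt_out, sp);
  return List::create(_["score"] = r.mean_score, _["satisfied"] = r.satisfied,
                      _["all_oscillating"] = r.all_oscillating,
                      _["per_gene_scores"] = NumericVector(r.per_gene.begin(),
                                                           r.per_gene.end()),
                      _["n_peaks"] = IntegerVector(r.n_peaks.begin(),
                                                   r.n_peaks.end()));
}

// [[Rcpp::export(name = ".bistable_cpp")]]
List bistable_cpp(IntegerMatrix M, NumericVector a, NumericVector b,
                  NumericVector K, int hill, List spec, double dt_out,
                  double rtol, double atol) {
  Model m;
  m.N = M.nrow();
  m.hill = hill;
  m.a = as<std::vector<double> >(a);
  m.b = as<std::vector<double> >(b);
  m.edges = edges_from_matrix(M, K.begin(), K.size());
  BistSpecC sp = bist_spec_from_list(spec);
  BistResult r = bistable_check(m, dt_out, rtol, atol, sp);
  return List::create(_["satisfied"] = r.satisfied,
                      _["evaluable"] = r.evaluable,
                      _["max_fluctuation"] = r.fluct_max);
}

// Monte Carlo robustness: draws (a_i..., b_i..., K_edge... row-major) per
// sample from R's RNG, evaluates the behavior, accumulates Boolean counts and
// quantitative deviations. behavior: "oscillation" or "bistability".
// [[Rcpp::export(name = ".mc_robustness_cpp")]]
List mc_robustness_cpp(IntegerMatrix M, int hill, NumericVector basal_range,
                       NumericVector degradation_range,
                       NumericVector threshold_range, int n_samples,
                       std::string behavior, List spec, double ref_score,
                       double dt_out, double rtol, double atol) {
  Model m;
  const int N = M.nrow();
  m.N = N;
  m.hill = hill;
  m.a.assign(N, 0.0);
  m.b.assign(N, 0.0);
  m.edges = edges_from_matrix(M, nullptr, 0);
  const int I = (int)m.edges.size();

  const bool is_osc = (behavior == "oscillation");
  OscSpecC osp;
  BistSpecC bsp;
  double t_end = 0.0, init0 = 0.0;
  if (is_osc) {
    osp = osc_spec_from_list(spec);
    t_end = as<double>(spec["t_end"]);
    init0 = as<double>(spec["initial_concentration"]);
  } else {
    bsp = bist_spec_from_list(spec);
  }

  int n_satisfied = 0, n_failed = 0;
  double sum_dev = 0.0;
  std::vector<double> out;
  int ngrid = 0;

  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < N; ++i)
      m.a[i] = R::runif(basal_range[0], basal_range[1]);
    for (int i = 0; i < N; ++i)
      m.b[i] = R::runif(degradation_range[0], degradation_range[1]);
    for (int e = 0; e < I; ++e)
      m.edges[e].K = R::runif(threshold_range[0], threshold_range[1]);

    bool sat = false;
    double score = 0.0;
    if (is_osc) {
      std::vector<double> init(N, init0);
      if (simulate_grid(m, init, t_end, dt_out, rtol, atol, out, ngrid)) {
        OscResult r = osc_score(out, ngrid, N, dt_out, osp);
        sat = r.satisfied;
        score = r.mean_score;
      } else {
        ++n_failed;
      }
    } else {
      BistResult r = bistable_check(m, dt_out, rtol, atol, bsp);
      if (!r.evaluable) ++n_failed;
      sat = r.satisfied;
      score = sat ? 1.0 : 0.0;
    }
    if (sat) {
      ++n_satisfied;
      sum_dev += std::fabs(ref_score - score);
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["n_satisfied"] = n_satisfied,
                      _["n_samples"] = n_samples,
                      _["sum_deviation"] = sum_dev,
                      _["n_failed"] = n_failed);
}
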