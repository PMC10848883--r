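// Backward-induction core for the (length, stores, month) dynamic program.
// All allometry is precomputed in R and passed in as per-length,
// per-calendar-month tables; this file only performs the transition
// arithmetic, the starvation logistic, bilinear interpolation of the value
// function, and the maximization over the allocation lattice.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double z) {
  // 1 / (1 + exp(-z)); safe at extreme z (exp overflow yields 0 or 1).
  if (z > 0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// [[Rcpp::export(name = ".solve_backward_cpp")]]
List solve_backward_cpp(NumericVector lengths, NumericVector fracs,
                        NumericVector lat_g, NumericVector lat_r,
                        IntegerVector lat_gi, NumericVector g_levels,
                        NumericMatrix net_in,   // L x 12, J/month
                        NumericVector gpred,    // L
                        LogicalVector spawn,    // 12
                        int t_max,
                        double a, double rho, double upsilon,
                        double store_cap, double phi,
                        double q_abs,           // <= 0 selects relative rule
                        double k_rel,
                        double max_length) {
  const int L = lengths.size();
  const int S = fracs.size();
  const int A = lat_g.size();
  const int G = g_levels.size();
  const double step = fracs[1] - fracs[0];

  // Per-length constants.
  std::vector<double> wl(L), maxrep(L);
  for (int i = 0; i < L; ++i) {
    wl[i] = a * lengths[i] * lengths[i] * lengths[i];
    maxrep[i] = phi * wl[i] * rho;
  }

  // Store level in J at each (length, frac) node.
  std::vector<double> sJ(L * S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < L; ++i)
      sJ[i + L * j] = fracs[j] * wl[i] * rho;

  // Growth successor l' and its interpolation data depend only on
  // (length, stores, g); precompute once.
  const size_t NP = (size_t)L * S * G;
  std::vector<double> wt_l(NP), wprho(NP);
  std::vector<int> idx_l(NP);
  for (int gi = 0; gi < G; ++gi) {
    double g = g_levels[gi];
    for (int j = 0; j < S; ++j) {
      for (int i = 0; i < L; ++i) {
        size_t p = (size_t)i + L * ((size_t)j + (size_t)S * gi);
        double l = lengths[i];
        double lp = std::cbrt(l * l * l + g * sJ[i + L * j] / (a * rho));
        if (lp > max_length) lp = max_length;
        // lower interpolation index on the (increasing) length grid
        int lo = 0, hi = L - 1;
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (lengths[mid] <= lp) lo = mid; else hi = mid;
        }
        if (lo > L - 2) lo = L - 2;
        idx_l[p] = lo;
        wt_l[p] = (lp - lengths[lo]) / (lengths[lo + 1] - lengths[lo]);
        if (wt_l[p] < 0) wt_l[p] = 0;
        if (wt_l[p] > 1) wt_l[p] = 1;
        wprho[p] = a * lp * lp * lp * rho;
      }
    }
  }

  NumericVector V(Dimension(L, S, t_max + 1));   // zero-initialized: V(.,.,T)=0
  NumericVector g_star(Dimension(L, S, t_max));
  NumericVector r_star(Dimension(L, S, t_max));
  LogicalVector feasible(Dimension(L, S, 12));
  for (int m = 0; m < 12; ++m)
    for (int j = 0; j < S; ++j)
      for (int i = 0; i < L; ++i)
        feasible[i + L * (j + S * m)] =
          sJ[i + L * j] + net_in(i, m) >= 0.0;

  const size_t slab = (size_t)L * S;
  for (int t = t_max - 1; t >= 0; --t) {
    const int m = t % 12;
    const bool sp_ok = spawn[m];
    const double *Vn = REAL(V) + slab * (t + 1);
    double *Vt = REAL(V) + slab * t;
    double *Gt = REAL(g_star) + slab * t;
    double *Rt = REAL(r_star) + slab * t;

    for (int i = 0; i < L; ++i) {
      const double ni = net_in(i, m);
      const double gp = gpred[i];
      const double mr = maxrep[i] * (1.0 + 1e-9);
      for (int j = 0; j < S; ++j) {
        const size_t node = (size_t)i + (size_t)L * j;
        if (sJ[node] + ni < 0.0) {           // inviable even at g = r = 0
          Vt[node] = 0.0; Gt[node] = 0.0; Rt[node] = 0.0;
          continue;
        }
        const double s0 = sJ[node];
        double best = -1.0, bg = 0.0, br = 0.0;
        for (int k = 0; k < A; ++k) {
          const double r = lat_r[k];
          if (r > 0.0 && (!sp_ok || r * s0 > mr)) continue;
          const double g = lat_g[k];
          const double s_raw = (1.0 - g - r) * s0 + ni;
          const size_t p = node + slab * (size_t)lat_gi[k];
          const double thr = upsilon * wprho[p];
          const double z = (q_abs > 0.0)
            ? q_abs * (s_raw - thr)
            : k_rel * (s_raw / thr - 1.0);
          const double gs = logistic(z);
          double fp = s_raw > 0.0 ? s_raw / wprho[p] : 0.0;
          if (fp > store_cap) fp = store_cap;
          int js = (int)(fp / step);
          if (js > S - 2) js = S - 2;
          const double wf = fp / step - js;
          const int il = idx_l[p];
          const double wlw = wt_l[p];
          const double v00 = Vn[il + L * js];
          const double v10 = Vn[il + 1 + L * js];
          const double v01 = Vn[il + L * (js + 1)];
          const double v11 = Vn[il + 1 + L * (js + 1)];
          const double vint = (1.0 - wlw) * ((1.0 - wf) * v00 + wf * v01)
                            + wlw * ((1.0 - wf) * v10 + wf * v11);
          const double val = r * s0 + gp * gs * vint;
          const double tol = 1e-12 * (best > 1.0 ? best : 1.0);
          if (val > best + tol) {
            best = val; bg = g; br = r;
          } else if (val >= best - tol) {
            // deterministic tie-break: prefer reproduction, then growth
            if (r > br || (r == br && g > bg)) {
              if (val > best) best = val;
              bg = g; br = r;
            }
          }
        }
        Vt[node] = best > 0.0 ? best : 0.0;
        Gt[node] = bg; Rt[node] = br;
      }
    }
    if (t % 24 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["V"] = V, _["g_star"] = g_star,
                      _["r_star"] = r_star, _["feasible"] = feasible);
}
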