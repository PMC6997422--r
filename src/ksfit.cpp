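// Penalized Kolmogorov-Smirnov objective on a distinct-value histogram and
// the Nelder-Mead / brute-force truncation search that minimizes it.
//
// The histogram representation (sorted distinct values + cumulative counts)
// keeps every evaluation O(#distinct values), which is what makes the
// brute-force search over truncation pairs feasible.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

struct ObjParts {
  double ks, p1, p2, total;
};

// Objective for one (mu, sigma) and the truncation interval spanning the
// distinct values x[i1]..x[i2] (inclusive).
//
// The distinct values are bin centers at the dataset's rounding precision,
// so the empirical CDF steps at the upper bin edges: D evaluated at value i
// is the observed mass up to ue[i], and the model CDF is evaluated there
// too.  The truncation interval runs from the lower edge of bin i1 (le[i1])
// to the upper edge of bin i2, so a correctly specified model matches the
// conditional empirical CDF bin for bin, including the first one.
//
// Inside T the conditional empirical CDF (anchored at 0 at le[i1] and 1 at
// ue[i2]) is compared to the conditional Gaussian CDF.  Outside T the model
// CDF, rescaled by the implied physiological fraction c of the full dataset,
// may not exceed the observed cumulative mass below T (p1) nor may the
// rescaled model survival exceed the observed survival above T (p2);
// negative excursions carry no penalty.  All three terms are divided by
// sqrt(n_inside).
static ObjParts eval_objective(const double* ue, const double* le,
                               const double* cum, int m,
                               double n_total, int i1, int i2,
                               double mu, double sigma) {
  ObjParts r = {0.0, 0.0, 0.0, R_PosInf};
  if (!(sigma > 0.0) || !R_finite(mu) || !R_finite(sigma)) return r;
  const double P1 = norm_cdf((le[i1] - mu) / sigma);
  const double P2 = norm_cdf((ue[i2] - mu) / sigma);
  const double q = P2 - P1;
  if (q < 1e-6) return r;  // degenerate: model mass inside T vanishes
  const double below = (i1 > 0) ? cum[i1 - 1] : 0.0;
  const double nin = cum[i2] - below;
  const double sqn = std::sqrt(nin);
  const double c = (nin / n_total) / q;

  // The empirical CDF is a step function, so the supremum against the
  // continuous model CDF is attained next to a jump: at each upper bin edge
  // both the level after the jump and the level before it must be checked.
  // The pre-jump check keeps the sup honest on coarse histograms -- the
  // model cannot sneak between checkpoints, and every fit pays at least
  // half the largest conditional bin mass inside T.
  double ks = 0.0;
  for (int i = i1; i <= i2; ++i) {
    double F = (norm_cdf((ue[i] - mu) / sigma) - P1) / q;
    double d_hi = (cum[i] - below) / nin - F;
    double prev = (i > i1) ? (cum[i - 1] - below) / nin : 0.0;
    double d = std::max(std::fabs(d_hi), std::fabs(prev - F));
    if (d > ks) ks = d;
  }

  // p1: at every distinct value below T the c-scaled model CDF may not
  // exceed the observed CDF.  c*Phi is increasing, so walking downward the
  // running bound c*Phi caps every remaining term: stop once it cannot
  // improve the supremum.
  double p1 = 0.0;
  for (int i = i1 - 1; i >= 0; --i) {
    double ub = c * norm_cdf((ue[i] - mu) / sigma);
    if (ub <= p1) break;
    double v = ub - cum[i] / n_total;
    if (v > p1) p1 = v;
  }
  // p2: at every distinct value above T the c-scaled model survival may not
  // exceed the observed survival; mirrored early exit with the decreasing
  // bound c*(1-Phi).
  double p2 = 0.0;
  for (int i = i2 + 1; i < m; ++i) {
    double s = c * (1.0 - norm_cdf((ue[i] - mu) / sigma));
    if (s <= p2) break;
    double v = cum[i] / n_total - (1.0 - s);
    if (v > p2) p2 = v;
  }

  r.ks = ks / sqn;
  r.p1 = p1 / sqn;
  r.p2 = p2 / sqn;
  r.total = r.ks + r.p1 + r.p2;
  return r;
}

// weighted quantile over distinct values restricted to [i1, i2]
static double wquantile(const double* x, const double* cum,
                        int i1, int i2, double p) {
  double below = (i1 > 0) ? cum[i1 - 1] : 0.0;
  double target = below + p * (cum[i2] - below);
  int lo = i1, hi = i2;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] >= target) hi = mid; else lo = mid + 1;
  }
  return x[lo];
}

struct FitResult {
  double mu, sigma;
  ObjParts obj;
  bool hit_cap;
};

// 2-parameter Nelder-Mead (reflection 1, expansion 2, contraction 0.5,
// shrink 0.5); converges when the objective spread across the simplex
// drops below tol, or when the simplex has collapsed in parameter space
// (spread below scale_tol in both coordinates) -- the sup-type objective is
// only piecewise smooth, and the second criterion prevents slow terminal
// shrinkage around its kinks.
static FitResult nelder_mead(const double* ue, const double* le,
                             const double* x, const double* cum, int m,
                             double n_total, int i1, int i2,
                             double mu0, double s0, double step,
                             double scale_tol,
                             double tol, int max_iter) {
  double P[3][2] = {{mu0, s0}, {mu0 + step, s0}, {mu0, s0 + step}};
  double f[3];
  for (int i = 0; i < 3; ++i)
    f[i] = eval_objective(ue, le, cum, m, n_total, i1, i2, P[i][0], P[i][1]).total;

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // order: b best, w worst, s second-worst
    int b = 0, w = 0;
    for (int i = 1; i < 3; ++i) {
      if (f[i] < f[b]) b = i;
      if (f[i] > f[w]) w = i;
    }
    if (w == b) break;  // flat simplex
    int s = 3 - b - w;
    if (f[w] - f[b] < tol) break;
    {
      double dmu = std::max(std::fabs(P[0][0] - P[1][0]),
                            std::max(std::fabs(P[0][0] - P[2][0]),
                                     std::fabs(P[1][0] - P[2][0])));
      double dsi = std::max(std::fabs(P[0][1] - P[1][1]),
                            std::max(std::fabs(P[0][1] - P[2][1]),
                                     std::fabs(P[1][1] - P[2][1])));
      if (dmu < scale_tol && dsi < scale_tol) break;
    }

    double cx = 0.5 * (P[b][0] + P[s][0]);
    double cy = 0.5 * (P[b][1] + P[s][1]);
    double rx = cx + (cx - P[w][0]);
    double ry = cy + (cy - P[w][1]);
    double fr = eval_objective(ue, le, cum, m, n_total, i1, i2, rx, ry).total;
    if (fr < f[b]) {
      double ex = cx + 2.0 * (cx - P[w][0]);
      double ey = cy + 2.0 * (cy - P[w][1]);
      double fe = eval_objective(ue, le, cum, m, n_total, i1, i2, ex, ey).total;
      if (fe < fr) { P[w][0] = ex; P[w][1] = ey; f[w] = fe; }
      else         { P[w][0] = rx; P[w][1] = ry; f[w] = fr; }
    } else if (fr < f[s]) {
      P[w][0] = rx; P[w][1] = ry; f[w] = fr;
    } else {
      double hx, hy;
      if (fr < f[w]) { hx = cx + 0.5 * (rx - cx); hy = cy + 0.5 * (ry - cy); }
      else           { hx = cx + 0.5 * (P[w][0] - cx); hy = cy + 0.5 * (P[w][1] - cy); }
      double fh = eval_objective(ue, le, cum, m, n_total, i1, i2, hx, hy).total;
      if (fh < std::min(fr, f[w])) {
        P[w][0] = hx; P[w][1] = hy; f[w] = fh;
      } else {  // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if (i == b) continue;
          P[i][0] = P[b][0] + 0.5 * (P[i][0] - P[b][0]);
          P[i][1] = P[b][1] + 0.5 * (P[i][1] - P[b][1]);
          f[i] = eval_objective(ue, le, cum, m, n_total, i1, i2, P[i][0], P[i][1]).total;
        }
      }
    }
  }

  int b = 0;
  for (int i = 1; i < 3; ++i) if (f[i] < f[b]) b = i;
  FitResult out;
  out.mu = P[b][0];
  out.sigma = P[b][1];
  out.obj = eval_objective(ue, le, cum, m, n_total, i1, i2, P[b][0], P[b][1]);
  out.hit_cap = (iter >= max_iter);
  return out;
}

// Robust start (median, IQR/1.349) with one restart from (mean, SD) inside
// T if the first run exhausts the iteration budget; keeps the better of the
// two.  When a warm start from a neighbouring truncation pair is supplied,
// it replaces the robust start (the optima of adjacent pairs are close, so
// this saves most of the search); the iteration-cap restart still falls
// back to moments of the data inside T.
static FitResult fit_pair(const double* ue, const double* le,
                          const double* x, const double* cum, int m,
                          double n_total, int i1, int i2,
                          double tol, int max_iter,
                          bool warm = false, double warm_mu = 0.0,
                          double warm_sigma = -1.0) {
  double mu0 = wquantile(x, cum, i1, i2, 0.5);
  double s0 = (wquantile(x, cum, i1, i2, 0.75) -
               wquantile(x, cum, i1, i2, 0.25)) / 1.349;
  if (!(s0 > 0.0)) s0 = (x[i2] - x[i1]) / 4.0;
  if (!(s0 > 0.0)) s0 = 1.0;
  double scale_tol = 1e-3 * s0;

  // warm starts sit close to the optimum, so they use a smaller initial
  // simplex; Nelder-Mead expansion recovers the scale if that guess is wrong
  FitResult best;
  if (warm && warm_sigma > 0.0) {
    best = nelder_mead(ue, le, x, cum, m, n_total, i1, i2,
                       warm_mu, warm_sigma, 0.05 * s0, scale_tol,
                       tol, max_iter);
  } else {
    best = nelder_mead(ue, le, x, cum, m, n_total, i1, i2,
                       mu0, s0, 0.25 * s0, scale_tol, tol, max_iter);
  }
  if (best.hit_cap) {
    double below = (i1 > 0) ? cum[i1 - 1] : 0.0;
    double nin = cum[i2] - below;
    double sum = 0.0, sumsq = 0.0;
    for (int i = i1; i <= i2; ++i) {
      double w = cum[i] - ((i > 0) ? cum[i - 1] : 0.0);
      sum += w * x[i];
      sumsq += w * x[i] * x[i];
    }
    double mean = sum / nin;
    double var = (sumsq - nin * mean * mean) / std::max(nin - 1.0, 1.0);
    double sd = (var > 0.0) ? std::sqrt(var) : s0;
    FitResult alt = nelder_mead(ue, le, x, cum, m, n_total, i1, i2,
                                mean, sd, 0.25 * s0, scale_tol, tol, max_iter);
    if (alt.obj.total < best.obj.total) best = alt;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector ks_objective_cpp(NumericVector ue, NumericVector le,
                               NumericVector cum,
                               double n_total, int i1, int i2,
                               double mu, double sigma) {
  ObjParts o = eval_objective(ue.begin(), le.begin(), cum.begin(), ue.size(),
                              n_total, i1, i2, mu, sigma);
  return NumericVector::create(_["ks_main"] = o.ks, _["p1"] = o.p1,
                               _["p2"] = o.p2, _["total"] = o.total);
}

// [[Rcpp::export]]
List ks_fit_pair_cpp(NumericVector xt, NumericVector ue, NumericVector le,
                     NumericVector cum, double n_total,
                     int i1, int i2, double nm_tol, int nm_max_iter) {
  FitResult f = fit_pair(ue.begin(), le.begin(), xt.begin(), cum.begin(),
                         xt.size(), n_total, i1, i2, nm_tol, nm_max_iter);
  if (!R_finite(f.obj.total))
    return List::create(_["mu"] = f.mu, _["sigma"] = f.sigma,
                        _["ks_main"] = f.obj.ks, _["p1"] = f.obj.p1,
                        _["p2"] = f.obj.p2, _["total"] = f.obj.total);
  return List::create(_["mu"] = f.mu, _["sigma"] = f.sigma,
                      _["ks_main"] = f.obj.ks, _["p1"] = f.obj.p1,
                      _["p2"] = f.obj.p2, _["total"] = f.obj.total);
}

// Brute force over all candidate truncation pairs at one lambda: fit
// (mu, sigma) per pair, return the best.  Ties within 1e-12 on the total
// prefer the wider interval (larger n_inside), then the earlier pair in
// (i1 ascending, i2 ascending) order, so the result is deterministic.
// [[Rcpp::export]]
List ks_best_fit_cpp(NumericVector xt, NumericVector ue, NumericVector le,
                     NumericVector cum, double n_total,
                     IntegerVector cand1, IntegerVector cand2,
                     double min_n_inside, double nm_tol, int nm_max_iter) {
  const double* x = xt.begin();
  const double* u = ue.begin();
  const double* l = le.begin();
  const double* c = cum.begin();
  const int m = xt.size();

  bool found = false;
  double best_total = R_PosInf, best_nin = -1.0;
  int best_i1 = -1, best_i2 = -1;
  FitResult best_fit;
  int n_pairs = 0;

  for (int a = 0; a < cand1.size(); ++a) {
    int i1 = cand1[a];
    double below = (i1 > 0) ? c[i1 - 1] : 0.0;
    bool warm = false;
    double warm_mu = 0.0, warm_sigma = -1.0;  // cold start per i1 row
    for (int b = 0; b < cand2.size(); ++b) {
      int i2 = cand2[b];
      if (i2 <= i1) continue;
      double nin = c[i2] - below;
      if (nin < min_n_inside) continue;
      ++n_pairs;
      FitResult f = fit_pair(u, l, x, c, m, n_total, i1, i2,
                             nm_tol, nm_max_iter, warm, warm_mu, warm_sigma);
      if (!R_finite(f.obj.total)) { warm = false; continue; }
      warm = true;
      warm_mu = f.mu;
      warm_sigma = f.sigma;
      bool take = false;
      if (f.obj.total < best_total - 1e-12) take = true;
      else if (f.obj.total <= best_total + 1e-12 && nin > best_nin) take = true;
      if (take) {
        found = true;
        best_total = f.obj.total;
        best_nin = nin;
        best_i1 = i1;
        best_i2 = i2;
        best_fit = f;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  if (!found)
    return List::create(_["ok"] = false, _["n_pairs"] = n_pairs);
  return List::create(
      _["ok"] = true, _["i1"] = best_i1, _["i2"] = best_i2,
      _["mu"] = best_fit.mu, _["sigma"] = best_fit.sigma,
      _["ks_main"] = best_fit.obj.ks, _["p1"] = best_fit.obj.p1,
      _["p2"] = best_fit.obj.p2, _["total"] = best_fit.obj.total,
      _["n_inside"] = best_nin, _["n_pairs"] = n_pairs);
}
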