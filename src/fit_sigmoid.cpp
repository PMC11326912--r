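#include <Rcpp.h>
using namespace Rcpp;

// Two-sigmoid tachometric model v(x) = max(L(x), R(x), 0) with
//   L(x) = B + (AL - B) / (1 + exp((x - CL)/DL))   (falling branch, AL -> B)
//   R(x) = B + (AR - B) / (1 + exp(-(x - CR)/DR))  (rising branch,  B -> AR)
// AL is fixed at chance (0.5); free parameters are (B, AR, CL, DL, CR, DR).

static inline double vmax(double x, const double *p, double al) {
  // p = {B, AR, CL, DL, CR, DR}
  double L = p[0] + (al   - p[0]) / (1.0 + std::exp( (x - p[2]) / p[3]));
  double R = p[0] + (p[1] - p[0]) / (1.0 + std::exp(-(x - p[4]) / p[5]));
  double v = L > R ? L : R;
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export]]
NumericVector sigmoid_eval_cpp(NumericVector x, NumericVector par, double al) {
  const int n = x.size();
  NumericVector out(n);
  double p[6];
  for (int j = 0; j < 6; ++j) p[j] = par[j];
  for (int i = 0; i < n; ++i) out[i] = vmax(x[i], p, al);
  return out;
}

// MAE between binned proportions and the model. With half_bin > 0 the model
// is averaged over each bin by 3-point Gauss-Legendre quadrature, matching
// what a running-bin proportion estimates; half_bin = 0 evaluates at the
// bin centers.
static double mae_obj(const double *p, double al,
                      const double *x, const double *y, int n,
                      double half_bin) {
  double s = 0.0;
  if (half_bin <= 0.0) {
    for (int i = 0; i < n; ++i) s += std::fabs(y[i] - vmax(x[i], p, al));
  } else {
    // 2-point Gauss-Legendre on [x-h, x+h]: exact through cubic terms,
    // ample for a logistic over a 20-ms bin
    const double a = half_bin / std::sqrt(3.0);
    for (int i = 0; i < n; ++i) {
      double m = 0.5 * (vmax(x[i] - a, p, al) + vmax(x[i] + a, p, al));
      s += std::fabs(y[i] - m);
    }
  }
  return s / n;
}

// logistic map from unbounded u to the box [lo, hi]
static inline double to_box(double u, double lo, double hi) {
  return lo + (hi - lo) / (1.0 + std::exp(-u));
}
static inline double from_box(double p, double lo, double hi) {
  double f = (p - lo) / (hi - lo);
  if (f < 1e-6) f = 1e-6;
  if (f > 1 - 1e-6) f = 1 - 1e-6;
  return std::log(f / (1.0 - f));
}

// Nelder-Mead simplex on the box-transformed 6-parameter MAE objective.
// Returns the best parameters in natural units.
// [[Rcpp::export]]
List fit_sigmoid_nm(NumericVector start, NumericVector lower, NumericVector upper,
                    NumericVector x, NumericVector y, double al,
                    int maxit = 2000, double tol = 1e-8, double half_bin = 0.0) {
  const int d = 6, m = d + 1, n = x.size();
  std::vector<double> lo(d), hi(d);
  for (int j = 0; j < d; ++j) { lo[j] = lower[j]; hi[j] = upper[j]; }

  std::vector< std::vector<double> > simp(m, std::vector<double>(d));
  std::vector<double> fv(m);
  double pnat[6];

  // objective in u-space
  auto feval = [&](const std::vector<double> &u) {
    for (int j = 0; j < d; ++j) pnat[j] = to_box(u[j], lo[j], hi[j]);
    return mae_obj(pnat, al, REAL(x), REAL(y), n, half_bin);
  };

  for (int j = 0; j < d; ++j) simp[0][j] = from_box(start[j], lo[j], hi[j]);
  for (int i = 1; i < m; ++i) {
    simp[i] = simp[0];
    simp[i][i - 1] += 0.25;
  }
  for (int i = 0; i < m; ++i) fv[i] = feval(simp[i]);
  int fevals = m;

  std::vector<double> cen(d), xr(d), xe(d), xc(d);
  int it = 0;
  for (; it < maxit; ++it) {
    // order
    int lo_i = 0, hi_i = 0, nh_i = 0;
    for (int i = 1; i < m; ++i) {
      if (fv[i] < fv[lo_i]) lo_i = i;
      if (fv[i] > fv[hi_i]) hi_i = i;
    }
    nh_i = lo_i;
    for (int i = 0; i < m; ++i)
      if (i != hi_i && fv[i] > fv[nh_i]) nh_i = i;

    if (fv[hi_i] - fv[lo_i] < tol * (std::fabs(fv[lo_i]) + tol)) break;

    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) if (i != hi_i) s += simp[i][j];
      cen[j] = s / d;
    }
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - simp[hi_i][j]);
    double fr = feval(xr); ++fevals;

    if (fr < fv[lo_i]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - simp[hi_i][j]);
      double fe = feval(xe); ++fevals;
      if (fe < fr) { simp[hi_i] = xe; fv[hi_i] = fe; }
      else         { simp[hi_i] = xr; fv[hi_i] = fr; }
    } else if (fr < fv[nh_i]) {
      simp[hi_i] = xr; fv[hi_i] = fr;
    } else {
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (simp[hi_i][j] - cen[j]);
      double fc = feval(xc); ++fevals;
      if (fc < fv[hi_i]) { simp[hi_i] = xc; fv[hi_i] = fc; }
      else {
        for (int i = 0; i < m; ++i) {
          if (i == lo_i) continue;
          for (int j = 0; j < d; ++j)
            simp[i][j] = simp[lo_i][j] + 0.5 * (simp[i][j] - simp[lo_i][j]);
          fv[i] = feval(simp[i]); ++fevals;
        }
      }
    }
  }

  int best = 0;
  for (int i = 1; i < m; ++i) if (fv[i] < fv[best]) best = i;
  NumericVector par(d);
  for (int j = 0; j < d; ++j) par[j] = to_box(simp[best][j], lo[j], hi[j]);
  return List::create(_["par"] = par, _["value"] = fv[best],
                      _["fevals"] = fevals, _["converged"] = it < maxit);
}
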