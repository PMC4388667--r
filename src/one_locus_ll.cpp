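#include <Rcpp.h>
using namespace Rcpp;

// One-locus Gaussian-process log-likelihood for a single site: delta-method
// moment recursion (means, variances, cross-time covariances) plus the
// Gaussian sequencing emission and capped conditional masses.  Mirrors the
// R reference implementation exactly; used by the per-site scan where the
// call count is large.
// [[Rcpp::export]]
double one_locus_ll_cpp(double s, double h, double x0,
                        NumericMatrix freq, NumericMatrix cov,
                        IntegerVector times, double ne, double obs_n) {
  const int T = times.size();
  const int R = freq.ncol();
  const double n2 = 2.0 * ne;
  std::vector<double> mean(T), muv(T);
  std::vector<double> cv(T * T, 0.0);
  std::vector<double> live(T, 0.0);
  // recursion
  {
    double xbar = x0, mu = 0.0, s2 = 0.0;
    int ti = 0;
    const int tmax = times[T - 1];
    const double a = 1.0 - 2.0 * h;
    for (int t = 1; t <= tmax; ++t) {
      double f, f1, f2;
      if (s == 0.0) {
        f = xbar; f1 = 1.0; f2 = 0.0;
      } else {
        const double x = xbar;
        const double g  = s * (h * x + (1 - 3 * h) * x * x - a * x * x * x);
        const double g1 = s * (h + 2 * (1 - 3 * h) * x - 3 * a * x * x);
        const double g2 = s * (2 * (1 - 3 * h) - 6 * a * x);
        const double w  = 1 + s * (2 * h * x + a * x * x);
        const double w1 = s * (2 * h + 2 * a * x);
        const double w2 = 2 * s * a;
        f  = x + g / w;
        f1 = 1 + (g1 * w - g * w1) / (w * w);
        f2 = g2 / w - 2 * g1 * w1 / (w * w) - g * w2 / (w * w) +
             2 * g * w1 * w1 / (w * w * w);
      }
      const double ex  = f + f1 * mu + f2 * s2 / 2.0;
      const double ef2 = f * f + 2 * f * f1 * mu + (f1 * f1 + f * f2) * s2;
      const double ex2 = (1 - 1 / n2) * ef2 + ex / n2;
      s2 = std::max(ex2 - f * f - 2 * f * (ex - f), 0.0);
      mu = ex - f;
      xbar = f;
      for (int b = 0; b < ti; ++b) live[b] *= f1;
      if (ti < T && t == times[ti]) {
        mean[ti] = xbar + mu;
        muv[ti] = mu;
        live[ti] = s2;
        for (int b = 0; b <= ti; ++b) {
          const double v = live[b] - mu * muv[b];
          cv[ti * T + b] = v;
          cv[b * T + ti] = v;
        }
        ++ti;
      }
    }
  }
  const double clip_lo = 1e-6, clip_hi = 1.0 - 1e-6;
  for (int i = 0; i < T; ++i) {
    if (mean[i] < clip_lo) mean[i] = clip_lo;
    if (mean[i] > clip_hi) mean[i] = clip_hi;
  }
  double ll = 0.0;
  std::vector<double> sig(T * T), chol(T * T), xv(T), res(T);
  for (int r = 0; r < R; ++r) {
    // keep entries with data and positive (or infinite) coverage
    int n = 0;
    std::vector<int> idx;
    for (int i = 0; i < T; ++i) {
      const double x = freq(i, r), c = cov(i, r);
      const bool fin = std::isfinite(c);
      if (ISNAN(x)) continue;
      if (fin && c <= 0) continue;
      idx.push_back(i);
      ++n;
    }
    if (n == 0) continue;
    for (int i = 0; i < n; ++i) {
      const double c = cov(idx[i], r);
      const bool fin = std::isfinite(c);
      xv[i] = freq(idx[i], r);
      res[i] = fin ? std::max(c, 1.0) : 2.0 * obs_n;
      for (int j = 0; j < n; ++j) sig[i * n + j] = cv[idx[i] * T + idx[j]];
      if (fin) {
        const double m = mean[idx[i]];
        sig[i * n + i] += m * (1 - m) / std::max(c, 1.0);
      }
    }
    // Cholesky with jitter fallback
    double jit = 0.0;
    for (int i = 0; i < n; ++i)
      jit = std::max(jit, sig[i * n + i]);
    jit = std::max(jit * 1e-10, 1e-22);
    for (int attempt = 0; attempt < 40; ++attempt) {
      bool ok = true;
      for (int i = 0; i < n * n; ++i) chol[i] = sig[i];
      if (attempt > 0)
        for (int i = 0; i < n; ++i) chol[i * n + i] += jit;
      // lower-triangular Cholesky
      for (int i = 0; i < n && ok; ++i) {
        for (int j = 0; j <= i; ++j) {
          double acc = chol[i * n + j];
          for (int k = 0; k < j; ++k) acc -= chol[i * n + k] * chol[j * n + k];
          if (i == j) {
            if (acc <= 0) { ok = false; break; }
            chol[i * n + i] = std::sqrt(acc);
          } else {
            chol[i * n + j] = acc / chol[j * n + j];
          }
        }
      }
      if (ok) break;
      jit *= 10.0;
      if (attempt == 39) stop("covariance not positive definite");
    }
    // z = L^{-1} (x - mean); capped conditional masses
    std::vector<double> z(n);
    for (int i = 0; i < n; ++i) {
      double acc = xv[i] - mean[idx[i]];
      for (int k = 0; k < i; ++k) acc -= chol[i * n + k] * z[k];
      z[i] = acc / chol[i * n + i];
      const double lcond = -0.918938533204672741780 -  // log(sqrt(2 pi))
        std::log(chol[i * n + i]) - 0.5 * z[i] * z[i] - std::log(res[i]);
      ll += std::min(lcond, 0.0);
    }
  }
  return ll;
}
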