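// Per-timepoint linear soft-margin SVM, solved with a small deterministic
// SMO loop. Training sets in the pseudo-trial decoding pipeline are tiny
// (2-6 cases), but the pipeline needs ~10^5-10^6 fits per calibration run,
// so the solver lives in compiled code. Labels are +1/-1; +1 is the
// first-listed class and wins exact decision-boundary ties.
#include <Rcpp.h>
using namespace Rcpp;

static void smo_fit(const std::vector<double>& K, const std::vector<double>& y,
                    int n, double C, double tol, std::vector<double>& alpha,
                    double& b) {
  alpha.assign(n, 0.0);
  b = 0.0;
  auto f = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j) s += alpha[j] * y[j] * K[j * n + i];
    return s;
  };
  int passes = 0, guard = 0;
  const int max_passes = 3, max_guard = 500;
  while (passes < max_passes && guard++ < max_guard) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = f(i) - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0)))
        continue;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double Ej = f(j) - y[j];
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj - ai);
          H = std::min(C, C + aj - ai);
        } else {
          L = std::max(0.0, ai + aj - C);
          H = std::min(C, ai + aj);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[i * n + j] - K[i * n + i] - K[j * n + j];
        if (eta >= -1e-12) continue;
        double ajn = aj - y[j] * (Ei - Ej) / eta;
        ajn = std::min(H, std::max(L, ajn));
        if (std::fabs(ajn - aj) < 1e-8) continue;
        double ain = ai + y[i] * y[j] * (aj - ajn);
        double b1 = b - Ei - y[i] * (ain - ai) * K[i * n + i] -
                    y[j] * (ajn - aj) * K[i * n + j];
        double b2 = b - Ej - y[i] * (ain - ai) * K[i * n + j] -
                    y[j] * (ajn - aj) * K[j * n + j];
        if (ain > 0 && ain < C) b = b1;
        else if (ajn > 0 && ajn < C) b = b2;
        else b = 0.5 * (b1 + b2);
        alpha[i] = ain;
        alpha[j] = ajn;
        ++changed;
        break;
      }
    }
    if (changed == 0) ++passes; else passes = 0;
  }
}

// train: n_train x (nchan * ntime), feature column = t * nchan + c.
// test:  n_test  x (nchan * ntime), same layout.
// Returns n_test x ntime matrix of predicted labels (+1 / -1).
// [[Rcpp::export(name = ".svm_decode_batch")]]
IntegerMatrix svm_decode_batch(NumericMatrix train, IntegerVector y_train,
                               NumericMatrix test, int nchan, int ntime,
                               double cost = 1.0, double tol = 1e-4) {
  const int n = train.nrow(), m = test.nrow();
  if (y_train.size() != n) stop("label / training-case count mismatch");
  if (train.ncol() != nchan * ntime || test.ncol() != nchan * ntime)
    stop("feature layout mismatch: expected nchan * ntime columns");
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) {
    if (y_train[i] != 1 && y_train[i] != -1) stop("labels must be +1/-1");
    y[i] = y_train[i];
  }
  IntegerMatrix pred(m, ntime);
  std::vector<double> K(n * n), alpha;
  for (int t = 0; t < ntime; ++t) {
    const int col0 = t * nchan;
    // kernel matrix at this timepoint
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j) {
        double s = 0.0;
        for (int c = 0; c < nchan; ++c)
          s += train(i, col0 + c) * train(j, col0 + c);
        K[i * n + j] = K[j * n + i] = s;
      }
    double b;
    smo_fit(K, y, n, cost, tol, alpha, b);
    for (int q = 0; q < m; ++q) {
      double s = b;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] == 0.0) continue;
        double dot = 0.0;
        for (int c = 0; c < nchan; ++c)
          dot += train(i, col0 + c) * test(q, col0 + c);
        s += alpha[i] * y[i] * dot;
      }
      pred(q, t) = (s >= 0.0) ? 1 : -1;  // tie -> first-listed class (+1)
    }
  }
  return pred;
}
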