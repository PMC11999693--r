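#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_w 0.5 w'w + C sum_i max(0, 1 - y_i w'x_i)
// The bias is handled by an augmented constant feature (last column of X),
// the liblinear convention. Deterministic cyclic sweep order so that fits
// are reproducible without touching the RNG.
static void dcd_fit(const double* X, int n, int d, const double* y,
                    double C, int max_iter, double tol, double* w) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  for (int j = 0; j < d; ++j) w[j] = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = X[i + (size_t)n * j]; s += v * v; }
    Qii[i] = s;
  }
  for (int it = 0; it < max_iter; ++it) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X[i + (size_t)n * j];
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X[i + (size_t)n * j];
      }
    }
    if (max_viol < tol) break;
  }
}

// [[Rcpp::export(name = ".svm_fit_cpp")]]
NumericVector svm_fit_cpp(NumericMatrix X, NumericVector y, double C = 1.0,
                          int max_iter = 500, double tol = 1e-4) {
  int n = X.nrow(), d = X.ncol();
  NumericVector w(d);
  dcd_fit(REAL(X), n, d, REAL(y), C, max_iter, tol, REAL(w));
  return w;
}

static double fold_accuracy(const double* w, const double* Xte, int nte, int d,
                            const double* yte) {
  int correct = 0;
  for (int i = 0; i < nte; ++i) {
    double dec = 0.0;
    for (int j = 0; j < d; ++j) dec += w[j] * Xte[i + (size_t)nte * j];
    double pred = dec >= 0.0 ? 1.0 : -1.0;
    if (pred == yte[i]) ++correct;
  }
  return (double)correct / (double)nte;
}

// Train on (Xtr, ytr), test on (Xte, yte); additionally refit n_perm times
// with training labels shuffled (R's RNG, so set.seed() controls it) and
// record the null test accuracies. Matrices must already carry the augmented
// bias column. Returns accuracy, null accuracies, test decision values and
// the norm of the feature weights (bias column excluded).
// [[Rcpp::export(name = ".svm_fold_cpp")]]
List svm_fold_cpp(NumericMatrix Xtr, NumericVector ytr,
                  NumericMatrix Xte, NumericVector yte,
                  double C = 1.0, int n_perm = 0,
                  int max_iter = 500, double tol = 1e-4) {
  int ntr = Xtr.nrow(), d = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> w(d);
  dcd_fit(REAL(Xtr), ntr, d, REAL(ytr), C, max_iter, tol, w.data());
  NumericVector dec(nte);
  for (int i = 0; i < nte; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += w[j] * Xte(i, j);
    dec[i] = s;
  }
  double acc = fold_accuracy(w.data(), REAL(Xte), nte, d, REAL(yte));
  double wnorm = 0.0;
  for (int j = 0; j < d - 1; ++j) wnorm += w[j] * w[j];
  wnorm = std::sqrt(wnorm);

  NumericVector null_acc(n_perm);
  if (n_perm > 0) {
    std::vector<double> yp(REAL(ytr), REAL(ytr) + ntr);
    std::vector<double> wp(d);
    for (int p = 0; p < n_perm; ++p) {
      // Fisher-Yates with R's RNG for reproducibility under set.seed()
      for (int i = ntr - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(yp[i], yp[j]);
      }
      dcd_fit(REAL(Xtr), ntr, d, yp.data(), C, max_iter, tol, wp.data());
      null_acc[p] = fold_accuracy(wp.data(), REAL(Xte), nte, d, REAL(yte));
    }
  }
  return List::create(_["accuracy"] = acc, _["null_acc"] = null_acc,
                      _["decision"] = dec, _["w_norm"] = wnorm,
                      _["w"] = NumericVector(w.begin(), w.end()));
}
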