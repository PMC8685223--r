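// Soft-margin RBF-kernel SVM trained with sequential minimal
// optimisation (Platt's SMO with an error cache). Deterministic: all
// candidate loops are ordered, no random selection.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

class Smo {
public:
  const NumericMatrix& X;
  const NumericVector& y;
  double C, gamma, tol, eps;
  int n;
  std::vector<double> alpha, E;
  std::vector<std::vector<double> > K;
  double b;
  long steps, max_steps;

  Smo(const NumericMatrix& X_, const NumericVector& y_, double C_,
      double gamma_, double tol_, long max_steps_)
    : X(X_), y(y_), C(C_), gamma(gamma_), tol(tol_), eps(1e-12),
      n(X_.nrow()), alpha(n, 0.0), E(n), b(0.0), steps(0),
      max_steps(max_steps_) {
    K.assign(n, std::vector<double>(n));
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j)
        K[i][j] = K[j][i] = rbf(X, i, j, gamma);
    for (int i = 0; i < n; ++i) E[i] = -y[i]; // f(i)=0 initially
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1o = alpha[i1], a2o = alpha[i2];
    const double y1 = y[i1], y2 = y[i2];
    const double E1 = E[i1], E2 = E[i2];
    const double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2o - a1o);
      H = std::min(C, C + a2o - a1o);
    } else {
      L = std::max(0.0, a1o + a2o - C);
      H = std::min(C, a1o + a2o);
    }
    if (L >= H) return false;
    const double k11 = K[i1][i1], k12 = K[i1][i2], k22 = K[i2][i2];
    const double eta = k11 + k22 - 2.0 * k12;
    double a2;
    if (eta > 0) {
      a2 = a2o + y2 * (E1 - E2) / eta;
      if (a2 < L) a2 = L; else if (a2 > H) a2 = H;
    } else {
      // objective at the two clip bounds
      const double f1 = y1 * (E1 + b) - a1o * k11 - s * a2o * k12;
      const double f2 = y2 * (E2 + b) - s * a1o * k12 - a2o * k22;
      const double L1 = a1o + s * (a2o - L);
      const double H1 = a1o + s * (a2o - H);
      const double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
        0.5 * L * L * k22 + s * L * L1 * k12;
      const double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
        0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - 1e-12) a2 = L;
      else if (objL > objH + 1e-12) a2 = H;
      else return false;
    }
    if (std::fabs(a2 - a2o) < 1e-10 * (a2 + a2o + 1e-10)) return false;
    const double a1 = a1o + s * (a2o - a2);
    // threshold update
    const double b1 = E1 + y1 * (a1 - a1o) * k11 + y2 * (a2 - a2o) * k12 + b;
    const double b2 = E2 + y1 * (a1 - a1o) * k12 + y2 * (a2 - a2o) * k22 + b;
    const double b_new =
      (a1 > 0 && a1 < C) ? b1 : ((a2 > 0 && a2 < C) ? b2 : 0.5 * (b1 + b2));
    const double db = b - b_new; // f uses -b in Platt's form: f(i) = sum - b
    for (int i = 0; i < n; ++i)
      E[i] += y1 * (a1 - a1o) * K[i1][i] + y2 * (a2 - a2o) * K[i2][i] + db;
    b = b_new;
    alpha[i1] = a1;
    alpha[i2] = a2;
    ++steps;
    return true;
  }

  bool examine(int i2) {
    const double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    const double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximise |E1 - E2| over non-bound alphas
      int best = -1;
      double bestgap = -1.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > 0 && alpha[i] < C) {
          const double gap = std::fabs(E[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return true;
      // heuristic 2: all non-bound, then all, in fixed order from i2+1
      for (int k = 0; k < n; ++k) {
        const int i = (i2 + 1 + k) % n;
        if (alpha[i] > 0 && alpha[i] < C && take_step(i, i2)) return true;
      }
      for (int k = 0; k < n; ++k) {
        const int i = (i2 + 1 + k) % n;
        if (take_step(i, i2)) return true;
      }
    }
    return false;
  }

  void solve() {
    int num_changed = 0;
    bool examine_all = true;
    while ((num_changed > 0 || examine_all) && steps < max_steps) {
      num_changed = 0;
      if (examine_all) {
        for (int i = 0; i < n && steps < max_steps; ++i)
          num_changed += examine(i) ? 1 : 0;
      } else {
        for (int i = 0; i < n && steps < max_steps; ++i)
          if (alpha[i] > 0 && alpha[i] < C)
            num_changed += examine(i) ? 1 : 0;
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
    }
  }
};

// [[Rcpp::export(name = ".svm_smo_fit")]]
List svm_smo_fit(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol = 1e-3, double max_steps = 5e6) {
  if (X.nrow() != y.size()) stop("X and y size mismatch");
  Smo smo(X, y, C, gamma, tol, (long)max_steps);
  smo.solve();
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b,
                      _["steps"] = (double)smo.steps,
                      _["converged"] = smo.steps < (long)max_steps);
}

// Decision values f(x) = sum_j coef_j K(x_j, x) - b with coef = alpha*y.
// [[Rcpp::export(name = ".svm_decision")]]
NumericVector svm_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int m = Xnew.nrow(), nsv = Xsv.nrow(), d = Xsv.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double f = -b;
    for (int j = 0; j < nsv; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = Xnew(i, k) - Xsv(j, k);
        s += diff * diff;
      }
      f += coef[j] * std::exp(-gamma * s);
    }
    out[i] = f;
  }
  return out;
}
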