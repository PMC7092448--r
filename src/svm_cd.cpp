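#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate descent for the elastic-net penalized linear SVM with a
// huberized hinge loss.  For smoothing width g > 0,
//
//   h_g(u) = 0                   u >= 1
//          = (1 - u)^2 / (2 g)   1 - g < u < 1
//          = 1 - u - g / 2       u <= 1 - g
//
// converges to the hinge max(0, 1 - u) uniformly as g -> 0 (the gap is at
// most g/2 per observation).  The objective minimized here, on the feature
// matrix as supplied (standardization happens in R), is
//
//   J(b0, b) = sum_i h_g(y_i (x_i' b + b0))
//              + lambda * (0.5 * (1 - alpha) * ||b||_2^2 + alpha * ||b||_1)
//
// Each coordinate step is a proximal Newton step using the curvature of the
// observations inside the quadratic band, followed by step halving so that
// the objective never increases.  A continuation scheme starts from a wide
// band (g = 1) and shrinks it to the requested gamma, which keeps the
// per-coordinate curvature well conditioned on the way down.

static inline double hub(double u, double g) {
  if (u >= 1.0) return 0.0;
  if (u > 1.0 - g) { double r = 1.0 - u; return r * r / (2.0 * g); }
  return 1.0 - u - 0.5 * g;
}

static inline double hubp(double u, double g) {
  if (u >= 1.0) return 0.0;
  if (u > 1.0 - g) return (u - 1.0) / g;
  return -1.0;
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

namespace {

struct Problem {
  const double* X;   // n x p, column major
  const double* y;   // +1 / -1
  int n, p;
  double lam1, lam2; // lambda * alpha, lambda * (1 - alpha)
  double gamma;
  std::vector<double> u;  // margins y_i * (x_i' b + b0)
  std::vector<double> b;
  double b0;

  // One coordinate move for feature j (j == -1 means the intercept).
  // Returns |delta| actually applied.
  double update(int j) {
    const double* xj = (j >= 0) ? X + (size_t)j * n : nullptr;
    double grad = 0.0, curv = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = hubp(u[i], gamma);
      double xij = xj ? xj[i] : 1.0;
      if (d != 0.0) grad += d * y[i] * xij;
      if (u[i] < 1.0 && u[i] > 1.0 - gamma) curv += xij * xij / gamma;
    }
    double del;
    if (j >= 0) {
      double a = curv + lam2;
      if (a < 1e-10) a = 1e-10;
      double z = a * b[j] - (grad + lam2 * b[j]);
      del = soft(z, lam1) / a - b[j];
    } else {
      double a = curv;
      if (a < 1e-10) a = 1e-10;
      del = -grad / a;
    }
    if (std::fabs(del) < 1e-14) return 0.0;
    // step halving: accept only a non-increasing objective. The margin
    // update is applied tentatively while the objective change is being
    // accumulated and reverted on the (rare) rejection, so the common
    // accepted step costs a single pass.
    double bj = (j >= 0) ? b[j] : b0;
    for (int ls = 0; ls < 60; ++ls) {
      double dobj = 0.0;
      if (j >= 0) {
        double bn = bj + del;
        dobj += 0.5 * lam2 * (bn * bn - bj * bj) +
                lam1 * (std::fabs(bn) - std::fabs(bj));
      }
      for (int i = 0; i < n; ++i) {
        double step = y[i] * (xj ? xj[i] : 1.0) * del;
        dobj -= hub(u[i], gamma);
        u[i] += step;
        dobj += hub(u[i], gamma);
      }
      if (dobj <= 1e-12) {
        if (j >= 0) b[j] = bj + del; else b0 = bj + del;
        return std::fabs(del);
      }
      for (int i = 0; i < n; ++i) {
        u[i] -= y[i] * (xj ? xj[i] : 1.0) * del;
      }
      del *= 0.5;
      if (std::fabs(del) < 1e-14) break;
    }
    return 0.0;
  }

  // Cycle to convergence at the current gamma. Returns cycles used.
  int solve(double tol, int maxit, bool* conv) {
    // settle the unpenalized intercept first: it stabilizes the path start
    for (int it = 0; it < 1000; ++it) {
      if (update(-1) < tol) break;
    }
    bool full = true;
    int it = 0;
    for (; it < maxit; ++it) {
      double maxd = update(-1);
      for (int j = 0; j < p; ++j) {
        if (full || b[j] != 0.0) {
          double d = update(j);
          if (d > maxd) maxd = d;
        }
      }
      if (maxd < tol) {
        if (full) { *conv = true; return it + 1; }
        full = true;
      } else {
        full = false;
      }
    }
    *conv = false;
    return it;
  }
};

} // namespace

// Fit a decreasing lambda path at fixed alpha with warm starts.
// gamma continuation (1 -> gamma, factor 8) runs at the first lambda only;
// warm starts keep later fits inside the narrow band's basin.
// [[Rcpp::export(name = ".cd_svm_path")]]
List cd_svm_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                 double alpha, double gamma, double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  Problem pr;
  pr.X = REAL(X);
  pr.y = REAL(y);
  pr.n = n;
  pr.p = p;
  pr.gamma = gamma;
  pr.u.assign(n, 0.0);
  pr.b.assign(p, 0.0);
  pr.b0 = 0.0;

  NumericMatrix beta(p, L);
  NumericVector beta0(L);
  IntegerVector iters(L);
  LogicalVector conv(L);

  for (int l = 0; l < L; ++l) {
    pr.lam1 = lambdas[l] * alpha;
    pr.lam2 = lambdas[l] * (1.0 - alpha);
    bool cv = false;
    int used = 0;
    if (l == 0) {
      double g = 1.0;
      if (g < gamma) g = gamma;
      while (true) {
        pr.gamma = g;
        double stage_tol = (g <= gamma) ? tol : std::max(tol, 1e-4);
        used += pr.solve(stage_tol, maxit, &cv);
        if (g <= gamma) break;
        g = std::max(g / 8.0, gamma);
      }
    } else {
      pr.gamma = gamma;
      used = pr.solve(tol, maxit, &cv);
    }
    for (int j = 0; j < p; ++j) beta(j, l) = pr.b[j];
    beta0[l] = pr.b0;
    iters[l] = used;
    conv[l] = cv;
  }
  return List::create(_["beta"] = beta, _["beta0"] = beta0,
                      _["iters"] = iters, _["converged"] = conv);
}

// Gradient of the huberized loss at the intercept-only optimum; used by the
// R side to anchor lambda_max.
// [[Rcpp::export(name = ".cd_svm_grad0")]]
NumericVector cd_svm_grad0(NumericMatrix X, NumericVector y, double gamma) {
  int n = X.nrow(), p = X.ncol();
  Problem pr;
  pr.X = REAL(X);
  pr.y = REAL(y);
  pr.n = n;
  pr.p = p;
  pr.lam1 = 0.0;
  pr.lam2 = 0.0;
  pr.u.assign(n, 0.0);
  pr.b.assign(p, 0.0);
  pr.b0 = 0.0;
  double g = 1.0;
  if (g < gamma) g = gamma;
  while (true) {
    pr.gamma = g;
    for (int it = 0; it < 2000; ++it) {
      if (pr.update(-1) < 1e-10) break;
    }
    if (g <= gamma) break;
    g = std::max(g / 8.0, gamma);
  }
  NumericVector out(p + 1);
  for (int j = 0; j < p; ++j) {
    const double* xj = REAL(X) + (size_t)j * n;
    double grad = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = hubp(pr.u[i], gamma);
      if (d != 0.0) grad += d * y[i] * xj[i];
    }
    out[j] = grad;
  }
  out[p] = pr.b0;
  return out;
}
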