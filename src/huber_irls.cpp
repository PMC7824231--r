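#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Small dense Cholesky: A (p x p, upper triangle filled, row-major) is
// factored in place; returns false when not positive definite.
static bool chol_small(std::vector<double>& A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= A[k * p + j] * A[k * p + j];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[j * p + i];
      for (int k = 0; k < j; ++k) s -= A[k * p + j] * A[k * p + i];
      A[j * p + i] = s / d;
    }
  }
  return true;
}

// Solve A x = b given the Cholesky factor (upper triangle, row-major).
static void chol_solve(const std::vector<double>& L, int p,
                       const double* b, double* x) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[k * p + i] * x[k];
    x[i] = s / L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < p; ++k) s -= L[i * p + k] * x[k];
    x[i] = s / L[i * p + i];
  }
}

static double median_abs(std::vector<double>& buf) {
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double med = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    med = 0.5 * (med + lo);
  }
  return med;
}

// Huber M-estimation by IRLS for many outcome columns sharing one design.
// Used by the training/testing screening step, where the same
// feeding + surrogate-variable design is fitted to every CpG, so the
// per-CpG work must stay at microseconds.
//
// Returns a 2 x m matrix: row 0 the coefficient of design column `which`
// (1-based), row 1 its standard error from the final weighted LS fit.
// Columns that fail to fit (singular weighted design) are NaN.
// [[Rcpp::export]]
NumericMatrix huber_irls_cpp(const NumericMatrix& X, const NumericMatrix& Y,
                             const int which, const double k,
                             const int maxit, const double tol) {
  const int n = X.nrow(), p = X.ncol(), m = Y.ncol();
  const int j0 = which - 1;
  NumericMatrix out(2, m);
  std::fill(out.begin(), out.end(), NA_REAL);

  // X transposed for row-wise access: xt[i*p + a]
  std::vector<double> xt(static_cast<size_t>(n) * p);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < p; ++a) xt[static_cast<size_t>(i) * p + a] = X(i, a);

  std::vector<double> A(p * p), L(p * p), c(p), b(p), bnew(p), fit(n),
      r(n), absr(n), w(n), ej(p), z(p);

  for (int j = 0; j < m; ++j) {
    const double* y = &Y(0, j);

    // unweighted start
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(c.begin(), c.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* xi = &xt[static_cast<size_t>(i) * p];
      for (int a = 0; a < p; ++a) {
        c[a] += xi[a] * y[i];
        for (int bcol = a; bcol < p; ++bcol)
          A[a * p + bcol] += xi[a] * xi[bcol];
      }
    }
    L = A;
    if (!chol_small(L, p)) continue;
    chol_solve(L, p, c.data(), b.data());

    bool ok = true;
    for (int it = 0; it < maxit; ++it) {
      // residuals and Huber weights at the current coefficients
      for (int i = 0; i < n; ++i) {
        const double* xi = &xt[static_cast<size_t>(i) * p];
        double f = 0.0;
        for (int a = 0; a < p; ++a) f += xi[a] * b[a];
        r[i] = y[i] - f;
        absr[i] = std::fabs(r[i]);
      }
      std::vector<double> tmp(absr);
      double s = 1.4826 * median_abs(tmp);
      if (s < 1e-10) s = 1e-10;
      const double cut = k * s;
      for (int i = 0; i < n; ++i)
        w[i] = (absr[i] > cut) ? cut / absr[i] : 1.0;

      // weighted normal equations
      std::fill(A.begin(), A.end(), 0.0);
      std::fill(c.begin(), c.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        const double* xi = &xt[static_cast<size_t>(i) * p];
        const double wi = w[i];
        for (int a = 0; a < p; ++a) {
          const double wx = wi * xi[a];
          c[a] += wx * y[i];
          for (int bcol = a; bcol < p; ++bcol)
            A[a * p + bcol] += wx * xi[bcol];
        }
      }
      L = A;
      if (!chol_small(L, p)) { ok = false; break; }
      chol_solve(L, p, c.data(), bnew.data());
      double step = 0.0, bmax = 0.0;
      for (int a = 0; a < p; ++a) {
        step = std::max(step, std::fabs(bnew[a] - b[a]));
        bmax = std::max(bmax, std::fabs(bnew[a]));
      }
      b = bnew;
      if (step < tol * (1.0 + bmax)) break;
    }
    if (!ok) continue;

    // final residuals/weights for the standard error
    double wrss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &xt[static_cast<size_t>(i) * p];
      double f = 0.0;
      for (int a = 0; a < p; ++a) f += xi[a] * b[a];
      r[i] = y[i] - f;
      absr[i] = std::fabs(r[i]);
    }
    std::vector<double> tmp(absr);
    double s = 1.4826 * median_abs(tmp);
    if (s < 1e-10) s = 1e-10;
    const double cut = k * s;
    std::fill(A.begin(), A.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* xi = &xt[static_cast<size_t>(i) * p];
      const double wi = (absr[i] > cut) ? cut / absr[i] : 1.0;
      wrss += wi * r[i] * r[i];
      for (int a = 0; a < p; ++a)
        for (int bcol = a; bcol < p; ++bcol)
          A[a * p + bcol] += wi * xi[a] * xi[bcol];
    }
    L = A;
    if (!chol_small(L, p)) continue;
    std::fill(ej.begin(), ej.end(), 0.0);
    ej[j0] = 1.0;
    chol_solve(L, p, ej.data(), z.data());
    const double sigma2 = wrss / static_cast<double>(n - p);
    out(0, j) = b[j0];
    out(1, j) = std::sqrt(z[j0] * sigma2);
  }
  return out;
}
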