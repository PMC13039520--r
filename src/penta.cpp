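#include <Rcpp.h>
using namespace Rcpp;

// Solve (diag(w) + P) z = rhs where P is a symmetric positive-definite
// pentadiagonal matrix given by its main (p0, length n), first (p1, n-1)
// and second (p2, n-2) diagonals. Banded Cholesky, O(n); this is the inner
// solve of the iteratively reweighted baseline estimator, called once per
// reweighting iteration per spectrum.
// [[Rcpp::export]]
NumericVector penta_solve(NumericVector w, NumericVector rhs,
                          NumericVector p0, NumericVector p1,
                          NumericVector p2) {
  const int n = w.size();
  if (rhs.size() != n || p0.size() != n || p1.size() != n - 1 ||
      p2.size() != n - 2)
    stop("penta_solve: inconsistent band lengths");
  std::vector<double> l0(n), l1(n > 1 ? n - 1 : 0), l2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) {
    double s = w[i] + p0[i];
    if (i >= 1) s -= l1[i - 1] * l1[i - 1];
    if (i >= 2) s -= l2[i - 2] * l2[i - 2];
    if (!(s > 0.0))
      stop("singular system: penalized matrix not positive definite");
    l0[i] = std::sqrt(s);
    if (i + 1 < n) {
      double t = p1[i];
      if (i >= 1) t -= l2[i - 1] * l1[i - 1];
      l1[i] = t / l0[i];
    }
    if (i + 2 < n) l2[i] = p2[i] / l0[i];
  }
  // forward substitution L u = rhs
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) {
    double s = rhs[i];
    if (i >= 1) s -= l1[i - 1] * u[i - 1];
    if (i >= 2) s -= l2[i - 2] * u[i - 2];
    u[i] = s / l0[i];
  }
  // back substitution L^T z = u
  NumericVector z(n);
  for (int i = n - 1; i >= 0; --i) {
    double s = u[i];
    if (i + 1 < n) s -= l1[i] * z[i + 1];
    if (i + 2 < n) s -= l2[i] * z[i + 2];
    z[i] = s / l0[i];
  }
  return z;
}
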