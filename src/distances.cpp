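#include <Rcpp.h>

using namespace Rcpp;

// Weighted L1 cross-distance: out[i, j] = sum_r w[r] * |X(i, r) - Y(j, r)|.
// Shared workhorse for all four microbiome distances (abundance matrices for
// weighted UniFrac / Bray-Curtis, presence indicators for unweighted
// UniFrac / Hamming); the metric-specific denominators are cheap BLAS-style
// operations done in R.
// [[Rcpp::export]]
NumericMatrix cross_weighted_l1(NumericMatrix X, NumericMatrix Y,
                                NumericVector w) {
  const int n1 = X.nrow(), n2 = Y.nrow(), R = X.ncol();
  if (Y.ncol() != R || w.size() != R)
    stop("feature dimensions of X, Y and w must agree");
  NumericMatrix out(n1, n2);
  for (int r = 0; r < R; ++r) {
    const double wr = w[r];
    if (wr == 0.0) continue;
    const double *xr = &X(0, r), *yr = &Y(0, r);
    for (int j = 0; j < n2; ++j) {
      const double yj = yr[j];
      double *oj = &out(0, j);
      for (int i = 0; i < n1; ++i)
        oj[i] += wr * std::fabs(xr[i] - yj);
    }
  }
  return out;
}

// Symmetric variant computing only the upper triangle and mirroring.
// [[Rcpp::export]]
NumericMatrix self_weighted_l1(NumericMatrix X, NumericVector w) {
  const int n = X.nrow(), R = X.ncol();
  if (w.size() != R) stop("feature dimensions of X and w must agree");
  NumericMatrix out(n, n);
  for (int r = 0; r < R; ++r) {
    const double wr = w[r];
    if (wr == 0.0) continue;
    const double *xr = &X(0, r);
    for (int j = 1; j < n; ++j) {
      const double xj = xr[j];
      double *oj = &out(0, j);
      for (int i = 0; i < j; ++i)
        oj[i] += wr * std::fabs(xr[i] - xj);
    }
  }
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i)
      out(j, i) = out(i, j);
  return out;
}
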