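#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact Euclidean distance transform on a regular anisotropic 3-D grid,
// via the separable lower-envelope-of-parabolas algorithm of
// Felzenszwalb & Huttenlocher (squared distances, one pass per axis).

static const double INF = std::numeric_limits<double>::infinity();

// One-dimensional squared distance transform of sampled function f at
// positions x_i = i * h. Writes the result back into f.
static void dt1d(std::vector<double> &f, int n, double h,
                 std::vector<int> &v, std::vector<double> &z,
                 std::vector<double> &d) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) {
      // both parabolas at infinity: keep the later one as a placeholder
      v[k] = q;
      continue;
    }
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      if (f[v[k]] == INF) {
        s = -INF; // new finite parabola dominates everywhere left of z[k]
      } else {
        s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      }
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector mask,
                              Rcpp::IntegerVector dim,
                              Rcpp::NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n)
    Rcpp::stop("mask length does not match dim");
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i)
    g[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying, stride 1)
  for (R_xlen_t j = 0; j < (R_xlen_t)n2 * n3; ++j) {
    R_xlen_t base = j * n1;
    for (int i = 0; i < n1; ++i) f[i] = g[base + i];
    f.resize(n1);
    dt1d(f, n1, spacing[0], v, z, d);
    for (int i = 0; i < n1; ++i) g[base + i] = f[i];
    f.resize(nmax);
  }
  // axis 2 (stride n1)
  for (int k3 = 0; k3 < n3; ++k3) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + i;
      for (int q = 0; q < n2; ++q) f[q] = g[base + (R_xlen_t)q * n1];
      f.resize(n2);
      dt1d(f, n2, spacing[1], v, z, d);
      for (int q = 0; q < n2; ++q) g[base + (R_xlen_t)q * n1] = f[q];
      f.resize(nmax);
    }
  }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t i = 0; i < s3; ++i) {
    for (int q = 0; q < n3; ++q) f[q] = g[i + (R_xlen_t)q * s3];
    f.resize(n3);
    dt1d(f, n3, spacing[2], v, z, d);
    for (int q = 0; q < n3; ++q) g[i + (R_xlen_t)q * s3] = f[q];
    f.resize(nmax);
  }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
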