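#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Nearest-neighbour distances from each row of X to the point set Y.
// Plain double loop; exactness (not speed) is the contract, and the
// R-level oracle used in tests is an independent implementation.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double dx = xi - Y(j, 0), dy = yi - Y(j, 1), dz = zi - Y(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static const double INF = std::numeric_limits<double>::infinity();

// Abscissa where the parabolas rooted at samples p and q (values f[p], f[q],
// horizontal scale w) intersect; +/-Inf samples give degenerate envelopes.
static inline double intersect(const std::vector<double> &f, int p, int q,
                               double w2) {
  if (f[q] == INF) return INF;
  if (f[p] == INF) return -INF;
  return ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
}

// Felzenszwalb & Huttenlocher lower-envelope squared distance transform
// along one line with physical sample spacing w.
static void dt_1d(const std::vector<double> &f, std::vector<double> &d, int n,
                  std::vector<int> &v, std::vector<double> &z, double w) {
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = intersect(f, v[k], q, w2);
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0) s = intersect(f, v[k], q, w2);
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const int p = v[j];
    if (f[p] == INF) {
      d[q] = INF;
    } else {
      const double dq = w * (q - p);
      d[q] = dq * dq + f[p];
    }
  }
}

// Exact squared Euclidean distance transform of a 3D indicator on an
// anisotropic grid: for every voxel, the squared physical distance to the
// centre of the nearest voxel with mask != 0. Column-major voxel order,
// dims `dim`, edge lengths `spacing` in mm. All-zero mask gives +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t N = nxy * nz;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = k * nxy + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt_1d(f, d, nx, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = k * nxy + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt_1d(f, d, ny, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + k * nxy];
      dt_1d(f, d, nz, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + k * nxy] = d[k];
    }
  return out;
}

// Foreground voxels with at least one 6-connected background (or
// out-of-grid) neighbour.
// [[Rcpp::export]]
LogicalVector cpp_boundary6(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector out(nxy * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = k * nxy + (R_xlen_t)j * nx + i;
        if (!mask[idx]) { out[idx] = FALSE; continue; }
        bool b = false;
        if (i == 0 || !mask[idx - 1]) b = true;
        else if (i == nx - 1 || !mask[idx + 1]) b = true;
        else if (j == 0 || !mask[idx - nx]) b = true;
        else if (j == ny - 1 || !mask[idx + nx]) b = true;
        else if (k == 0 || !mask[idx - nxy]) b = true;
        else if (k == nz - 1 || !mask[idx + nxy]) b = true;
        out[idx] = b;
      }
  return out;
}
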