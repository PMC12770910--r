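#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform on a sampled grid with physical
// spacing s (Felzenszwalb & Huttenlocher lower-envelope algorithm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector feature, IntegerVector dim,
                    NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of infinity: the envelope intersection
  // arithmetic must stay NaN-free
  const double INF = 1e20;
  const double ANY = 1e19;
  NumericVector d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = feature[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = d2[base + x]; if (f[x] < ANY) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d2[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = d2[base + (R_xlen_t)y * nx]; if (f[y] < ANY) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d2[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t pz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = d2[base + z * pz]; if (f[z] < ANY) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d2[base + z * pz] = d[z];
    }
  return d2;
}

// [[Rcpp::export(name = ".labelComponents3d")]]
IntegerVector labelComponents3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int cur = 0;
  const R_xlen_t px = 1, py = nx, pz = (R_xlen_t)nx * ny;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++cur;
    queue.clear();
    queue.push_back(seed);
    lab[seed] = cur;
    while (!queue.empty()) {
      R_xlen_t i = queue.back();
      queue.pop_back();
      int x = (int)(i % nx);
      int y = (int)((i / nx) % ny);
      int z = (int)(i / pz);
      // 6-connected neighbours
      if (x > 0      && mask[i - px] && lab[i - px] == 0) { lab[i - px] = cur; queue.push_back(i - px); }
      if (x < nx - 1 && mask[i + px] && lab[i + px] == 0) { lab[i + px] = cur; queue.push_back(i + px); }
      if (y > 0      && mask[i - py] && lab[i - py] == 0) { lab[i - py] = cur; queue.push_back(i - py); }
      if (y < ny - 1 && mask[i + py] && lab[i + py] == 0) { lab[i + py] = cur; queue.push_back(i + py); }
      if (z > 0      && mask[i - pz] && lab[i - pz] == 0) { lab[i - pz] = cur; queue.push_back(i - pz); }
      if (z < nz - 1 && mask[i + pz] && lab[i + pz] == 0) { lab[i + pz] = cur; queue.push_back(i + pz); }
    }
  }
  return lab;
}
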