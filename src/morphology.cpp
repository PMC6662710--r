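#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
// f: input squared distances along one line (stride apart), overwritten output in d.
static void dt1d(std::vector<double> &ff, std::vector<double> &dd,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      int p = v[k];
      s = ((ff[q] + (double)q * q) - (ff[p] + (double)p * p)) /
          (2.0 * q - 2.0 * p);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    dd[q] = (double)(q - p) * (q - p) + ff[p];
  }
}

// Exact 3D squared Euclidean distance transform, in voxel units, to the
// nearest TRUE voxel. Voxels with no TRUE voxel anywhere get a value >= 1e19.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> ff(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) ff[i] = out[base + i];
      dt1d(ff, dd, v, z, nx);
      for (int i = 0; i < nx; i++) out[base + i] = dd[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) ff[j] = out[base + (R_xlen_t)nx * j];
      dt1d(ff, dd, v, z, ny);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = dd[j];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; k++) ff[k] = out[base + sz * k];
      dt1d(ff, dd, v, z, nz);
      for (int k = 0; k < nz; k++) out[base + sz * k] = dd[k];
    }
  return out;
}

// TRUE for every TRUE voxel of `open` that is 6-connected to the grid
// boundary through TRUE voxels (breadth-first flood from all boundary cells).
// [[Rcpp::export]]
LogicalVector cpp_boundary_connected(LogicalVector open, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> seen(n, 0);
  std::queue<R_xlen_t> q;

  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (open[id] && !seen[id]) {
      seen[id] = 1;
      q.push(id);
    }
  };

  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
            k == nz - 1)
          push(i, j, k);

  while (!q.empty()) {
    R_xlen_t id = q.front();
    q.pop();
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int rem = (int)(id - (R_xlen_t)nx * ny * k);
    int j = rem / nx;
    int i = rem - nx * j;
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = seen[i] != 0;
  return out;
}
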