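#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 3D connected-component labeling of a logical volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns an integer volume with labels 1..ncomp (0 = background),
// components numbered in decreasing voxel count.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim,
                         int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        off_x.push_back(dx); off_y.push_back(dy); off_z.push_back(dz);
      }
  const size_t noff = off_x.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<std::pair<int, R_xlen_t> > sizes; // (count, seed) per label

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    int count = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++count;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < noff; ++k) {
        int xx = x + off_x[k], yy = y + off_y[k], zz = z + off_z[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(std::make_pair(count, s));
  }

  // renumber so label 1 is the largest component
  std::vector<int> order(next), rank_of(next + 1);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return sizes[a].first > sizes[b].first;
  });
  for (int r = 0; r < next; ++r) rank_of[order[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = rank_of[lab[s]];
  lab.attr("dim") = dim;
  return lab;
}

// One pass of the exact 1D squared-distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher), with sample step h (mm).
static inline double parab_intersect(const double *f, int q, int p, double h) {
  double qq = q * h, pp = p * h;
  return ((f[q] + qq * qq) - (f[p] + pp * pp)) / (2.0 * qq - 2.0 * pp);
}

static void dt1d(const double *f, double *d, int n, double h,
                 std::vector<int> &v, std::vector<double> &zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never enter the envelope
    double s = parab_intersect(f, q, v[k], h);
    while (k > 0 && s <= zbuf[k]) {
      --k;
      s = parab_intersect(f, q, v[k], h);
    }
    if (k == 0 && s <= zbuf[0]) {
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      zbuf[k] = s;
    }
    zbuf[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * h;
    while (zbuf[k + 1] < qq) ++k;
    double vv = v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// TRUE voxel of `mask`, honoring anisotropic spacing. Voxels inside the
// mask get 0. If the mask is empty, all distances are Inf.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = d[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nx, spacing[0], v, zbuf);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = d[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), ny, spacing[1], v, zbuf);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = out[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = d[base + (R_xlen_t)z * nx * ny]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nz, spacing[2], v, zbuf);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nx * ny] = out[z];
    }
  d.attr("dim") = dim;
  return d;
}
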