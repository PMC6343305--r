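#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), first index fastest.
// All geometry below works in voxel units on the integer grid of voxel centers.

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// distance to the nearest off-phase voxel center; voxels outside the volume
// count as off-phase (a single padding layer suffices: clamping any outside
// voxel's coordinates into the padded box never increases its distance).
// ---------------------------------------------------------------------------

static const double INF = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// squared EDT on the padded grid; returns unpadded volume of squared distances
static std::vector<double> sedt_core(const int* mask, int nz, int ny, int nx) {
  int pz = nz + 2, py = ny + 2, px = nx + 2;
  std::vector<double> g((size_t)pz * py * px);
  // init: 0 at off-phase (incl. padding), INF at in-phase
  for (int x = 0; x < px; x++)
    for (int y = 0; y < py; y++)
      for (int z = 0; z < pz; z++) {
        bool inphase = false;
        if (z >= 1 && z <= nz && y >= 1 && y <= ny && x >= 1 && x <= nx)
          inphase = mask[vidx(z - 1, y - 1, x - 1, nz, ny)] != 0;
        g[vidx(z, y, x, pz, py)] = inphase ? INF : 0.0;
      }
  int nmax = std::max(pz, std::max(py, px));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < px; x++)
    for (int y = 0; y < py; y++) {
      for (int z = 0; z < pz; z++) f[z] = g[vidx(z, y, x, pz, py)];
      dt1d(f, d, pz, v, zbuf);
      for (int z = 0; z < pz; z++) g[vidx(z, y, x, pz, py)] = d[z];
    }
  // pass along y
  for (int x = 0; x < px; x++)
    for (int z = 0; z < pz; z++) {
      for (int y = 0; y < py; y++) f[y] = g[vidx(z, y, x, pz, py)];
      dt1d(f, d, py, v, zbuf);
      for (int y = 0; y < py; y++) g[vidx(z, y, x, pz, py)] = d[y];
    }
  // pass along x
  for (int y = 0; y < py; y++)
    for (int z = 0; z < pz; z++) {
      for (int x = 0; x < px; x++) f[x] = g[vidx(z, y, x, pz, py)];
      dt1d(f, d, px, v, zbuf);
      for (int x = 0; x < px; x++) g[vidx(z, y, x, pz, py)] = d[x];
    }
  std::vector<double> out((size_t)nz * ny * nx);
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++)
        out[vidx(z, y, x, nz, ny)] = g[vidx(z + 1, y + 1, x + 1, pz, py)];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sedt(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> out = sedt_core(INTEGER(mask), nz, ny, nx);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dim;
  return res;
}

// Exact predicate for ||q - c|| <= sqrt(R2) - 0.5 with d2 = ||q - c||^2 integer:
//   d ≤ s − 1/2  ⇔  s ≤ R2 + 1/4 − d2  ⇔  t ≥ 0 ∧ R2 ≤ t², t = R2 + 0.25 − d2.
// R2, d2 are exact integers in double; t and t^2 are exactly representable for
// the volume sizes allowed here, so the comparison involves no rounding.
static inline bool in_sphere(double R2, double d2) {
  double t = R2 + 0.25 - d2;
  return t >= 0.0 && R2 <= t * t;
}

// ---------------------------------------------------------------------------
// Local thickness: tau(p) = max over in-phase centers c covering p of
// 2*sqrt(EDT2(c)) - 1 voxels, where c covers p iff ||p-c|| <= sqrt(EDT2(c))-0.5.
// Fast path prunes centers whose sphere is provably contained in a
// 26-neighbour's sphere: sqrt(R2') >= sqrt(R2) + ||delta||, checked exactly via
// u = R2' - R2 - d2 >= 0 and u^2 >= 4*d2*R2. Containment is transitive, so the
// maximum over surviving spheres is unchanged.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* m = INTEGER(mask);
  std::vector<double> D2 = sedt_core(m, nz, ny, nx);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector tau(n);
  tau.attr("dim") = dim;

  struct Center { int z, y, x; double R2; };
  std::vector<Center> centers;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        if (!m[i]) continue;
        double R2 = D2[i];
        // ridge pruning against 26-neighbourhood
        bool pruned = false;
        for (int dx = -1; dx <= 1 && !pruned; dx++)
          for (int dy = -1; dy <= 1 && !pruned; dy++)
            for (int dz = -1; dz <= 1 && !pruned; dz++) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              R_xlen_t j = vidx(zz, yy, xx, nz, ny);
              if (!m[j]) continue;
              double d2 = (double)(dx * dx + dy * dy + dz * dz);
              double u = D2[j] - R2 - d2;
              if (u >= 0.0 && u * u >= 4.0 * d2 * R2) pruned = true;
            }
        if (!pruned) centers.push_back({z, y, x, R2});
      }

  for (const Center& c : centers) {
    double s = std::sqrt(c.R2);
    double tval = 2.0 * s - 1.0;
    int rad = (int)std::floor(s - 0.5 + 1e-12);
    if (rad < 0) rad = 0;
    int z0 = std::max(0, c.z - rad), z1 = std::min(nz - 1, c.z + rad);
    int y0 = std::max(0, c.y - rad), y1 = std::min(ny - 1, c.y + rad);
    int x0 = std::max(0, c.x - rad), x1 = std::min(nx - 1, c.x + rad);
    for (int x = x0; x <= x1; x++) {
      double dx2 = (double)(x - c.x) * (x - c.x);
      for (int y = y0; y <= y1; y++) {
        double dxy2 = dx2 + (double)(y - c.y) * (y - c.y);
        for (int z = z0; z <= z1; z++) {
          double d2 = dxy2 + (double)(z - c.z) * (z - c.z);
          if (!in_sphere(c.R2, d2)) continue;
          R_xlen_t i = vidx(z, y, x, nz, ny);
          if (tval > tau[i]) tau[i] = tval;
        }
      }
    }
  }
  return tau;
}

// Brute-force oracle: identical definition, no pruning, independently coded
// painting loop over every in-phase center.
// [[Rcpp::export]]
NumericVector cpp_brute_thickness(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* m = INTEGER(mask);
  std::vector<double> D2 = sedt_core(m, nz, ny, nx);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector tau(n);
  tau.attr("dim") = dim;
  for (int cx = 0; cx < nx; cx++)
    for (int cy = 0; cy < ny; cy++)
      for (int cz = 0; cz < nz; cz++) {
        R_xlen_t ci = vidx(cz, cy, cx, nz, ny);
        if (!m[ci]) continue;
        double R2 = D2[ci];
        double s = std::sqrt(R2);
        double tval = 2.0 * s - 1.0;
        int rad = (int)std::ceil(s);
        for (int x = std::max(0, cx - rad); x <= std::min(nx - 1, cx + rad); x++)
          for (int y = std::max(0, cy - rad); y <= std::min(ny - 1, cy + rad); y++)
            for (int z = std::max(0, cz - rad); z <= std::min(nz - 1, cz + rad); z++) {
              double d2 = (double)(x - cx) * (x - cx) + (double)(y - cy) * (y - cy) +
                          (double)(z - cz) * (z - cz);
              if (in_sphere(R2, d2)) {
                R_xlen_t i = vidx(z, y, x, nz, ny);
                if (tval > tau[i]) tau[i] = tval;
              }
            }
      }
  return tau;
}

// ---------------------------------------------------------------------------
// 6-connected component labelling (BFS), labels 1..k, 0 off-phase.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* m = INTEGER(mask);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        if (!m[i] || lab[i]) continue;
        next++;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int k = 0; k < 6; k++) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = vidx(zz, yy, xx, nz, ny);
            if (m[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, replicate edges, kernel truncated at 3.5 sigma.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& a, int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * rad + 1);
  double sum = 0;
  for (int i = -rad; i <= rad; i++) {
    k[i + rad] = std::exp(-0.5 * i * (double)i / (sigma * sigma));
    sum += k[i + rad];
  }
  for (double& v : k) v /= sum;
  int len, n1, n2;
  R_xlen_t stride, s1, s2;
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  if (axis == 0)      { len = nz; stride = sz; n1 = ny; s1 = sy; n2 = nx; s2 = sx; }
  else if (axis == 1) { len = ny; stride = sy; n1 = nz; s1 = sz; n2 = nx; s2 = sx; }
  else                { len = nx; stride = sx; n1 = nz; s1 = sz; n2 = ny; s2 = sy; }
  // line padded by edge replication so the convolution loop is branch-free
  std::vector<double> line(len + 2 * rad), out(len);
  for (int i2 = 0; i2 < n2; i2++)
    for (int i1 = 0; i1 < n1; i1++) {
      R_xlen_t base = (R_xlen_t)i1 * s1 + (R_xlen_t)i2 * s2;
      for (int t = 0; t < len; t++) line[rad + t] = a[base + (R_xlen_t)t * stride];
      for (int i = 0; i < rad; i++) {
        line[i] = line[rad];
        line[rad + len + i] = line[rad + len - 1];
      }
      for (int t = 0; t < len; t++) {
        double acc = 0;
        const double* lp = &line[t];
        for (int i = 0; i <= 2 * rad; i++) acc += k[i] * lp[i];
        out[t] = acc;
      }
      for (int t = 0; t < len; t++) a[base + (R_xlen_t)t * stride] = out[t];
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector arr, IntegerVector dim, NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(a, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(a, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Per-slice 2D filters with edge replication. Slices are (y, x) planes.
// ---------------------------------------------------------------------------

static inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

// sharpen: 3x3 kernel, centre 12, neighbours -1, divided by 4; clip to [lo, hi]
// [[Rcpp::export]]
NumericVector cpp_sharpen(NumericVector arr, IntegerVector dim, double lo, double hi) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(arr.size());
  out.attr("dim") = dim;
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        double acc = 0;
        for (int dx = -1; dx <= 1; dx++)
          for (int dy = -1; dy <= 1; dy++) {
            double w = (dx == 0 && dy == 0) ? 12.0 : -1.0;
            acc += w * arr[vidx(z, clampi(y + dy, 0, ny - 1), clampi(x + dx, 0, nx - 1), nz, ny)];
          }
        acc /= 4.0;
        if (acc < lo) acc = lo;
        if (acc > hi) acc = hi;
        out[vidx(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// despeckle: 3x3 median per slice, edge replication
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector arr, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(arr.size());
  out.attr("dim") = dim;
  double buf[9];
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        int k = 0;
        for (int dx = -1; dx <= 1; dx++)
          for (int dy = -1; dy <= 1; dy++)
            buf[k++] = arr[vidx(z, clampi(y + dy, 0, ny - 1), clampi(x + dx, 0, nx - 1), nz, ny)];
        std::nth_element(buf, buf + 4, buf + 9);
        out[vidx(z, y, x, nz, ny)] = buf[4];
      }
  return out;
}

// block-mean downsample by integer factor along all three axes
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector arr, IntegerVector dim, int f) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int oz = nz / f, oy = ny / f, ox = nx / f;
  NumericVector out((R_xlen_t)oz * oy * ox);
  out.attr("dim") = IntegerVector::create(oz, oy, ox);
  double inv = 1.0 / ((double)f * f * f);
  for (int x = 0; x < ox; x++)
    for (int y = 0; y < oy; y++)
      for (int z = 0; z < oz; z++) {
        double acc = 0;
        for (int dx = 0; dx < f; dx++)
          for (int dy = 0; dy < f; dy++)
            for (int dz = 0; dz < f; dz++)
              acc += arr[vidx(z * f + dz, y * f + dy, x * f + dx, nz, ny)];
        out[vidx(z, y, x, oz, oy)] = acc * inv;
      }
  return out;
}
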