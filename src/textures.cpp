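// Texture-matrix builders for discretized 3D dose volumes, plus a fast
// Kendall tau-b. Levels are 1..n_levels inside the mask and NA outside.
// All families use distance 1 and 26-connectivity (13 unique directions).
#include <Rcpp.h>
#include <vector>
#include <stack>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Symmetric co-occurrence counts, one Ng x Ng matrix per direction.
// [[Rcpp::export]]
List cpp_glcm(IntegerVector levels, IntegerVector dim, int n_levels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<NumericMatrix> mats;
  for (int d = 0; d < 13; ++d)
    mats.push_back(NumericMatrix(n_levels, n_levels));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == NA_INTEGER) continue;
        for (int d = 0; d < 13; ++d) {
          int x2 = x + DIRS[d][0], y2 = y + DIRS[d][1], z2 = z + DIRS[d][2];
          if (!inb(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == NA_INTEGER) continue;
          mats[d](a - 1, b - 1) += 1.0;
          mats[d](b - 1, a - 1) += 1.0;
        }
      }
  List out(13);
  for (int d = 0; d < 13; ++d) out[d] = mats[d];
  return out;
}

// Run-length counts, one Ng x Lmax matrix per direction. A run is a maximal
// streak of in-mask voxels sharing a level along the direction vector.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dim, int n_levels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  std::vector<NumericMatrix> mats;
  for (int d = 0; d < 13; ++d)
    mats.push_back(NumericMatrix(n_levels, lmax));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == NA_INTEGER) continue;
        for (int d = 0; d < 13; ++d) {
          int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
          // run starts here iff the previous voxel along -d does not
          // continue it
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inb(xp, yp, zp, nx, ny, nz)) {
            int p = levels[idx3(xp, yp, zp, nx, ny)];
            if (p != NA_INTEGER && p == a) continue;
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inb(xn, yn, zn, nx, ny, nz)) {
            int q = levels[idx3(xn, yn, zn, nx, ny)];
            if (q == NA_INTEGER || q != a) break;
            ++len; xn += dx; yn += dy; zn += dz;
          }
          mats[d](a - 1, len - 1) += 1.0;
        }
      }
  List out(13);
  for (int d = 0; d < 13; ++d) out[d] = mats[d];
  return out;
}

// 26-connected zones of constant level: returns (level, size) per zone.
// [[Rcpp::export]]
List cpp_glszm(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::stack<int> st;
  for (int v = 0; v < n; ++v) {
    if (seen[v] || levels[v] == NA_INTEGER) continue;
    int lev = levels[v];
    int size = 0;
    st.push(v);
    seen[v] = 1;
    while (!st.empty()) {
      int u = st.top(); st.pop();
      ++size;
      int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int wx = ux + dx, wy = uy + dy, wz = uz + dz;
            if (!inb(wx, wy, wz, nx, ny, nz)) continue;
            int w = idx3(wx, wy, wz, nx, ny);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; st.push(w); }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  return List::create(_["level"] = wrap(zl), _["size"] = wrap(zs));
}

// Neighbouring gray-tone difference: per level, count of contributing voxels
// and the summed |level - mean neighbour level|. Voxels without any in-mask
// neighbour do not contribute.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dim, int n_levels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector ncount(n_levels), ssum(n_levels);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == NA_INTEGER) continue;
        double tot = 0.0; int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int wx = x + dx, wy = y + dy, wz = z + dz;
              if (!inb(wx, wy, wz, nx, ny, nz)) continue;
              int b = levels[idx3(wx, wy, wz, nx, ny)];
              if (b == NA_INTEGER) continue;
              tot += b; ++k;
            }
        if (k == 0) continue;
        ncount[a - 1] += 1.0;
        ssum[a - 1] += std::fabs(a - tot / k);
      }
  return List::create(_["n"] = ncount, _["s"] = ssum);
}

// Dependence counts: dependence of a voxel = 1 + number of in-mask
// 26-neighbours whose level differs by at most alpha. Ng x 27 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int n_levels,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(n_levels, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == NA_INTEGER) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int wx = x + dx, wy = y + dy, wz = z + dz;
              if (!inb(wx, wy, wz, nx, ny, nz)) continue;
              int b = levels[idx3(wx, wy, wz, nx, ny)];
              if (b == NA_INTEGER) continue;
              if (std::abs(a - b) <= alpha) ++dep;
            }
        M(a - 1, dep - 1) += 1.0;
      }
  return M;
}

// ---- Kendall tau-b (Knight's algorithm) --------------------------------

static long long merge_count(std::vector<double>& y, std::vector<double>& buf,
                             int lo, int hi) {
  if (hi - lo < 2) return 0;
  int mid = (lo + hi) / 2;
  long long sw = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[i] <= y[j]) buf[k++] = y[i++];
    else { sw += mid - i; buf[k++] = y[j++]; }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return sw;
}

static double tau_b(const double* xs, const double* ys, int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (xs[a] != xs[b]) return xs[a] < xs[b];
    return ys[a] < ys[b];
  });
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = ys[ord[i]];
  long long n0 = (long long)n * (n - 1) / 2;
  long long n1 = 0, n3 = 0;
  { // ties in x, and joint ties
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && xs[ord[j]] == xs[ord[i]]) ++j;
      long long t = j - i;
      n1 += t * (t - 1) / 2;
      int a = i;
      while (a < j) {
        int b = a;
        while (b < j && ys[ord[b]] == ys[ord[a]]) ++b;
        long long u = b - a;
        n3 += u * (u - 1) / 2;
        a = b;
      }
      i = j;
    }
  }
  std::vector<double> ycopy(y), buf(n);
  long long swaps = merge_count(ycopy, buf, 0, n);
  long long n2 = 0;
  { // ties in y (ycopy now sorted)
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && ycopy[j] == ycopy[i]) ++j;
      long long t = j - i;
      n2 += t * (t - 1) / 2;
      i = j;
    }
  }
  double den = std::sqrt((double)(n0 - n1)) * std::sqrt((double)(n0 - n2));
  if (den <= 0) return NA_REAL;
  double s = (double)(n0 - n1 - n2 + n3) - 2.0 * (double)swaps;
  return s / den;
}

// [[Rcpp::export]]
NumericMatrix cpp_kendall_matrix(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(p, p);
  for (int i = 0; i < p; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < p; ++j) {
      double t = tau_b(&x(0, i), &x(0, j), n);
      out(i, j) = t;
      out(j, i) = t;
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_kendall_tau(NumericVector x, NumericVector y) {
  return tau_b(x.begin(), y.begin(), x.size());
}
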