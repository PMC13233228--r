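#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Trilinear fetch at continuous 0-based voxel coordinate; out-of-grid corners
// contribute the fill value so regions leaving the field of view fade to fill.
static inline double fetch(const double* src, int nx, int ny, int nz,
                           int i, int j, int k, double fill) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return src[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

static inline double sample_linear(const double* src, int nx, int ny, int nz,
                                   double x, double y, double z, double fill) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double v = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        v += wx * wy * wz * fetch(src, nx, ny, nz, x0 + di, y0 + dj, z0 + dk, fill);
      }
    }
  }
  return v;
}

static inline double sample_nearest(const double* src, int nx, int ny, int nz,
                                    double x, double y, double z, double fill) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  return fetch(src, nx, ny, nz, i, j, k, fill);
}

// Pull-back resampling: for every voxel v (0-based) of the target grid,
//   x_world = t_v2w %*% v; x_world += disp[v] (if given); p_vox = w2v %*% x_world
// and the source volume is sampled at p_vox. `interp` 0 = linear, 1 = nearest.
// Attribute "oob" counts samples whose 8-corner support left the source grid.
// [[Rcpp::export]]
NumericVector c_resample(NumericVector src, IntegerVector sdim,
                         NumericMatrix w2v, IntegerVector tdim,
                         NumericMatrix t_v2w, Nullable<NumericMatrix> disp,
                         int interp, double fill) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const double* s = src.begin();
  NumericVector out((R_xlen_t)tx * ty * tz);
  const bool has_disp = disp.isNotNull();
  NumericMatrix d;
  if (has_disp) d = NumericMatrix(disp);
  double A[12], B[12];  // affines, row-major 3x4
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) {
      A[4 * r + c] = t_v2w(r, c);
      B[4 * r + c] = w2v(r, c);
    }
  R_xlen_t idx = 0, oob = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++idx) {
        double xw = A[0] * i + A[1] * j + A[2] * k + A[3];
        double yw = A[4] * i + A[5] * j + A[6] * k + A[7];
        double zw = A[8] * i + A[9] * j + A[10] * k + A[11];
        if (has_disp) {
          xw += d(idx, 0);
          yw += d(idx, 1);
          zw += d(idx, 2);
        }
        double px = B[0] * xw + B[1] * yw + B[2] * zw + B[3];
        double py = B[4] * xw + B[5] * yw + B[6] * zw + B[7];
        double pz = B[8] * xw + B[9] * yw + B[10] * zw + B[11];
        if (px < 0 || py < 0 || pz < 0 ||
            px > nx - 1 || py > ny - 1 || pz > nz - 1) ++oob;
        out[idx] = (interp == 1)
          ? sample_nearest(s, nx, ny, nz, px, py, pz, fill)
          : sample_linear(s, nx, ny, nz, px, py, pz, fill);
      }
  out.attr("oob") = (double)oob;
  return out;
}

// Largest 6-connected component of a logical mask (used for brain masking).
// [[Rcpp::export]]
LogicalVector c_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int next = 0, best_lab = 0;
  R_xlen_t best_size = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    R_xlen_t size = 0;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
    if (size > best_size) { best_size = size; best_lab = next; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (lab[s] == best_lab);
  out.attr("dim") = dim;
  return out;
}
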