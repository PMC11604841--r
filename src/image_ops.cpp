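// Image-domain helpers: trilinear sampling of 3D volumes at arbitrary
// (fractional, 1-based) voxel coordinates, and 6-connected seeded region
// growing with a running-mean acceptance rule.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double sample_tl(const double* v, int n1, int n2, int n3,
                               double x, double y, double z) {
  // 0-based coordinates; clamp to the valid box (replicate edges).
  if (x < 0) x = 0; if (x > n1 - 1) x = n1 - 1;
  if (y < 0) y = 0; if (y > n2 - 1) y = n2 - 1;
  if (z < 0) z = 0; if (z > n3 - 1) z = n3 - 1;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  int x1 = x0 < n1 - 1 ? x0 + 1 : x0;
  int y1 = y0 < n2 - 1 ? y0 + 1 : y0;
  int z1 = z0 < n3 - 1 ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t s2 = (size_t)n1, s3 = (size_t)n1 * n2;
  const double* p000 = v + x0 + y0 * s2 + z0 * s3;
  double c00 = p000[0] * (1 - fx) + v[x1 + y0 * s2 + z0 * s3] * fx;
  double c10 = v[x0 + y1 * s2 + z0 * s3] * (1 - fx) + v[x1 + y1 * s2 + z0 * s3] * fx;
  double c01 = v[x0 + y0 * s2 + z1 * s3] * (1 - fx) + v[x1 + y0 * s2 + z1 * s3] * fx;
  double c11 = v[x0 + y1 * s2 + z1 * s3] * (1 - fx) + v[x1 + y1 * s2 + z1 * s3] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample volume vol (dim n) at displaced positions: out(i) = vol(i + u(i)).
// ux, uy, uz are displacement volumes in voxels (may be length 1 => constant).
// [[Rcpp::export]]
NumericVector warp_trilinear(NumericVector vol, IntegerVector n,
                             NumericVector ux, NumericVector uy,
                             NumericVector uz) {
  int n1 = n[0], n2 = n[1], n3 = n[2];
  size_t nv = (size_t)n1 * n2 * n3;
  NumericVector out(nv);
  bool cx = ux.size() == 1, cy = uy.size() == 1, cz = uz.size() == 1;
  const double* v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++idx) {
        double dx = cx ? ux[0] : ux[idx];
        double dy = cy ? uy[0] : uy[idx];
        double dz = cz ? uz[0] : uz[idx];
        out[idx] = sample_tl(v, n1, n2, n3, i + dx, j + dy, k + dz);
      }
  return out;
}

// Sample volume at explicit 0-based coordinates (S x 3 matrix).
// [[Rcpp::export]]
NumericVector sample_points(NumericVector vol, IntegerVector n,
                            NumericMatrix pts) {
  int n1 = n[0], n2 = n[1], n3 = n[2];
  int S = pts.nrow();
  NumericVector out(S);
  const double* v = vol.begin();
  for (int s = 0; s < S; ++s)
    out[s] = sample_tl(v, n1, n2, n3, pts(s, 0), pts(s, 1), pts(s, 2));
  return out;
}

// 6-connected region growing.  Accept a voxel when
// |I - mean(region so far)| <= tol_abs.  Seeds are 0-based voxel indices
// into the flattened volume.
// [[Rcpp::export]]
LogicalVector region_grow6(NumericVector vol, IntegerVector n,
                           IntegerVector seeds, double tol_abs) {
  int n1 = n[0], n2 = n[1], n3 = n[2];
  size_t nv = (size_t)n1 * n2 * n3;
  std::vector<char> in(nv, 0);
  std::queue<size_t> q;
  double sum = 0.0;
  long cnt = 0;
  for (int s = 0; s < seeds.size(); ++s) {
    size_t id = (size_t)seeds[s];
    if (!in[id]) {
      in[id] = 1;
      sum += vol[id];
      ++cnt;
      q.push(id);
    }
  }
  size_t s2 = (size_t)n1, s3 = (size_t)n1 * n2;
  while (!q.empty()) {
    size_t id = q.front();
    q.pop();
    int i = id % n1, j = (id / s2) % n2, k = id / s3;
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      size_t nid = ii + jj * s2 + kk * s3;
      if (in[nid]) continue;
      double mu = sum / cnt;
      if (std::fabs(vol[nid] - mu) <= tol_abs) {
        in[nid] = 1;
        sum += vol[nid];
        ++cnt;
        q.push(nid);
      }
    }
  }
  LogicalVector out(nv);
  for (size_t i = 0; i < nv; ++i) out[i] = in[i] != 0;
  return out;
}
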