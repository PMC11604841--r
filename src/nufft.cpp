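// Gridding kernels for the non-uniform Fourier operator.
//
// Coordinates are in oversampled-grid frequency units: g = k_norm * n_os,
// with k_norm in cycles/sample of the reconstruction grid, i.e. [-0.5, 0.5].
// Periodic wrap-around in all three axes.  The Kaiser-Bessel kernel is
// passed in as a lookup table over radius [0, halfwidth]; lookups use
// linear interpolation so spread and interp are exact transposes of each
// other by construction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double tab_lookup(const double* tab, int m, double invstep,
                                double r) {
  double x = r * invstep;
  int i = (int)x;
  if (i >= m - 1) return 0.0;
  double f = x - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// Per-sample axis taps: integer grid indices within halfwidth of g.
struct AxisTaps {
  int idx[16];
  double w[16];
  int n;
};

static inline void axis_taps(double g, int nos, double hw, const double* tab,
                             int m, double invstep, AxisTaps& t) {
  int lo = (int)std::ceil(g - hw);
  int hi = (int)std::floor(g + hw);
  t.n = 0;
  for (int j = lo; j <= hi; ++j) {
    double r = std::fabs(j - g);
    double wv = tab_lookup(tab, m, invstep, r);
    if (wv <= 0.0) continue;
    int jj = j % nos;
    if (jj < 0) jj += nos;
    t.idx[t.n] = jj;
    t.w[t.n] = wv;
    ++t.n;
  }
}

// Spread non-uniform samples onto the oversampled grid (adjoint direction).
// coords: S x 3 (grid frequency units); vals: complex length S.
// [[Rcpp::export]]
ComplexVector nufft_spread3(NumericMatrix coords, ComplexVector vals,
                            IntegerVector nos, NumericVector ktab,
                            double halfwidth) {
  const int S = coords.nrow();
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const int m = ktab.size();
  const double invstep = (m - 1) / halfwidth;
  ComplexVector grid(n1 * (R_xlen_t)n2 * n3);
  std::vector<double> gre(n1 * (size_t)n2 * n3, 0.0),
      gim(n1 * (size_t)n2 * n3, 0.0);
  AxisTaps tx, ty, tz;
  const Rcomplex* vp = COMPLEX(vals);
  const double* c1 = &coords(0, 0);
  const double* c2 = &coords(0, 1);
  const double* c3 = &coords(0, 2);
  for (int s = 0; s < S; ++s) {
    axis_taps(c1[s], n1, halfwidth, ktab.begin(), m, invstep, tx);
    axis_taps(c2[s], n2, halfwidth, ktab.begin(), m, invstep, ty);
    axis_taps(c3[s], n3, halfwidth, ktab.begin(), m, invstep, tz);
    double vr = vp[s].r, vi = vp[s].i;
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * n2;
      double wz = tz.w[c];
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = (oz + ty.idx[b]) * n1;
        double wyz = wz * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          double w = wyz * tx.w[a];
          size_t o = oy + tx.idx[a];
          gre[o] += w * vr;
          gim[o] += w * vi;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < grid.size(); ++i) {
    grid[i].r = gre[i];
    grid[i].i = gim[i];
  }
  return grid;
}

// Interpolate the oversampled grid at non-uniform locations (forward).
// [[Rcpp::export]]
ComplexVector nufft_interp3(NumericMatrix coords, ComplexVector grid,
                            IntegerVector nos, NumericVector ktab,
                            double halfwidth) {
  const int S = coords.nrow();
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const int m = ktab.size();
  const double invstep = (m - 1) / halfwidth;
  ComplexVector out(S);
  AxisTaps tx, ty, tz;
  const Rcomplex* gp = COMPLEX(grid);
  Rcomplex* op = COMPLEX(out);
  const double* c1 = &coords(0, 0);
  const double* c2 = &coords(0, 1);
  const double* c3 = &coords(0, 2);
  for (int s = 0; s < S; ++s) {
    axis_taps(c1[s], n1, halfwidth, ktab.begin(), m, invstep, tx);
    axis_taps(c2[s], n2, halfwidth, ktab.begin(), m, invstep, ty);
    axis_taps(c3[s], n3, halfwidth, ktab.begin(), m, invstep, tz);
    double ar = 0.0, ai = 0.0;
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * n2;
      double wz = tz.w[c];
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = (oz + ty.idx[b]) * n1;
        double wyz = wz * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          double w = wyz * tx.w[a];
          const Rcomplex& gv = gp[oy + tx.idx[a]];
          ar += w * gv.r;
          ai += w * gv.i;
        }
      }
    }
    op[s].r = ar;
    op[s].i = ai;
  }
  return out;
}

// Multi-coil variants: taps are computed once per sample and applied to
// all coil grids, which is what the SENSE normal operator needs.

// coords: S x 3; grids: concatenated C grids (each n1*n2*n3).
// Returns S x C complex matrix.
// [[Rcpp::export]]
ComplexMatrix nufft_interp3_multi(NumericMatrix coords, ComplexVector grids,
                                  IntegerVector nos, int ncoil,
                                  NumericVector ktab, double halfwidth) {
  const int S = coords.nrow();
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const size_t ng = (size_t)n1 * n2 * n3;
  const int m = ktab.size();
  const double invstep = (m - 1) / halfwidth;
  ComplexMatrix out(S, ncoil);
  AxisTaps tx, ty, tz;
  const Rcomplex* gp = COMPLEX(grids);
  Rcomplex* op = COMPLEX(out);
  const double* c1 = &coords(0, 0);
  const double* c2 = &coords(0, 1);
  const double* c3 = &coords(0, 2);
  std::vector<double> ar(ncoil), ai(ncoil);
  for (int s = 0; s < S; ++s) {
    axis_taps(c1[s], n1, halfwidth, ktab.begin(), m, invstep, tx);
    axis_taps(c2[s], n2, halfwidth, ktab.begin(), m, invstep, ty);
    axis_taps(c3[s], n3, halfwidth, ktab.begin(), m, invstep, tz);
    std::fill(ar.begin(), ar.end(), 0.0);
    std::fill(ai.begin(), ai.end(), 0.0);
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * n2;
      double wz = tz.w[c];
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = (oz + ty.idx[b]) * n1;
        double wyz = wz * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          double w = wyz * tx.w[a];
          size_t o = oy + tx.idx[a];
          for (int q = 0; q < ncoil; ++q) {
            const Rcomplex& gv = gp[o + q * ng];
            ar[q] += w * gv.r;
            ai[q] += w * gv.i;
          }
        }
      }
    }
    for (int q = 0; q < ncoil; ++q) {
      op[s + (size_t)q * S].r = ar[q];
      op[s + (size_t)q * S].i = ai[q];
    }
  }
  return out;
}

// vals: S x C; returns concatenated C grids.
// [[Rcpp::export]]
ComplexVector nufft_spread3_multi(NumericMatrix coords, ComplexMatrix vals,
                                  IntegerVector nos, NumericVector ktab,
                                  double halfwidth) {
  const int S = coords.nrow();
  const int ncoil = vals.ncol();
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const size_t ng = (size_t)n1 * n2 * n3;
  const int m = ktab.size();
  const double invstep = (m - 1) / halfwidth;
  std::vector<double> gre(ng * ncoil, 0.0), gim(ng * ncoil, 0.0);
  AxisTaps tx, ty, tz;
  const Rcomplex* vp = COMPLEX(vals);
  const double* c1 = &coords(0, 0);
  const double* c2 = &coords(0, 1);
  const double* c3 = &coords(0, 2);
  for (int s = 0; s < S; ++s) {
    axis_taps(c1[s], n1, halfwidth, ktab.begin(), m, invstep, tx);
    axis_taps(c2[s], n2, halfwidth, ktab.begin(), m, invstep, ty);
    axis_taps(c3[s], n3, halfwidth, ktab.begin(), m, invstep, tz);
    for (int c = 0; c < tz.n; ++c) {
      size_t oz = (size_t)tz.idx[c] * n2;
      double wz = tz.w[c];
      for (int b = 0; b < ty.n; ++b) {
        size_t oy = (oz + ty.idx[b]) * n1;
        double wyz = wz * ty.w[b];
        for (int a = 0; a < tx.n; ++a) {
          double w = wyz * tx.w[a];
          size_t o = oy + tx.idx[a];
          for (int q = 0; q < ncoil; ++q) {
            const Rcomplex& vv = vp[s + (size_t)q * S];
            gre[o + q * ng] += w * vv.r;
            gim[o + q * ng] += w * vv.i;
          }
        }
      }
    }
  }
  ComplexVector grid(ng * ncoil);
  Rcomplex* gpo = COMPLEX(grid);
  for (size_t i = 0; i < ng * ncoil; ++i) {
    gpo[i].r = gre[i];
    gpo[i].i = gim[i];
  }
  return grid;
}
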