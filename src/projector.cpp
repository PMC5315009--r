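// CPU projection kernels for 2-D parallel-beam geometry.
//
// Conventions (shared with the R layer):
//   image:  ny x nx R matrix, column-major; pixel (iy, ix) 0-based has its
//           centre at x = (ix - (nx-1)/2) * px, y = (iy - (ny-1)/2) * px.
//   sino:   n_ang x n_det R matrix; detector bin j 0-based is centred at
//           t_j = (j - (n_det-1)/2 - c_off) * dw.
//   ray at angle th, offset t: { x cos(th) + y sin(th) = t }.
//
// Backprojection is the literal transpose of forward projection: both
// directions enumerate identical (ray, pixel, weight) triples, so the
// adjoint identity is structural.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// CDF of the trapezoidal footprint of a px-sized square projected onto the
// detector axis at angle th: A = px|cos th|, B = px|sin th|; support
// half-width r2 = (A+B)/2, plateau half-width r1 = |A-B|/2, height px^2/hi.
struct Trapezoid {
  double r1, r2, hi, lo, area;
  void set(double c, double s, double px) {
    double A = px * std::fabs(c), B = px * std::fabs(s);
    hi = std::max(A, B);
    lo = std::min(A, B);
    r1 = 0.5 * (hi - lo);
    r2 = 0.5 * (hi + lo);
    area = px * px;
  }
  double cdf(double sgn) const {
    if (sgn <= -r2) return 0.0;
    if (sgn >= r2) return area;
    double H = area / hi;  // plateau height
    if (sgn < -r1) {
      double d = sgn + r2;
      return 0.5 * H * d * d / lo;
    }
    if (sgn <= r1) return 0.5 * H * lo + H * (sgn + r1);
    double d = r2 - sgn;
    return area - 0.5 * H * d * d / lo;
  }
};

// Enumerate strip-kernel weights; cb(ray_index, pixel_index, w).
template <typename F>
void strip_enumerate(int n_ang, int n_det, double dw, double c_off,
                     int nx, int ny, double px,
                     const NumericVector& cosv, const NumericVector& sinv,
                     F cb) {
  const double t0 = -((n_det - 1) / 2.0 + c_off) * dw;  // t of bin 0
  for (int a = 0; a < n_ang; ++a) {
    const double c = cosv[a], s = sinv[a];
    Trapezoid tz;
    tz.set(c, s, px);
    const bool box = tz.lo < 1e-300;  // axis-aligned: box footprint
    for (int ix = 0; ix < nx; ++ix) {
      const double x = (ix - (nx - 1) / 2.0) * px;
      for (int iy = 0; iy < ny; ++iy) {
        const double y = (iy - (ny - 1) / 2.0) * px;
        const double sc = x * c + y * s;  // footprint centre on detector
        int j0 = (int)std::floor((sc - tz.r2 - t0) / dw - 0.5);
        int j1 = (int)std::ceil((sc + tz.r2 - t0) / dw + 0.5);
        j0 = std::max(j0, 0);
        j1 = std::min(j1, n_det - 1);
        for (int j = j0; j <= j1; ++j) {
          const double tj = t0 + j * dw;
          double wgt;
          if (box) {
            // degenerate trapezoid: uniform box of width hi, height px^2/hi
            double a1 = std::max(tj - 0.5 * dw, sc - tz.r2);
            double b1 = std::min(tj + 0.5 * dw, sc + tz.r2);
            wgt = b1 > a1 ? (b1 - a1) * (tz.area / tz.hi) : 0.0;
          } else {
            wgt = tz.cdf(tj + 0.5 * dw - sc) - tz.cdf(tj - 0.5 * dw - sc);
          }
          if (wgt > 0.0) cb(a * n_det + j, ix * ny + iy, wgt / dw);
        }
      }
    }
  }
}

// Enumerate Joseph (line) kernel weights: step along the axis most aligned
// with the ray direction (-sin th, cos th), linear interpolation transverse,
// scaled by the step length along the ray.
template <typename F>
void joseph_enumerate(int n_ang, int n_det, double dw, double c_off,
                      int nx, int ny, double px,
                      const NumericVector& cosv, const NumericVector& sinv,
                      F cb) {
  const double t0 = -((n_det - 1) / 2.0 + c_off) * dw;
  const double hx = (nx - 1) / 2.0, hy = (ny - 1) / 2.0;
  for (int a = 0; a < n_ang; ++a) {
    const double c = cosv[a], s = sinv[a];
    for (int j = 0; j < n_det; ++j) {
      const double t = t0 + j * dw;
      const int ray = a * n_det + j;
      if (std::fabs(c) >= std::fabs(s)) {
        // drive along y (rows): x = (t - y sin) / cos
        const double scale = px / std::fabs(c);
        for (int iy = 0; iy < ny; ++iy) {
          const double y = (iy - hy) * px;
          const double x = (t - y * s) / c;
          const double u = x / px + hx;  // fractional column
          const int ix0 = (int)std::floor(u);
          const double f = u - ix0;
          if (ix0 >= 0 && ix0 < nx && f < 1.0)
            cb(ray, ix0 * ny + iy, scale * (1.0 - f));
          if (ix0 + 1 >= 0 && ix0 + 1 < nx && f > 0.0)
            cb(ray, (ix0 + 1) * ny + iy, scale * f);
        }
      } else {
        // drive along x (columns): y = (t - x cos) / sin
        const double scale = px / std::fabs(s);
        for (int ix = 0; ix < nx; ++ix) {
          const double x = (ix - hx) * px;
          const double y = (t - x * c) / s;
          const double v = y / px + hy;  // fractional row
          const int iy0 = (int)std::floor(v);
          const double f = v - iy0;
          if (iy0 >= 0 && iy0 < ny && f < 1.0)
            cb(ray, ix * ny + iy0, scale * (1.0 - f));
          if (iy0 + 1 >= 0 && iy0 + 1 < ny && f > 0.0)
            cb(ray, ix * ny + iy0 + 1, scale * f);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector proj_apply_cpp(NumericVector x, bool forward, bool strip,
                             int n_ang, int n_det, double dw, double c_off,
                             int nx, int ny, double px,
                             NumericVector cosv, NumericVector sinv) {
  NumericVector out(forward ? n_ang * n_det : nx * ny);
  const double* xp = x.begin();
  double* op = out.begin();
  auto fwd = [&](int ray, int pix, double w) { op[ray] += w * xp[pix]; };
  auto bwd = [&](int ray, int pix, double w) { op[pix] += w * xp[ray]; };
  if (strip) {
    if (forward)
      strip_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, fwd);
    else
      strip_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, bwd);
  } else {
    if (forward)
      joseph_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, fwd);
    else
      joseph_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, bwd);
  }
  return out;
}

// [[Rcpp::export]]
List proj_triplets_cpp(bool strip, int n_ang, int n_det, double dw,
                       double c_off, int nx, int ny, double px,
                       NumericVector cosv, NumericVector sinv) {
  std::vector<int> ri, ci;
  std::vector<double> wv;
  auto cb = [&](int ray, int pix, double w) {
    ri.push_back(ray + 1);  // 1-based for Matrix::sparseMatrix
    ci.push_back(pix + 1);
    wv.push_back(w);
  };
  if (strip)
    strip_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, cb);
  else
    joseph_enumerate(n_ang, n_det, dw, c_off, nx, ny, px, cosv, sinv, cb);
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["w"] = wrap(wv));
}

// Kaiser-Bessel gridding: accumulate weighted complex samples at fractional
// grid coordinates (gu, gv) onto an M x M complex grid (column-major,
// coordinates measured from the grid centre at index M/2, 0-based).
// [[Rcpp::export]]
ComplexVector kb_grid_cpp(NumericVector gu, NumericVector gv,
                          NumericVector wre, NumericVector wim,
                          int M, double width, double beta) {
  ComplexVector grid(M * M);  // zero-initialised
  const double half = width / 2.0;
  const double i0b = R::bessel_i(beta, 0.0, 1.0);
  const int ctr = M / 2;
  // tabulate the radial profile once; linear interpolation thereafter
  const int nlut = 4096;
  std::vector<double> lut(nlut + 1);
  for (int i = 0; i <= nlut; ++i) {
    double r = half * i / nlut;
    double q = 1.0 - (r / half) * (r / half);
    lut[i] = q <= 0.0 ? 0.0
                      : R::bessel_i(beta * std::sqrt(q), 0.0, 1.0) / i0b;
  }
  auto kb = [&](double r) -> double {
    double a = std::fabs(r) / half * nlut;
    if (a >= nlut) return 0.0;
    int i = (int)a;
    double f = a - i;
    return lut[i] * (1.0 - f) + lut[i + 1] * f;
  };
  const int n = gu.size();
  for (int k = 0; k < n; ++k) {
    const double u = gu[k] + ctr, v = gv[k] + ctr;
    const int u0 = (int)std::ceil(u - half), u1 = (int)std::floor(u + half);
    const int v0 = (int)std::ceil(v - half), v1 = (int)std::floor(v + half);
    for (int iu = std::max(u0, 0); iu <= std::min(u1, M - 1); ++iu) {
      const double ku = kb(iu - u);
      if (ku == 0.0) continue;
      for (int iv = std::max(v0, 0); iv <= std::min(v1, M - 1); ++iv) {
        const double w = ku * kb(iv - v);
        if (w == 0.0) continue;
        Rcomplex& g = grid[iu * M + iv];
        g.r += w * wre[k];
        g.i += w * wim[k];
      }
    }
  }
  return grid;
}

// Plain 2-D median filter with edge replication (used for zinger removal).
// [[Rcpp::export]]
NumericMatrix median_filter_2d(NumericMatrix x, int size) {
  const int nr = x.nrow(), nc = x.ncol(), h = size / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(size * size);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        const int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          const int ii = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(x(ii, jj));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(i, j) = buf[buf.size() / 2];
    }
  }
  return out;
}
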