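#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a matrix at fractional (col = x, row = y), 1-based
// pixel-center coordinates. Outside the matrix the value is 0.
static inline double bilinear(const NumericMatrix& m, double x, double y) {
  const int nr = m.nrow(), nc = m.ncol();
  if (x < 0.5 || y < 0.5 || x > nc + 0.5 || y > nr + 0.5) return 0.0;
  int j0 = (int)std::floor(x), i0 = (int)std::floor(y);
  double fx = x - j0, fy = y - i0;
  // clamp so that border pixels extrapolate flat within the half-pixel rim
  int j1 = j0 + 1, i1 = i0 + 1;
  j0 = std::min(std::max(j0, 1), nc); j1 = std::min(std::max(j1, 1), nc);
  i0 = std::min(std::max(i0, 1), nr); i1 = std::min(std::max(i1, 1), nr);
  double v00 = m(i0 - 1, j0 - 1), v01 = m(i0 - 1, j1 - 1);
  double v10 = m(i1 - 1, j0 - 1), v11 = m(i1 - 1, j1 - 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Overlap between a fixed seed mask and a model mask mapped into the seed
// grid by a similarity transform.  The transform sends model pixel p (col,
// row, 1-based centers) to  s * R(phi) * F * (p - c) + t  where c = (cx,cy)
// is the model anchor (its centroid), t = (tx,ty) is where the anchor lands
// in the seed grid and F mirrors the model about its vertical axis when
// flip is true.  Pixels are accumulated over the union of the seed grid and
// the transformed model bounding box, so foreground falling outside the
// seed image still counts toward the union.
// Returns c(S_hard, T_hard, S_soft, T_soft): hard counts threshold the
// bilinear resampled model at 0.5; soft sums use min/max of the fractional
// coverage, giving a continuous objective for the optimizer.
// [[Rcpp::export]]
NumericVector overlap_counts_cpp(const LogicalMatrix& seed,
                                 const NumericMatrix& model,
                                 double cx, double cy,
                                 double tx, double ty,
                                 double s, double phi, bool flip) {
  const int nrs = seed.nrow(), ncs = seed.ncol();
  const double ca = std::cos(phi), sa = std::sin(phi);
  // forward-transform model corners to bound the loop
  double rmin = 1, rmax = nrs, cmin = 1, cmax = ncs;
  double corners[4][2] = {{0.5, 0.5},
                          {model.ncol() + 0.5, 0.5},
                          {0.5, model.nrow() + 0.5},
                          {model.ncol() + 0.5, model.nrow() + 0.5}};
  for (int k = 0; k < 4; ++k) {
    double mx = corners[k][0] - cx, my = corners[k][1] - cy;
    if (flip) mx = -mx;
    double u = s * (ca * mx - sa * my) + tx;
    double v = s * (sa * mx + ca * my) + ty;
    cmin = std::min(cmin, std::floor(u)); cmax = std::max(cmax, std::ceil(u));
    rmin = std::min(rmin, std::floor(v)); rmax = std::max(rmax, std::ceil(v));
  }
  const double inv_s = 1.0 / s;
  double Ss = 0.0, Ts = 0.0;
  long Sh = 0, Th = 0;
  for (int v = (int)rmin; v <= (int)rmax; ++v) {
    const bool vin = (v >= 1 && v <= nrs);
    for (int u = (int)cmin; u <= (int)cmax; ++u) {
      double dx = (u - tx) * inv_s, dy = (v - ty) * inv_s;
      double qx =  ca * dx + sa * dy;
      double qy = -sa * dx + ca * dy;
      if (flip) qx = -qx;
      double w = bilinear(model, cx + qx, cy + qy);
      double sd = (vin && u >= 1 && u <= ncs && seed(v - 1, u - 1)) ? 1.0 : 0.0;
      if (w <= 0.0 && sd <= 0.0) continue;
      bool wh = (w >= 0.5);
      if (wh && sd > 0.5) ++Sh;
      if (wh || sd > 0.5) ++Th;
      Ss += std::min(w, sd);
      Ts += std::max(w, sd);
    }
  }
  return NumericVector::create((double)Sh, (double)Th, Ss, Ts);
}

// Resample a model mask into an output grid under the same similarity
// transform convention as overlap_counts_cpp (bilinear, threshold 0.5).
// [[Rcpp::export]]
LogicalMatrix warp_mask_cpp(const NumericMatrix& model,
                            int out_nrow, int out_ncol,
                            double cx, double cy,
                            double tx, double ty,
                            double s, double phi, bool flip) {
  LogicalMatrix out(out_nrow, out_ncol);
  const double ca = std::cos(phi), sa = std::sin(phi), inv_s = 1.0 / s;
  for (int v = 1; v <= out_nrow; ++v) {
    for (int u = 1; u <= out_ncol; ++u) {
      double dx = (u - tx) * inv_s, dy = (v - ty) * inv_s;
      double qx =  ca * dx + sa * dy;
      double qy = -sa * dx + ca * dy;
      if (flip) qx = -qx;
      out(v - 1, u - 1) = bilinear(model, cx + qx, cy + qy) >= 0.5;
    }
  }
  return out;
}

// Even-odd scanline rasterization of a closed polygon given in pixel
// coordinates (x = col, y = row, 1-based centers).  A pixel is foreground
// iff its center lies inside the polygon.
// [[Rcpp::export]]
LogicalMatrix polygon_mask_cpp(const NumericVector& xs, const NumericVector& ys,
                               int nrow, int ncol) {
  const int n = xs.size();
  LogicalMatrix out(nrow, ncol);
  std::vector<double> xc;
  for (int r = 1; r <= nrow; ++r) {
    xc.clear();
    const double y = (double)r;
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y1 = ys[i], y2 = ys[j];
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        double t = (y - y1) / (y2 - y1);
        xc.push_back(xs[i] + t * (xs[j] - xs[i]));
      }
    }
    if (xc.empty()) continue;
    std::sort(xc.begin(), xc.end());
    for (size_t k = 0; k + 1 < xc.size(); k += 2) {
      int c0 = (int)std::ceil(xc[k]);
      int c1 = (int)std::floor(xc[k + 1]);
      if (std::floor(xc[k]) == xc[k]) c0 = (int)xc[k] + 1;  // center on edge -> open
      for (int c = std::max(c0, 1); c <= std::min(c1, ncol); ++c)
        out(r - 1, c - 1) = true;
    }
  }
  return out;
}
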