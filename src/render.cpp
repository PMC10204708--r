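#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Render root systems as chains of tapered capsules with anti-aliasing and a
// radial front-light shading profile (rounded appearance). Roots are painted
// in list order, later roots occluding earlier ones.
//
// roots: list; each element a list with
//   x, y : polyline coordinates (pixels, 1-based, x = column, y = row)
//   r    : per-vertex radius (pixels, >= 0)
//   col  : RGB base colour (0..255, length 3)
//   shade_axis, shade_edge : brightness multipliers at axis / edge
// bg: background RGB (0..255). Returns H x W x 3 array (0..255 doubles).
// [[Rcpp::export(name = ".cpp_render_scene")]]
NumericVector cpp_render_scene(int H, int W, NumericVector bg, List roots) {
  NumericVector out(Dimension(H, W, 3));
  for (int ch = 0; ch < 3; ++ch)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out[(size_t)ch * H * W + (size_t)j * H + i] = bg[ch];

  std::vector<double> alpha((size_t)H * W), depth((size_t)H * W),
      radius((size_t)H * W);

  for (int rI = 0; rI < roots.size(); ++rI) {
    List rt = roots[rI];
    NumericVector x = rt["x"], y = rt["y"], r = rt["r"], col = rt["col"];
    double shade_axis = as<double>(rt["shade_axis"]);
    double shade_edge = as<double>(rt["shade_edge"]);
    int n = x.size();
    if (n < 2) continue;
    // bounding box of this root
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300,
           rmax = 0.0;
    for (int k = 0; k < n; ++k) {
      xmin = std::min(xmin, x[k]); xmax = std::max(xmax, x[k]);
      ymin = std::min(ymin, y[k]); ymax = std::max(ymax, y[k]);
      rmax = std::max(rmax, r[k]);
    }
    int j0 = std::max(0, (int)std::floor(xmin - rmax - 2) - 1);
    int j1 = std::min(W - 1, (int)std::ceil(xmax + rmax + 2));
    int i0 = std::max(0, (int)std::floor(ymin - rmax - 2) - 1);
    int i1 = std::min(H - 1, (int)std::ceil(ymax + rmax + 2));
    if (j0 > j1 || i0 > i1) continue;
    int bw = j1 - j0 + 1, bh = i1 - i0 + 1;
    size_t bn = (size_t)bw * bh;
    std::fill(alpha.begin(), alpha.begin() + bn, 0.0);
    std::fill(depth.begin(), depth.begin() + bn, -1e300);
    std::fill(radius.begin(), radius.begin() + bn, 1.0);

    for (int k = 0; k < n - 1; ++k) {
      double ax = x[k] - 1.0, ay = y[k] - 1.0;       // 0-based
      double bx = x[k + 1] - 1.0, by = y[k + 1] - 1.0;
      double ra = r[k], rb = r[k + 1];
      double rm = std::max(ra, rb);
      int sj0 = std::max(j0, (int)std::floor(std::min(ax, bx) - rm - 1));
      int sj1 = std::min(j1, (int)std::ceil(std::max(ax, bx) + rm + 1));
      int si0 = std::max(i0, (int)std::floor(std::min(ay, by) - rm - 1));
      int si1 = std::min(i1, (int)std::ceil(std::max(ay, by) + rm + 1));
      double vx = bx - ax, vy = by - ay;
      double vv = vx * vx + vy * vy;
      for (int j = sj0; j <= sj1; ++j) {
        for (int i = si0; i <= si1; ++i) {
          double px = j - ax, py = i - ay;
          double t = vv > 0 ? (px * vx + py * vy) / vv : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = px - t * vx, dy = py - t * vy;
          double d = std::sqrt(dx * dx + dy * dy);
          double rr = ra + t * (rb - ra);
          double a = rr - d + 0.5;           // 1-px anti-alias ramp
          if (a <= 0) continue;
          if (a > 1) a = 1;
          size_t bidx = (size_t)(j - j0) * bh + (i - i0);
          double dep = rr - d;               // most interior segment wins
          if (a > alpha[bidx]) alpha[bidx] = a;
          if (dep > depth[bidx]) {
            depth[bidx] = dep;
            radius[bidx] = std::max(rr, 1e-6);
          }
        }
      }
    }

    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        size_t bidx = (size_t)(j - j0) * bh + (i - i0);
        double a = alpha[bidx];
        if (a <= 0) continue;
        double rr = radius[bidx];
        double d = rr - depth[bidx];
        if (d < 0) d = 0;
        double rel = d / rr;
        if (rel > 1) rel = 1;
        double f = shade_edge +
                   (shade_axis - shade_edge) * std::sqrt(1.0 - rel * rel);
        for (int ch = 0; ch < 3; ++ch) {
          size_t oidx = (size_t)ch * H * W + (size_t)j * H + i;
          out[oidx] = a * (col[ch] * f) + (1.0 - a) * out[oidx];
        }
      }
    }
  }
  return out;
}
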