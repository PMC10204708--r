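#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Per-pixel ridge candidate info
struct Cand {
  double resp;      // |second directional derivative| (eigenvalue magnitude)
  double subr, subc; // sub-pixel position
  double nx, ny;    // unit normal (nx along columns/x, ny along rows/y)
  bool valid;
  bool seed;
  bool visited;
};

// Extract bright-line ridge candidates and link them into lines with
// hysteresis: points with resp >= u seed lines, points with resp >= l extend
// them along the local line direction.
// excl: integer matrix, nonzero = pixel excluded from candidacy.
// [[Rcpp::export(name = ".cpp_detect_ridges")]]
List cpp_detect_ridges(NumericMatrix rx, NumericMatrix ry, NumericMatrix rxx,
                       NumericMatrix rxy, NumericMatrix ryy,
                       double u, double l, IntegerMatrix excl) {
  const int H = rx.nrow(), W = rx.ncol();
  const bool has_excl = excl.nrow() == H && excl.ncol() == W;
  std::vector<Cand> cand((size_t)H * W);
  std::vector<int> seeds;
  seeds.reserve(1024);

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t idx = (size_t)j * H + i;
      Cand& c = cand[idx];
      c.valid = false; c.visited = false; c.seed = false;
      if (has_excl && excl(i, j) != 0) continue;
      const double a = rxx(i, j), b = rxy(i, j), d = ryy(i, j);
      const double m = 0.5 * (a + d);
      const double s = std::sqrt(0.25 * (a - d) * (a - d) + b * b);
      const double lam = m - s;             // most negative eigenvalue
      if (lam >= 0.0) continue;             // not a bright line
      const double resp = -lam;
      if (resp < l) continue;
      // the other eigenvalue (curvature along the line) must be small: a
      // radially decaying blob or strongly curved edge produces tangential
      // responses with a large positive cross curvature that are not lines
      if (m + s > 0.5 * resp) continue;
      // eigenvector for lam: (a - lam) vx + b vy = 0 ; pick stable form
      double nx, ny;
      if (std::fabs(b) > 1e-12) {
        nx = b; ny = lam - a;
      } else if (a <= d) {                  // eigenvector along x
        nx = 1.0; ny = 0.0;
      } else {
        nx = 0.0; ny = 1.0;
      }
      double nn = std::sqrt(nx * nx + ny * ny);
      nx /= nn; ny /= nn;
      // sub-pixel: first directional derivative along n vanishes at t*n
      const double denom = a * nx * nx + 2.0 * b * nx * ny + d * ny * ny;
      if (std::fabs(denom) < 1e-12) continue;
      const double t = -(rx(i, j) * nx + ry(i, j) * ny) / denom;
      const double px = t * nx, py = t * ny;
      // 0.6 rather than 0.5: on flat-topped profiles whose true center lies
      // on a pixel boundary the Taylor estimate overshoots slightly and a
      // strict 0.5 test loses the two center-adjacent pixels
      if (std::fabs(px) > 0.6 || std::fabs(py) > 0.6) continue;
      c.valid = true;
      c.resp = resp;
      c.subc = j + px;  // 0-based here; converted on output
      c.subr = i + py;
      c.nx = nx; c.ny = ny;
      // 0.9 sampling slack: the response peak of an even-width structure
      // falls between pixels and its pixel samples sit a few percent below
      // the analytic center response u
      if (resp >= 0.9 * u) { c.seed = true; seeds.push_back((int)idx); }
    }
  }

  std::stable_sort(seeds.begin(), seeds.end(), [&](int p, int q) {
    return cand[p].resp > cand[q].resp;
  });

  // trace from pixel idx0 in tangent direction sign; returns pixel indices
  auto trace = [&](int idx0, int sgn) {
    std::vector<int> out;
    int i = idx0 % H, j = idx0 / H;
    const Cand& c0 = cand[(size_t)idx0];
    double dx = -c0.ny * sgn, dy = c0.nx * sgn;   // tangent
    while (true) {
      // 3 neighbours closest to direction (dx,dy)
      int best = -1;
      double best_score = 1e300;
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          if (ox == 0 && oy == 0) continue;
          double on = std::sqrt((double)(ox * ox + oy * oy));
          double dot = (ox * dx + oy * dy) / on;
          if (dot < 0.7) continue;          // within ~45 deg of direction
          int ni = i + oy, nj = j + ox;
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          size_t nidx = (size_t)nj * H + ni;
          const Cand& nc = cand[nidx];
          if (!nc.valid || nc.visited) continue;
          const Cand& cc = cand[(size_t)j * H + i];
          double dr = nc.subr - cc.subr, dc = nc.subc - cc.subc;
          double dist = std::sqrt(dr * dr + dc * dc);
          // normal angle difference, fold (normal sign is ambiguous)
          double dotn = std::fabs(nc.nx * cc.nx + nc.ny * cc.ny);
          if (dotn > 1.0) dotn = 1.0;
          double dang = std::acos(dotn);
          double score = dist + 2.0 * dang;
          if (score < best_score) { best_score = score; best = (int)nidx; }
        }
      }
      if (best < 0) break;
      Cand& nc = cand[(size_t)best];
      nc.visited = true;
      out.push_back(best);
      // update direction, keep orientation continuity
      double ndx = -nc.ny, ndy = nc.nx;
      if (ndx * dx + ndy * dy < 0) { ndx = -ndx; ndy = -ndy; }
      dx = ndx; dy = ndy;
      i = best % H; j = best / H;
    }
    return out;
  };

  List lines;
  for (int sidx : seeds) {
    Cand& c = cand[(size_t)sidx];
    if (c.visited) continue;
    c.visited = true;
    std::vector<int> fwd = trace(sidx, +1);
    std::vector<int> bwd = trace(sidx, -1);
    std::vector<int> all;
    all.reserve(bwd.size() + 1 + fwd.size());
    for (auto it = bwd.rbegin(); it != bwd.rend(); ++it) all.push_back(*it);
    all.push_back(sidx);
    for (int v : fwd) all.push_back(v);
    const int n = (int)all.size();
    NumericMatrix m(n, 7);
    for (int k = 0; k < n; ++k) {
      const Cand& p = cand[(size_t)all[k]];
      m(k, 0) = all[k] % H + 1;       // row, 1-based
      m(k, 1) = all[k] / H + 1;       // col, 1-based
      m(k, 2) = p.subr + 1.0;
      m(k, 3) = p.subc + 1.0;
      m(k, 4) = p.nx;
      m(k, 5) = p.ny;
      m(k, 6) = p.resp;
    }
    colnames(m) = CharacterVector::create("row", "col", "subr", "subc",
                                          "nx", "ny", "response");
    lines.push_back(m);
  }
  return lines;
}

static inline double bilin(const NumericMatrix& m, double r, double c,
                           bool& outside) {
  // r, c are 0-based fractional coordinates
  int H = m.nrow(), W = m.ncol();
  if (r < 0 || c < 0 || r > H - 1 || c > W - 1) { outside = true; return 0.0; }
  int i0 = (int)std::floor(r), j0 = (int)std::floor(c);
  if (i0 >= H - 1) i0 = H - 2;
  if (j0 >= W - 1) j0 = W - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  double fr = r - i0, fc = c - j0;
  return (1 - fr) * (1 - fc) * m(i0, j0) + (1 - fr) * fc * m(i0, j0 + 1) +
         fr * (1 - fc) * m(i0 + 1, j0) + fr * fc * m(i0 + 1, j0 + 1);
}

// |gradient| profile along direction (dx,dy) from subpixel point (r0,c0)
// (0-based), sampled every `step` px up to max_dist; returns index of the
// last valid sample (samples beyond the image are cut off).
static int grad_profile(const NumericMatrix& rx, const NumericMatrix& ry,
                        double r0, double c0, double dx, double dy,
                        double max_dist, double step, std::vector<double>& g) {
  int K = (int)std::floor(max_dist / step);
  g.assign(K + 1, 0.0);
  int last = K;
  for (int k = 0; k <= K; ++k) {
    double s = k * step;
    bool outside = false;
    double gx = bilin(rx, r0 + s * dy, c0 + s * dx, outside);
    double gy = bilin(ry, r0 + s * dy, c0 + s * dx, outside);
    if (outside) { last = k - 1; break; }
    g[k] = std::sqrt(gx * gx + gy * gy);
  }
  return last;
}

// first local maximum of g above thresh, parabolically refined; -1 if none
static double first_peak(const std::vector<double>& g, int last,
                         double thresh, double step, double& strength) {
  for (int k = 1; k < last; ++k) {
    if (g[k] >= g[k - 1] && g[k] >= g[k + 1] && g[k] >= thresh) {
      double denom = g[k - 1] - 2.0 * g[k] + g[k + 1];
      double off = 0.0;
      if (std::fabs(denom) > 1e-12) {
        off = 0.5 * (g[k - 1] - g[k + 1]) / denom;
        if (off > 0.5) off = 0.5;
        if (off < -0.5) off = -0.5;
      }
      strength = g[k];
      return (k + off) * step;
    }
  }
  strength = 0.0;
  return -1.0;
}

// Edge distances on both sides of every line point: the first local maximum
// of the absolute gradient along +-normal. An admissible edge must carry at
// least half of the strongest gradient on its own side and a fifth of the
// strongest gradient on either side: weak shading gradients inside rounded
// root profiles otherwise masquerade as edges (genuinely asymmetric
// contrasts remain well above these fractions).
// line: matrix from .cpp_detect_ridges (1-based coords). Returns n x 2 matrix
// (left = +normal, right = -normal), NA when missing.
// [[Rcpp::export(name = ".cpp_line_edges")]]
NumericMatrix cpp_line_edges(NumericMatrix line, NumericMatrix rx,
                             NumericMatrix ry, NumericMatrix r0,
                             double max_dist, double min_grad, double step) {
  int n = line.nrow();
  NumericMatrix out(n, 8);
  std::vector<double> gl, gr;
  for (int k = 0; k < n; ++k) {
    double r0_ = line(k, 2) - 1.0, c0_ = line(k, 3) - 1.0;
    double nx = line(k, 4), ny = line(k, 5);
    int ll = grad_profile(rx, ry, r0_, c0_, nx, ny, max_dist, step, gl);
    int lr = grad_profile(rx, ry, r0_, c0_, -nx, -ny, max_dist, step, gr);
    double maxl = 0.0, maxr = 0.0;
    for (int i = 0; i <= ll; ++i) maxl = std::max(maxl, gl[i]);
    for (int i = 0; i <= lr; ++i) maxr = std::max(maxr, gr[i]);
    double gmax = std::max(maxl, maxr);
    double tl = std::max(min_grad, std::max(0.5 * maxl, 0.2 * gmax));
    double tr = std::max(min_grad, std::max(0.5 * maxr, 0.2 * gmax));
    double sl = 0.0, sr = 0.0;
    double dl = first_peak(gl, ll, tl, step, sl);
    double dr = first_peak(gr, lr, tr, step, sr);
    out(k, 0) = dl < 0 ? NA_REAL : dl;
    out(k, 1) = dr < 0 ? NA_REAL : dr;
    out(k, 2) = dl < 0 ? NA_REAL : sl;
    out(k, 3) = dr < 0 ? NA_REAL : sr;
    // gradient magnitude at the line point itself (true centerline points
    // sit at a gradient minimum between their edges)
    out(k, 4) = (ll >= 0 && gl.size() > 0) ? gl[0] : 0.0;
    // smoothed brightness at the point and at its edges: a bright-line
    // center must not be darker than its own edge positions
    bool oo = false;
    out(k, 5) = bilin(r0, r0_, c0_, oo);
    out(k, 6) = dl < 0 ? NA_REAL : bilin(r0, r0_ + dl * ny, c0_ + dl * nx, oo);
    out(k, 7) = dr < 0 ? NA_REAL : bilin(r0, r0_ - dr * ny, c0_ - dr * nx, oo);
  }
  colnames(out) = CharacterVector::create("edge_left", "edge_right",
                                          "strength_left", "strength_right",
                                          "grad_center", "bright_center",
                                          "bright_left", "bright_right");
  return out;
}
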