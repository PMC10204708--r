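#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Guo-Hall thinning of a binary mask (1 = foreground), 8-connectivity;
// produces minimal 8-connected digital lines without the staircase corner
// doublets of the classic two-pass scheme.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img((size_t)H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      img[(size_t)j * H + i] = mask(i, j) != 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img[(size_t)j * H + i];
  };

  bool changed = true;
  std::vector<size_t> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!img[(size_t)j * H + i]) continue;
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int C = (!p2 && (p3 || p4)) + (!p4 && (p5 || p6)) +
                  (!p6 && (p7 || p8)) + (!p8 && (p9 || p2));
          if (C != 1) continue;
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          if (N < 2 || N > 3) continue;
          int m = pass == 0 ? ((p6 || p7 || !p9) && p8)
                            : ((p2 || p3 || !p5) && p4);
          if (m != 0) continue;
          del.push_back((size_t)j * H + i);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t idx : del) img[idx] = 0;
    }
  }

  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = img[(size_t)j * H + i];
  return out;
}

// Paint filled discs of per-point radius into an existing binary mask
// (in place on a copy). rows/cols are 1-based.
// [[Rcpp::export(name = ".cpp_paint_disks")]]
IntegerMatrix cpp_paint_disks(IntegerMatrix mask, IntegerVector rows,
                              IntegerVector cols, NumericVector radius) {
  IntegerMatrix out = clone(mask);
  int H = out.nrow(), W = out.ncol();
  for (int k = 0; k < rows.size(); ++k) {
    int i0 = rows[k] - 1, j0 = cols[k] - 1;
    double r = radius[k];
    int ri = (int)std::ceil(r);
    for (int dj = -ri; dj <= ri; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= W) continue;
      for (int di = -ri; di <= ri; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= H) continue;
        if ((double)di * di + (double)dj * dj <= r * r) out(i, j) = 1;
      }
    }
  }
  return out;
}
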