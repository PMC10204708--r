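#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sampled Gaussian kernels of degree 0/1/2 at scale sigma, support ceil(3.5*sigma).
// Calibrated so that responses to constant / linear / quadratic signals are exact:
//   sum g0 = 1;  sum g1 = 0, sum -i*g1 = 1;  sum g2 = 0, sum i^2/2*g2 = 1.
static void make_kernels(double sigma, std::vector<double>& g0,
                         std::vector<double>& g1, std::vector<double>& g2,
                         int& radius) {
  radius = (int)std::ceil(3.5 * sigma);
  if (radius < 1) radius = 1;
  int n = 2 * radius + 1;
  g0.assign(n, 0.0); g1.assign(n, 0.0); g2.assign(n, 0.0);
  const double s2 = sigma * sigma;
  const double norm = 1.0 / (std::sqrt(2.0 * M_PI) * sigma);
  for (int i = -radius; i <= radius; ++i) {
    double g = norm * std::exp(-0.5 * i * i / s2);
    g0[i + radius] = g;
    g1[i + radius] = -(double)i / s2 * g;
    g2[i + radius] = ((double)i * i / (s2 * s2) - 1.0 / s2) * g;
  }
  double s0 = 0.0;
  for (double v : g0) s0 += v;
  for (double& v : g0) v /= s0;
  // g1: remove DC, normalize first moment (convolution flips sign: response to
  // signal f(x)=x must be 1, i.e. sum_i -i*g1[i] = 1)
  double m0 = 0.0;
  for (double v : g1) m0 += v;
  for (double& v : g1) v -= m0 / n;
  double m1 = 0.0;
  for (int i = -radius; i <= radius; ++i) m1 += -(double)i * g1[i + radius];
  for (double& v : g1) v /= m1;
  // g2: remove DC, normalize second moment (response to f(x)=x^2/2 must be 1)
  m0 = 0.0;
  for (double v : g2) m0 += v;
  for (double& v : g2) v -= m0 / n;
  double m2 = 0.0;
  for (int i = -radius; i <= radius; ++i) m2 += 0.5 * i * i * g2[i + radius];
  for (double& v : g2) v /= m2;
}

// [[Rcpp::export(name = ".cpp_gauss_kernels")]]
List cpp_gauss_kernels(double sigma) {
  std::vector<double> g0, g1, g2;
  int radius;
  make_kernels(sigma, g0, g1, g2, radius);
  return List::create(_["g0"] = NumericVector(g0.begin(), g0.end()),
                      _["g1"] = NumericVector(g1.begin(), g1.end()),
                      _["g2"] = NumericVector(g2.begin(), g2.end()),
                      _["radius"] = radius);
}

static inline int reflect(int i, int n) {
  // reflect-101 border handling
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// convolve along rows (vertical direction, index i) for each column
static void conv_vert(const NumericMatrix& src, NumericMatrix& dst,
                      const std::vector<double>& k, int radius) {
  int H = src.nrow(), W = src.ncol();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * src(reflect(i - d, H), j);
      dst(i, j) = acc;
    }
  }
}

// convolve along columns (horizontal direction, index j) for each row
static void conv_horiz(const NumericMatrix& src, NumericMatrix& dst,
                       const std::vector<double>& k, int radius) {
  int H = src.nrow(), W = src.ncol();
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * src(i, reflect(j - d, W));
      dst(i, j) = acc;
    }
  }
}

// Full set of Gaussian partial derivatives of an image at scale sigma.
// Row index = y (vertical), column index = x (horizontal).
// [[Rcpp::export(name = ".cpp_gauss_derivs")]]
List cpp_gauss_derivs(NumericMatrix img, double sigma) {
  std::vector<double> g0, g1, g2;
  int radius;
  make_kernels(sigma, g0, g1, g2, radius);
  int H = img.nrow(), W = img.ncol();
  NumericMatrix s0v(H, W), s1v(H, W), s2v(H, W);
  conv_vert(img, s0v, g0, radius);   // smoothed in y
  conv_vert(img, s1v, g1, radius);   // d/dy in y
  conv_vert(img, s2v, g2, radius);   // d2/dy2 in y
  NumericMatrix rx(H, W), ry(H, W), rxx(H, W), rxy(H, W), ryy(H, W), r0(H, W);
  conv_horiz(s0v, rx, g1, radius);   // d/dx of y-smoothed
  conv_horiz(s1v, ry, g0, radius);   // d/dy smoothed in x
  conv_horiz(s0v, rxx, g2, radius);
  conv_horiz(s1v, rxy, g1, radius);
  conv_horiz(s2v, ryy, g0, radius);
  conv_horiz(s0v, r0, g0, radius);   // plain smoothed image
  return List::create(_["r"] = r0, _["rx"] = rx, _["ry"] = ry,
                      _["rxx"] = rxx, _["rxy"] = rxy, _["ryy"] = ryy,
                      _["sigma"] = sigma, _["radius"] = radius);
}
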