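#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// modified Bessel function I0 (power series; adequate for beta <= ~30)
static double bessel_i0(double x) {
  double t = x / 2.0, s = 1.0, term = 1.0;
  for (int k = 1; k < 80; ++k) {
    term *= (t / k) * (t / k);
    s += term;
    if (term < 1e-18 * s) break;
  }
  return s;
}

// Kaiser-Bessel kernel sampled on [0, J/2]; linear interpolation at eval time
struct KBTable {
  std::vector<double> tab;
  double half_width, step_inv;
  KBTable(int J, double beta, int n = 32768) {
    half_width = J / 2.0;
    tab.resize(n + 2);
    double i0b = bessel_i0(beta);
    for (int i = 0; i <= n; ++i) {
      double d = half_width * i / n;
      double arg = 1.0 - (d / half_width) * (d / half_width);
      tab[i] = arg <= 0 ? 0.0 : bessel_i0(beta * std::sqrt(arg)) / i0b;
    }
    tab[n + 1] = 0.0;
    step_inv = n / half_width;
  }
  inline double operator()(double d) const {
    d = std::fabs(d);
    if (d >= half_width) return 0.0;
    double u = d * step_inv;
    int i = (int)u;
    double f = u - i;
    return tab[i] * (1 - f) + tab[i + 1] * f;
  }
};

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Spread nonuniform complex samples onto a periodic oversampled grid.
// pts: M x 3 coordinates in centered oversampled-grid index units
// (coordinate 0 corresponds to array index nos/2, 0-based).
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(NumericMatrix pts, ComplexVector vals,
                            IntegerVector nos, int J, double beta) {
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const R_xlen_t M = pts.nrow();
  KBTable kb(J, beta);
  std::vector<double> gre((size_t)n1 * n2 * n3, 0.0),
      gim((size_t)n1 * n2 * n3, 0.0);
  const double hw = J / 2.0;
  std::vector<double> w1(J + 1), w2(J + 1), w3(J + 1);
  std::vector<int> i1(J + 1), i2(J + 1), i3(J + 1);
  for (R_xlen_t m = 0; m < M; ++m) {
    double u1 = pts(m, 0) + n1 / 2.0, u2 = pts(m, 1) + n2 / 2.0,
           u3 = pts(m, 2) + n3 / 2.0;
    int l1 = (int)std::ceil(u1 - hw), h1 = (int)std::floor(u1 + hw);
    int l2 = (int)std::ceil(u2 - hw), h2 = (int)std::floor(u2 + hw);
    int l3 = (int)std::ceil(u3 - hw), h3 = (int)std::floor(u3 + hw);
    int c1 = 0, c2 = 0, c3 = 0;
    for (int a = l1; a <= h1; ++a) { w1[c1] = kb(u1 - a); i1[c1++] = wrap(a, n1); }
    for (int a = l2; a <= h2; ++a) { w2[c2] = kb(u2 - a); i2[c2++] = wrap(a, n2); }
    for (int a = l3; a <= h3; ++a) { w3[c3] = kb(u3 - a); i3[c3++] = wrap(a, n3); }
    double vr = vals[m].r, vi = vals[m].i;
    for (int c = 0; c < c3; ++c) {
      size_t off3 = (size_t)i3[c] * n1 * n2;
      double wc = w3[c];
      for (int b = 0; b < c2; ++b) {
        size_t off2 = off3 + (size_t)i2[b] * n1;
        double wbc = wc * w2[b];
        for (int a = 0; a < c1; ++a) {
          double w = wbc * w1[a];
          gre[off2 + i1[a]] += w * vr;
          gim[off2 + i1[a]] += w * vi;
        }
      }
    }
  }
  ComplexVector out((R_xlen_t)n1 * n2 * n3);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    out[i].r = gre[i];
    out[i].i = gim[i];
  }
  out.attr("dim") = IntegerVector::create(n1, n2, n3);
  return out;
}

// Interpolate a periodic oversampled complex grid at nonuniform points
// (exact transpose of cpp_kb_spread).
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(ComplexVector grid, IntegerVector nos,
                            NumericMatrix pts, int J, double beta) {
  const int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  const R_xlen_t M = pts.nrow();
  KBTable kb(J, beta);
  ComplexVector out(M);
  const double hw = J / 2.0;
  std::vector<double> w1(J + 1), w2(J + 1), w3(J + 1);
  std::vector<int> i1(J + 1), i2(J + 1), i3(J + 1);
  for (R_xlen_t m = 0; m < M; ++m) {
    double u1 = pts(m, 0) + n1 / 2.0, u2 = pts(m, 1) + n2 / 2.0,
           u3 = pts(m, 2) + n3 / 2.0;
    int l1 = (int)std::ceil(u1 - hw), h1 = (int)std::floor(u1 + hw);
    int l2 = (int)std::ceil(u2 - hw), h2 = (int)std::floor(u2 + hw);
    int l3 = (int)std::ceil(u3 - hw), h3 = (int)std::floor(u3 + hw);
    int c1 = 0, c2 = 0, c3 = 0;
    for (int a = l1; a <= h1; ++a) { w1[c1] = kb(u1 - a); i1[c1++] = wrap(a, n1); }
    for (int a = l2; a <= h2; ++a) { w2[c2] = kb(u2 - a); i2[c2++] = wrap(a, n2); }
    for (int a = l3; a <= h3; ++a) { w3[c3] = kb(u3 - a); i3[c3++] = wrap(a, n3); }
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < c3; ++c) {
      size_t off3 = (size_t)i3[c] * n1 * n2;
      double wc = w3[c];
      for (int b = 0; b < c2; ++b) {
        size_t off2 = off3 + (size_t)i2[b] * n1;
        double wbc = wc * w2[b];
        for (int a = 0; a < c1; ++a) {
          double w = wbc * w1[a];
          sr += w * grid[off2 + i1[a]].r;
          si += w * grid[off2 + i1[a]].i;
        }
      }
    }
    out[m].r = sr;
    out[m].i = si;
  }
  return out;
}

// Trilinear interpolation of a real volume at continuous 0-based index
// coordinates; points outside the volume return `outside`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, double outside) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t M = pts.nrow();
  NumericVector out(M);
  for (R_xlen_t m = 0; m < M; ++m) {
    double x = pts(m, 0), y = pts(m, 1), z = pts(m, 2);
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[m] = outside;
      continue;
    }
    int x0 = (int)x, y0 = (int)y, z0 = (int)z;
    if (x0 == n1 - 1) x0--;
    if (y0 == n2 - 1) y0--;
    if (z0 == n3 - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    size_t b = (size_t)z0 * n1 * n2 + (size_t)y0 * n1 + x0;
    size_t s1 = 1, s2 = n1, s3 = (size_t)n1 * n2;
    double v000 = vol[b], v100 = vol[b + s1], v010 = vol[b + s2],
           v110 = vol[b + s1 + s2], v001 = vol[b + s3], v101 = vol[b + s1 + s3],
           v011 = vol[b + s2 + s3], v111 = vol[b + s1 + s2 + s3];
    double c00 = v000 * (1 - fx) + v100 * fx, c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx, c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    out[m] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour lookup of an integer volume at continuous 0-based index
// coordinates; outside -> 0.
// [[Rcpp::export]]
IntegerVector cpp_nearest(IntegerVector vol, IntegerVector dim,
                          NumericMatrix pts) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t M = pts.nrow();
  IntegerVector out(M);
  for (R_xlen_t m = 0; m < M; ++m) {
    int x = (int)std::lround(pts(m, 0)), y = (int)std::lround(pts(m, 1)),
        z = (int)std::lround(pts(m, 2));
    if (x < 0 || y < 0 || z < 0 || x >= n1 || y >= n2 || z >= n3) {
      out[m] = 0;
    } else {
      out[m] = vol[(size_t)z * n1 * n2 + (size_t)y * n1 + x];
    }
  }
  return out;
}
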