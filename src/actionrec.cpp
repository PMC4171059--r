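#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---- small image primitives ------------------------------------------------

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// column-major flat image
struct Img {
  int nr = 0, nc = 0;
  std::vector<double> v;
  Img() {}
  Img(int r, int c) : nr(r), nc(c), v((size_t)r * c, 0.0) {}
  double& at(int i, int j) { return v[(size_t)i + (size_t)j * nr]; }
  double at(int i, int j) const { return v[(size_t)i + (size_t)j * nr]; }
};

static Img from_R(const NumericMatrix& m) {
  Img out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.v.begin());
  return out;
}

static NumericMatrix to_R(const Img& im) {
  NumericMatrix out(im.nr, im.nc);
  std::copy(im.v.begin(), im.v.end(), out.begin());
  return out;
}

static inline double sample_bilinear(const Img& img, double r, double c) {
  r = clampd(r, 0.0, img.nr - 1.0);
  c = clampd(c, 0.0, img.nc - 1.0);
  int r0 = (int)r, c0 = (int)c;
  int r1 = std::min(r0 + 1, img.nr - 1), c1 = std::min(c0 + 1, img.nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img.at(r0, c0) + fc * img.at(r0, c1)) +
         fr * ((1 - fc) * img.at(r1, c0) + fc * img.at(r1, c1));
}

static Img resize_bilinear(const Img& img, int nrow, int ncol) {
  Img out(nrow, ncol);
  const double sr = (img.nr - 1.0) / std::max(nrow - 1.0, 1.0);
  const double sc = (img.nc - 1.0) / std::max(ncol - 1.0, 1.0);
  for (int j = 0; j < ncol; ++j)
    for (int i = 0; i < nrow; ++i)
      out.at(i, j) = sample_bilinear(img, i * sr, j * sc);
  return out;
}

static Img gauss_blur(const Img& img, double sigma) {
  if (sigma <= 0) return img;
  const int nr = img.nr, nc = img.nc;
  const int rad = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + rad];
  }
  for (double& w : k) w /= s;
  Img tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int t = -rad; t <= rad; ++t)
        a += k[t + rad] * img.at(i, std::min(std::max(j + t, 0), nc - 1));
      tmp.at(i, j) = a;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int t = -rad; t <= rad; ++t)
        a += k[t + rad] * tmp.at(std::min(std::max(i + t, 0), nr - 1), j);
      out.at(i, j) = a;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int nrow, int ncol) {
  return to_R(resize_bilinear(from_R(img), nrow, ncol));
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img,
                                const NumericMatrix& u,
                                const NumericMatrix& v) {
  Img im = from_R(img);
  const int nr = im.nr, nc = im.nc;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = sample_bilinear(im, i + v(i, j), j + u(i, j));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  return to_R(gauss_blur(from_R(img), sigma));
}

// grayscale dilation over a (2*radius+1) square window, separable running max
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = -INFINITY;
      for (int t = std::max(0, j - radius); t <= std::min(nc - 1, j + radius); ++t)
        m = std::max(m, img(i, t));
      tmp(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = -INFINITY;
      for (int t = std::max(0, i - radius); t <= std::min(nr - 1, i + radius); ++t)
        m = std::max(m, tmp(t, j));
      out(i, j) = m;
    }
  return out;
}

// local mean over a (2*radius+1) square window (border: window cropped)
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<double> S((size_t)(nr + 1) * (nc + 1), 0.0);
  const int W = nc + 1;
  for (int i = 1; i <= nr; ++i)
    for (int j = 1; j <= nc; ++j)
      S[(size_t)i * W + j] = img(i - 1, j - 1) + S[(size_t)(i - 1) * W + j] +
                             S[(size_t)i * W + j - 1] -
                             S[(size_t)(i - 1) * W + j - 1];
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int r0 = std::max(0, i - radius), r1 = std::min(nr - 1, i + radius);
      int c0 = std::max(0, j - radius), c1 = std::min(nc - 1, j + radius);
      double sum = S[(size_t)(r1 + 1) * W + (c1 + 1)] -
                   S[(size_t)r0 * W + (c1 + 1)] -
                   S[(size_t)(r1 + 1) * W + c0] + S[(size_t)r0 * W + c0];
      out(i, j) = sum / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  return out;
}

// ---- variational optical flow ---------------------------------------------
//
// Robust (Charbonnier) data + smoothness terms, optional symmetry coupling of
// the forward and backward fields, minimised coarse-to-fine with inner
// fixed-point reweighting and Gauss-Seidel sweeps.  A warp update is accepted
// only if it does not increase the objective at its pyramid level, so the
// per-level energy trace is non-increasing by construction.

static inline double charb(double s2, double eps2) {
  return std::sqrt(s2 + eps2);
}

// objective for one direction (data + smoothness) plus optional symmetry term
static double flow_energy_dir(const Img& I1, const Img& I2,
                              const Img& u, const Img& v,
                              const Img& ub, const Img& vb,
                              double rho, double xi, double eps2) {
  const int nr = I1.nr, nc = I1.nc;
  double E = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double w = sample_bilinear(I2, i + v.at(i, j), j + u.at(i, j)) - I1.at(i, j);
      E += charb(w * w, eps2);
      int jp = std::min(nc - 1, j + 1), ip = std::min(nr - 1, i + 1);
      double ux = u.at(i, jp) - u.at(i, j), uy = u.at(ip, j) - u.at(i, j);
      double vx = v.at(i, jp) - v.at(i, j), vy = v.at(ip, j) - v.at(i, j);
      E += xi * (charb(ux * ux + uy * uy, eps2) + charb(vx * vx + vy * vy, eps2));
      if (rho > 0) {
        // symmetry term is quadratic: a robust weight would diverge at the
        // consistent fixed point w_f = -w_b and freeze both fields at zero
        double ubw = sample_bilinear(ub, i + v.at(i, j), j + u.at(i, j));
        double vbw = sample_bilinear(vb, i + v.at(i, j), j + u.at(i, j));
        double du = u.at(i, j) + ubw, dv = v.at(i, j) + vbw;
        E += rho * 0.5 * (du * du + dv * dv);
      }
    }
  return E;
}

// one warp step for one direction: linearise at the current flow, inner
// fixed-point reweighting, Gauss-Seidel sweeps on the coupled 2x2 systems
static void warp_step(const Img& I1, const Img& I2, Img& u, Img& v,
                      const Img& ub, const Img& vb,
                      double rho, double xi, int inner_iters, double eps2) {
  const int nr = I1.nr, nc = I1.nc;
  const size_t N = (size_t)nr * nc;
  Img I2w(nr, nc), Ix(nr, nc), Iy(nr, nc), ct(nr, nc), ubw(nr, nc), vbw(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      I2w.at(i, j) = sample_bilinear(I2, i + v.at(i, j), j + u.at(i, j));
  for (int j = 0; j < nc; ++j) {
    int jm = std::max(0, j - 1), jp = std::min(nc - 1, j + 1);
    double dj = jp - jm > 0 ? jp - jm : 1;
    for (int i = 0; i < nr; ++i) {
      int im = std::max(0, i - 1), ip = std::min(nr - 1, i + 1);
      double di = ip - im > 0 ? ip - im : 1;
      double g1x = (I1.at(i, jp) - I1.at(i, jm)) / dj;
      double g2x = (I2w.at(i, jp) - I2w.at(i, jm)) / dj;
      double g1y = (I1.at(ip, j) - I1.at(im, j)) / di;
      double g2y = (I2w.at(ip, j) - I2w.at(im, j)) / di;
      Ix.at(i, j) = 0.5 * (g1x + g2x);
      Iy.at(i, j) = 0.5 * (g1y + g2y);
      ct.at(i, j) = I2w.at(i, j) - I1.at(i, j) -
                    Ix.at(i, j) * u.at(i, j) - Iy.at(i, j) * v.at(i, j);
    }
  }
  if (rho > 0) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        ubw.at(i, j) = sample_bilinear(ub, i + v.at(i, j), j + u.at(i, j));
        vbw.at(i, j) = sample_bilinear(vb, i + v.at(i, j), j + u.at(i, j));
      }
  }
  std::vector<double> wd(N), ws(N);
  std::vector<double> wr(rho > 0 ? N : 0);
  const int sweeps = 2;
  for (int it = 0; it < inner_iters; ++it) {
    for (int j = 0; j < nc; ++j) {
      int jp = std::min(nc - 1, j + 1);
      for (int i = 0; i < nr; ++i) {
        int ip = std::min(nr - 1, i + 1);
        size_t p = (size_t)i + (size_t)j * nr;
        double r = ct.v[p] + Ix.v[p] * u.v[p] + Iy.v[p] * v.v[p];
        wd[p] = 1.0 / (2.0 * charb(r * r, eps2));
        double ux = u.at(i, jp) - u.v[p], uy = u.at(ip, j) - u.v[p];
        double vx = v.at(i, jp) - v.v[p], vy = v.at(ip, j) - v.v[p];
        ws[p] = 1.0 / (2.0 * charb(ux * ux + uy * uy + vx * vx + vy * vy, eps2));
        if (rho > 0) wr[p] = 0.5;   // quadratic symmetry penalty
      }
    }
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t p = (size_t)i + (size_t)j * nr;
          double sumw = 0, sumu = 0, sumv = 0;
          if (i > 0) {
            double wpq = 0.5 * (ws[p] + ws[p - 1]);
            sumw += wpq; sumu += wpq * u.v[p - 1]; sumv += wpq * v.v[p - 1];
          }
          if (i < nr - 1) {
            double wpq = 0.5 * (ws[p] + ws[p + 1]);
            sumw += wpq; sumu += wpq * u.v[p + 1]; sumv += wpq * v.v[p + 1];
          }
          if (j > 0) {
            double wpq = 0.5 * (ws[p] + ws[p - nr]);
            sumw += wpq; sumu += wpq * u.v[p - nr]; sumv += wpq * v.v[p - nr];
          }
          if (j < nc - 1) {
            double wpq = 0.5 * (ws[p] + ws[p + nr]);
            sumw += wpq; sumu += wpq * u.v[p + nr]; sumv += wpq * v.v[p + nr];
          }
          double d = wd[p], ix = Ix.v[p], iy = Iy.v[p], c = ct.v[p];
          double au = d * ix * ix + xi * sumw;
          double av = d * iy * iy + xi * sumw;
          double cross = d * ix * iy;
          double bu = -d * ix * c + xi * sumu;
          double bv = -d * iy * c + xi * sumv;
          if (rho > 0) {
            au += rho * wr[p];
            av += rho * wr[p];
            bu += -rho * wr[p] * ubw.v[p];
            bv += -rho * wr[p] * vbw.v[p];
          }
          double det = au * av - cross * cross;
          if (det > 1e-12) {
            u.v[p] = (av * bu - cross * bv) / det;
            v.v[p] = (au * bv - cross * bu) / det;
          }
        }
    }
  }
}

// [[Rcpp::export]]
List cpp_estimate_flow(const NumericMatrix& I1, const NumericMatrix& I2,
                       double rho, double xi, int levels, int warps,
                       int inner_iters, double eps) {
  const double eps2 = eps * eps;
  std::vector<Img> P1, P2;
  P1.push_back(from_R(I1));
  P2.push_back(from_R(I2));
  for (int l = 1; l < levels; ++l) {
    const Img& prev = P1.back();
    int nr = (int)std::lround(prev.nr * 0.5);
    int nc = (int)std::lround(prev.nc * 0.5);
    if (nr < 8 || nc < 8) break;
    P1.push_back(resize_bilinear(gauss_blur(P1.back(), 0.8), nr, nc));
    P2.push_back(resize_bilinear(gauss_blur(P2.back(), 0.8), nr, nc));
  }
  const int L = (int)P1.size();
  Img u1(P1[L - 1].nr, P1[L - 1].nc), v1 = u1, u2 = u1, v2 = u1;
  std::vector<int> tr_level, tr_warp;
  std::vector<double> tr_energy;
  for (int l = L - 1; l >= 0; --l) {
    const Img& A = P1[l];
    const Img& B = P2[l];
    if (l < L - 1) {
      double fr = (double)A.nr / P1[l + 1].nr;
      double fc = (double)A.nc / P1[l + 1].nc;
      u1 = resize_bilinear(u1, A.nr, A.nc);
      v1 = resize_bilinear(v1, A.nr, A.nc);
      u2 = resize_bilinear(u2, A.nr, A.nc);
      v2 = resize_bilinear(v2, A.nr, A.nc);
      for (double& x : u1.v) x *= fc;
      for (double& x : v1.v) x *= fr;
      for (double& x : u2.v) x *= fc;
      for (double& x : v2.v) x *= fr;
    }
    double E0 = flow_energy_dir(A, B, u1, v1, u2, v2, rho, xi, eps2) +
                flow_energy_dir(B, A, u2, v2, u1, v1, rho, xi, eps2);
    for (int w = 0; w < warps; ++w) {
      Img cu1 = u1, cv1 = v1, cu2 = u2, cv2 = v2;
      warp_step(A, B, cu1, cv1, u2, v2, rho, xi, inner_iters, eps2);
      warp_step(B, A, cu2, cv2, cu1, cv1, rho, xi, inner_iters, eps2);
      double E1 = flow_energy_dir(A, B, cu1, cv1, cu2, cv2, rho, xi, eps2) +
                  flow_energy_dir(B, A, cu2, cv2, cu1, cv1, rho, xi, eps2);
      if (E1 <= E0) {
        u1 = cu1; v1 = cv1; u2 = cu2; v2 = cv2;
        E0 = E1;
      } // else: update rejected, objective unchanged
      tr_energy.push_back(E0);
      tr_level.push_back(l);
      tr_warp.push_back(w + 1);
    }
  }
  DataFrame trace = DataFrame::create(_["level"] = tr_level, _["warp"] = tr_warp,
                                      _["energy"] = tr_energy);
  return List::create(_["u_fwd"] = to_R(u1), _["v_fwd"] = to_R(v1),
                      _["u_bwd"] = to_R(u2), _["v_bwd"] = to_R(v2),
                      _["trace"] = trace);
}
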