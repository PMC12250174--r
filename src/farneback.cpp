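// Dense polynomial-expansion optical flow (Farneback) and landmark
// rasterization. Images are grayscale matrices (rows = image y,
// columns = image x), stored column-major like R. Borders are handled
// by replication throughout. polyN is the neighborhood size of the
// polynomial fit (window half-width polyN / 2).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// simple column-major image buffer
struct Img {
  int H = 0, W = 0;
  std::vector<double> d;
  Img() = default;
  Img(int h, int w) : H(h), W(w), d((size_t)h * w, 0.0) {}
  double& at(int r, int c) { return d[(size_t)c * H + r]; }
  double at(int r, int c) const { return d[(size_t)c * H + r]; }
};

static Img fromR(const NumericMatrix& m) {
  Img out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.d.begin());
  return out;
}

static NumericMatrix toR(const Img& im) {
  NumericMatrix out(im.H, im.W);
  std::copy(im.d.begin(), im.d.end(), out.begin());
  return out;
}

// ---- rasterization -------------------------------------------------------

static Img render_pose(const double* px, const double* py, int nlm,
                       int width, int height, int radius,
                       double intensity) {
  Img img(height, width);
  int r2 = radius * radius;
  for (int k = 0; k < nlm; ++k) {
    if (!R_finite(px[k]) || !R_finite(py[k])) continue;
    int cc = (int)std::lround(px[k] * (width - 1));
    int cr = (int)std::lround(py[k] * (height - 1));
    for (int dc = -radius; dc <= radius; ++dc) {
      int c = cc + dc;
      if (c < 0 || c >= width) continue;
      for (int dr = -radius; dr <= radius; ++dr) {
        if (dr * dr + dc * dc > r2) continue;
        int rr = cr + dr;
        if (rr < 0 || rr >= height) continue;
        img.at(rr, c) = intensity;
      }
    }
  }
  return img;
}

// Draw landmarks as filled circles on a black image. px/py are
// normalized [0,1] coordinates (x -> column, y -> row).
// [[Rcpp::export(name = "nm_render_pose")]]
NumericMatrix nm_render_pose(NumericVector px, NumericVector py,
                             int width, int height, int radius,
                             double intensity) {
  return toR(render_pose(px.begin(), py.begin(), px.size(), width,
                         height, radius, intensity));
}

// ---- polynomial expansion ------------------------------------------------

// Fit f(dx,dy) ~ r1 + r2*dx + r3*dy + r4*dx^2 + r5*dy^2 + r6*dx*dy in a
// (2n+1)^2 window (n = polyN/2) with separable Gaussian applicability.
// Outputs the quadratic form A = [[r4, r6/2], [r6/2, r5]] and the
// linear part b = (r2, r3).
struct PolyExp {
  Img a11, a12, a22, bx, by;
};

static PolyExp poly_expand(const Img& img, int polyN, double sigma) {
  int n = polyN / 2;
  if (n < 1) n = 1;
  int H = img.H, W = img.W;
  std::vector<double> g(2 * n + 1);
  double gs = 0.0;
  for (int i = -n; i <= n; ++i) {
    g[i + n] = std::exp(-(double)(i * i) / (2.0 * sigma * sigma));
    gs += g[i + n];
  }
  for (auto& v : g) v /= gs;
  double b2 = 0.0, b4 = 0.0;
  for (int i = -n; i <= n; ++i) {
    b2 += g[i + n] * i * i;
    b4 += g[i + n] * i * i * i * i;
  }
  double b2sq = b2 * b2;
  // inverse of [[1,b2,b2],[b2,b4,b2sq],[b2,b2sq,b4]] for (r1,r4,r5)
  double G[3][3] = {{1.0, b2, b2}, {b2, b4, b2sq}, {b2, b2sq, b4}};
  double det = G[0][0] * (G[1][1] * G[2][2] - G[1][2] * G[2][1]) -
               G[0][1] * (G[1][0] * G[2][2] - G[1][2] * G[2][0]) +
               G[0][2] * (G[1][0] * G[2][1] - G[1][1] * G[2][0]);
  double I10 = (G[1][2] * G[2][0] - G[1][0] * G[2][2]) / det;
  double I11 = (G[0][0] * G[2][2] - G[0][2] * G[2][0]) / det;
  double I12 = (G[0][2] * G[1][0] - G[0][0] * G[1][2]) / det;
  double I20 = (G[1][0] * G[2][1] - G[1][1] * G[2][0]) / det;
  double I21 = (G[0][1] * G[2][0] - G[0][0] * G[2][1]) / det;
  double I22 = (G[0][0] * G[1][1] - G[0][1] * G[1][0]) / det;

  // vertical pass first (unit stride down columns): moments in the
  // y (row) offset j
  Img s0(H, W), s1(H, W), s2(H, W);
  for (int c = 0; c < W; ++c) {
    const double* col = &img.d[(size_t)c * H];
    double* p0 = &s0.d[(size_t)c * H];
    double* p1 = &s1.d[(size_t)c * H];
    double* p2 = &s2.d[(size_t)c * H];
    for (int r = 0; r < H; ++r) {
      double v0 = 0, v1 = 0, v2 = 0;
      if (r >= n && r < H - n) {
        for (int j = -n; j <= n; ++j) {
          double w = g[j + n], val = col[r + j];
          v0 += w * val; v1 += w * j * val; v2 += w * j * j * val;
        }
      } else {
        for (int j = -n; j <= n; ++j) {
          double w = g[j + n], val = col[clampi(r + j, 0, H - 1)];
          v0 += w * val; v1 += w * j * val; v2 += w * j * j * val;
        }
      }
      p0[r] = v0; p1[r] = v1; p2[r] = v2;
    }
  }
  PolyExp out;
  out.a11 = Img(H, W); out.a12 = Img(H, W); out.a22 = Img(H, W);
  out.bx = Img(H, W); out.by = Img(H, W);
  // horizontal pass: moments in the x (column) offset i
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m00 = 0, m01 = 0, m02 = 0, m10 = 0, m11 = 0, m20 = 0;
      for (int i = -n; i <= n; ++i) {
        int cc = clampi(c + i, 0, W - 1);
        double w = g[i + n];
        double v0 = s0.at(r, cc), v1 = s1.at(r, cc), v2 = s2.at(r, cc);
        m00 += w * v0;
        m10 += w * i * v0;       // x moment of y-smoothed image
        m20 += w * i * i * v0;
        m01 += w * v1;           // y moment
        m11 += w * i * v1;       // xy moment
        m02 += w * v2;           // y^2 moment
      }
      double r2c = m10 / b2;          // x coefficient
      double r3c = m01 / b2;          // y coefficient
      double r6c = m11 / b2sq;        // xy coefficient
      double r4c = I10 * m00 + I11 * m20 + I12 * m02;
      double r5c = I20 * m00 + I21 * m20 + I22 * m02;
      out.a11.at(r, c) = r4c;
      out.a12.at(r, c) = 0.5 * r6c;
      out.a22.at(r, c) = r5c;
      out.bx.at(r, c) = r2c;
      out.by.at(r, c) = r3c;
    }
  }
  return out;
}

// [[Rcpp::export(name = "nm_poly_expand")]]
List nm_poly_expand(NumericMatrix img, int polyN, double polySigma) {
  PolyExp pe = poly_expand(fromR(img), polyN, polySigma);
  return List::create(_["a11"] = toR(pe.a11), _["a12"] = toR(pe.a12),
                      _["a22"] = toR(pe.a22), _["bx"] = toR(pe.bx),
                      _["by"] = toR(pe.by));
}

// normalized separable box blur via running sums (replicate border)
static void box_blur(Img& m, int winsize) {
  int n = winsize / 2;
  if (n < 1) return;
  int H = m.H, W = m.W;
  double inv = 1.0 / (2 * n + 1);
  Img tmp(H, W);
  // vertical pass down each column
  std::vector<double> buf;
  for (int c = 0; c < W; ++c) {
    const double* col = &m.d[(size_t)c * H];
    double* out = &tmp.d[(size_t)c * H];
    double s = 0;
    for (int j = -n; j <= n; ++j) s += col[clampi(j, 0, H - 1)];
    out[0] = s * inv;
    for (int r = 1; r < H; ++r) {
      s += col[clampi(r + n, 0, H - 1)] - col[clampi(r - 1 - n, 0, H - 1)];
      out[r] = s * inv;
    }
  }
  // horizontal pass along each row
  for (int r = 0; r < H; ++r) {
    double s = 0;
    for (int i = -n; i <= n; ++i) s += tmp.at(r, clampi(i, 0, W - 1));
    m.at(r, 0) = s * inv;
    for (int c = 1; c < W; ++c) {
      s += tmp.at(r, clampi(c + n, 0, W - 1)) -
           tmp.at(r, clampi(c - 1 - n, 0, W - 1));
      m.at(r, c) = s * inv;
    }
  }
}

// one pyramid level of displacement refinement
static void flow_level(const PolyExp& p1, const PolyExp& p2,
                       Img& u, Img& v, int winsize, int iterations) {
  int H = u.H, W = u.W;
  for (int it = 0; it < iterations; ++it) {
    Img G11(H, W), G12(H, W), G22(H, W), h1(H, W), h2(H, W);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int du = (int)std::lround(u.at(r, c));
        int dv = (int)std::lround(v.at(r, c));
        int c2 = clampi(c + du, 0, W - 1);
        int r2 = clampi(r + dv, 0, H - 1);
        double a11 = 0.5 * (p1.a11.at(r, c) + p2.a11.at(r2, c2));
        double a12 = 0.5 * (p1.a12.at(r, c) + p2.a12.at(r2, c2));
        double a22 = 0.5 * (p1.a22.at(r, c) + p2.a22.at(r2, c2));
        double dbx = -0.5 * (p2.bx.at(r2, c2) - p1.bx.at(r, c)) +
                     a11 * du + a12 * dv;
        double dby = -0.5 * (p2.by.at(r2, c2) - p1.by.at(r, c)) +
                     a12 * du + a22 * dv;
        G11.at(r, c) = a11 * a11 + a12 * a12;
        G12.at(r, c) = a12 * (a11 + a22);
        G22.at(r, c) = a12 * a12 + a22 * a22;
        h1.at(r, c) = a11 * dbx + a12 * dby;
        h2.at(r, c) = a12 * dbx + a22 * dby;
      }
    }
    box_blur(G11, winsize); box_blur(G12, winsize); box_blur(G22, winsize);
    box_blur(h1, winsize); box_blur(h2, winsize);
    for (size_t i = 0; i < u.d.size(); ++i) {
      double det = G11.d[i] * G22.d[i] - G12.d[i] * G12.d[i];
      if (std::fabs(det) > 1e-12) {
        u.d[i] = (G22.d[i] * h1.d[i] - G12.d[i] * h2.d[i]) / det;
        v.d[i] = (G11.d[i] * h2.d[i] - G12.d[i] * h1.d[i]) / det;
      } else {
        u.d[i] = 0.0;
        v.d[i] = 0.0;
      }
    }
  }
}

// 2x2-average downsampling (pyramid scale fixed at 0.5)
static Img downsample2(const Img& m) {
  int H = m.H / 2, W = m.W / 2;
  Img out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out.at(r, c) = 0.25 * (m.at(2 * r, 2 * c) + m.at(2 * r + 1, 2 * c) +
                             m.at(2 * r, 2 * c + 1) +
                             m.at(2 * r + 1, 2 * c + 1));
  return out;
}

// upsample a flow field by 2 (nearest neighbour), doubling magnitudes
static Img upsample_flow(const Img& m, int H, int W) {
  Img out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out.at(r, c) = 2.0 * m.at(clampi(r / 2, 0, m.H - 1),
                                clampi(c / 2, 0, m.W - 1));
  return out;
}

// per-frame pyramid of polynomial expansions
struct FramePyr {
  std::vector<int> Hs, Ws;
  std::vector<PolyExp> exps;
};

static FramePyr build_pyr(const Img& im, int levels, int polyN,
                          double sigma) {
  FramePyr fp;
  std::vector<Img> pyr;
  pyr.push_back(im);
  for (int l = 1; l < levels; ++l) {
    const Img& prev = pyr.back();
    if (prev.H / 2 < 16 || prev.W / 2 < 16) break;
    pyr.push_back(downsample2(prev));
  }
  for (auto& p : pyr) {
    fp.Hs.push_back(p.H);
    fp.Ws.push_back(p.W);
    fp.exps.push_back(poly_expand(p, polyN, sigma));
  }
  return fp;
}

static void flow_from_pyrs(const FramePyr& f1, const FramePyr& f2,
                           int winsize, int iterations, Img& u, Img& v) {
  int L = (int)f1.exps.size();
  u = Img(f1.Hs[L - 1], f1.Ws[L - 1]);
  v = Img(f1.Hs[L - 1], f1.Ws[L - 1]);
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      u = upsample_flow(u, f1.Hs[l], f1.Ws[l]);
      v = upsample_flow(v, f1.Hs[l], f1.Ws[l]);
    }
    flow_level(f1.exps[l], f2.exps[l], u, v, winsize, iterations);
  }
}

// [[Rcpp::export(name = "nm_farneback_flow")]]
List nm_farneback_flow(NumericMatrix im1, NumericMatrix im2,
                       double pyrScale, int levels, int winsize,
                       int iterations, int polyN, double polySigma) {
  if (pyrScale != 0.5) stop("only pyrScale = 0.5 is supported");
  FramePyr f1 = build_pyr(fromR(im1), levels, polyN, polySigma);
  FramePyr f2 = build_pyr(fromR(im2), levels, polyN, polySigma);
  Img u, v;
  flow_from_pyrs(f1, f2, winsize, iterations, u, v);
  return List::create(_["u"] = toR(u), _["v"] = toR(v));
}

static double flow_mag_sum(const Img& u, const Img& v) {
  double s = 0.0;
  for (size_t i = 0; i < u.d.size(); ++i)
    s += std::sqrt(u.d[i] * u.d[i] + v.d[i] * v.d[i]);
  return s;
}

// Per-transition Farneback flow magnitudes for a whole sequence.
// X, Y are landmarks x frames matrices of normalized coordinates.
// Each frame's expansion pyramid is built once and shared by the two
// transitions it participates in.
// [[Rcpp::export(name = "farneback_pair_sums")]]
NumericVector farneback_pair_sums(NumericMatrix X, NumericMatrix Y,
                                  int width, int height, int radius,
                                  double intensity, double pyrScale,
                                  int levels, int winsize, int iterations,
                                  int polyN, double polySigma) {
  if (pyrScale != 0.5) stop("only pyrScale = 0.5 is supported");
  int n = X.ncol(), L = X.nrow();
  NumericVector out(n - 1);
  std::vector<double> px(L), py(L);
  auto frameImg = [&](int t) {
    for (int k = 0; k < L; ++k) {
      px[k] = X(k, t);
      py[k] = Y(k, t);
    }
    return render_pose(px.data(), py.data(), L, width, height, radius,
                       intensity);
  };
  Img prevImg = frameImg(0);
  FramePyr prev = build_pyr(prevImg, levels, polyN, polySigma);
  bool prevBuilt = true;
  for (int t = 1; t < n; ++t) {
    Img curImg = frameImg(t);
    if (curImg.d == prevImg.d) {
      out[t - 1] = 0.0;      // identical frames: exactly zero flow
      prevBuilt = false;     // expansion not needed yet
    } else {
      if (!prevBuilt) prev = build_pyr(prevImg, levels, polyN, polySigma);
      FramePyr cur = build_pyr(curImg, levels, polyN, polySigma);
      Img u, v;
      flow_from_pyrs(prev, cur, winsize, iterations, u, v);
      out[t - 1] = flow_mag_sum(u, v);
      prev = std::move(cur);
      prevBuilt = true;
    }
    prevImg = std::move(curImg);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
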