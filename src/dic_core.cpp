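// Core numerics for facet-based digital image correlation.
//
// Image convention throughout: an image is an R numeric matrix with
// nrow = height (y, downwards) and ncol = width (x, rightwards); the centre
// of pixel (x, y) sits at the integer coordinate pair (x, y), 1-based, so
// img(y-1, x-1) in C++ indexing. Intensities are floats, nominally in [0,1].

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cubic convolution interpolation (Keys kernel, a = -0.5)

static inline double cubw(double s) {
  s = std::fabs(s);
  if (s < 1.0) return ((1.5 * s - 2.5) * s) * s + 1.0;
  if (s < 2.0) return ((-0.5 * s + 2.5) * s - 4.0) * s + 2.0;
  return 0.0;
}

// derivative of cubw with respect to its (signed) argument
static inline double cubw_d(double s) {
  double a = std::fabs(s);
  double sgn = (s < 0.0) ? -1.0 : 1.0;
  if (a < 1.0) return sgn * ((4.5 * a - 5.0) * a);
  if (a < 2.0) return sgn * ((-1.5 * a + 5.0) * a - 4.0);
  return 0.0;
}

static inline double sample_clamped(const NumericMatrix &img, int x, int y) {
  if (x < 1) x = 1;
  if (x > img.ncol()) x = img.ncol();
  if (y < 1) y = 1;
  if (y > img.nrow()) y = img.nrow();
  return img(y - 1, x - 1);
}

static double interp_one(const NumericMatrix &img, double x, double y) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double fx = x - ix, fy = y - iy;
  double wx[4], wy[4];
  for (int m = 0; m < 4; ++m) {
    wx[m] = cubw(fx - (m - 1));
    wy[m] = cubw(fy - (m - 1));
  }
  double v = 0.0;
  for (int j = 0; j < 4; ++j) {
    double rowv = 0.0;
    for (int i = 0; i < 4; ++i)
      rowv += wx[i] * sample_clamped(img, ix - 1 + i, iy - 1 + j);
    v += wy[j] * rowv;
  }
  return v;
}

// [[Rcpp::export]]
NumericVector interp_bicubic_cpp(NumericMatrix img, NumericVector x,
                                 NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = interp_one(img, x[i], y[i]);
  return out;
}

// value plus partial derivatives with respect to x and y (per pixel unit)
// [[Rcpp::export]]
NumericMatrix interp_bicubic_grad_cpp(NumericMatrix img, NumericVector x,
                                      NumericVector y) {
  int n = x.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(x[i]), iy = (int)std::floor(y[i]);
    double fx = x[i] - ix, fy = y[i] - iy;
    double wx[4], wy[4], dx[4], dy[4];
    for (int m = 0; m < 4; ++m) {
      wx[m] = cubw(fx - (m - 1));
      wy[m] = cubw(fy - (m - 1));
      dx[m] = cubw_d(fx - (m - 1));
      dy[m] = cubw_d(fy - (m - 1));
    }
    double v = 0.0, gx = 0.0, gy = 0.0;
    for (int j = 0; j < 4; ++j) {
      double rv = 0.0, rg = 0.0;
      for (int k = 0; k < 4; ++k) {
        double s = sample_clamped(img, ix - 1 + k, iy - 1 + j);
        rv += wx[k] * s;
        rg += dx[k] * s;
      }
      v += wy[j] * rv;
      gx += wy[j] * rg;
      gy += dy[j] * rv;
    }
    out(i, 0) = v;
    out(i, 1) = gx;
    out(i, 2) = gy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// ZNCC

// Returns NA_real_ if either patch has zero intensity variance.
// [[Rcpp::export]]
double zncc_cpp(NumericVector a, NumericVector b) {
  int n = a.size();
  if (n != b.size()) stop("patches must have equal size");
  double ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 1e-20 * n || sbb <= 1e-20 * n) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// zncc between a fixed reference patch (flattened, with precomputed mean and
// norm) and an integer-aligned window of def at (cx+du-h .. , cy+dv-h ..)
static double zncc_window(const NumericMatrix &def, const std::vector<double> &f,
                          double fmean, double fnorm, int cx, int cy, int half) {
  int m = 2 * half + 1, n = m * m;
  double gm = 0.0;
  std::vector<double> g((size_t)n);
  int k = 0;
  for (int j = -half; j <= half; ++j)
    for (int i = -half; i <= half; ++i) {
      double v = def(cy + j - 1, cx + i - 1);
      g[k++] = v;
      gm += v;
    }
  gm /= n;
  double sgg = 0.0, sfg = 0.0;
  for (int i = 0; i < n; ++i) {
    double dg = g[i] - gm;
    sgg += dg * dg;
    sfg += (f[i] - fmean) * dg;
  }
  if (sgg <= 1e-20 * n || fnorm * fnorm <= 1e-20 * n) return NA_REAL;
  return sfg / (fnorm * std::sqrt(sgg));
}

// ---------------------------------------------------------------------------
// Integer-pixel ZNCC search.
// Returns (du, dv, zncc, ok). Ties broken by smaller du^2+dv^2, then row-major
// order (dv outer loop from -r, du inner from -r).

// [[Rcpp::export]]
NumericVector integer_search_cpp(NumericMatrix ref, NumericMatrix def, int cx,
                                 int cy, int half, int radius) {
  int m = 2 * half + 1, n = m * m;
  std::vector<double> f((size_t)n);
  double fmean = 0.0;
  int k = 0;
  for (int j = -half; j <= half; ++j)
    for (int i = -half; i <= half; ++i) {
      double v = sample_clamped(ref, cx + i, cy + j);
      f[k++] = v;
      fmean += v;
    }
  fmean /= n;
  double fss = 0.0;
  for (int i = 0; i < n; ++i) fss += (f[i] - fmean) * (f[i] - fmean);
  double fnorm = std::sqrt(fss);

  double best = -2.0;
  int bdu = 0, bdv = 0, bd2 = INT_MAX;
  bool found = false;
  for (int dv = -radius; dv <= radius; ++dv) {
    for (int du = -radius; du <= radius; ++du) {
      int x0 = cx + du, y0 = cy + dv;
      if (x0 - half < 1 || x0 + half > def.ncol() || y0 - half < 1 ||
          y0 + half > def.nrow())
        continue;
      double c = zncc_window(def, f, fmean, fnorm, x0, y0, half);
      if (ISNA(c)) continue;
      int d2 = du * du + dv * dv;
      if (!found || c > best + 1e-12 ||
          (std::fabs(c - best) <= 1e-12 && d2 < bd2)) {
        best = c; bdu = du; bdv = dv; bd2 = d2; found = true;
      }
    }
  }
  return NumericVector::create(_["du"] = (double)bdu, _["dv"] = (double)bdv,
                               _["zncc"] = found ? best : NA_REAL,
                               _["ok"] = found ? 1.0 : 0.0);
}

// ---------------------------------------------------------------------------
// Inverse-compositional Gauss-Newton refinement on the ZNSSD criterion with a
// first-order (affine) facet shape function and bicubic interpolation of the
// deformed image. Warp parameters p = (u, ux, uy, v, vx, vy):
//   x' = x + u + ux*dx + uy*dy,  y' = y + v + vx*dx + vy*dy
// Convergence: sqrt(du^2 + dv^2) of the incremental update below tol.

static bool solve6(double H[6][6], double b[6], double out[6]) {
  // Gaussian elimination with partial pivoting
  double A[6][7];
  for (int i = 0; i < 6; ++i) {
    for (int j = 0; j < 6; ++j) A[i][j] = H[i][j];
    A[i][6] = b[i];
  }
  for (int c = 0; c < 6; ++c) {
    int p = c;
    for (int r = c + 1; r < 6; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[p][c])) p = r;
    if (std::fabs(A[p][c]) < 1e-14) return false;
    if (p != c)
      for (int j = c; j < 7; ++j) std::swap(A[p][j], A[c][j]);
    for (int r = 0; r < 6; ++r) {
      if (r == c) continue;
      double fac = A[r][c] / A[c][c];
      for (int j = c; j < 7; ++j) A[r][j] -= fac * A[c][j];
    }
  }
  for (int i = 0; i < 6; ++i) out[i] = A[i][6] / A[i][i];
  return true;
}

// [[Rcpp::export]]
NumericVector icgn_refine_cpp(NumericMatrix ref, NumericMatrix def, int cx,
                              int cy, int half, NumericVector p_init,
                              double tol, int max_iter) {
  int m = 2 * half + 1, n = m * m;
  std::vector<double> f((size_t)n), fx((size_t)n), fy((size_t)n),
      dxv((size_t)n), dyv((size_t)n);
  double fmean = 0.0;
  int k = 0;
  for (int j = -half; j <= half; ++j)
    for (int i = -half; i <= half; ++i) {
      f[k] = sample_clamped(ref, cx + i, cy + j);
      // central differences on the reference image
      fx[k] = 0.5 * (sample_clamped(ref, cx + i + 1, cy + j) -
                     sample_clamped(ref, cx + i - 1, cy + j));
      fy[k] = 0.5 * (sample_clamped(ref, cx + i, cy + j + 1) -
                     sample_clamped(ref, cx + i, cy + j - 1));
      dxv[k] = (double)i;
      dyv[k] = (double)j;
      fmean += f[k];
      ++k;
    }
  fmean /= n;
  double fss = 0.0;
  for (int i = 0; i < n; ++i) fss += (f[i] - fmean) * (f[i] - fmean);
  double fnorm = std::sqrt(fss);
  bool f_flat = fss <= 1e-20 * n;
  NumericVector fail = NumericVector::create(
      _["u"] = NA_REAL, _["v"] = NA_REAL, _["ux"] = NA_REAL, _["uy"] = NA_REAL,
      _["vx"] = NA_REAL, _["vy"] = NA_REAL, _["zncc"] = NA_REAL,
      _["converged"] = 0.0, _["iterations"] = 0.0);
  if (f_flat) return fail;

  // steepest-descent images and (constant) Hessian
  double H[6][6] = {{0}};
  std::vector<double> J((size_t)n * 6);
  for (int i = 0; i < n; ++i) {
    double *Ji = &J[(size_t)i * 6];
    Ji[0] = fx[i];
    Ji[1] = fx[i] * dxv[i];
    Ji[2] = fx[i] * dyv[i];
    Ji[3] = fy[i];
    Ji[4] = fy[i] * dxv[i];
    Ji[5] = fy[i] * dyv[i];
    for (int a = 0; a < 6; ++a)
      for (int b = 0; b < 6; ++b) H[a][b] += Ji[a] * Ji[b];
  }

  // warp as 3x3 matrix [[1+ux, uy, u],[vx, 1+vy, v],[0,0,1]]
  double W[3][3] = {{1.0 + p_init[1], p_init[2], p_init[0]},
                    {p_init[4], 1.0 + p_init[5], p_init[3]},
                    {0.0, 0.0, 1.0}};
  std::vector<double> g((size_t)n);
  bool converged = false;
  int iter = 0;
  double last_gmean = 0.0, last_gnorm = 0.0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double gmean = 0.0;
    for (int i = 0; i < n; ++i) {
      double X = cx + W[0][0] * dxv[i] + W[0][1] * dyv[i] + W[0][2];
      double Y = cy + W[1][0] * dxv[i] + W[1][1] * dyv[i] + W[1][2];
      if (X < 1.0 || X > def.ncol() || Y < 1.0 || Y > def.nrow()) return fail;
      g[i] = interp_one(def, X, Y);
      gmean += g[i];
    }
    gmean /= n;
    double gss = 0.0;
    for (int i = 0; i < n; ++i) gss += (g[i] - gmean) * (g[i] - gmean);
    if (gss <= 1e-20 * n) return fail;
    double gnorm = std::sqrt(gss);
    last_gmean = gmean;
    last_gnorm = gnorm;

    double b[6] = {0, 0, 0, 0, 0, 0};
    double ratio = fnorm / gnorm;
    for (int i = 0; i < n; ++i) {
      double e = (f[i] - fmean) - ratio * (g[i] - gmean);
      const double *Ji = &J[(size_t)i * 6];
      for (int a = 0; a < 6; ++a) b[a] += Ji[a] * e;
    }
    double dp[6];
    if (!solve6(H, b, dp)) return fail;
    for (int a = 0; a < 6; ++a) dp[a] = -dp[a];

    // inverse composition: W <- W * inv(dW)
    double dW[3][3] = {{1.0 + dp[1], dp[2], dp[0]},
                       {dp[4], 1.0 + dp[5], dp[3]},
                       {0.0, 0.0, 1.0}};
    double det = dW[0][0] * dW[1][1] - dW[0][1] * dW[1][0];
    if (std::fabs(det) < 1e-12) return fail;
    double iW[3][3];
    iW[0][0] = dW[1][1] / det;
    iW[0][1] = -dW[0][1] / det;
    iW[1][0] = -dW[1][0] / det;
    iW[1][1] = dW[0][0] / det;
    iW[0][2] = -(iW[0][0] * dW[0][2] + iW[0][1] * dW[1][2]);
    iW[1][2] = -(iW[1][0] * dW[0][2] + iW[1][1] * dW[1][2]);
    iW[2][0] = 0.0; iW[2][1] = 0.0; iW[2][2] = 1.0;
    double Wn[3][3];
    for (int r = 0; r < 2; ++r)
      for (int c = 0; c < 3; ++c)
        Wn[r][c] = W[r][0] * iW[0][c] + W[r][1] * iW[1][c] +
                   ((c == 2) ? W[r][2] : 0.0) * 1.0;
    // note: third row of both is (0,0,1)
    for (int c = 0; c < 3; ++c) { W[0][c] = Wn[0][c]; W[1][c] = Wn[1][c]; }

    double upd = std::sqrt(dp[0] * dp[0] + dp[3] * dp[3]);
    if (upd > (double)(2 * half + 10)) return fail;  // diverging
    if (upd < tol) { converged = true; break; }
  }

  // equivalent ZNCC of the final match
  double sfg = 0.0;
  for (int i = 0; i < n; ++i) sfg += (f[i] - fmean) * (g[i] - last_gmean);
  double zncc = (last_gnorm > 0.0) ? sfg / (fnorm * last_gnorm) : NA_REAL;
  return NumericVector::create(
      _["u"] = W[0][2], _["v"] = W[1][2], _["ux"] = W[0][0] - 1.0,
      _["uy"] = W[0][1], _["vx"] = W[1][0], _["vy"] = W[1][1] - 1.0,
      _["zncc"] = zncc, _["converged"] = converged ? 1.0 : 0.0,
      _["iterations"] = (double)iter);
}

// ---------------------------------------------------------------------------
// Track one frame: for each facet centre run (optionally) an integer search
// followed by IC-GN refinement. init columns (u, v) may be NA to force an
// integer search.

// [[Rcpp::export]]
NumericMatrix track_frame_cpp(NumericMatrix ref, NumericMatrix def,
                              IntegerVector cx, IntegerVector cy, int half,
                              int radius, NumericMatrix init, double tol,
                              int max_iter) {
  int nf = cx.size();
  NumericMatrix out(nf, 5);  // u, v, zncc, converged, iterations
  colnames(out) = CharacterVector::create("u", "v", "zncc", "converged",
                                          "iterations");
  NumericVector p0(6);
  for (int i = 0; i < nf; ++i) {
    double ui = init(i, 0), vi = init(i, 1);
    bool have_init = !ISNA(ui) && !ISNAN(ui) && !ISNA(vi) && !ISNAN(vi);
    bool searched = false;
    if (!have_init) {
      NumericVector s = integer_search_cpp(ref, def, cx[i], cy[i], half, radius);
      searched = true;
      if (s["ok"] == 0.0) {
        out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
        out(i, 3) = 0.0; out(i, 4) = 0.0;
        continue;
      }
      ui = s["du"]; vi = s["dv"];
    }
    for (int a = 0; a < 6; ++a) p0[a] = 0.0;
    p0[0] = ui; p0[3] = vi;
    NumericVector r = icgn_refine_cpp(ref, def, cx[i], cy[i], half, p0, tol,
                                      max_iter);
    if ((r["converged"] == 0.0 || ISNA((double)r["zncc"])) && !searched) {
      // retry from a fresh integer search around the initialization
      NumericVector s = integer_search_cpp(ref, def, cx[i], cy[i], half, radius);
      if (s["ok"] == 1.0) {
        for (int a = 0; a < 6; ++a) p0[a] = 0.0;
        p0[0] = s["du"]; p0[3] = s["dv"];
        r = icgn_refine_cpp(ref, def, cx[i], cy[i], half, p0, tol, max_iter);
      }
    }
    out(i, 0) = r["u"]; out(i, 1) = r["v"]; out(i, 2) = r["zncc"];
    out(i, 3) = r["converged"]; out(i, 4) = r["iterations"];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Speckle rasterization: hard-edged discs of intensity `dot` on a `bg` field.

// [[Rcpp::export]]
NumericMatrix draw_dots_cpp(int width, int height, NumericVector x,
                            NumericVector y, NumericVector r, double bg,
                            double dot) {
  NumericMatrix img(height, width);
  std::fill(img.begin(), img.end(), bg);
  int nd = x.size();
  for (int d = 0; d < nd; ++d) {
    double rr = r[d];
    if (rr <= 0) continue;
    int x0 = std::max(1, (int)std::floor(x[d] - rr));
    int x1 = std::min(width, (int)std::ceil(x[d] + rr));
    int y0 = std::max(1, (int)std::floor(y[d] - rr));
    int y1 = std::min(height, (int)std::ceil(y[d] + rr));
    double r2 = rr * rr;
    for (int yy = y0; yy <= y1; ++yy) {
      double dy = yy - y[d];
      for (int xx = x0; xx <= x1; ++xx) {
        double dx = xx - x[d];
        if (dx * dx + dy * dy <= r2) img(yy - 1, xx - 1) = dot;
      }
    }
  }
  return img;
}

// Separable Gaussian blur, kernel truncated at 3 sigma, edge-replicated.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  int H = img.nrow(), W = img.ncol();
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern((size_t)(2 * rad + 1));
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + rad];
  }
  for (auto &v : kern) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int xx = std::min(W - 1, std::max(0, x + i));
        acc += kern[i + rad] * img(y, xx);
      }
      tmp(y, x) = acc;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int yy = std::min(H - 1, std::max(0, y + i));
        acc += kern[i + rad] * tmp(yy, x);
      }
      out(y, x) = acc;
    }
  return out;
}
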