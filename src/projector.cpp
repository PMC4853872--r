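#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parallel-beam geometry. Image is an n x n R matrix (column-major), pixel
// size 1 in detector-step units, grid centred on the origin. Pixel (row r,
// col c) has centre x = c - (n-1)/2, y = (n-1)/2 - r (y up, row 0 on top).
// A ray at angle theta (rad) travels along u = (-sin, cos); its detector
// coordinate is s = x cos + y sin. theta = 0 sends rays along +y so that the
// sinogram row equals an x-profile; theta grows counterclockwise.

struct RayHit {
  std::vector<int> idx;   // column-major pixel index r + c*n
  std::vector<double> w;  // intersection length (pixel units)
};

static void trace_ray(int n, double theta, double s, bool binary, RayHit &hit) {
  hit.idx.clear();
  hit.w.clear();
  const double ux = -std::sin(theta), uy = std::cos(theta);
  const double px = s * std::cos(theta), py = s * std::sin(theta);
  const double h = n / 2.0;
  // slab intersection of the line p + t*u with the box [-h, h]^2
  double tmin = -1e30, tmax = 1e30;
  const double eps = 1e-12;
  if (std::fabs(ux) < eps) {
    if (px <= -h || px >= h) return;
  } else {
    double t1 = (-h - px) / ux, t2 = (h - px) / ux;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (std::fabs(uy) < eps) {
    if (py <= -h || py >= h) return;
  } else {
    double t1 = (-h - py) / uy, t2 = (h - py) / uy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (tmax - tmin < eps) return;
  double t = tmin;
  int guard = 0, maxsteps = 4 * n + 8;
  while (t < tmax - 1e-9 && guard++ < maxsteps) {
    // grid coordinates in [0, n]
    double gx = px + t * ux + h;
    double gy = py + t * uy + h;
    double tx = 1e30, ty = 1e30;
    if (ux > eps) {
      double nx = std::floor(gx + 1e-9) + 1.0;
      tx = t + (nx - gx) / ux;
    } else if (ux < -eps) {
      double nx = std::ceil(gx - 1e-9) - 1.0;
      tx = t + (nx - gx) / ux;
    }
    if (uy > eps) {
      double ny = std::floor(gy + 1e-9) + 1.0;
      ty = t + (ny - gy) / uy;
    } else if (uy < -eps) {
      double ny = std::ceil(gy - 1e-9) - 1.0;
      ty = t + (ny - gy) / uy;
    }
    double tn = std::min(std::min(tx, ty), tmax);
    if (tn <= t + 1e-12) tn = t + 1e-9;
    double tm = 0.5 * (t + tn);
    double xm = px + tm * ux + h;
    double ym = py + tm * uy + h;
    int c = (int)std::floor(xm);
    int r = n - 1 - (int)std::floor(ym);
    if (c >= 0 && c < n && r >= 0 && r < n) {
      double len = tn - t;
      if (len > 1e-9) {
        hit.idx.push_back(r + c * n);
        hit.w.push_back(binary ? 1.0 : len);
      }
    }
    t = tn;
  }
}

// [[Rcpp::export]]
List ray_weights_cpp(int n, NumericVector angles, NumericVector s, bool binary) {
  // triplets for the full system matrix W (rows = rays in angle-major order)
  std::vector<int> ri, ci;
  std::vector<double> wv;
  RayHit hit;
  int M = angles.size(), P = s.size();
  for (int a = 0; a < M; ++a) {
    for (int k = 0; k < P; ++k) {
      trace_ray(n, angles[a], s[k], binary, hit);
      int row = a * P + k;
      for (size_t q = 0; q < hit.idx.size(); ++q) {
        ri.push_back(row);
        ci.push_back(hit.idx[q]);
        wv.push_back(hit.w[q]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["w"] = wrap(wv),
                      _["nrow"] = M * P, _["ncol"] = n * n);
}

// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericMatrix f, NumericVector angles,
                                  NumericVector s, bool binary) {
  int n = f.nrow();
  int M = angles.size(), P = s.size();
  NumericMatrix p(M, P);
  RayHit hit;
  const double *fp = f.begin();
  for (int a = 0; a < M; ++a) {
    for (int k = 0; k < P; ++k) {
      trace_ray(n, angles[a], s[k], binary, hit);
      double acc = 0.0;
      for (size_t q = 0; q < hit.idx.size(); ++q) acc += hit.w[q] * fp[hit.idx[q]];
      p(a, k) = acc;
    }
  }
  return p;
}

// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix r, NumericVector angles,
                              NumericVector s, int n, bool binary) {
  // W^T r  (unfiltered algebraic backprojection)
  int M = angles.size(), P = s.size();
  NumericMatrix img(n, n);
  double *ip = img.begin();
  RayHit hit;
  for (int a = 0; a < M; ++a) {
    for (int k = 0; k < P; ++k) {
      double v = r(a, k);
      if (v == 0.0) continue;
      trace_ray(n, angles[a], s[k], binary, hit);
      for (size_t q = 0; q < hit.idx.size(); ++q) ip[hit.idx[q]] += hit.w[q] * v;
    }
  }
  return img;
}

// compressed row storage of W built once for the iterative solvers
struct CSR {
  std::vector<int> ptr, col;
  std::vector<double> val;
  int nrow, ncol;
};

static void build_csr(int n, NumericVector angles, NumericVector s, bool binary,
                      CSR &W) {
  int M = angles.size(), P = s.size();
  W.nrow = M * P;
  W.ncol = n * n;
  W.ptr.assign(1, 0);
  RayHit hit;
  for (int a = 0; a < M; ++a) {
    for (int k = 0; k < P; ++k) {
      trace_ray(n, angles[a], s[k], binary, hit);
      for (size_t q = 0; q < hit.idx.size(); ++q) {
        W.col.push_back(hit.idx[q]);
        W.val.push_back(hit.w[q]);
      }
      W.ptr.push_back((int)W.col.size());
    }
  }
}

// [[Rcpp::export]]
List sirt_cpp(NumericMatrix p, NumericVector angles, NumericVector s, int n,
              double relax, int n_iter, bool binary, bool nonneg,
              NumericMatrix init) {
  int M = angles.size(), P = s.size();
  CSR W;
  build_csr(n, angles, s, binary, W);
  int nray = W.nrow, npix = W.ncol;
  std::vector<double> f(init.begin(), init.end());
  std::vector<double> rowsum(nray, 0.0), colsum(npix, 0.0);
  for (int i = 0; i < nray; ++i)
    for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q) {
      rowsum[i] += W.val[q];
      colsum[W.col[q]] += W.val[q];
    }
  std::vector<double> pr(nray);
  for (int a = 0; a < M; ++a)
    for (int k = 0; k < P; ++k) pr[a * P + k] = p(a, k);
  NumericVector resid(n_iter);
  std::vector<double> r(nray), corr(npix);
  for (int it = 0; it < n_iter; ++it) {
    double rn = 0.0;
    for (int i = 0; i < nray; ++i) {
      double acc = 0.0;
      for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q) acc += W.val[q] * f[W.col[q]];
      double d = pr[i] - acc;
      rn += d * d;
      r[i] = rowsum[i] > 0 ? d / rowsum[i] : 0.0;
    }
    resid[it] = std::sqrt(rn);
    std::fill(corr.begin(), corr.end(), 0.0);
    for (int i = 0; i < nray; ++i)
      for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q)
        corr[W.col[q]] += W.val[q] * r[i];
    for (int j = 0; j < npix; ++j) {
      if (colsum[j] > 0) f[j] += relax * corr[j] / colsum[j];
      if (nonneg && f[j] < 0) f[j] = 0.0;
    }
  }
  NumericMatrix out(n, n);
  std::copy(f.begin(), f.end(), out.begin());
  return List::create(_["f"] = out, _["residuals"] = resid);
}

// [[Rcpp::export]]
List art_cpp(NumericMatrix p, NumericVector angles, NumericVector s, int n,
             double relax, int n_iter, bool binary, bool nonneg,
             NumericMatrix init) {
  int M = angles.size(), P = s.size();
  CSR W;
  build_csr(n, angles, s, binary, W);
  int nray = W.nrow, npix = W.ncol;
  std::vector<double> f(init.begin(), init.end());
  std::vector<double> nrm2(nray, 0.0);
  for (int i = 0; i < nray; ++i)
    for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q)
      nrm2[i] += W.val[q] * W.val[q];
  std::vector<double> pr(nray);
  for (int a = 0; a < M; ++a)
    for (int k = 0; k < P; ++k) pr[a * P + k] = p(a, k);
  NumericVector resid(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < nray; ++i) {
      if (nrm2[i] <= 0) continue;
      double acc = 0.0;
      for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q) acc += W.val[q] * f[W.col[q]];
      double upd = relax * (pr[i] - acc) / nrm2[i];
      for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q) {
        f[W.col[q]] += upd * W.val[q];
        if (nonneg && f[W.col[q]] < 0) f[W.col[q]] = 0.0;
      }
    }
    double rn = 0.0;
    for (int i = 0; i < nray; ++i) {
      double acc = 0.0;
      for (int q = W.ptr[i]; q < W.ptr[i + 1]; ++q) acc += W.val[q] * f[W.col[q]];
      double d = pr[i] - acc;
      rn += d * d;
    }
    resid[it] = std::sqrt(rn);
  }
  NumericMatrix out(n, n);
  std::copy(f.begin(), f.end(), out.begin());
  return List::create(_["f"] = out, _["residuals"] = resid);
}

// [[Rcpp::export]]
NumericMatrix fbp_backproject_cpp(NumericMatrix q, NumericVector angles,
                                  double s0, double ds, int n) {
  // smear filtered projections back with linear interpolation along s
  int M = angles.size(), P = q.ncol();
  NumericMatrix img(n, n);
  double c0 = (n - 1) / 2.0;
  for (int a = 0; a < M; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int c = 0; c < n; ++c) {
      double x = c - c0;
      double tx = x * ct;
      for (int r = 0; r < n; ++r) {
        double y = c0 - r;
        double t = tx + y * st;
        double k = (t - s0) / ds;
        int k0 = (int)std::floor(k);
        if (k0 < 0 || k0 >= P - 1) continue;
        double fr = k - k0;
        img(r, c) += q(a, k0) * (1.0 - fr) + q(a, k0 + 1) * fr;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
List southwell_cpp(NumericMatrix gx, NumericMatrix gy, double w,
                   bool gauss_seidel, int max_iter, double tol) {
  // Staggered least-squares integration of a gradient pair; gx, gy are in
  // rad/pixel. NA gradients sever the corresponding neighbour link.
  int nr = gx.nrow(), nc = gx.ncol();
  NumericMatrix phi(nr, nc), phin(nr, nc);
  double maxch = R_PosInf;
  int it = 0;
  auto link = [](double a, double b) {
    if (NumericVector::is_na(a) || NumericVector::is_na(b)) return NA_REAL;
    return 0.5 * (a + b);
  };
  for (it = 0; it < max_iter; ++it) {
    maxch = 0.0;
    NumericMatrix &src = gauss_seidel ? phi : phi;
    NumericMatrix &dst = gauss_seidel ? phi : phin;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double num = 0.0;
        int cnt = 0;
        if (j + 1 < nc) {
          double l = link(gx(i, j), gx(i, j + 1));
          if (!NumericVector::is_na(l)) { num += src(i, j + 1) - l; ++cnt; }
        }
        if (j - 1 >= 0) {
          double l = link(gx(i, j - 1), gx(i, j));
          if (!NumericVector::is_na(l)) { num += src(i, j - 1) + l; ++cnt; }
        }
        if (i + 1 < nr) {
          double l = link(gy(i, j), gy(i + 1, j));
          if (!NumericVector::is_na(l)) { num += src(i + 1, j) - l; ++cnt; }
        }
        if (i - 1 >= 0) {
          double l = link(gy(i - 1, j), gy(i, j));
          if (!NumericVector::is_na(l)) { num += src(i - 1, j) + l; ++cnt; }
        }
        double nv = cnt > 0 ? (1.0 - w) * src(i, j) + w * num / cnt : src(i, j);
        double ch = std::fabs(nv - src(i, j));
        if (ch > maxch) maxch = ch;
        dst(i, j) = nv;
      }
    }
    if (!gauss_seidel) {
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) phi(i, j) = phin(i, j);
    }
    if (maxch < tol) { ++it; break; }
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["converged"] = maxch < tol, _["max_change"] = maxch);
}

// [[Rcpp::export]]
List local_stats_cpp(NumericMatrix x, int k) {
  // windowed median and median absolute deviation (window k x k, clipped at
  // the frame border) used by the hot-pixel detector
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix med(nr, nc), mad(nr, nc);
  std::vector<double> buf;
  buf.reserve(k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -h; di <= h; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          if (ii == i && jj == j) continue;  // centre excluded: robust to itself
          buf.push_back(x(ii, jj));
        }
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double mv = buf[m];
      med(i, j) = mv;
      for (size_t q = 0; q < buf.size(); ++q) buf[q] = std::fabs(buf[q] - mv);
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      mad(i, j) = buf[m];
    }
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}
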