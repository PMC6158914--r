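// Numerical core: grayscale morphology, rank/box/Gaussian filters, the BSCB
// inpainting sweeps, the local Chan-Vese evolution loop, and small binary
// mask utilities (8-connected labeling, hole filling, disc dilation).
//
// Conventions shared with the R layer:
//  - matrices are H x W, row = i (y direction), col = j (x direction);
//  - spatial derivatives use central differences on a unit grid;
//  - out-of-frame indices reflect at the border (symmetric reflection, the
//    edge pixel is duplicated), so constant images are exact fixed points
//    of every stencil.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i; else i = 2 * n - 1 - i;
  }
  return i;
}

// ---------------------------------------------------------------------------
// Grayscale morphology with a flat rectangular structuring element.
// Offsets [o0, o1] describe the SE footprint relative to its anchor; erosion
// takes the window minimum over p + o, dilation over p - o (reflected SE).
// The window is clipped at the frame, which for min/max filters coincides
// with border reflection.
// ---------------------------------------------------------------------------
static NumericMatrix minmax_filter(const NumericMatrix& x, int o0, int o1,
                                   bool take_min) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {   // horizontal pass
    int j0 = std::max(0, j + o0), j1 = std::min(W - 1, j + o1);
    for (int i = 0; i < H; ++i) {
      double v = x(i, j0);
      for (int jj = j0 + 1; jj <= j1; ++jj) {
        double u = x(i, jj);
        if (take_min ? (u < v) : (u > v)) v = u;
      }
      tmp(i, j) = v;
    }
  }
  for (int j = 0; j < W; ++j) {   // vertical pass
    for (int i = 0; i < H; ++i) {
      int i0 = std::max(0, i + o0), i1 = std::min(H - 1, i + o1);
      double v = tmp(i0, j);
      for (int ii = i0 + 1; ii <= i1; ++ii) {
        double u = tmp(ii, j);
        if (take_min ? (u < v) : (u > v)) v = u;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode(NumericMatrix x, int o0, int o1) {
  return minmax_filter(x, o0, o1, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate(NumericMatrix x, int o0, int o1) {
  return minmax_filter(x, -o1, -o0, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2, n = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(n);
  std::vector<const double*> cols(k);
  std::vector<int> ri(k);
  const double* xp = x.begin();
  for (int j = 0; j < W; ++j) {
    for (int d = -r; d <= r; ++d) cols[d + r] = xp + (size_t)refl(j + d, W) * H;
    for (int i = 0; i < H; ++i) {
      for (int d = -r; d <= r; ++d) ri[d + r] = refl(i + d, H);
      int m = 0;
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) buf[m++] = cols[b][ri[a]];
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_box_mean(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) s += x(refl(i + d, H), j);
      tmp(i, j) = s / k;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) s += tmp(i, refl(j + d, W));
      out(i, j) = s / k;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma) {
  const int H = x.nrow(), W = x.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int d = -r; d <= r; ++d) {
    w[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += w[d + r];
  }
  for (auto& v : w) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) a += w[d + r] * x(refl(i + d, H), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) a += w[d + r] * tmp(i, refl(j + d, W));
      out(i, j) = a;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Fast full-frame stencils (pointer loops, reflected borders)
// ---------------------------------------------------------------------------

// Second differences along columns (x) and rows (y).
static void second_diffs(const double* u, int H, int W,
                         double* uxx, double* uyy) {
  for (int j = 0; j < W; ++j) {
    const double* cm = u + (size_t)(j == 0 ? 0 : j - 1) * H;
    const double* cc = u + (size_t)j * H;
    const double* cp = u + (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
    double* ox = uxx + (size_t)j * H;
    double* oy = uyy + (size_t)j * H;
    for (int i = 0; i < H; ++i) ox[i] = cm[i] - 2.0 * cc[i] + cp[i];
    if (H == 1) { oy[0] = 0.0; continue; }
    oy[0] = cc[1] - cc[0];                 // u[-1] reflects to u[0]
    for (int i = 1; i < H - 1; ++i)
      oy[i] = cc[i - 1] - 2.0 * cc[i] + cc[i + 1];
    oy[H - 1] = cc[H - 2] - cc[H - 1];
  }
}

// Separable 3x3 mean, src -> dst, using scratch.
static void box3(const double* src, int H, int W, double* scratch,
                 double* dst) {
  for (int j = 0; j < W; ++j) {
    const double* cc = src + (size_t)j * H;
    double* t = scratch + (size_t)j * H;
    if (H == 1) { t[0] = cc[0]; continue; }
    t[0] = (2.0 * cc[0] + cc[1]) / 3.0;
    for (int i = 1; i < H - 1; ++i)
      t[i] = (cc[i - 1] + cc[i] + cc[i + 1]) / 3.0;
    t[H - 1] = (cc[H - 2] + 2.0 * cc[H - 1]) / 3.0;
  }
  for (int j = 0; j < W; ++j) {
    const double* cm = scratch + (size_t)(j == 0 ? 0 : j - 1) * H;
    const double* cc = scratch + (size_t)j * H;
    const double* cp = scratch + (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
    double* o = dst + (size_t)j * H;
    for (int i = 0; i < H; ++i) o[i] = (cm[i] + cc[i] + cp[i]) / 3.0;
  }
}

// Central-difference gradient; writes gx, gy (either may be nullptr-free:
// always both) and, when gm/nx/ny given, the magnitude and the normalized
// field with regularizer `reg`.
static void grad_fields(const double* u, int H, int W, double* nx, double* ny,
                        double* gm, double reg) {
  for (int j = 0; j < W; ++j) {
    const double* cm = u + (size_t)(j == 0 ? 0 : j - 1) * H;
    const double* cc = u + (size_t)j * H;
    const double* cp = u + (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
    double* ax = nx + (size_t)j * H;
    double* ay = ny + (size_t)j * H;
    double* am = gm + (size_t)j * H;
    for (int i = 0; i < H; ++i) {
      const int im = i == 0 ? 0 : i - 1, ip = i == H - 1 ? H - 1 : i + 1;
      const double ux = 0.5 * (cp[i] - cm[i]);
      const double uy = 0.5 * (cc[ip] - cc[im]);
      const double m = std::sqrt(ux * ux + uy * uy);
      am[i] = m;
      ax[i] = ux / (m + reg);
      ay[i] = uy / (m + reg);
    }
  }
}

// ---------------------------------------------------------------------------
// BSCB inpainting
// ---------------------------------------------------------------------------

// Propagation information L: second differences, optionally averaged over
// the 3x3 neighborhood, combined as a sum (discrete Laplacian) or product.
static void compute_L(const std::vector<double>& u, int H, int W,
                      bool nbhd_mean, bool product,
                      std::vector<double>& uxx, std::vector<double>& uyy,
                      std::vector<double>& sc1, std::vector<double>& sc2,
                      std::vector<double>& L) {
  const size_t N = (size_t)H * W;
  second_diffs(u.data(), H, W, uxx.data(), uyy.data());
  const double* pxx = uxx.data();
  const double* pyy = uyy.data();
  if (nbhd_mean) {
    box3(uxx.data(), H, W, L.data(), sc1.data());  // L as scratch
    box3(uyy.data(), H, W, L.data(), sc2.data());
    pxx = sc1.data();
    pyy = sc2.data();
  }
  if (product)
    for (size_t p = 0; p < N; ++p) L[p] = pxx[p] * pyy[p];
  else
    for (size_t p = 0; p < N; ++p) L[p] = pxx[p] + pyy[p];
}

// One Jacobi transport sweep over Omega; returns mean |update| per Omega px.
// The update is dt * beta * |grad u|_sl with beta = grad(L) . T (central
// differences, T the unit isophote direction) and |grad u|_sl the
// slope-limited upwind gradient norm chosen by the sign of beta; the upwind
// norm is what keeps the explicit transport stable and lets it act in
// near-flat regions only in proportion to the actual local contrast.
static double inpaint_sweep(std::vector<double>& u, int H, int W,
                            const std::vector<int>& om, double dt,
                            bool nbhd_mean, bool product,
                            std::vector<double>& uxx, std::vector<double>& uyy,
                            std::vector<double>& sc1, std::vector<double>& sc2,
                            std::vector<double>& L, std::vector<double>& upd,
                            int iter) {
  if (om.empty()) return 0.0;
  compute_L(u, H, W, nbhd_mean, product, uxx, uyy, sc1, sc2, L);
  double acc = 0.0;
  for (size_t t = 0; t < om.size(); ++t) {
    const int p = om[t], i = p % H, j = p / H;
    const size_t im = (i == 0 ? 0 : i - 1), ip = (i == H - 1 ? H - 1 : i + 1);
    const size_t jm = (size_t)(j == 0 ? 0 : j - 1) * H;
    const size_t jp = (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
    const size_t jc = (size_t)j * H;
    const double Lx = 0.5 * (L[i + jp] - L[i + jm]);
    const double Ly = 0.5 * (L[ip + jc] - L[im + jc]);
    const double ux = 0.5 * (u[i + jp] - u[i + jm]);
    const double uy = 0.5 * (u[ip + jc] - u[im + jc]);
    const double m = std::sqrt(ux * ux + uy * uy);
    double d = 0.0;
    if (m >= 1e-8) {
      const double Tx = -uy / m, Ty = ux / m;  // unit isophote direction
      const double beta = Lx * Tx + Ly * Ty;
      const double uxb = u[i + jc] - u[i + jm], uxf = u[i + jp] - u[i + jc];
      const double uyb = u[i + jc] - u[im + jc], uyf = u[ip + jc] - u[i + jc];
      double sl;
      if (beta > 0)
        sl = std::sqrt(std::pow(std::min(uxb, 0.0), 2) +
                       std::pow(std::max(uxf, 0.0), 2) +
                       std::pow(std::min(uyb, 0.0), 2) +
                       std::pow(std::max(uyf, 0.0), 2));
      else
        sl = std::sqrt(std::pow(std::max(uxb, 0.0), 2) +
                       std::pow(std::min(uxf, 0.0), 2) +
                       std::pow(std::max(uyb, 0.0), 2) +
                       std::pow(std::min(uyf, 0.0), 2));
      d = dt * beta * sl;
    }
    if (!std::isfinite(d))
      stop("non-finite inpainting update at iteration %d; reduce dt", iter);
    upd[t] = d;
    acc += std::fabs(d);
  }
  for (size_t t = 0; t < om.size(); ++t) u[om[t]] += upd[t];
  return acc / om.size();
}

// One Jacobi curvature-diffusion sweep over the band Omega^eps.
static void diffuse_sweep(std::vector<double>& u, int H, int W,
                          const std::vector<int>& band,
                          const std::vector<double>& g, double dt,
                          std::vector<double>& nx, std::vector<double>& ny,
                          std::vector<double>& gm, std::vector<double>& upd,
                          int iter) {
  if (band.empty()) return;
  grad_fields(u.data(), H, W, nx.data(), ny.data(), gm.data(), 1e-8);
  for (size_t t = 0; t < band.size(); ++t) {
    const int p = band[t], i = p % H, j = p / H;
    const size_t im = (i == 0 ? 0 : i - 1), ip = (i == H - 1 ? H - 1 : i + 1);
    const size_t jm = (size_t)(j == 0 ? 0 : j - 1) * H;
    const size_t jp = (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
    const size_t jc = (size_t)j * H;
    const double kappa = 0.5 * (nx[i + jp] - nx[i + jm]) +
                         0.5 * (ny[ip + jc] - ny[im + jc]);
    const double d = dt * g[p] * kappa * gm[p];
    if (!std::isfinite(d))
      stop("non-finite diffusion update at iteration %d; reduce dt", iter);
    upd[t] = d;
  }
  for (size_t t = 0; t < band.size(); ++t) u[band[t]] += upd[t];
}

static std::vector<int> which_idx(const LogicalMatrix& m) {
  std::vector<int> idx;
  const int n = m.nrow() * m.ncol();
  for (int p = 0; p < n; ++p)
    if (m[p]) idx.push_back(p);
  return idx;
}

// [[Rcpp::export]]
NumericMatrix cpp_propagation_info(NumericMatrix u, bool nbhd_mean,
                                   bool product) {
  const int H = u.nrow(), W = u.ncol();
  const size_t N = (size_t)H * W;
  std::vector<double> uv(u.begin(), u.end());
  std::vector<double> uxx(N), uyy(N), sc1(N), sc2(N), L(N);
  compute_L(uv, H, W, nbhd_mean, product, uxx, uyy, sc1, sc2, L);
  NumericMatrix out(H, W);
  std::copy(L.begin(), L.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_inpaint_sweep(NumericMatrix u, LogicalMatrix omega, double dt,
                       bool nbhd_mean, bool product, int iter) {
  const int H = u.nrow(), W = u.ncol();
  const size_t N = (size_t)H * W;
  std::vector<double> uv(u.begin(), u.end());
  std::vector<int> om = which_idx(omega);
  std::vector<double> uxx(N), uyy(N), sc1(N), sc2(N), L(N), upd(om.size());
  double res = inpaint_sweep(uv, H, W, om, dt, nbhd_mean, product,
                             uxx, uyy, sc1, sc2, L, upd, iter);
  NumericMatrix out(H, W);
  std::copy(uv.begin(), uv.end(), out.begin());
  return List::create(_["u"] = out, _["residual"] = res);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_sweep(NumericMatrix u, LogicalMatrix band,
                                NumericMatrix g, double dt, int iter) {
  const int H = u.nrow(), W = u.ncol();
  const size_t N = (size_t)H * W;
  std::vector<double> uv(u.begin(), u.end());
  std::vector<double> gv(g.begin(), g.end());
  std::vector<int> bd = which_idx(band);
  std::vector<double> nx(N), ny(N), gm(N), upd(bd.size());
  diffuse_sweep(uv, H, W, bd, gv, dt, nx, ny, gm, upd, 0);
  NumericMatrix out(H, W);
  std::copy(uv.begin(), uv.end(), out.begin());
  return out;
}

// Full schedule: blocks of `inpaint_steps` transport sweeps followed by
// `diffuse_steps` diffusion sweeps, until `total_iters` sweeps have run or
// the mean |change| per Omega pixel and sweep over a whole block falls
// below `stop_tol`.  `dt_transport` is the improvement rate for the
// transport half (the caller passes dt/255: beta*|grad u| is quadratic in
// intensity, so the rate applies per unit intensity range); `dt` drives the
// diffusion half, which is linear in intensity.
// [[Rcpp::export]]
List cpp_bscb_run(NumericMatrix u0, LogicalMatrix omega, LogicalMatrix band,
                  NumericMatrix g, double dt_transport, double dt,
                  int total_iters, int inpaint_steps, int diffuse_steps,
                  double stop_tol, bool nbhd_mean, bool product) {
  const int H = u0.nrow(), W = u0.ncol();
  const size_t N = (size_t)H * W;
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> gv(g.begin(), g.end());
  std::vector<int> om = which_idx(omega), bd = which_idx(band);
  std::vector<double> uxx(N), uyy(N), sc1(N), sc2(N), L(N);
  std::vector<double> nx(N), ny(N), gm(N);
  std::vector<double> upd(std::max(om.size(), bd.size()));
  std::vector<double> usnap(om.size());
  int n = 0;
  double res = 0.0;
  bool converged = om.empty();
  while (n < total_iters && !converged) {
    for (size_t t = 0; t < om.size(); ++t) usnap[t] = u[om[t]];
    const int n0 = n;
    for (int s = 0; s < inpaint_steps && n < total_iters; ++s) {
      inpaint_sweep(u, H, W, om, dt_transport, nbhd_mean, product,
                    uxx, uyy, sc1, sc2, L, upd, n);
      ++n;
    }
    for (int s = 0; s < diffuse_steps && n < total_iters; ++s) {
      diffuse_sweep(u, H, W, bd, gv, dt, nx, ny, gm, upd, n);
      ++n;
    }
    double acc = 0.0;
    for (size_t t = 0; t < om.size(); ++t) acc += std::fabs(u[om[t]] - usnap[t]);
    res = acc / om.size() / (n - n0);
    if (res < stop_tol) converged = true;
  }
  NumericMatrix out(H, W);
  std::copy(u.begin(), u.end(), out.begin());
  return List::create(_["u"] = out, _["iterations"] = n,
                      _["residual"] = res, _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Local Chan-Vese evolution
// ---------------------------------------------------------------------------

static inline double heavi(double z, double eps) {
  return 0.5 * (1.0 + (2.0 / M_PI) * std::atan(z / eps));
}
static inline double dirac(double z, double eps) {
  return (1.0 / M_PI) * eps / (eps * eps + z * z);
}

// `steps` explicit gradient-descent iterations on the LCV energy
//   mu * Length(phi) + int_in (I-c1)^2 + int_out (I-c2)^2
//   + alpha * [ int_in (Id-d1)^2 + int_out (Id-d2)^2 ],
// Id = boxmean(I) - I precomputed by the caller.  Records the energy of the
// current phi at the start of every iteration.
// The domain weight `w` (0/1) restricts the model to a region of interest
// (the optic disc): pixels with w = 0 contribute to no integral and their
// phi is frozen.
// [[Rcpp::export]]
List cpp_lcv_chunk(NumericMatrix I, NumericMatrix Id, NumericMatrix phi0,
                   NumericMatrix w, double alpha, double mu, double dt,
                   double eps, int steps, double clamp) {
  const int H = I.nrow(), W = I.ncol();
  const size_t N = (size_t)H * W;
  const double* Ip = I.begin();
  const double* Dp = Id.begin();
  const double* wp = w.begin();
  std::vector<double> phi(phi0.begin(), phi0.end()), phin(N);
  std::vector<double> Hs(N), dl(N), nx(N), ny(N), gm(N);
  NumericVector energy(steps);
  for (int s = 0; s < steps; ++s) {
    double sw = 0, sH = 0, sI1 = 0, sI0 = 0, sD1 = 0, sD0 = 0;
    for (size_t p = 0; p < N; ++p) {
      const double z = phi[p];
      const double h = heavi(z, eps);
      const double v = wp[p];
      Hs[p] = h;
      dl[p] = dirac(z, eps);
      sw += v;
      sH += v * h;
      sI1 += v * h * Ip[p];
      sI0 += v * (1.0 - h) * Ip[p];
      sD1 += v * h * Dp[p];
      sD0 += v * (1.0 - h) * Dp[p];
    }
    const double a1 = sH, a0 = sw - sH;
    const double c1 = a1 > 1e-12 ? sI1 / a1 : 0.0;
    const double c2 = a0 > 1e-12 ? sI0 / a0 : 0.0;
    const double d1 = a1 > 1e-12 ? sD1 / a1 : 0.0;
    const double d2 = a0 > 1e-12 ? sD0 / a0 : 0.0;
    grad_fields(phi.data(), H, W, nx.data(), ny.data(), gm.data(), 1e-8);
    double en = 0.0;
    for (int j = 0; j < W; ++j) {
      const size_t jc = (size_t)j * H;
      const size_t jm = (size_t)(j == 0 ? 0 : j - 1) * H;
      const size_t jp = (size_t)(j == W - 1 ? W - 1 : j + 1) * H;
      for (int i = 0; i < H; ++i) {
        const size_t p = i + jc;
        if (wp[p] == 0.0) { phin[p] = phi[p]; continue; }
        const size_t im = (i == 0 ? 0 : i - 1), ip = (i == H - 1 ? H - 1 : i + 1);
        const double h = Hs[p];
        const double rg = Ip[p] - c1, rb = Ip[p] - c2;
        const double lg = Dp[p] - d1, lb = Dp[p] - d2;
        en += mu * dl[p] * gm[p] + h * rg * rg + (1.0 - h) * rb * rb +
              alpha * (h * lg * lg + (1.0 - h) * lb * lb);
        const double kappa = 0.5 * (nx[i + jp] - nx[i + jm]) +
                             0.5 * (ny[ip + jc] - ny[im + jc]);
        const double F = mu * kappa - rg * rg + rb * rb -
                         alpha * (lg * lg - lb * lb);
        // clamp the per-iteration displacement to one pixel: the explicit
        // scheme otherwise violates its CFL bound for stiff settings
        // (large mu), making the front chatter
        double d = dt * dl[p] * F;
        if (d > clamp) d = clamp; else if (d < -clamp) d = -clamp;
        phin[p] = phi[p] + d;
      }
    }
    if (!std::isfinite(en) || !std::isfinite(phin[0]))
      stop("non-finite level-set update; reduce dt");
    energy[s] = en;
    phi.swap(phin);
  }
  NumericMatrix out(H, W);
  std::copy(phi.begin(), phi.end(), out.begin());
  return List::create(_["phi"] = out, _["energy"] = energy);
}

// ---------------------------------------------------------------------------
// Binary mask utilities
// ---------------------------------------------------------------------------

// 8-connected labeling of foreground pixels, labels 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (m(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * H);
            }
          }
      }
    }
  return lab;
}

// Fill interior holes: background is flood-filled 4-connectedly from the
// frame border; unreached background pixels are holes.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  LogicalMatrix outside(H, W);
  std::vector<int> stack;
  auto push = [&](int i, int j) {
    if (i >= 0 && i < H && j >= 0 && j < W && !m(i, j) && !outside(i, j)) {
      outside(i, j) = true;
      stack.push_back(i + j * H);
    }
  };
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int i = p % H, j = p / H;
    push(i - 1, j); push(i + 1, j); push(i, j - 1); push(i, j + 1);
  }
  LogicalMatrix out(H, W);
  for (int p = 0; p < H * W; ++p) out[p] = m[p] || !outside[p];
  return out;
}

// Dilation by a Euclidean disc: q is set if some true p has |p-q| <= radius.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(LogicalMatrix m, double radius) {
  const int H = m.nrow(), W = m.ncol();
  const int r = (int)std::floor(radius);
  std::vector<std::pair<int, int>> off;
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      if (di * di + dj * dj <= radius * radius) off.push_back({di, dj});
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!m(i, j)) continue;
      for (auto& d : off) {
        const int qi = i + d.first, qj = j + d.second;
        if (qi >= 0 && qi < H && qj >= 0 && qj < W) out(qi, qj) = true;
      }
    }
  return out;
}
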