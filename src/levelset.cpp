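// Narrow-band-free geodesic-active-contour evolution and 3D connected
// components. The implicit function phi is a (clamped) signed distance in
// millimetres, negative inside the front. Per iteration:
//
//   phi_t = -(F)|grad phi|_upwind            balloon / barrier term
//         + curv_w * g * kappa |grad phi|    curvature regularisation
//         + advect_w * (grad g . grad phi)   edge attraction (upwind)
//
// with F = prop_w * g * region - barrier, where `region` in [-1, 1] is a
// blood-pool intensity-consistency term: the balloon coasts inside pool,
// stalls at edges, and retreats in tissue whose attenuation departs from
// the seed intensity. All spatial derivatives are spacing-aware.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".ls_evolve")]]
List ls_evolve(NumericVector phi0, NumericVector g, NumericVector region,
               NumericVector barrier,
               IntegerVector dims, NumericVector spacing,
               double prop_w, double curv_w, double advect_w,
               double dt, int max_iter, double conv_tol,
               int reinit_every, double clamp_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> nphi(n), gx(n, 0.0), gy(n, 0.0), gz(n, 0.0);

  // central-difference gradient of the edge-stopping function g
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idx3(i, j, k, nx, ny);
        int ip = idx3(std::min(i + 1, nx - 1), j, k, nx, ny);
        int im = idx3(std::max(i - 1, 0), j, k, nx, ny);
        int jp = idx3(i, std::min(j + 1, ny - 1), k, nx, ny);
        int jm = idx3(i, std::max(j - 1, 0), k, nx, ny);
        int kp = idx3(i, j, std::min(k + 1, nz - 1), nx, ny);
        int km = idx3(i, j, std::max(k - 1, 0), nx, ny);
        gx[c] = (g[ip] - g[im]) / (2.0 * hx);
        gy[c] = (g[jp] - g[jm]) / (2.0 * hy);
        gz[c] = (g[kp] - g[km]) / (2.0 * hz);
      }

  std::vector<signed char> sign_prev(n);
  for (int c = 0; c < n; ++c) sign_prev[c] = phi[c] < 0 ? 1 : 0;

  int it = 0;
  bool converged = false;
  const int check_every = 10;

  for (it = 1; it <= max_iter; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c = idx3(i, j, k, nx, ny);
          double p = phi[c];
          int ip = idx3(std::min(i + 1, nx - 1), j, k, nx, ny);
          int im = idx3(std::max(i - 1, 0), j, k, nx, ny);
          int jp = idx3(i, std::min(j + 1, ny - 1), k, nx, ny);
          int jm = idx3(i, std::max(j - 1, 0), k, nx, ny);
          int kp = idx3(i, j, std::min(k + 1, nz - 1), nx, ny);
          int km = idx3(i, j, std::max(k - 1, 0), nx, ny);

          double dxm = (p - phi[im]) / hx, dxp = (phi[ip] - p) / hx;
          double dym = (p - phi[jm]) / hy, dyp = (phi[jp] - p) / hy;
          double dzm = (p - phi[km]) / hz, dzp = (phi[kp] - p) / hz;

          double F = prop_w * g[c] * region[c] - barrier[c];
          double upw;
          if (F > 0) {
            double a = std::max(dxm, 0.0), b = std::min(dxp, 0.0);
            double cc = std::max(dym, 0.0), d = std::min(dyp, 0.0);
            double e = std::max(dzm, 0.0), f = std::min(dzp, 0.0);
            upw = std::sqrt(a * a + b * b + cc * cc + d * d + e * e + f * f);
          } else {
            double a = std::min(dxm, 0.0), b = std::max(dxp, 0.0);
            double cc = std::min(dym, 0.0), d = std::max(dyp, 0.0);
            double e = std::min(dzm, 0.0), f = std::max(dzp, 0.0);
            upw = std::sqrt(a * a + b * b + cc * cc + d * d + e * e + f * f);
          }
          double dphi = -F * upw;

          if (curv_w > 0.0) {
            // mean curvature with central differences
            double cx = (dxm + dxp) / 2.0, cy = (dym + dyp) / 2.0,
                   cz = (dzm + dzp) / 2.0;
            double gm = std::sqrt(cx * cx + cy * cy + cz * cz);
            if (gm > 1e-8) {
              double pxx = (phi[ip] - 2.0 * p + phi[im]) / (hx * hx);
              double pyy = (phi[jp] - 2.0 * p + phi[jm]) / (hy * hy);
              double pzz = (phi[kp] - 2.0 * p + phi[km]) / (hz * hz);
              int ipjp = idx3(std::min(i + 1, nx - 1), std::min(j + 1, ny - 1), k, nx, ny);
              int ipjm = idx3(std::min(i + 1, nx - 1), std::max(j - 1, 0), k, nx, ny);
              int imjp = idx3(std::max(i - 1, 0), std::min(j + 1, ny - 1), k, nx, ny);
              int imjm = idx3(std::max(i - 1, 0), std::max(j - 1, 0), k, nx, ny);
              int ipkp = idx3(std::min(i + 1, nx - 1), j, std::min(k + 1, nz - 1), nx, ny);
              int ipkm = idx3(std::min(i + 1, nx - 1), j, std::max(k - 1, 0), nx, ny);
              int imkp = idx3(std::max(i - 1, 0), j, std::min(k + 1, nz - 1), nx, ny);
              int imkm = idx3(std::max(i - 1, 0), j, std::max(k - 1, 0), nx, ny);
              int jpkp = idx3(i, std::min(j + 1, ny - 1), std::min(k + 1, nz - 1), nx, ny);
              int jpkm = idx3(i, std::min(j + 1, ny - 1), std::max(k - 1, 0), nx, ny);
              int jmkp = idx3(i, std::max(j - 1, 0), std::min(k + 1, nz - 1), nx, ny);
              int jmkm = idx3(i, std::max(j - 1, 0), std::max(k - 1, 0), nx, ny);
              double pxy = (phi[ipjp] - phi[ipjm] - phi[imjp] + phi[imjm]) / (4.0 * hx * hy);
              double pxz = (phi[ipkp] - phi[ipkm] - phi[imkp] + phi[imkm]) / (4.0 * hx * hz);
              double pyz = (phi[jpkp] - phi[jpkm] - phi[jmkp] + phi[jmkm]) / (4.0 * hy * hz);
              double kappa = (pxx * (cy * cy + cz * cz) + pyy * (cx * cx + cz * cz) +
                              pzz * (cx * cx + cy * cy) -
                              2.0 * (pxy * cx * cy + pxz * cx * cz + pyz * cy * cz)) /
                             (gm * gm * gm);
              // cap curvature so dt stays stable near kinks
              double kmax = 1.0 / std::min(hx, std::min(hy, hz));
              if (kappa > kmax) kappa = kmax;
              if (kappa < -kmax) kappa = -kmax;
              dphi += curv_w * g[c] * kappa * gm;
            }
          }

          if (advect_w > 0.0) {
            // phi_t += advect_w * (grad g . grad phi), upwinded on -grad g
            double wx = gx[c], wy = gy[c], wz = gz[c];
            double adv = wx * (wx > 0 ? dxp : dxm) +
                         wy * (wy > 0 ? dyp : dym) +
                         wz * (wz > 0 ? dzp : dzm);
            dphi += advect_w * adv;
          }

          double np = p + dt * dphi;
          if (np > clamp_mm) np = clamp_mm;
          if (np < -clamp_mm) np = -clamp_mm;
          nphi[c] = np;
        }
    phi.swap(nphi);

    if (reinit_every > 0 && it % reinit_every == 0) {
      // a few Sussman redistancing sweeps: phi_t = S(phi)(1 - |grad phi|)
      double rdt = 0.3 * std::min(hx, std::min(hy, hz));
      for (int s = 0; s < 4; ++s) {
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
              int c = idx3(i, j, k, nx, ny);
              double p = phi[c];
              int ip = idx3(std::min(i + 1, nx - 1), j, k, nx, ny);
              int im = idx3(std::max(i - 1, 0), j, k, nx, ny);
              int jp = idx3(i, std::min(j + 1, ny - 1), k, nx, ny);
              int jm = idx3(i, std::max(j - 1, 0), k, nx, ny);
              int kp = idx3(i, j, std::min(k + 1, nz - 1), nx, ny);
              int km = idx3(i, j, std::max(k - 1, 0), nx, ny);
              double dxm = (p - phi[im]) / hx, dxp = (phi[ip] - p) / hx;
              double dym = (p - phi[jm]) / hy, dyp = (phi[jp] - p) / hy;
              double dzm = (p - phi[km]) / hz, dzp = (phi[kp] - p) / hz;
              double sgn = p / std::sqrt(p * p + hx * hx);
              double gm;
              if (sgn > 0) {
                double a = std::max(dxm, 0.0), b = std::min(dxp, 0.0);
                double cc = std::max(dym, 0.0), d = std::min(dyp, 0.0);
                double e = std::max(dzm, 0.0), f = std::min(dzp, 0.0);
                gm = std::sqrt(a * a + b * b + cc * cc + d * d + e * e + f * f);
              } else {
                double a = std::min(dxm, 0.0), b = std::max(dxp, 0.0);
                double cc = std::min(dym, 0.0), d = std::max(dyp, 0.0);
                double e = std::min(dzm, 0.0), f = std::max(dzp, 0.0);
                gm = std::sqrt(a * a + b * b + cc * cc + d * d + e * e + f * f);
              }
              nphi[c] = p + rdt * sgn * (1.0 - gm);
            }
        phi.swap(nphi);
      }
    }

    if (it % check_every == 0) {
      int changed = 0;
      for (int c = 0; c < n; ++c) {
        signed char s = phi[c] < 0 ? 1 : 0;
        if (s != sign_prev[c]) ++changed;
        sign_prev[c] = s;
      }
      if ((double)changed / n < conv_tol) { converged = true; break; }
    }
  }

  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = dims;
  return List::create(_["phi"] = out,
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged);
}

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    q.push(start);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int k = c / (nx * ny), r = c % (nx * ny);
      int j = r / nx, i = r % nx;
      const int ni[6] = {i - 1, i + 1, i, i, i, i};
      const int nj[6] = {j, j, j - 1, j + 1, j, j};
      const int nk[6] = {k, k, k, k, k - 1, k + 1};
      for (int t = 0; t < 6; ++t) {
        if (ni[t] < 0 || ni[t] >= nx || nj[t] < 0 || nj[t] >= ny ||
            nk[t] < 0 || nk[t] >= nz) continue;
        int d = idx3(ni[t], nj[t], nk[t], nx, ny);
        if (mask[d] && !lab[d]) { lab[d] = next; q.push(d); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
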