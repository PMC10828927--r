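#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

static inline double tab_interp2(const double* tab, int ng, double phi) {
  const double period = 1.5707963267948966;
  double u = phi / period;
  u -= std::floor(u);
  if (u >= 1.0) u = 0.0;      // tiny negative phi can round up to exactly 1
  double g = u * ng;
  int i = (int)g;
  double f = g - i;
  int j = (i + 1 >= ng) ? 0 : i + 1;
  return tab[i] * (1.0 - f) + tab[j] * f;
}

// Many-body run-and-tumble-turn particles in a periodic box:
//   dr_i   = [v0 n(phi_i) + eps F_hertz_i] dt
//   dphi_i = [-Gamma V'(phi_i) - J sum_j sin(phi_i - phi_j) 1(r_ij < 2 rA)] dt
//            + sqrt(2 Dr) dW_i
// Hertzian repulsion V_R = (1 - r/(2 rc))^{5/2} for r < 2 rc; minimum-image
// convention; neighbours from a cell list rebuilt every step, visited as
// unordered pairs (Newton's third law: every pair interaction is applied to
// both members).  All-pairs fallback when the box holds fewer than 4x4 cells.
// [[Rcpp::export]]
List tt_interacting_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                        double L, double v0, double Gamma, double Dr,
                        double J, double eps, double rc, double rA,
                        double dt, int n_steps, int save_every,
                        double seed, double stream, double step_offset,
                        NumericVector grad_tab) {
  const int np = phi0.size();
  const int ng = grad_tab.size();
  const int nsave = n_steps / save_every;
  const uint64_t sd = (uint64_t)seed, st = (uint64_t)stream;
  const uint64_t off = (uint64_t)step_offset;
  const double noise = std::sqrt(2.0 * Dr * dt);
  const double r_int = 2.0 * std::max(rc, rA);
  const double r2rc = 2.0 * rc, r2rA = 2.0 * rA;
  const double cut2 = r_int * r_int;
  const double halfL = 0.5 * L;

  int ncell = (int)std::floor(L / r_int);
  const bool use_cells = (ncell >= 4);
  if (!use_cells) ncell = 1;
  const double cellw = L / ncell;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> cphi(np), sphi(np);
  std::vector<double> fx(np), fy(np), tq(np);
  std::vector<int> head(ncell * ncell), nxt(np);

  NumericMatrix xs(nsave, np), ys(nsave, np), ps(nsave, np);
  const double* tab = REAL(grad_tab);
  double max_disp2 = 0.0;
  uint64_t step_now = 0;

  // unordered pair interaction, applied to both members
  auto pair_ij = [&](int i, int j) {
    double ddx = x[i] - x[j];
    double ddy = y[i] - y[j];
    if (ddx > halfL) ddx -= L; else if (ddx < -halfL) ddx += L;
    if (ddy > halfL) ddy -= L; else if (ddy < -halfL) ddy += L;
    double r2 = ddx * ddx + ddy * ddy;
    if (r2 >= cut2) return;
    double r = std::sqrt(r2);
    if (r < r2rc) {
      double mag;
      if (r < 1e-9) {
        // coincident pair: deterministic seeded kick direction
        double a = 6.283185307179586 *
                   tt_unif(sd, st + 7, (uint64_t)i, off + step_now);
        ddx = std::cos(a); ddy = std::sin(a); r = 1.0;
        mag = eps * 1.25 / rc;
      } else {
        double ov = 1.0 - r / r2rc;
        mag = eps * 1.25 / rc * ov * std::sqrt(ov);  // eps*(5/(4 rc))*ov^{3/2}
      }
      double fxi = mag * ddx / r, fyi = mag * ddy / r;
      fx[i] += fxi; fy[i] += fyi;
      fx[j] -= fxi; fy[j] -= fyi;
    }
    if (r < r2rA && J != 0.0) {
      double sij = sphi[i] * cphi[j] - cphi[i] * sphi[j];  // sin(phi_i - phi_j)
      tq[i] -= J * sij;
      tq[j] += J * sij;
    }
  };

  // half of the 8 neighbour offsets (E, NE, N, NW) so each cell pair is
  // visited once
  const int offx[4] = {1, 1, 0, -1};
  const int offy[4] = {0, 1, 1, 1};

  for (int s = 1; s <= n_steps; ++s) {
    step_now = (uint64_t)s;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);

    if (use_cells) {
      std::fill(head.begin(), head.end(), -1);
      for (int i = 0; i < np; ++i) {
        int cxi = (int)(x[i] / cellw); if (cxi >= ncell) cxi = ncell - 1;
        int cyi = (int)(y[i] / cellw); if (cyi >= ncell) cyi = ncell - 1;
        int c = cyi * ncell + cxi;
        nxt[i] = head[c]; head[c] = i;
      }
      for (int cy = 0; cy < ncell; ++cy)
        for (int cx = 0; cx < ncell; ++cx) {
          int c = cy * ncell + cx;
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j])
              pair_ij(i, j);                     // within-cell pairs
          for (int k = 0; k < 4; ++k) {
            int c2 = ((cy + offy[k]) % ncell) * ncell +
                     ((cx + offx[k] + ncell) % ncell);
            for (int i = head[c]; i >= 0; i = nxt[i])
              for (int j = head[c2]; j >= 0; j = nxt[j])
                pair_ij(i, j);                   // cross-cell pairs, once
          }
        }
    } else {
      for (int i = 0; i < np; ++i)
        for (int j = i + 1; j < np; ++j)
          pair_ij(i, j);
    }

    int row = s / save_every - 1;
    bool do_save = (s % save_every == 0);
    for (int i = 0; i < np; ++i) {
      double g = tab_interp2(tab, ng, phi[i]);
      double n = tt_norm(sd, st, (uint64_t)i, off + (uint64_t)s);
      phi[i] += (-Gamma * g + tq[i]) * dt + noise * n;
      cphi[i] = std::cos(phi[i]); sphi[i] = std::sin(phi[i]);
      double ux = (v0 * cphi[i] + fx[i]) * dt;
      double uy = (v0 * sphi[i] + fy[i]) * dt;
      double d2 = ux * ux + uy * uy;
      if (d2 > max_disp2) max_disp2 = d2;
      x[i] += ux; y[i] += uy;
      x[i] -= L * std::floor(x[i] / L);
      y[i] -= L * std::floor(y[i] / L);
      if (do_save) { xs(row, i) = x[i]; ys(row, i) = y[i]; ps(row, i) = phi[i]; }
    }
  }

  return List::create(_["x"] = xs, _["y"] = ys, _["phi"] = ps,
                      _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["y_final"] = NumericVector(y.begin(), y.end()),
                      _["phi_final"] = NumericVector(phi.begin(), phi.end()),
                      _["max_disp"] = std::sqrt(max_disp2));
}
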