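#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Linear interpolation of a tabulated pi/2-periodic function.
static inline double tab_interp(const double* tab, int ng, double phi) {
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

// Euler-Maruyama integration of the solitary run-and-tumble-turn particle:
//   dphi = -Gamma V'(phi) dt + sqrt(2 Dr) dW,   dr = v0 (cos phi, sin phi) dt
// V' is supplied as a lookup table on [0, pi/2) (the potential is
// pi/2-periodic); positions are unbounded, angles unwrapped.
// [[Rcpp::export]]
List tt_langevin_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                     double v0, double Gamma, double Dr, double dt,
                     int n_steps, int save_every,
                     double seed, double stream, double step_offset,
                     NumericVector grad_tab) {
  const int np = phi0.size();
  const int ng = grad_tab.size();
  const int nsave = n_steps / save_every;
  const uint64_t sd = (uint64_t)seed, st = (uint64_t)stream;
  const uint64_t off = (uint64_t)step_offset;
  const double noise = std::sqrt(2.0 * Dr * dt);

  NumericMatrix xs(nsave, np), ys(nsave, np), ps(nsave, np);
  NumericVector xf(np), yf(np), pf(np);
  const double* tab = REAL(grad_tab);

  for (int p = 0; p < np; ++p) {
    double x = x0[p], y = y0[p], phi = phi0[p];
    int row = 0;
    for (int s = 1; s <= n_steps; ++s) {
      double g = tab_interp(tab, ng, phi);
      double n = tt_norm(sd, st, (uint64_t)p, off + (uint64_t)s);
      phi += -Gamma * g * dt + noise * n;
      x += v0 * std::cos(phi) * dt;
      y += v0 * std::sin(phi) * dt;
      if (s % save_every == 0) {
        xs(row, p) = x; ys(row, p) = y; ps(row, p) = phi;
        ++row;
      }
    }
    xf[p] = x; yf[p] = y; pf[p] = phi;
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["phi"] = ps,
                      _["x_final"] = xf, _["y_final"] = yf,
                      _["phi_final"] = pf);
}

// Uniform variates from the counter-based generator, exposed so that R code
// (initial conditions, seeding of interacting runs) shares one mechanism.
// [[Rcpp::export]]
NumericVector tt_unif_cpp(double seed, double stream, double particle,
                          double counter0, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tt_unif((uint64_t)seed, (uint64_t)stream, (uint64_t)particle,
                     (uint64_t)counter0 + (uint64_t)i);
  return out;
}
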