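#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped (Brownian) integrator for a charged elastic network under an
// oscillating external field:
//   r <- r + (dt/gamma) (F_spring + F_anchor + q E(t)) + sqrt(2 kBT dt/gamma) eta
// with E(t) = Eamp * cos(omega t) * axis (force units kJ/mol/nm, already
// converted per unit charge). Gaussian noise is drawn from R's RNG, so runs
// are reproducible under set.seed(). Frames are saved every `stride` steps,
// including the initial configuration.
// [[Rcpp::export]]
NumericVector simulate_enm_cpp(NumericMatrix coords0,
                               IntegerVector si, IntegerVector sj,
                               NumericVector sk, NumericVector sr0,
                               NumericVector anchor_k, NumericMatrix anchor_pos,
                               NumericVector charge,
                               double famp, NumericVector axis,
                               double omega, double gamma_f, double kBT,
                               double dt, int n_steps, int stride) {
  const int n = coords0.nrow();
  const int ns = si.size();
  const int n_frames = n_steps / stride + 1;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
  }
  NumericVector out(Dimension(n_frames, n, 3));
  const double mob = dt / gamma_f;
  const double sig = std::sqrt(2.0 * kBT * dt / gamma_f);
  const double ax = axis[0], ay = axis[1], az = axis[2];
  std::vector<double> fx(n), fy(n), fz(n);
  int fr = 0;
  for (int i = 0; i < n; ++i) {
    out[fr + n_frames * i] = x[i];
    out[fr + n_frames * (n + i)] = y[i];
    out[fr + n_frames * (2 * n + i)] = z[i];
  }
  ++fr;
  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      int i = si[s], j = sj[s];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double f = -sk[s] * (r - sr0[s]) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    double et = famp * std::cos(omega * (step * dt));
    NumericVector eta = Rcpp::rnorm(3 * n);
    double max_d2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (anchor_k[i] > 0.0) {
        fx[i] -= anchor_k[i] * (x[i] - anchor_pos(i, 0));
        fy[i] -= anchor_k[i] * (y[i] - anchor_pos(i, 1));
        fz[i] -= anchor_k[i] * (z[i] - anchor_pos(i, 2));
      }
      double q = charge[i];
      double ddx = mob * (fx[i] + q * et * ax) + sig * eta[3 * i];
      double ddy = mob * (fy[i] + q * et * ay) + sig * eta[3 * i + 1];
      double ddz = mob * (fz[i] + q * et * az) + sig * eta[3 * i + 2];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > max_d2) max_d2 = d2;
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
    }
    if (max_d2 > 0.25) {
      stop("integration instability at step %d: displacement %.3f nm > 0.5 nm",
           step + 1, std::sqrt(max_d2));
    }
    if ((step + 1) % stride == 0) {
      for (int i = 0; i < n; ++i) {
        out[fr + n_frames * i] = x[i];
        out[fr + n_frames * (n + i)] = y[i];
        out[fr + n_frames * (2 * n + i)] = z[i];
      }
      ++fr;
    }
  }
  return out;
}
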