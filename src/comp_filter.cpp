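#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Complementary attitude filter tracking the "up" direction (the unit
// vector opposite gravity) in the sensor frame.
//
// A world-fixed vector u expressed in sensor coordinates evolves as
// du/dt = -omega x u, with omega the sensor-frame angular rate. Each step
// propagates u by an exact Rodrigues rotation using the trapezoidal mean
// of the surrounding gyro samples, then blends it toward the normalized
// accelerometer vector with per-step weight `gain`. Zero-norm
// accelerometer samples skip the blend (gyro-only propagation).
//
// accel: N x 3 (m/s^2), gyro: N x 3 (deg/s), t: seconds, init_up: fallback
// initial up direction when the first accelerometer sample is unusable.
// [[Rcpp::export]]
NumericMatrix comp_filter_up(NumericMatrix accel, NumericMatrix gyro,
                             NumericVector t, double gain,
                             NumericVector init_up) {
  const int n = accel.nrow();
  const double d2r = M_PI / 180.0;
  NumericMatrix U(n, 3);
  double u[3] = {init_up[0], init_up[1], init_up[2]};

  double a0 = std::sqrt(accel(0, 0) * accel(0, 0) +
                        accel(0, 1) * accel(0, 1) +
                        accel(0, 2) * accel(0, 2));
  if (a0 > 1e-9) {
    u[0] = accel(0, 0) / a0;
    u[1] = accel(0, 1) / a0;
    u[2] = accel(0, 2) / a0;
  }
  U(0, 0) = u[0]; U(0, 1) = u[1]; U(0, 2) = u[2];

  for (int i = 1; i < n; ++i) {
    const double dt = t[i] - t[i - 1];
    const double wx = 0.5 * (gyro(i - 1, 0) + gyro(i, 0)) * d2r;
    const double wy = 0.5 * (gyro(i - 1, 1) + gyro(i, 1)) * d2r;
    const double wz = 0.5 * (gyro(i - 1, 2) + gyro(i, 2)) * d2r;
    const double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
    const double ang = wn * dt;
    if (ang > 0.0) {
      // rotate u about k = -omega/|omega| by |omega| dt (exact Rodrigues)
      const double kx = -wx / wn, ky = -wy / wn, kz = -wz / wn;
      const double c = std::cos(ang), s = std::sin(ang);
      const double kdu = kx * u[0] + ky * u[1] + kz * u[2];
      const double cx = ky * u[2] - kz * u[1];
      const double cy = kz * u[0] - kx * u[2];
      const double cz = kx * u[1] - ky * u[0];
      const double nx = u[0] * c + cx * s + kx * kdu * (1.0 - c);
      const double ny = u[1] * c + cy * s + ky * kdu * (1.0 - c);
      const double nz = u[2] * c + cz * s + kz * kdu * (1.0 - c);
      u[0] = nx; u[1] = ny; u[2] = nz;
    }
    const double an = std::sqrt(accel(i, 0) * accel(i, 0) +
                                accel(i, 1) * accel(i, 1) +
                                accel(i, 2) * accel(i, 2));
    if (an > 1e-9) {
      u[0] = (1.0 - gain) * u[0] + gain * accel(i, 0) / an;
      u[1] = (1.0 - gain) * u[1] + gain * accel(i, 1) / an;
      u[2] = (1.0 - gain) * u[2] + gain * accel(i, 2) / an;
    }
    const double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    u[0] /= un; u[1] /= un; u[2] /= un;
    U(i, 0) = u[0]; U(i, 1) = u[1]; U(i, 2) = u[2];
  }
  return U;
}
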