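#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the stochastic Lotka-Volterra competition
// system with the slaved rate Y = a + b*C + f*D^2.
//
// model 0: state (X1, X2), rates of the two competing populations:
//   dX1 = [ k X1 (w X1 + X2 + k1 Y + k0) + h0 ] dt + sigma(X1) dW1
//   dX2 = [ k X2 (X1 + w X2 + k1 Y + k0) + h0 ] dt + sigma(X2) dW2
// model 1: state (C, D) stepped with the sum/difference form of the same
//   field (dC = k C ((w+1)C + k1 Y + k0) + k (w-1) D^2 + h0,
//    dD = k D (2 w C + k1 Y + k0)), noise applied to C and D.
//
// noise_type 0: none; 1: additive sigma = eta; 2: multiplicative sigma = eta*X.
// Rates are kept nonnegative by reflection at 0 (in the (X1, X2) coordinates).
// Deterministic runs (noise_type 0) use classical RK4 in the (X1, X2)
// coordinates instead of the Euler step, so they can serve as accurate
// reference trajectories. Output: one row per `sub` steps, (t, X1, X2, Y).
// [[Rcpp::export]]
NumericMatrix cpp_lv_sde(double x1, double x2, double k, double w, double k1,
                         double k0, double h0, double a, double b, double f,
                         int model, int noise_type, double eta,
                         double dt, int n_steps, int sub) {
  int n_out = n_steps / sub + 1;
  NumericMatrix out(n_out, 4);
  const double sqdt = std::sqrt(dt);
  int row = 0;
  double C = 0.5 * (x1 + x2), D = 0.5 * (x1 - x2);

  for (int s = 0; s <= n_steps; ++s) {
    double Cc = 0.5 * (x1 + x2), Dd = 0.5 * (x1 - x2);
    double Y = a + b * Cc + f * Dd * Dd;
    if (s % sub == 0) {
      out(row, 0) = s * dt;
      out(row, 1) = x1;
      out(row, 2) = x2;
      out(row, 3) = Y;
      ++row;
    }
    if (s == n_steps) break;

    if (noise_type == 0 && model == 0) {
      // deterministic: classical RK4 on the slaved-Y field
      auto fx = [&](double u1, double u2, double& d1, double& d2) {
        double Cu = 0.5 * (u1 + u2), Du = 0.5 * (u1 - u2);
        double Yu = a + b * Cu + f * Du * Du;
        d1 = k * u1 * (w * u1 + u2 + k1 * Yu + k0) + h0;
        d2 = k * u2 * (u1 + w * u2 + k1 * Yu + k0) + h0;
      };
      double a1, a2, b1, b2, c1, c2, e1, e2;
      fx(x1, x2, a1, a2);
      fx(x1 + 0.5 * dt * a1, x2 + 0.5 * dt * a2, b1, b2);
      fx(x1 + 0.5 * dt * b1, x2 + 0.5 * dt * b2, c1, c2);
      fx(x1 + dt * c1, x2 + dt * c2, e1, e2);
      x1 += dt / 6.0 * (a1 + 2 * b1 + 2 * c1 + e1);
      x2 += dt / 6.0 * (a2 + 2 * b2 + 2 * c2 + e2);
      if (x1 < 0) x1 = -x1;
      if (x2 < 0) x2 = -x2;
      if (!std::isfinite(x1) || !std::isfinite(x2))
        stop("ODE integration diverged at t = %.1f ms", s * dt);
      continue;
    }

    double n1 = 0.0, n2 = 0.0;
    if (noise_type == 1) {
      n1 = eta * sqdt * norm_rand();
      n2 = eta * sqdt * norm_rand();
    } else if (noise_type == 2) {
      n1 = eta * sqdt * norm_rand();  // scaled by the state below
      n2 = eta * sqdt * norm_rand();
    }

    if (model == 0) {
      double d1 = k * x1 * (w * x1 + x2 + k1 * Y + k0) + h0;
      double d2 = k * x2 * (x1 + w * x2 + k1 * Y + k0) + h0;
      if (noise_type == 2) { n1 *= x1; n2 *= x2; }
      x1 += d1 * dt + n1;
      x2 += d2 * dt + n2;
    } else {
      C = Cc; D = Dd;
      double dC = k * C * ((w + 1.0) * C + k1 * Y + k0) + k * (w - 1.0) * D * D + h0;
      double dD = k * D * (2.0 * w * C + k1 * Y + k0);
      if (noise_type == 2) { n1 *= C; n2 *= D; }
      C += dC * dt + n1;
      D += dD * dt + n2;
      x1 = C + D;
      x2 = C - D;
    }
    if (x1 < 0) x1 = -x1;
    if (x2 < 0) x2 = -x2;
    if (!std::isfinite(x1) || !std::isfinite(x2))
      stop("SDE integration diverged at t = %.1f ms (reduce dt or eta)", s * dt);
    if (x1 > 1e6 || x2 > 1e6)
      stop("SDE state exceeded 1e6 kHz at t = %.1f ms: step-size instability", s * dt);
  }
  return out;
}
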