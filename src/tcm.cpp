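#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact convolution of a piecewise-linear input (uniform grid, spacing dt)
// with exp(-theta * t).  Over one step the update is a first-order recursion
//   y[k+1] = a * y[k] + b0 * f[k] + b1 * f[k+1]
// with coefficients obtained by integrating exp(-theta*(dt - s)) against the
// linear segment analytically; series expansions guard theta*dt -> 0.
static inline void conv_coefs(double theta, double dt,
                              double &a, double &b0, double &b1) {
  double x = theta * dt;
  a = std::exp(-x);
  if (x < 1e-6) {
    // J0 = dt (1 - x/2 + x^2/6), J1 = dt (1/2 - x/6 + x^2/24)
    double J0 = dt * (1.0 - x / 2.0 + x * x / 6.0);
    double J1 = dt * (0.5 - x / 6.0 + x * x / 24.0);
    b1 = J1;
    b0 = J0 - J1;
  } else {
    double J0 = (1.0 - a) / theta;
    double J1 = J0 - (1.0 - a * (1.0 + x)) / (theta * theta * dt);
    b1 = J1;
    b0 = J0 - J1;
  }
}

// Decompose 2TCM rates into the biexponential impulse response
// IRF(t) = phi1 exp(-theta1 t) + phi2 exp(-theta2 t), theta1 >= theta2.
// A coincident-root pair (discriminant ~ 0) is split by a relatively tiny
// amount so the generic two-exponential path stays numerically valid.
static inline void irf_decomp(double K1, double k2, double k3, double k4,
                              double &phi1, double &phi2,
                              double &theta1, double &theta2) {
  double s = k2 + k3 + k4;
  double disc = s * s - 4.0 * k2 * k4;
  double floor_ = s * 1e-7;
  double sq = std::sqrt(std::max(disc, floor_ * floor_));
  theta1 = 0.5 * (s + sq);
  theta2 = 0.5 * (s - sq);
  phi1 = K1 * (theta1 - k3 - k4) / sq;
  phi2 = K1 * (k3 + k4 - theta2) / sq;
}

// [[Rcpp::export]]
NumericVector cpp_exp_conv(NumericVector f, double dt, double theta) {
  int n = f.size();
  NumericVector y(n);
  if (n == 0) return y;
  double a, b0, b1;
  conv_coefs(theta, dt, a, b0, b1);
  y[0] = 0.0;
  for (int k = 0; k + 1 < n; ++k)
    y[k + 1] = a * y[k] + b0 * f[k] + b1 * f[k + 1];
  return y;
}

// Frame values of the 2TCM prediction:
//   C(t) = (1 - vB) * (IRF (x) Cp)(t) + vB * Cwb(t)
// cp: parent plasma on the uniform grid (t = 0, dt, ..., (n-1) dt);
// ia/ib: 1-based grid indices of frame start/end (boundaries on the grid);
// wb_fr: frame-averaged whole blood.  Tissue frame values are trapezoidal
// time-averages over each frame.
// [[Rcpp::export]]
NumericVector cpp_tcm_frames(double K1, double k2, double k3, double k4,
                             double vB, NumericVector cp, double dt,
                             IntegerVector ia, IntegerVector ib,
                             NumericVector wb_fr) {
  int n = cp.size(), nf = ia.size();
  double phi1, phi2, theta1, theta2;
  irf_decomp(K1, k2, k3, k4, phi1, phi2, theta1, theta2);
  double a1, b10, b11, a2, b20, b21;
  conv_coefs(theta1, dt, a1, b10, b11);
  conv_coefs(theta2, dt, a2, b20, b21);

  // cumulative trapezoid of the tissue curve
  std::vector<double> ct(n);
  double y1 = 0.0, y2 = 0.0, prev = 0.0, cum = 0.0;
  ct[0] = 0.0;
  for (int k = 0; k + 1 < n; ++k) {
    y1 = a1 * y1 + b10 * cp[k] + b11 * cp[k + 1];
    y2 = a2 * y2 + b20 * cp[k] + b21 * cp[k + 1];
    double cur = phi1 * y1 + phi2 * y2;
    cum += 0.5 * (prev + cur) * dt;
    ct[k + 1] = cum;
    prev = cur;
  }

  NumericVector out(nf);
  for (int j = 0; j < nf; ++j) {
    int a = ia[j] - 1, b = ib[j] - 1;
    double avg = (ct[b] - ct[a]) / ((b - a) * dt);
    out[j] = (1.0 - vB) * avg + vB * wb_fr[j];
  }
  return out;
}

// Weighted residual sum of squares for one regional TAC against the 2TCM.
// [[Rcpp::export]]
double cpp_tcm_wrss(double K1, double k2, double k3, double k4, double vB,
                    NumericVector cp, double dt, IntegerVector ia,
                    IntegerVector ib, NumericVector wb_fr,
                    NumericVector tac, NumericVector w) {
  NumericVector m = cpp_tcm_frames(K1, k2, k3, k4, vB, cp, dt, ia, ib, wb_fr);
  double ss = 0.0;
  for (int j = 0; j < m.size(); ++j) {
    double r = tac[j] - m[j];
    ss += w[j] * r * r;
  }
  return ss;
}

// WRSS plus its analytic gradient in (K1, k2, k3, k4).
//
// The model is linear in (phi1, phi2); d/dtheta of conv(exp(-theta t), cp)
// is -conv(t exp(-theta t), cp), which obeys the coupled recursion
//   z[k+1] = a (z[k] + dt y[k]) + cp[k+1] M1 + (cp[k] - cp[k+1]) M2 / dt
// with M1 = int_0^dt u e^{-theta u} du, M2 = int_0^dt u^2 e^{-theta u} du.
// Gradients are chained through theta_{1,2}(k2,k3,k4) and
// phi_{1,2}(K1,k2,k3,k4); when the root discriminant is clamped the
// clamped sqrt is treated as constant.
// Returns (wrss, dK1, dk2, dk3, dk4).
// [[Rcpp::export]]
NumericVector cpp_tcm_wrss_grad(double K1, double k2, double k3, double k4,
                                double vB, NumericVector cp, double dt,
                                IntegerVector ia, IntegerVector ib,
                                NumericVector wb_fr, NumericVector tac,
                                NumericVector w) {
  int n = cp.size(), nf = ia.size();
  double s = k2 + k3 + k4, aa = k3 + k4;
  double disc = s * s - 4.0 * k2 * k4;
  double floor_ = s * 1e-7;
  bool clamped = disc <= floor_ * floor_;
  double q = std::sqrt(std::max(disc, floor_ * floor_));
  double theta1 = 0.5 * (s + q), theta2 = 0.5 * (s - q);
  double phi1 = K1 * (theta1 - aa) / q, phi2 = K1 * (aa - theta2) / q;

  double a1, b10, b11, a2, b20, b21;
  conv_coefs(theta1, dt, a1, b10, b11);
  conv_coefs(theta2, dt, a2, b20, b21);
  // t-weighted kernel moments
  auto moments = [dt](double theta, double alpha, double &M1, double &M2) {
    double x = theta * dt;
    if (x < 1e-5) {
      M1 = dt * dt * (0.5 - x / 3.0 + x * x / 8.0);
      M2 = dt * dt * dt * (1.0 / 3.0 - x / 4.0 + x * x / 10.0);
    } else {
      M1 = (1.0 - alpha * (1.0 + x)) / (theta * theta);
      M2 = (2.0 - alpha * (x * x + 2.0 * x + 2.0)) / (theta * theta * theta);
    }
  };
  double M11, M12, M21, M22;
  moments(theta1, a1, M11, M12);
  moments(theta2, a2, M21, M22);

  // cumulative trapezoids of y1, y2, z1, z2
  std::vector<double> cy1(n), cy2(n), cz1(n), cz2(n);
  double y1 = 0, y2 = 0, z1 = 0, z2 = 0;
  double py1 = 0, py2 = 0, pz1 = 0, pz2 = 0;
  double s1 = 0, s2 = 0, s3 = 0, s4 = 0;
  cy1[0] = cy2[0] = cz1[0] = cz2[0] = 0.0;
  for (int k = 0; k + 1 < n; ++k) {
    double z1n = a1 * (z1 + dt * y1) + cp[k + 1] * M11 +
                 (cp[k] - cp[k + 1]) * M12 / dt;
    double z2n = a2 * (z2 + dt * y2) + cp[k + 1] * M21 +
                 (cp[k] - cp[k + 1]) * M22 / dt;
    y1 = a1 * y1 + b10 * cp[k] + b11 * cp[k + 1];
    y2 = a2 * y2 + b20 * cp[k] + b21 * cp[k + 1];
    z1 = z1n; z2 = z2n;
    s1 += 0.5 * (py1 + y1) * dt; cy1[k + 1] = s1; py1 = y1;
    s2 += 0.5 * (py2 + y2) * dt; cy2[k + 1] = s2; py2 = y2;
    s3 += 0.5 * (pz1 + z1) * dt; cz1[k + 1] = s3; pz1 = z1;
    s4 += 0.5 * (pz2 + z2) * dt; cz2[k + 1] = s4; pz2 = z2;
  }

  double wrss = 0, A1 = 0, A2 = 0, B1 = 0, B2 = 0;
  for (int j = 0; j < nf; ++j) {
    int a = ia[j] - 1, b = ib[j] - 1;
    double span = (b - a) * dt;
    double Fy1 = (cy1[b] - cy1[a]) / span, Fy2 = (cy2[b] - cy2[a]) / span;
    double Fz1 = (cz1[b] - cz1[a]) / span, Fz2 = (cz2[b] - cz2[a]) / span;
    double m = (1.0 - vB) * (phi1 * Fy1 + phi2 * Fy2) + vB * wb_fr[j];
    double r = tac[j] - m;
    wrss += w[j] * r * r;
    double wr = w[j] * r;
    A1 += wr * Fy1; A2 += wr * Fy2;
    B1 += wr * Fz1; B2 += wr * Fz2;
  }
  double c = 1.0 - vB;
  double dphi1 = -2.0 * c * A1, dphi2 = -2.0 * c * A2;
  double dth1 = 2.0 * c * phi1 * B1, dth2 = 2.0 * c * phi2 * B2;

  // chain rule to the rate constants
  double dq2 = clamped ? 0.0 : (s - 2.0 * k4) / q;
  double dq3 = clamped ? 0.0 : s / q;
  double dq4 = clamped ? 0.0 : (s - 2.0 * k2) / q;
  NumericVector out(5);
  out[0] = wrss;
  out[1] = dphi1 * (theta1 - aa) / q + dphi2 * (aa - theta2) / q;
  double dqk[3] = {dq2, dq3, dq4};
  double dak[3] = {0.0, 1.0, 1.0};
  for (int i = 0; i < 3; ++i) {
    double dth1k = 0.5 * (1.0 + dqk[i]);
    double dth2k = 0.5 * (1.0 - dqk[i]);
    double dphi1k = K1 * ((dth1k - dak[i]) / q -
                          (theta1 - aa) * dqk[i] / (q * q));
    double dphi2k = K1 * ((dak[i] - dth2k) / q -
                          (aa - theta2) * dqk[i] / (q * q));
    out[i + 2] = dphi1 * dphi1k + dphi2 * dphi2k + dth1 * dth1k +
                 dth2 * dth2k;
  }
  return out;
}
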