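#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Noise modes: 0 = none, 1 = additive, 2 = multiplicative (state-dependent).
// Both integrators use the Heun predictor-corrector, which converges to the
// Stratonovich solution of the SDE without an explicit drift correction.

static inline double drift(double a, double b, double x, double u) {
  return a * x + b * u;
}

static inline double diffusion(int mode, double sigma, double x) {
  if (mode == 2) return sigma * x;
  if (mode == 1) return sigma;
  return 0.0;
}

// [[Rcpp::export]]
List heun_paths_cpp(NumericVector u, double dt, double a_mu, double a_M,
                    double b, double sigma_mu, double sigma_M, int mode,
                    NumericVector dw_mu, NumericVector dw_M,
                    double x0_mu, double x0_M) {
  int n = u.size();
  NumericVector x_mu(n), x_M(n);
  x_mu[0] = x0_mu;
  x_M[0] = x0_M;
  double as[2] = {a_mu, a_M};
  double sig[2] = {sigma_mu, sigma_M};
  for (int i = 0; i + 1 < n; ++i) {
    double xs[2] = {x_mu[i], x_M[i]};
    double dw[2];
    dw[0] = (mode == 0) ? 0.0 : dw_mu[i];
    dw[1] = (mode == 0) ? 0.0 : dw_M[i];
    double out[2];
    for (int ch = 0; ch < 2; ++ch) {
      double x = xs[ch];
      double g0 = diffusion(mode, sig[ch], x);
      double f0 = drift(as[ch], b, x, u[i]);
      double xp = x + f0 * dt + g0 * dw[ch];
      double g1 = diffusion(mode, sig[ch], xp);
      double f1 = drift(as[ch], b, xp, u[i + 1]);
      out[ch] = x + 0.5 * (f0 + f1) * dt + 0.5 * (g0 + g1) * dw[ch];
    }
    if (!std::isfinite(out[0]) || !std::isfinite(out[1]) ||
        std::fabs(out[0]) > 1e6 || std::fabs(out[1]) > 1e6) {
      stop("state divergence at step %d (|x| > 1e6 or non-finite)", i + 1);
    }
    x_mu[i + 1] = out[0];
    x_M[i + 1] = out[1];
  }
  return List::create(_["x_mu"] = x_mu, _["x_M"] = x_M);
}

// Floor the eigenvalues of a symmetric 2x2 matrix at `floor_at`.
// Returns true if a repair was applied.
static bool repair_cov2(double &p11, double &p12, double &p22,
                        double floor_at) {
  double tr = p11 + p22;
  double det = p11 * p22 - p12 * p12;
  double disc = tr * tr - 4.0 * det;
  if (disc < 0.0) disc = 0.0;
  double root = std::sqrt(disc);
  double l1 = 0.5 * (tr + root);
  double l2 = 0.5 * (tr - root);
  if (l2 >= 0.0) return false;  // zero eigenvalues are legitimate (P0 = 0)
  double l1c = (l1 < floor_at) ? floor_at : l1;
  double l2c = floor_at;
  // eigenvector for l1
  double v1, v2;
  if (std::fabs(p12) > 1e-300) {
    v1 = l1 - p22;
    v2 = p12;
  } else {
    if (p11 >= p22) { v1 = 1.0; v2 = 0.0; } else { v1 = 0.0; v2 = 1.0; }
  }
  double nrm = std::sqrt(v1 * v1 + v2 * v2);
  if (nrm < 1e-300) { v1 = 1.0; v2 = 0.0; nrm = 1.0; }
  v1 /= nrm; v2 /= nrm;
  // orthogonal complement
  double w1 = -v2, w2 = v1;
  p11 = l1c * v1 * v1 + l2c * w1 * w1;
  p12 = l1c * v1 * v2 + l2c * w1 * w2;
  p22 = l1c * v2 * v2 + l2c * w2 * w2;
  return true;
}

// Continuous-discrete extended Kalman filter log-likelihood for the
// two-channel latent LTI system with tanh observers.
//   latent:   dx_mu = (a_mu x_mu + b u) dt + s_mu dW,   s = sigma (additive)
//             or sigma * x (multiplicative, Stratonovich; the filter drift
//             carries the Ito correction a + sigma^2/2)
//   observed: y = c * tanh(k x) + e,  e ~ N(0, r_var), per channel
// Shared increments induce a rank-one cross-channel process noise covariance.
// [[Rcpp::export]]
List ekf_loglik_cpp(NumericVector y_mu, NumericVector y_M, NumericVector u,
                    double dt, double a_mu, double a_M, double b, double c,
                    double k_mu, double k_M, double sigma_mu, double sigma_M,
                    int mode, bool shared, double r_var) {
  const double LOG2PI = 1.837877066409345483560659472811;
  int n = y_mu.size();
  double m1 = 0.0, m2 = 0.0;
  double p11 = 0.0, p12 = 0.0, p22 = 0.0;
  double ll = 0.0;
  int repairs = 0;
  double ae1 = a_mu + ((mode == 2) ? 0.5 * sigma_mu * sigma_mu : 0.0);
  double ae2 = a_M + ((mode == 2) ? 0.5 * sigma_M * sigma_M : 0.0);
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      // mean: Heun step on the (corrected) drift, inputs at both ends
      double f01 = ae1 * m1 + b * u[i - 1];
      double f02 = ae2 * m2 + b * u[i - 1];
      double mp1 = m1 + f01 * dt;
      double mp2 = m2 + f02 * dt;
      double f11 = ae1 * mp1 + b * u[i];
      double f12 = ae2 * mp2 + b * u[i];
      // process noise intensity (evaluated at the pre-step mean)
      double q11 = 0.0, q12 = 0.0, q22 = 0.0;
      if (mode == 1) {
        q11 = sigma_mu * sigma_mu;
        q22 = sigma_M * sigma_M;
        q12 = shared ? sigma_mu * sigma_M : 0.0;
      } else if (mode == 2) {
        double l1 = sigma_mu * m1, l2 = sigma_M * m2;
        q11 = l1 * l1;
        q22 = l2 * l2;
        q12 = shared ? l1 * l2 : 0.0;
      }
      m1 += 0.5 * (f01 + f11) * dt;
      m2 += 0.5 * (f02 + f12) * dt;
      // covariance: linearized propagator matching the Heun mean map
      double F1 = 1.0 + ae1 * dt + 0.5 * ae1 * ae1 * dt * dt;
      double F2 = 1.0 + ae2 * dt + 0.5 * ae2 * ae2 * dt * dt;
      p11 = F1 * p11 * F1 + q11 * dt;
      p12 = F1 * p12 * F2 + q12 * dt;
      p22 = F2 * p22 * F2 + q22 * dt;
      if (!std::isfinite(m1) || !std::isfinite(m2) ||
          std::fabs(m1) > 1e6 || std::fabs(m2) > 1e6) {
        return List::create(_["loglik"] = R_NegInf, _["repairs"] = repairs);
      }
    }
    // measurement update
    double t1 = std::tanh(k_mu * m1), t2 = std::tanh(k_M * m2);
    double h1 = c * t1, h2 = c * t2;
    double H1 = c * k_mu * (1.0 - t1 * t1);
    double H2 = c * k_M * (1.0 - t2 * t2);
    double s11 = H1 * p11 * H1 + r_var;
    double s12 = H1 * p12 * H2;
    double s22 = H2 * p22 * H2 + r_var;
    double dets = s11 * s22 - s12 * s12;
    if (!(dets > 0.0) || !std::isfinite(dets)) {
      return List::create(_["loglik"] = R_NegInf, _["repairs"] = repairs);
    }
    double e1 = y_mu[i] - h1, e2 = y_M[i] - h2;
    double quad = (s22 * e1 * e1 - 2.0 * s12 * e1 * e2 + s11 * e2 * e2) / dets;
    ll += -LOG2PI - 0.5 * std::log(dets) - 0.5 * quad;
    // gain K = P H' S^{-1} (H diagonal)
    double ph11 = p11 * H1, ph12 = p12 * H2;
    double ph21 = p12 * H1, ph22 = p22 * H2;
    double K11 = (ph11 * s22 - ph12 * s12) / dets;
    double K12 = (-ph11 * s12 + ph12 * s11) / dets;
    double K21 = (ph21 * s22 - ph22 * s12) / dets;
    double K22 = (-ph21 * s12 + ph22 * s11) / dets;
    m1 += K11 * e1 + K12 * e2;
    m2 += K21 * e1 + K22 * e2;
    // Joseph-form covariance update
    double A11 = 1.0 - K11 * H1, A12 = -K12 * H2;
    double A21 = -K21 * H1, A22 = 1.0 - K22 * H2;
    double ap11 = A11 * p11 + A12 * p12, ap12 = A11 * p12 + A12 * p22;
    double ap21 = A21 * p11 + A22 * p12, ap22 = A21 * p12 + A22 * p22;
    double np11 = ap11 * A11 + ap12 * A12 + r_var * (K11 * K11 + K12 * K12);
    double np22 = ap21 * A21 + ap22 * A22 + r_var * (K21 * K21 + K22 * K22);
    double np12 = 0.5 * ((ap11 * A21 + ap12 * A22) +
                         (ap21 * A11 + ap22 * A12)) +
                  r_var * (K11 * K21 + K12 * K22);
    p11 = np11; p12 = np12; p22 = np22;
    if (repair_cov2(p11, p12, p22, 1e-12)) ++repairs;
  }
  return List::create(_["loglik"] = ll, _["repairs"] = repairs);
}
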