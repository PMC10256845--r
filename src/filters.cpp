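#include <Rcpp.h>
using namespace Rcpp;

// Sequential belief-update kernels for the observer models. These sit inside
// the MAP objective and are evaluated ~10^5 times per recovery study, hence C++.

static inline double sgm(double x, double pfloor) {
  double p = 1.0 / (1.0 + std::exp(-x));
  if (p < pfloor) p = pfloor;
  if (p > 1.0 - pfloor) p = 1.0 - pfloor;
  return p;
}

static void check_finite(double x, int trial, const char *what) {
  if (!std::isfinite(x)) {
    stop("numerical overflow in %s at trial %d", what, trial + 1);
  }
}

// Two-level binary Hierarchical Gaussian Filter.
// Per trial: mu1hat = s(mu2), pi1hat = 1/(mu1hat(1-mu1hat)), delta = u - mu1hat,
// pi2hat = 1/(sigma2 + e^omega), pi2 = pi2hat + 1/pi1hat, epsilon = delta/pi2,
// mu2 <- mu2 + epsilon, sigma2 <- 1/pi2.
// [[Rcpp::export]]
List hgf2_filter_cpp(IntegerVector u, double omega, double mu2_0, double sigma2_0,
                     double pfloor) {
  int n = u.size();
  NumericVector mu1_hat(n), mu2(n), sigma2(n), pi2_hat(n), pi2(n), delta(n),
      epsilon(n);
  double m2 = mu2_0, s2 = sigma2_0, ew = std::exp(omega);
  for (int t = 0; t < n; ++t) {
    double mh = sgm(m2, pfloor);
    double p2h = 1.0 / (s2 + ew);
    double p2 = p2h + mh * (1.0 - mh);
    double d = (double)u[t] - mh;
    double eps = d / p2;
    m2 += eps;
    s2 = 1.0 / p2;
    check_finite(m2, t, "hgf2 mu2");
    check_finite(s2, t, "hgf2 sigma2");
    mu1_hat[t] = mh;
    pi2_hat[t] = p2h;
    pi2[t] = p2;
    delta[t] = d;
    epsilon[t] = eps;
    mu2[t] = m2;
    sigma2[t] = s2;
  }
  return List::create(_["mu1_hat"] = mu1_hat, _["mu2"] = mu2,
                      _["sigma2"] = sigma2, _["pi2_hat"] = pi2_hat,
                      _["pi2"] = pi2, _["delta"] = delta,
                      _["epsilon"] = epsilon);
}

// Three-level binary HGF (volatility level): level-2 step variance
// exp(kappa*mu3 + omega2); level-3 random walk with variance e^theta,
// updated by the volatility prediction error.
// [[Rcpp::export]]
List hgf3_filter_cpp(IntegerVector u, double omega2, double kappa, double theta,
                     double mu2_0, double sigma2_0, double mu3_0,
                     double sigma3_0, double pfloor) {
  int n = u.size();
  NumericVector mu1_hat(n), mu2(n), sigma2(n), mu3(n), sigma3(n), pi2_hat(n),
      pi2(n), delta(n), epsilon(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  double eth = std::exp(theta);
  for (int t = 0; t < n; ++t) {
    double v2 = std::exp(kappa * m3 + omega2);
    double mh = sgm(m2, pfloor);
    double p2h = 1.0 / (s2 + v2);
    double p2 = p2h + mh * (1.0 - mh);
    double d = (double)u[t] - mh;
    double eps = d / p2;
    double m2_prev = m2;
    m2 += eps;
    double s2_new = 1.0 / p2;
    // volatility prediction error at level 2
    double da2 = (s2_new + (m2 - m2_prev) * (m2 - m2_prev)) * p2h - 1.0;
    double w2 = v2 * p2h;
    double p3h = 1.0 / (s3 + eth);
    double p3 = p3h + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * da2);
    if (p3 <= 0.0)
      stop("numerical overflow in hgf3 pi3 at trial %d (negative precision)",
           t + 1);
    m3 += (kappa / 2.0) * (w2 / p3) * da2;
    s3 = 1.0 / p3;
    s2 = s2_new;
    check_finite(m2, t, "hgf3 mu2");
    check_finite(m3, t, "hgf3 mu3");
    mu1_hat[t] = mh;
    pi2_hat[t] = p2h;
    pi2[t] = p2;
    delta[t] = d;
    epsilon[t] = eps;
    mu2[t] = m2;
    sigma2[t] = s2;
    mu3[t] = m3;
    sigma3[t] = s3;
  }
  return List::create(_["mu1_hat"] = mu1_hat, _["mu2"] = mu2,
                      _["sigma2"] = sigma2, _["mu3"] = mu3,
                      _["sigma3"] = sigma3, _["pi2_hat"] = pi2_hat,
                      _["pi2"] = pi2, _["delta"] = delta,
                      _["epsilon"] = epsilon);
}

// Rescorla-Wagner: V <- V + alpha*(u - V); prediction for trial t is V_{t-1}.
// [[Rcpp::export]]
List rw_filter_cpp(IntegerVector u, double alpha, double v0) {
  int n = u.size();
  NumericVector mu1_hat(n), value(n), delta(n);
  double v = v0;
  for (int t = 0; t < n; ++t) {
    double d = (double)u[t] - v;
    mu1_hat[t] = v;
    delta[t] = d;
    v += alpha * d;
    value[t] = v;
  }
  return List::create(_["mu1_hat"] = mu1_hat, _["value"] = value,
                      _["delta"] = delta);
}

// Sutton (1992) K1 incremental delta-bar-delta:
// beta <- beta + mu_meta*delta*h; alpha = min(exp(beta), 1);
// V <- V + alpha*delta; h <- h*max(0, 1-alpha) + alpha*delta.
// [[Rcpp::export]]
List k1_filter_cpp(IntegerVector u, double mu_meta, double beta0, double v0) {
  int n = u.size();
  NumericVector mu1_hat(n), value(n), delta(n), lrate(n);
  double v = v0, beta = beta0, h = 0.0;
  for (int t = 0; t < n; ++t) {
    double d = (double)u[t] - v;
    beta += mu_meta * d * h;
    if (beta > 0.0) beta = 0.0;  // caps alpha = exp(beta) at 1
    double a = std::exp(beta);
    mu1_hat[t] = v;
    delta[t] = d;
    v += a * d;
    h = h * std::max(0.0, 1.0 - a) + a * d;
    value[t] = v;
    lrate[t] = a;
    check_finite(v, t, "k1 value");
  }
  return List::create(_["mu1_hat"] = mu1_hat, _["value"] = value,
                      _["delta"] = delta, _["lrate"] = lrate);
}

// Scalar Kalman filter with process noise q and observation noise r_obs:
// k = (s+q)/(s+q+r); V <- V + k*(u-V); s <- (1-k)(s+q).
// [[Rcpp::export]]
List kalman_filter_cpp(IntegerVector u, double q, double r_obs, double v0,
                       double s0) {
  int n = u.size();
  NumericVector mu1_hat(n), value(n), delta(n), gain(n), svar(n);
  double v = v0, s = s0;
  for (int t = 0; t < n; ++t) {
    double sp = s + q;
    double k = sp / (sp + r_obs);
    double d = (double)u[t] - v;
    mu1_hat[t] = v;
    delta[t] = d;
    v += k * d;
    s = (1.0 - k) * sp;
    value[t] = v;
    gain[t] = k;
    svar[t] = s;
  }
  return List::create(_["mu1_hat"] = mu1_hat, _["value"] = value,
                      _["delta"] = delta, _["gain"] = gain, _["svar"] = svar);
}
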