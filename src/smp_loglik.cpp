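// Fast SMP trial-density kernel used by the hierarchical fitter.
//
// The candidate-path density of (reported association, generation time) has
// the transform-domain form
//   L_j(s) = P(A_j) acc_j G_j(s) / (1 - sum_i P(A_i)(1 - acc_i) G_i(s))
// with G_i(s) = (1 + s * scale_i)^(-shape) the gamma-time transform.  The
// uniform non-decision window on [tau0, tau0 + tau_r] composes exactly as a
// difference of the generation-time CDF divided by tau_r, so the joint
// density at rt is  w_j * (F(rt - tau0) - F(rt - tau0 - tau_r)) / tau_r
// where F is recovered from L_j(s)/s by Abate–Whitt Euler numerical
// inversion (two point evaluations per trial).  The slower grid-convolution
// reference implementation lives in R/smp-core.R; tests assert agreement
// between the two routes and against Monte-Carlo simulation.

#include <RcppArmadillo.h>
#include <complex>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cx;

static const double ACC_SLOPE = 10.0;
static const double LOG_FLOOR = -745.0;  // underflow guard on log densities

// Euler-inversion constants (Abate & Whitt): discretisation parameter A,
// N plain terms, M binomially averaged terms; ~1e-8 accuracy.
static const double AW_A = 18.4;
static const int AW_N = 24;
static const int AW_M = 12;

struct PathTransform {
  const arma::vec& w_rej;   // P(A_i)(1 - acc_i)
  const arma::vec& scl;     // gamma scales
  double shape;
  double w_j;               // P(A_j) acc_j
  int j0;

  cx operator()(cx s) const {
    cx gj = (scl[j0] > 0) ? std::pow(1.0 + s * scl[j0], -shape) : cx(1.0);
    cx denom(1.0, 0.0);
    for (arma::uword i = 0; i < w_rej.n_elem; ++i) {
      if (w_rej[i] <= 0) continue;
      cx gi = (scl[i] > 0) ? std::pow(1.0 + s * scl[i], -shape) : cx(1.0);
      denom -= w_rej[i] * gi;
    }
    return w_j * gj / denom;
  }
};

// CDF of the (defective) total-generation-time distribution at t,
// inverting L(s)/s by the Euler method.
static double euler_cdf(const PathTransform& L, double t) {
  if (t <= 0.0) return 0.0;
  const int n_terms = AW_N + AW_M;
  double terms[AW_N + AW_M + 1];
  double x = AW_A / (2.0 * t);
  double h = M_PI / t;
  terms[0] = 0.5 * std::real(L(cx(x, 0.0)) / cx(x, 0.0));
  for (int k = 1; k <= n_terms; ++k) {
    cx s(x, k * h);
    double re = std::real(L(s) / s);
    terms[k] = (k % 2 == 0) ? re : -re;
  }
  // partial sums s_N .. s_{N+M}, binomially averaged
  double partial = 0.0;
  for (int k = 0; k <= AW_N; ++k) partial += terms[k];
  double avg = 0.0, binom = 1.0, binom_sum = 0.0;
  for (int m = 0; m <= AW_M; ++m) {
    if (m > 0) {
      partial += terms[AW_N + m];
      binom = binom * (AW_M - m + 1) / m;
    }
    avg += binom * partial;
    binom_sum += binom;
  }
  avg /= binom_sum;  // binom_sum = 2^M
  double f = std::exp(AW_A / 2.0) / t * avg;
  return std::max(f, 0.0);
}

// joint density of (reported = j0 [0-based], rt seconds) for one cue
static double trial_density_core(const arma::vec& ptp, int j0, double rt,
                                 double beta, double alpha_i,
                                 double alpha_sign, double s_mu,
                                 double lambda, double tau0, double tau_r,
                                 bool no_rejection) {
  const int k = ptp.n_elem;
  arma::vec lw = std::exp(beta) * arma::log(ptp);
  lw -= lw.max();
  arma::vec prob = arma::exp(lw);
  prob /= arma::accu(prob);

  arma::vec acc(k, arma::fill::ones);
  if (!no_rejection) {
    double mn = ptp.min(), mx = ptp.max();
    for (int i = 0; i < k; ++i) {
      double m = (mx > mn) ? (ptp[i] - mn) / (mx - mn) : 0.5;
      if (alpha_sign < 0) m = 1.0 - m;
      acc[i] = 1.0 / (1.0 + std::exp(-ACC_SLOPE * (m - alpha_i)));
    }
  }

  arma::vec mu = std::exp(s_mu) * (-arma::log(prob));
  double shape = 1.0 / (lambda * lambda);
  arma::vec scl = (lambda * lambda) * mu;
  arma::vec w_rej = prob % (1.0 - acc);
  double q = arma::accu(w_rej);
  double w_j = prob[j0] * acc[j0];

  double u1 = rt - tau0;
  double u2 = rt - tau0 - tau_r;
  if (u1 <= 0.0) return 0.0;

  if (mu.max() < 1e-12) {  // all generation times degenerate at 0
    double ind = (u1 >= 0.0 ? 1.0 : 0.0) - (u2 >= 0.0 ? 1.0 : 0.0);
    return w_j / (1.0 - q) * ind / tau_r;
  }

  PathTransform L{w_rej, scl, shape, w_j, j0};
  double f1 = euler_cdf(L, u1);
  double f2 = (u2 > 0.0) ? euler_cdf(L, u2) : 0.0;
  f2 = std::min(f2, f1);  // enforce CDF monotonicity against inversion noise
  return (f1 - f2) / tau_r;
}

// Log-likelihood of one participant's trials under each parameter setting.
// cue_ptp: list of typicality vectors (one per trial); rep_idx: 1-based
// reported-candidate index per trial; rt: seconds; settings: n_settings x 7
// matrix with columns beta, alpha_i, alpha_sign, s_mu, lambda, tau0, tau_r.
// [[Rcpp::export]]
NumericVector participant_loglik_cpp(List cue_ptp, IntegerVector rep_idx,
                                     NumericVector rt,
                                     NumericMatrix settings,
                                     bool no_rejection) {
  const int n_trials = cue_ptp.size();
  const int n_set = settings.nrow();
  std::vector<arma::vec> ptps(n_trials);
  for (int t = 0; t < n_trials; ++t)
    ptps[t] = as<arma::vec>(cue_ptp[t]);

  NumericVector out(n_set);
  for (int s = 0; s < n_set; ++s) {
    double ll = 0.0;
    for (int t = 0; t < n_trials; ++t) {
      double d = trial_density_core(
          ptps[t], rep_idx[t] - 1, rt[t], settings(s, 0), settings(s, 1),
          settings(s, 2), settings(s, 3), settings(s, 4), settings(s, 5),
          settings(s, 6), no_rejection);
      double ld = (d > 0 && std::isfinite(d)) ? std::log(d) : LOG_FLOOR;
      ll += std::max(ld, LOG_FLOOR);
    }
    out[s] = ll;
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Single-trial density, exposed for cross-checking against the R reference.
// [[Rcpp::export]]
double trial_density_cpp(NumericVector ptp, int rep_idx, double rt,
                         NumericVector params, bool no_rejection) {
  return trial_density_core(as<arma::vec>(ptp), rep_idx - 1, rt, params[0],
                            params[1], params[2], params[3], params[4],
                            params[5], params[6], no_rejection);
}
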