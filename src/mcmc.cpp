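// MCMC engines for the Bayesian-alphabet whole-genome regression methods.
//
// Families: A  (every locus has an effect, locus-specific variance),
//           B  (mixture spike at zero + locus-specific variance, MH on the
//               variance with the effect integrated out),
//           Cpi (mixture spike at zero + one variance common to all loci).
// The flexible variants sample the scaled-inverse-chi-square hyperparameters:
// the scale S2 by a conjugate Gamma Gibbs step and the degrees of freedom v
// by accept-reject under an exponential envelope whose rate is tuned at the
// root x* of the derivative h(x) of the log ratio log f - log g.
//
// All random numbers come from R's RNG so chains are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// degrees-of-freedom target, envelope construction and accept-reject sampler
// ---------------------------------------------------------------------------

// log unnormalised full-conditional density of the prior degrees of freedom x:
//   f(x; q, eta) = (x/2)^{q x/2} Gamma(x/2)^{-q} exp(-eta x)        (variant 1)
// with an extra x^3 factor when the prior on v is Gamma(4, 1)       (variant 2)
static double log_target_df_c(double x, double q, double eta, int variant) {
  if (x <= 0.0) return R_NegInf;
  double lt = 0.5 * q * x * std::log(0.5 * x) - q * R::lgammafn(0.5 * x) - eta * x;
  if (variant == 2) lt += 3.0 * std::log(x);
  return lt;
}

// h(x) = d/dx log[f(x)/g(x)] after substituting the envelope rate theta = 1/x:
//   (q/2)[ln(x/2) + 1 - psi(x/2)] + 1/x - eta   (+ 3/x for variant 2)
// h is strictly decreasing with h -> +Inf as x -> 0+ and h -> q/2 - eta < 0.
static double h_df(double x, double q, double eta, int variant) {
  double h = 0.5 * q * (std::log(0.5 * x) + 1.0 - R::digamma(0.5 * x)) + 1.0 / x - eta;
  if (variant == 2) h += 3.0 / x;
  return h;
}

// unique root of h by exponential bracketing (double/halve from 1) followed
// by bisection; h is monotone so the bracket is valid once the signs differ.
static double solve_x_star_c(double q, double eta, int variant, double tol) {
  double lo = 1.0, hi = 1.0;
  int it = 0;
  while (h_df(lo, q, eta, variant) <= 0.0 && ++it < 3000) lo *= 0.5;
  it = 0;
  while (h_df(hi, q, eta, variant) >= 0.0 && ++it < 3000) hi *= 2.0;
  for (int k = 0; k < 500; ++k) {
    double mid = 0.5 * (lo + hi);
    double hm  = h_df(mid, q, eta, variant);
    if (std::fabs(hm) < tol || (hi - lo) < 1e-14 * mid) return mid;
    if (hm > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

struct df_diag { long proposals; long accepts; long violations; };

// one accept-reject draw of the degrees of freedom.  For q = 0 the target
// reduces to the prior itself (Exponential(eta) or Gamma(4, rate eta)) and is
// drawn directly.  Envelope domination ln f(c) <= logM + ln g(c; theta) is
// checked for every proposal.
static double sample_df_c(double q, double eta, int variant, df_diag *dg) {
  if (q < 0.5) {
    if (variant == 2) return R::rgamma(4.0, 1.0 / eta);
    return exp_rand() / eta;
  }
  double xs    = solve_x_star_c(q, eta, variant, 1e-10);
  double theta = 1.0 / xs;
  double logM  = log_target_df_c(xs, q, eta, variant) - (std::log(theta) - theta * xs);
  for (long k = 0; k < 1000000L; ++k) {
    double c    = exp_rand() / theta;
    double logf = log_target_df_c(c, q, eta, variant);
    double logg = std::log(theta) - theta * c;
    double logr = logf - logM - logg;
    dg->proposals++;
    if (logr > 1e-8) dg->violations++;
    if (std::log(unif_rand()) <= logr) { dg->accepts++; return c; }
  }
  stop("accept-reject sampler for the degrees of freedom exceeded 1e6 rejections");
  return NA_REAL; // not reached
}

// [[Rcpp::export]]
double cpp_log_target_df(double x, double q, double eta, int variant) {
  return log_target_df_c(x, q, eta, variant);
}

// [[Rcpp::export]]
double cpp_h_df(double x, double q, double eta, int variant) {
  return h_df(x, q, eta, variant);
}

// [[Rcpp::export]]
double cpp_solve_x_star(double q, double eta, int variant) {
  return solve_x_star_c(q, eta, variant, 1e-10);
}

// [[Rcpp::export]]
List cpp_sample_df(int n, double q, double eta, int variant) {
  NumericVector out(n);
  df_diag dg = {0L, 0L, 0L};
  for (int i = 0; i < n; ++i) out[i] = sample_df_c(q, eta, variant, &dg);
  double xs = (q < 0.5) ? NA_REAL : solve_x_star_c(q, eta, variant, 1e-10);
  return List::create(_["draws"] = out,
                      _["n_proposals"] = (double)dg.proposals,
                      _["n_accepts"] = (double)dg.accepts,
                      _["n_envelope_violations"] = (double)dg.violations,
                      _["x_star"] = xs);
}

// ---------------------------------------------------------------------------
// full Gibbs / MH chain
// ---------------------------------------------------------------------------

// marginal log-likelihood contribution of locus j as a function of its effect
// variance s2 with the effect integrated out: a = z'r ~ N(0, b^2 s2 + b se2)
// where b = z'z and r is the residual with locus j removed.
static inline double loglik_var(double a, double b, double s2, double se2) {
  double vv = b * b * s2 + b * se2;
  return -0.5 * std::log(vv) - a * a / (2.0 * vv);
}

// [[Rcpp::export]]
List cpp_bayes_chain(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                     int family,          // 0 = A, 1 = B, 2 = Cpi
                     int v_mode,          // 0 fixed, 1 Exponential(lambda), 2 Gamma(4,1)
                     int s2_mode,         // 0 fixed, 1 Gamma(1,1) prior, sampled
                     int pi_mode,         // 0 fixed, 1 Beta Gibbs update
                     double v_init, double S2_init, double pi_init, double lambda,
                     int n_iter, int burn_in, int mh_cycles) {
  const int n = (int)y.n_elem, P = (int)Z.n_cols, pf = (int)X.n_cols;
  if ((int)Z.n_rows != n || (int)X.n_rows != n) stop("dimension mismatch between y, X and Z");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  arma::vec zz(P), alpha(P, arma::fill::zeros), sigma_j2(P, arma::fill::zeros);
  std::vector<int> active(P, 1);
  int n_active = 0, n_mono = 0;
  for (int j = 0; j < P; ++j) {
    zz[j] = arma::dot(Z.col(j), Z.col(j));
    double m = arma::mean(Z.col(j));
    double var_j = zz[j] / n - m * m;
    if (var_j <= 1e-12) { active[j] = 0; n_mono++; } else n_active++;
  }

  arma::vec b(pf, arma::fill::zeros);
  double sigma_a2 = S2_init;
  double sigma_e2 = arma::var(y) * 0.5;
  if (sigma_e2 <= 0.0) sigma_e2 = 1.0;
  double v = v_init, S2 = S2_init, pi = pi_init;

  // family A fits every active locus from the start
  if (family == 0) for (int j = 0; j < P; ++j) sigma_j2[j] = active[j] ? S2_init : 0.0;

  arma::vec e = y - X * b - Z * alpha;

  const int n_keep = n_iter - burn_in;
  arma::vec alpha_sum(P, arma::fill::zeros), delta_sum(P, arma::fill::zeros),
            b_sum(pf, arma::fill::zeros);
  arma::mat trace(n_iter, 6); // v, S2, pi, sigma_e2, q, sigma_a2
  df_diag dg = {0L, 0L, 0L};
  long mh_prop = 0L, mh_acc = 0L;
  long eta_violations = 0L;
  const int variant = (v_mode == 2) ? 2 : 1;
  const double prior_shift = (variant == 2) ? 1.0 : lambda;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, flat prior ---
    for (int k = 0; k < pf; ++k) {
      arma::vec xk = X.col(k);
      e += xk * b[k];
      double xx = arma::dot(xk, xk);
      double mu = arma::dot(xk, e) / xx;
      b[k] = mu + norm_rand() * std::sqrt(sigma_e2 / xx);
      e -= xk * b[k];
    }

    int q = 0;                // loci with a non-zero effect this cycle
    double sum_alpha2 = 0.0;

    if (family == 0) {        // ---------------- BayesA / BayesFA ----------------
      for (int j = 0; j < P; ++j) {
        if (!active[j]) continue;
        double aold = alpha[j];
        if (aold != 0.0) e += Z.col(j) * aold;
        double a = arma::dot(Z.col(j), e);
        double C = sigma_e2 / (zz[j] + sigma_e2 / sigma_j2[j]);
        double an = C * a / sigma_e2 + norm_rand() * std::sqrt(C);
        alpha[j] = an;
        e -= Z.col(j) * an;
        sigma_j2[j] = (v * S2 + an * an) / R::rchisq(v + 1.0);
      }
      q = n_active;
    } else if (family == 1) { // ---------------- BayesB / BayesFB ----------------
      for (int j = 0; j < P; ++j) {
        if (!active[j]) continue;
        double aold = alpha[j];
        if (aold != 0.0) e += Z.col(j) * aold;
        double a  = arma::dot(Z.col(j), e);
        double l0 = loglik_var(a, zz[j], 0.0, sigma_e2);
        double scur = sigma_j2[j];
        double lcur = (scur > 0.0) ? loglik_var(a, zz[j], scur, sigma_e2) : l0;
        for (int c = 0; c < mh_cycles; ++c) {
          bool prop_zero = (unif_rand() < pi);
          if (prop_zero && scur == 0.0) continue; // ratio 1, state unchanged
          double sprop = prop_zero ? 0.0 : v * S2 / R::rchisq(v);
          double lprop = prop_zero ? l0 : loglik_var(a, zz[j], sprop, sigma_e2);
          mh_prop++;
          double lr = lprop - lcur;
          if (lr >= 0.0 || std::log(unif_rand()) <= lr) {
            scur = sprop; lcur = lprop; mh_acc++;
          }
        }
        sigma_j2[j] = scur;
        double an = 0.0;
        if (scur > 0.0) {
          double C = sigma_e2 / (zz[j] + sigma_e2 / scur);
          an = C * a / sigma_e2 + norm_rand() * std::sqrt(C);
          q++;
        }
        alpha[j] = an;
        if (an != 0.0) e -= Z.col(j) * an;
      }
    } else {                  // ---------------- BayesCpi / BayesFCpi ------------
      for (int j = 0; j < P; ++j) {
        if (!active[j]) continue;
        double aold = alpha[j];
        if (aold != 0.0) e += Z.col(j) * aold;
        double a = arma::dot(Z.col(j), e);
        double p_incl;
        if (pi <= 0.0) p_incl = 1.0;
        else if (pi >= 1.0) p_incl = 0.0;
        else {
          double l1 = loglik_var(a, zz[j], sigma_a2, sigma_e2);
          double l0 = loglik_var(a, zz[j], 0.0, sigma_e2);
          double logodds = l1 - l0 + std::log(1.0 - pi) - std::log(pi);
          p_incl = 1.0 / (1.0 + std::exp(-logodds));
        }
        double an = 0.0;
        if (unif_rand() < p_incl) {
          double C = sigma_e2 / (zz[j] + sigma_e2 / sigma_a2);
          an = C * a / sigma_e2 + norm_rand() * std::sqrt(C);
          q++; sum_alpha2 += an * an;
        }
        alpha[j] = an;
        if (an != 0.0) e -= Z.col(j) * an;
      }
      sigma_a2 = (v * S2 + sum_alpha2) / R::rchisq(v + (double)q);
    }

    // --- hyperparameters of the SNP-variance prior (flexible methods) ---
    // q_v / sums over the variances currently in the model
    double q_v, sum_inv, sum_log;
    if (family == 0) {
      q_v = n_active; sum_inv = 0.0; sum_log = 0.0;
      for (int j = 0; j < P; ++j) if (active[j]) {
        sum_inv += 1.0 / sigma_j2[j]; sum_log += std::log(sigma_j2[j]);
      }
    } else if (family == 1) {
      q_v = 0.0; sum_inv = 0.0; sum_log = 0.0;
      for (int j = 0; j < P; ++j) if (sigma_j2[j] > 0.0) {
        q_v += 1.0; sum_inv += 1.0 / sigma_j2[j]; sum_log += std::log(sigma_j2[j]);
      }
    } else {
      q_v = (double)q; sum_inv = q / sigma_a2; sum_log = q * std::log(sigma_a2);
    }

    if (s2_mode == 1) {       // S2 | ... ~ Gamma(v q/2 + 1, rate v/2 sum(1/s2) + 1)
      S2 = R::rgamma(0.5 * v * q_v + 1.0, 1.0 / (0.5 * v * sum_inv + 1.0));
    }
    if (v_mode != 0) {        // v by accept-reject under the exponential envelope
      double eta = 0.5 * (sum_log - q_v * std::log(S2)) + 0.5 * S2 * sum_inv + prior_shift;
      if (eta < 0.5 * q_v + prior_shift - 1e-8) eta_violations++;
      v = sample_df_c(q_v, eta, variant, &dg);
    }
    if (pi_mode == 1) pi = R::rbeta((double)(P - q) + 1.0, (double)q + 1.0);

    sigma_e2 = arma::dot(e, e) / R::rchisq((double)n - 2.0);

    if (!std::isfinite(sigma_e2) || !std::isfinite(v) || !std::isfinite(S2) ||
        !arma::is_finite(alpha))
      stop("non-finite sampled value at iteration %d", it + 1);

    trace(it, 0) = v;  trace(it, 1) = S2; trace(it, 2) = pi;
    trace(it, 3) = sigma_e2; trace(it, 4) = (double)q;
    trace(it, 5) = (family == 2) ? sigma_a2 : NA_REAL;

    if (it >= burn_in) {
      alpha_sum += alpha;
      b_sum += b;
      for (int j = 0; j < P; ++j) if (alpha[j] != 0.0) delta_sum[j] += 1.0;
    }
  }

  return List::create(
    _["alpha"] = alpha_sum / n_keep,
    _["b"] = b_sum / n_keep,
    _["inclusion"] = delta_sum / n_keep,
    _["trace"] = trace,
    _["n_monomorphic"] = n_mono,
    _["ar_proposals"] = (double)dg.proposals,
    _["ar_accepts"] = (double)dg.accepts,
    _["ar_envelope_violations"] = (double)dg.violations,
    _["eta_bound_violations"] = (double)eta_violations,
    _["mh_proposals"] = (double)mh_prop,
    _["mh_accepts"] = (double)mh_acc);
}
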