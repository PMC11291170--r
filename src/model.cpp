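#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood of one condition's trials under the
// lapse-contaminated cumulative-Gaussian psychometric function
//   theta = l1 + (1 - l1 - l2) * Phi((omega - B) / S).
// y is 1 for a rightward choice, 0 for leftward.
static double cond_ll(const NumericVector &om, const IntegerVector &y,
                      double B, double S, double l1, double l2) {
  if (S <= 0.0 || l1 < 0.0 || l2 < 0.0 || l1 + l2 >= 1.0) return R_NegInf;
  const double range = 1.0 - l1 - l2;
  double ll = 0.0;
  const int n = om.size();
  for (int i = 0; i < n; ++i) {
    double th = l1 + range * R::pnorm((om[i] - B) / S, 0.0, 1.0, 1, 0);
    if (th < 1e-12) th = 1e-12;
    else if (th > 1.0 - 1e-12) th = 1.0 - 1e-12;
    ll += y[i] ? std::log(th) : std::log1p(-th);
  }
  return ll;
}

// [[Rcpp::export]]
double cond_loglik_cpp(NumericVector omega, IntegerVector y,
                       double B, double S, double l1, double l2) {
  return cond_ll(omega, y, B, S, l1, l2);
}

static inline double bias_lp(double x, double m, double tau, bool flat) {
  if (flat) return (x >= -180.0 && x <= 180.0) ? 0.0 : R_NegInf;
  return R::dnorm(x, m, tau, 1);
}

static inline double s_lp(double s, double shape, double rate) {
  if (s <= 0.0) return R_NegInf;
  return R::dgamma(s, shape, 1.0 / rate, 1);
}

static inline double lapse_lp(double l, double g, double e) {
  if (l < 0.0 || l > 1.0) return R_NegInf;
  return R::dbeta(l, g, e, 1);
}

struct PsyPrior {
  double mPL, tPL, mPR, tPR, mD, tD; // Gaussian bias priors
  bool flat;                         // Uniform(-180, 180) on all biases
  double aS, bS;                     // gamma(shape, rate) on S
  double gl, el;                     // beta on lapses
};

// Parameter vector layout for the three-condition model:
// 0 PL, 1 PR, 2 D, 3 SL, 4 SN, 5 SR,
// 6 l1L, 7 l2L, 8 l1N, 9 l2N, 10 l1R, 11 l2R
static const int NPAR = 12;

// One Metropolis-within-Gibbs sweep over all 12 parameters.
// ll[0..2] caches the current condition log-likelihoods (L, N, R)
// and is kept in sync.  acc[i] incremented on acceptance.
static void sweep_once(const NumericVector &omL, const IntegerVector &yL,
                       const NumericVector &omN, const IntegerVector &yN,
                       const NumericVector &omR, const IntegerVector &yR,
                       double *par, double *ll, const double *scale,
                       const PsyPrior &pr, int *acc) {
  for (int i = 0; i < NPAR; ++i) {
    double cur = par[i];
    double prop = cur + scale[i] * norm_rand();
    double d_lp;     // prior log-density delta
    double new_ll[3] = {ll[0], ll[1], ll[2]};
    bool ok = true;
    switch (i) {
    case 0: // PL -> condition L
      d_lp = bias_lp(prop, pr.mPL, pr.tPL, pr.flat) -
             bias_lp(cur, pr.mPL, pr.tPL, pr.flat);
      new_ll[0] = cond_ll(omL, yL, prop + par[2], par[3], par[6], par[7]);
      break;
    case 1: // PR -> condition R
      d_lp = bias_lp(prop, pr.mPR, pr.tPR, pr.flat) -
             bias_lp(cur, pr.mPR, pr.tPR, pr.flat);
      new_ll[2] = cond_ll(omR, yR, prop + par[2], par[5], par[10], par[11]);
      break;
    case 2: // D -> all conditions
      d_lp = bias_lp(prop, pr.mD, pr.tD, pr.flat) -
             bias_lp(cur, pr.mD, pr.tD, pr.flat);
      new_ll[0] = cond_ll(omL, yL, par[0] + prop, par[3], par[6], par[7]);
      new_ll[1] = cond_ll(omN, yN, prop, par[4], par[8], par[9]);
      new_ll[2] = cond_ll(omR, yR, par[1] + prop, par[5], par[10], par[11]);
      break;
    case 3:
      d_lp = s_lp(prop, pr.aS, pr.bS) - s_lp(cur, pr.aS, pr.bS);
      ok = prop > 0.0;
      if (ok) new_ll[0] = cond_ll(omL, yL, par[0] + par[2], prop, par[6], par[7]);
      break;
    case 4:
      d_lp = s_lp(prop, pr.aS, pr.bS) - s_lp(cur, pr.aS, pr.bS);
      ok = prop > 0.0;
      if (ok) new_ll[1] = cond_ll(omN, yN, par[2], prop, par[8], par[9]);
      break;
    case 5:
      d_lp = s_lp(prop, pr.aS, pr.bS) - s_lp(cur, pr.aS, pr.bS);
      ok = prop > 0.0;
      if (ok) new_ll[2] = cond_ll(omR, yR, par[0 + 1] + par[2], prop, par[10], par[11]);
      break;
    default: { // lapses
      d_lp = lapse_lp(prop, pr.gl, pr.el) - lapse_lp(cur, pr.gl, pr.el);
      ok = prop >= 0.0 && prop <= 1.0;
      if (ok) {
        int which = (i - 6) / 2; // 0 L, 1 N, 2 R
        double l1, l2, B, S;
        if (which == 0) {
          l1 = (i == 6) ? prop : par[6]; l2 = (i == 7) ? prop : par[7];
          B = par[0] + par[2]; S = par[3];
        } else if (which == 1) {
          l1 = (i == 8) ? prop : par[8]; l2 = (i == 9) ? prop : par[9];
          B = par[2]; S = par[4];
        } else {
          l1 = (i == 10) ? prop : par[10]; l2 = (i == 11) ? prop : par[11];
          B = par[0 + 1] + par[2]; S = par[5];
        }
        ok = (l1 + l2) < 1.0;
        if (ok) {
          const NumericVector &om = (which == 0) ? omL : (which == 1 ? omN : omR);
          const IntegerVector &yy = (which == 0) ? yL : (which == 1 ? yN : yR);
          new_ll[which] = cond_ll(om, yy, B, S, l1, l2);
        }
      }
      break;
    }
    }
    if (!ok || !R_finite(d_lp)) {
      if (!R_finite(d_lp) && d_lp > 0) { /* never: keep -Inf rejections */ }
      continue;
    }
    double d_ll = (new_ll[0] - ll[0]) + (new_ll[1] - ll[1]) + (new_ll[2] - ll[2]);
    if (std::log(unif_rand()) < d_lp + d_ll) {
      par[i] = prop;
      ll[0] = new_ll[0]; ll[1] = new_ll[1]; ll[2] = new_ll[2];
      ++acc[i];
    }
  }
}

// Joint posterior sampler for the three-condition model.
// Adaptive random-walk scales during burn-in (target acceptance 0.44,
// batches of 50), frozen afterwards so the kept draws form a valid chain.
// [[Rcpp::export]]
List mcmc_psy_cpp(NumericVector omL, IntegerVector yL,
                  NumericVector omN, IntegerVector yN,
                  NumericVector omR, IntegerVector yR,
                  List prior, int n_samples, int burn_in) {
  PsyPrior pr;
  pr.flat = as<bool>(prior["flat"]);
  pr.mPL = as<double>(prior["P0L"]); pr.tPL = as<double>(prior["tauPL"]);
  pr.mPR = as<double>(prior["P0R"]); pr.tPR = as<double>(prior["tauPR"]);
  pr.mD = as<double>(prior["D0"]);  pr.tD = as<double>(prior["tauD"]);
  pr.aS = as<double>(prior["alpha_S"]); pr.bS = as<double>(prior["beta_S"]);
  pr.gl = as<double>(prior["gamma_lapse"]); pr.el = as<double>(prior["eps_lapse"]);

  double par[NPAR];
  par[0] = pr.flat ? 0.0 : pr.mPL;
  par[1] = pr.flat ? 0.0 : pr.mPR;
  par[2] = pr.flat ? 0.0 : pr.mD;
  par[3] = par[4] = par[5] = pr.aS / pr.bS;
  for (int i = 6; i < NPAR; ++i) par[i] = pr.gl / (pr.gl + pr.el);

  double scale[NPAR] = {5, 5, 5, 2, 2, 2, .03, .03, .03, .03, .03, .03};
  double ll[3];
  ll[0] = cond_ll(omL, yL, par[0] + par[2], par[3], par[6], par[7]);
  ll[1] = cond_ll(omN, yN, par[2], par[4], par[8], par[9]);
  ll[2] = cond_ll(omR, yR, par[1] + par[2], par[5], par[10], par[11]);

  const int n_keep = n_samples - burn_in;
  NumericMatrix draws(n_keep, NPAR);
  int acc[NPAR] = {0}, batch_acc[NPAR] = {0};
  int batch = 0;
  for (int it = 0; it < n_samples; ++it) {
    int before[NPAR];
    std::copy(acc, acc + NPAR, before);
    sweep_once(omL, yL, omN, yN, omR, yR, par, ll, scale, pr, acc);
    if (it < burn_in) {
      for (int i = 0; i < NPAR; ++i) batch_acc[i] += acc[i] - before[i];
      if ((it + 1) % 50 == 0) {
        ++batch;
        double d = std::min(0.05, 1.0 / std::sqrt((double)batch));
        for (int i = 0; i < NPAR; ++i) {
          double rate = batch_acc[i] / 50.0;
          scale[i] *= std::exp(rate > 0.44 ? d : -d);
          batch_acc[i] = 0;
        }
      }
    } else {
      for (int i = 0; i < NPAR; ++i) draws(it - burn_in, i) = par[i];
    }
  }
  NumericVector arate(NPAR), sc(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    arate[i] = acc[i] / (double)n_samples;
    sc[i] = scale[i];
  }
  colnames(draws) = CharacterVector::create(
      "PL", "PR", "D", "SL", "SN", "SR",
      "lambda1_L", "lambda2_L", "lambda1_N", "lambda2_N",
      "lambda1_R", "lambda2_R");
  return List::create(_["draws"] = draws, _["accept"] = arate,
                      _["scales"] = sc);
}

// One sweep of the 12 session-level parameters given externally supplied
// Gaussian prior means/SDs on PL and PR (the hierarchical model's
// conditionals).  par, scales are length 12; returns updated par and
// per-parameter acceptance indicators.
// [[Rcpp::export]]
List mwg_session_sweep_cpp(NumericVector omL, IntegerVector yL,
                           NumericVector omN, IntegerVector yN,
                           NumericVector omR, IntegerVector yR,
                           NumericVector par_in, NumericVector scales,
                           double mPL, double tPL, double mPR, double tPR,
                           double mD, double tD, double aS, double bS,
                           double gl, double el) {
  PsyPrior pr;
  pr.flat = false;
  pr.mPL = mPL; pr.tPL = tPL; pr.mPR = mPR; pr.tPR = tPR;
  pr.mD = mD; pr.tD = tD; pr.aS = aS; pr.bS = bS; pr.gl = gl; pr.el = el;
  double par[NPAR], scale[NPAR];
  for (int i = 0; i < NPAR; ++i) { par[i] = par_in[i]; scale[i] = scales[i]; }
  double ll[3];
  ll[0] = cond_ll(omL, yL, par[0] + par[2], par[3], par[6], par[7]);
  ll[1] = cond_ll(omN, yN, par[2], par[4], par[8], par[9]);
  ll[2] = cond_ll(omR, yR, par[1] + par[2], par[5], par[10], par[11]);
  int acc[NPAR] = {0};
  sweep_once(omL, yL, omN, yN, omR, yR, par, ll, scale, pr, acc);
  NumericVector out(NPAR);
  IntegerVector accepted(NPAR);
  for (int i = 0; i < NPAR; ++i) { out[i] = par[i]; accepted[i] = acc[i]; }
  return List::create(_["par"] = out, _["accepted"] = accepted);
}

// Single-condition sampler for the conventional (empirical-bias prior)
// baseline: parameters (B, S, l1, l2) with Gaussian (or flat) prior on B.
// [[Rcpp::export]]
List mcmc_cond_cpp(NumericVector om, IntegerVector y,
                   double mB, double tB, bool flatB,
                   double aS, double bS, double gl, double el,
                   int n_samples, int burn_in) {
  double par[4] = {flatB ? 0.0 : mB, aS / bS, gl / (gl + el), gl / (gl + el)};
  double scale[4] = {5, 2, .03, .03};
  double ll = cond_ll(om, y, par[0], par[1], par[2], par[3]);
  const int n_keep = n_samples - burn_in;
  NumericMatrix draws(n_keep, 4);
  int batch_acc[4] = {0};
  int batch = 0;
  for (int it = 0; it < n_samples; ++it) {
    for (int i = 0; i < 4; ++i) {
      double cur = par[i], prop = cur + scale[i] * norm_rand();
      double d_lp;
      if (i == 0) d_lp = bias_lp(prop, mB, tB, flatB) - bias_lp(cur, mB, tB, flatB);
      else if (i == 1) d_lp = s_lp(prop, aS, bS) - s_lp(cur, aS, bS);
      else d_lp = lapse_lp(prop, gl, el) - lapse_lp(cur, gl, el);
      if (!R_finite(d_lp)) continue;
      par[i] = prop;
      double new_ll = cond_ll(om, y, par[0], par[1], par[2], par[3]);
      if (R_finite(new_ll) &&
          std::log(unif_rand()) < d_lp + new_ll - ll) {
        ll = new_ll;
        if (it < burn_in) ++batch_acc[i];
      } else {
        par[i] = cur;
      }
    }
    if (it < burn_in && (it + 1) % 50 == 0) {
      ++batch;
      double d = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int i = 0; i < 4; ++i) {
        scale[i] *= std::exp(batch_acc[i] / 50.0 > 0.44 ? d : -d);
        batch_acc[i] = 0;
      }
    }
    if (it >= burn_in)
      for (int i = 0; i < 4; ++i) draws(it - burn_in, i) = par[i];
  }
  colnames(draws) = CharacterVector::create("B", "S", "lambda1", "lambda2");
  return List::create(_["draws"] = draws);
}

// Reinforcement-learning agent run over one session for the closed-form
// reward policies (those not needing an online MCMC estimator).
// cond is 0/1/2 for L/N/R; policy: 0 veridical, 1 oracle,
// 2 random-ambiguous, 3 always-ambiguous, 4 never-ambiguous.
// bound holds the per-condition oracle reward boundaries.
// [[Rcpp::export]]
List rl_session_cpp(NumericVector omega, IntegerVector cond,
                    NumericVector psi0, NumericVector P, NumericVector Sigma,
                    double alpha_lr, int policy, NumericVector bound) {
  const int n = omega.size();
  NumericVector psi = clone(psi0);
  IntegerVector choice(n), reward(n);
  NumericMatrix psi_trace(n, 3);
  // percept noise is pre-drawn so that reward-side randomness does not
  // perturb the percept stream: policies share percepts under one seed
  NumericVector omh_all(n);
  for (int t = 0; t < n; ++t) {
    int k = cond[t];
    omh_all[t] = R::rnorm(omega[t] - P[k], Sigma[k]);
  }
  for (int t = 0; t < n; ++t) {
    int k = cond[t];
    double omh = omh_all[t];
    int C = (omh >= psi[k]) ? 1 : -1;
    double Phi = R::pnorm((omh - psi[k]) / Sigma[k], 0.0, 1.0, 1, 0);
    double q = Phi > 0.5 ? Phi : 1.0 - Phi;
    if (omh == psi[k]) q = 0.5;
    int r;
    bool amb = false;
    if (policy >= 2) {
      double lo = std::min(0.0, P[k]), hi = std::max(0.0, P[k]);
      amb = (omega[t] > lo && omega[t] < hi);
    }
    if (amb) {
      if (policy == 2) r = unif_rand() < 0.5 ? 1 : 0;
      else r = (policy == 3) ? 1 : 0;
    } else {
      double b = (policy == 1) ? bound[k] : 0.0;
      if (omega[t] == b) r = unif_rand() < 0.5 ? 1 : 0;
      else r = ((C == -1 && omega[t] < b) || (C == 1 && omega[t] > b)) ? 1 : 0;
    }
    psi[k] = psi[k] - alpha_lr * C * (r - q);
    choice[t] = C;
    reward[t] = r;
    psi_trace(t, 0) = psi[0]; psi_trace(t, 1) = psi[1]; psi_trace(t, 2) = psi[2];
  }
  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["psi_end"] = psi, _["psi_trace"] = psi_trace);
}
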