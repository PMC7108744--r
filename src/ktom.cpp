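// Recursive theory-of-mind (k-ToM) learners and fast per-session likelihoods.
//
// The k-ToM agent maintains, for every opponent sophistication level kappa < k,
// a Gaussian belief over the opponent's hidden states x^kappa = (log sigma,
// log beta) together with a posterior simplex over levels.  Level predictions
// and their gradient W w.r.t. x^kappa are obtained from a bank of simulated
// kappa-ToM opponents run forward in lockstep at fixed offsets around the
// current posterior mean (central differences, step H_STEP).  This keeps the
// whole update O(1) per trial per simulated state, so 3-ToM sessions remain
// tractable at cohort scale.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <memory>

using namespace Rcpp;

static const double H_STEP = 1e-3;       // finite-difference step in x-space
static const double MOM_A = 3.0 / (M_PI * M_PI); // probit-style moment correction
static const double EIG_FLOOR = 1e-8;    // covariance eigenvalue floor
static const double EIG_CAP = 4.0;       // covariance eigenvalue cap (prior scale)
static const double MU_CLAMP = 2.0;      // hidden-state mean clamp in log space
static const double MU2_MAX = 0.7;       // cap on believed log-temperature: simulated
                                         // opponents are assumed to stay motivated
                                         // (beta <= 2) rather than purely random
static const double P_EPS = 1e-7;        // likelihood clipping

static inline double sigmoid(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// E[s(v)] under v ~ N(m, var), moment-matched
static inline double sig_moment(double m, double var) {
  return sigmoid(m / std::sqrt(1.0 + MOM_A * var));
}

// role: +1 seeker (wins on match), -1 hider (wins on mismatch)
static inline double delta_v(double p_op, int role) {
  return role * (2.0 * p_op - 1.0);
}

struct Mat2 { double a, b, c, d; };  // [a b; c d]

static inline Mat2 mat2_inv(const Mat2& m, bool& ok) {
  double det = m.a * m.d - m.b * m.c;
  if (std::fabs(det) < 1e-300) { ok = false; return Mat2{1, 0, 0, 1}; }
  ok = true;
  return Mat2{m.d / det, -m.b / det, -m.c / det, m.a / det};
}

// symmetrize + floor/cap eigenvalues; returns true if a PD repair was needed
// (the cap keeps the assumed-density filter within the prior's scale when
// the hidden states are weakly observable; without it the volatility
// inflation makes the posterior variance, and hence the mean-update gain,
// diverge in near-equilibrium play)
static inline bool mat2_repair(Mat2& m) {
  double off = 0.5 * (m.b + m.c);
  m.b = m.c = off;
  // eigen decomposition of symmetric 2x2
  double tr = m.a + m.d, det = m.a * m.d - off * off;
  double disc = std::sqrt(std::max(0.0, 0.25 * tr * tr - det));
  double l1 = 0.5 * tr + disc, l2 = 0.5 * tr - disc;
  if (l2 >= EIG_FLOOR && l1 <= EIG_CAP) return false;
  bool pd_broken = l2 < EIG_FLOOR;
  // eigenvector for l1
  double vx, vy;
  if (std::fabs(off) > 1e-14) { vx = l1 - m.d; vy = off; }
  else { vx = (m.a >= m.d) ? 1 : 0; vy = (m.a >= m.d) ? 0 : 1; }
  double n = std::sqrt(vx * vx + vy * vy);
  if (n < 1e-300) { vx = 1; vy = 0; n = 1; }
  vx /= n; vy /= n;
  double nl1 = std::min(EIG_CAP, std::max(l1, EIG_FLOOR));
  double nl2 = std::min(EIG_CAP, std::max(l2, EIG_FLOOR));
  // reconstruct V diag(l) V'
  double wx = -vy, wy = vx;
  m.a = nl1 * vx * vx + nl2 * wx * wx;
  m.b = m.c = nl1 * vx * vy + nl2 * wx * wy;
  m.d = nl1 * vy * vy + nl2 * wy * wy;
  return pd_broken;
}

// ---------------------------------------------------------------------------
// k-ToM learner (k = 0 is the frequency tracker)
// ---------------------------------------------------------------------------
struct KTom {
  int k;
  int role;             // role of THIS agent
  double sigma, beta;   // own volatility and temperature
  long repairs;

  // k == 0 state
  double mu0, var0;

  // k >= 1 state
  std::vector<double> lambda;              // level posterior, size k
  std::vector<double> mu1, mu2;            // per-level mean of x = (log sig, log bet)
  std::vector<Mat2> Sig;                   // per-level covariance
  // bank[kappa][j], j = 0 centre, 1..4 = +h e1, -h e1, +h e2, -h e2
  std::vector<std::vector<std::unique_ptr<KTom>>> bank;

  // per-trial cache (filled by predict(), consumed by update())
  std::vector<double> c_v;                 // v^kappa at centre
  std::vector<double> c_w1, c_w2;          // gradient W
  std::vector<double> c_pk;                // corrected level predictions
  double c_pop;                            // mixture prediction
  bool cache_ok;

  KTom(int k_, int role_, double sigma_, double beta_)
    : k(k_), role(role_), sigma(sigma_), beta(beta_), repairs(0), cache_ok(false) {
    mu0 = 0.0; var0 = 1.0;
    if (k >= 1) {
      lambda.assign(k, 1.0 / k);
      mu1.assign(k, 0.0); mu2.assign(k, 0.0);
      Sig.assign(k, Mat2{1, 0, 0, 1});
      c_v.assign(k, 0.0); c_w1.assign(k, 0.0); c_w2.assign(k, 0.0); c_pk.assign(k, 0.5);
      bank.resize(k);
      for (int kap = 0; kap < k; ++kap) {
        for (int j = 0; j < 5; ++j)
          bank[kap].emplace_back(new KTom(kap, -role_, 1.0, 1.0));
      }
    }
    c_pop = 0.5;
  }

  // set (sigma, beta) of a bank member from x-offset around current mean
  void set_bank_params(int kap) {
    static const double o1[5] = {0, H_STEP, -H_STEP, 0, 0};
    static const double o2[5] = {0, 0, 0, H_STEP, -H_STEP};
    for (int j = 0; j < 5; ++j) {
      bank[kap][j]->sigma = std::exp(mu1[kap] + o1[j]);
      bank[kap][j]->beta = std::exp(mu2[kap] + o2[j]);
    }
  }

  // probability this agent assigns to its own next action being 1
  // (zero bias: simulated levels carry no bias)
  double choice_prob() {
    double p = predict();
    return sigmoid(delta_v(p, role) / beta);
  }

  // predicted probability that the OPPONENT plays 1 next trial
  double predict() {
    if (k == 0) {
      c_pop = sig_moment(mu0, var0 + sigma);
      return c_pop;
    }
    double mix = 0.0;
    for (int kap = 0; kap < k; ++kap) {
      set_bank_params(kap);
      double v[5];
      for (int j = 0; j < 5; ++j) v[j] = logit_choice(bank[kap][j].get());
      c_v[kap] = v[0];
      c_w1[kap] = (v[1] - v[2]) / (2.0 * H_STEP);
      c_w2[kap] = (v[3] - v[4]) / (2.0 * H_STEP);
      // predictive variance of v along the belief (inflated by own volatility)
      double sa = Sig[kap].a + sigma, sd = Sig[kap].d + sigma, sb = Sig[kap].b;
      double var_v = c_w1[kap] * (sa * c_w1[kap] + sb * c_w2[kap]) +
                     c_w2[kap] * (sb * c_w1[kap] + sd * c_w2[kap]);
      c_pk[kap] = sig_moment(v[0], std::max(0.0, var_v));
      mix += lambda[kap] * c_pk[kap];
    }
    c_pop = std::min(1.0 - P_EPS, std::max(P_EPS, mix));
    cache_ok = true;
    return c_pop;
  }

  // v = logit of the member's own choice probability = role * (2p - 1) / beta
  static double logit_choice(KTom* m) {
    double p = m->predict();
    return delta_v(p, m->role) / m->beta;
  }

  // observe one trial: a_self / a_op from THIS agent's perspective
  void update(int a_self, int a_op) {
    if (k == 0) {
      double s = sigmoid(mu0);
      double v_new = 1.0 / (1.0 / (var0 + sigma) + s * (1.0 - s));
      mu0 = mu0 + v_new * (a_op - s);
      var0 = v_new;
      return;
    }
    if (!cache_ok) predict();
    // (i) level posterior reweighted by each level's predictive likelihood
    double tot = 0.0;
    std::vector<double> lam_new(k);
    for (int kap = 0; kap < k; ++kap) {
      double like = a_op == 1 ? c_pk[kap] : (1.0 - c_pk[kap]);
      lam_new[kap] = lambda[kap] * std::max(like, P_EPS);
      tot += lam_new[kap];
    }
    for (int kap = 0; kap < k; ++kap) lam_new[kap] /= tot;
    if (k == 1) lam_new[0] = 1.0;
    // (ii)/(iii) per-level Gaussian belief update
    for (int kap = 0; kap < k; ++kap) {
      double lam = lam_new[kap];
      double w1 = c_w1[kap], w2 = c_w2[kap];
      double sv = sigmoid(c_v[kap]);
      double sp = sv * (1.0 - sv);
      // precision recursion: Sig_t = [ (Sig_{t-1} + sig I)^-1 + s' lam W W^T ]^-1
      Mat2 pred{Sig[kap].a + sigma, Sig[kap].b, Sig[kap].c, Sig[kap].d + sigma};
      bool ok;
      Mat2 prec = mat2_inv(pred, ok);
      prec.a += sp * lam * w1 * w1;
      prec.b += sp * lam * w1 * w2;
      prec.c += sp * lam * w2 * w1;
      prec.d += sp * lam * w2 * w2;
      Mat2 Snew = mat2_inv(prec, ok);
      if (!ok) { Snew = Mat2{1, 0, 0, 1}; ++repairs; }
      if (mat2_repair(Snew)) ++repairs;
      // mean step along W scaled by lambda, Sigma and the prediction error
      double pe = a_op - sv;
      mu1[kap] += lam * (Snew.a * w1 + Snew.b * w2) * pe;
      mu2[kap] += lam * (Snew.c * w1 + Snew.d * w2) * pe;
      mu1[kap] = std::min(MU_CLAMP, std::max(-MU_CLAMP, mu1[kap]));
      mu2[kap] = std::min(MU2_MAX, std::max(-MU_CLAMP, mu2[kap]));
      Sig[kap] = Snew;
      // the simulated kappa-ToM opponents observe the trial from their side
      for (int j = 0; j < 5; ++j) bank[kap][j]->update(a_op, a_self);
    }
    lambda = lam_new;
    cache_ok = false;
  }
};

typedef XPtr<KTom> KTomPtr;

// [[Rcpp::export]]
SEXP cpp_tom_new(int k, double sigma, double beta, int role) {
  if (k < 0 || k > 3) stop("k must be in 0..3");
  if (sigma <= 0 || beta <= 0) stop("sigma and beta must be positive");
  if (role != 1 && role != -1) stop("role must be +1 (seeker) or -1 (hider)");
  return KTomPtr(new KTom(k, role, sigma, beta), true);
}

// [[Rcpp::export]]
double cpp_tom_predict(SEXP ptr) {
  KTomPtr p(ptr);
  return p->predict();
}

// [[Rcpp::export]]
void cpp_tom_update(SEXP ptr, int a_self, int a_op) {
  KTomPtr p(ptr);
  if ((a_self != 0 && a_self != 1) || (a_op != 0 && a_op != 1))
    stop("actions must be 0 or 1");
  p->predict();  // ensure cache for this trial
  p->update(a_self, a_op);
}

// [[Rcpp::export]]
List cpp_tom_state(SEXP ptr) {
  KTomPtr p(ptr);
  if (p->k == 0)
    return List::create(_["k"] = 0, _["mu"] = p->mu0, _["sigma2"] = p->var0,
                        _["volatility"] = p->sigma, _["repairs"] = (double)p->repairs);
  int k = p->k;
  NumericMatrix mu(k, 2);
  NumericVector lam(k);
  List sig(k);
  for (int kap = 0; kap < k; ++kap) {
    mu(kap, 0) = p->mu1[kap]; mu(kap, 1) = p->mu2[kap];
    lam[kap] = p->lambda[kap];
    NumericMatrix S(2, 2);
    S(0, 0) = p->Sig[kap].a; S(0, 1) = p->Sig[kap].b;
    S(1, 0) = p->Sig[kap].c; S(1, 1) = p->Sig[kap].d;
    sig[kap] = S;
  }
  return List::create(_["k"] = k, _["level_posterior"] = lam, _["mu"] = mu,
                      _["Sigma"] = sig, _["volatility"] = p->sigma,
                      _["repairs"] = (double)p->repairs);
}

// Replay semantics: probability that a kappa-ToM opponent with fixed hidden
// states x = (log sigma, log beta) and role `role_level` assigns to action 1
// at the next trial, after replaying the full history (given from the
// PARENT's perspective: a_self is the parent's own action sequence).
// [[Rcpp::export]]
double cpp_simulate_level(int kappa, NumericVector x, int role_level,
                          IntegerVector a_self, IntegerVector a_op) {
  if (kappa < 0 || kappa > 2) stop("kappa must be in 0..2");
  if (x.size() != 2) stop("x must have length 2 (log sigma, log beta)");
  if (a_self.size() != a_op.size()) stop("history lengths differ");
  KTom m(kappa, role_level, std::exp(x[0]), std::exp(x[1]));
  for (int t = 0; t < a_self.size(); ++t) {
    m.predict();
    m.update(a_op[t], a_self[t]);  // member's self = parent's opponent
  }
  return m.choice_prob();
}

// ---------------------------------------------------------------------------
// Per-session log likelihoods (theta in natural space)
// ---------------------------------------------------------------------------

static inline double ll_term(double p1, int a) {
  double p = a == 1 ? p1 : 1.0 - p1;
  return std::log(std::min(1.0 - P_EPS, std::max(P_EPS, p)));
}

// [[Rcpp::export]]
double cpp_loglik_ktom(int k, double sigma, double beta, double bias, int role,
                       IntegerVector a_self, IntegerVector a_op) {
  KTom agent(k, role, sigma, beta);
  double ll = 0.0;
  int n = a_self.size();
  for (int t = 0; t < n; ++t) {
    double p_op = agent.predict();
    double p1 = sigmoid((delta_v(p_op, role) + bias) / beta);
    ll += ll_term(p1, a_self[t]);
    agent.update(a_self[t], a_op[t]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik_rl(double alpha, double beta, double bias,
                     IntegerVector a_self, NumericVector reward) {
  double v0 = 0.0, v1 = 0.0, ll = 0.0;
  int n = a_self.size();
  for (int t = 0; t < n; ++t) {
    double p1 = sigmoid((v1 - v0 + bias) / beta);
    ll += ll_term(p1, a_self[t]);
    if (a_self[t] == 1) v1 += alpha * (reward[t] - v1);
    else v0 += alpha * (reward[t] - v0);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik_wsls(double beta, double bias,
                       IntegerVector a_self, NumericVector reward) {
  double v0 = 0.0, v1 = 0.0, ll = 0.0;
  int n = a_self.size();
  for (int t = 0; t < n; ++t) {
    double p1 = sigmoid((v1 - v0 + bias) / beta);
    ll += ll_term(p1, a_self[t]);
    double rs = reward[t] > 0.5 ? 1.0 : -1.0;  // signed reward
    if (a_self[t] == 1) { v1 = rs; v0 = -rs; }
    else { v0 = rs; v1 = -rs; }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik_inf(double eta, double w, double beta, double bias, int role,
                      IntegerVector a_self, IntegerVector a_op, double clip_eps) {
  double p = 0.5, ll = 0.0;
  int n = a_self.size();
  for (int t = 0; t < n; ++t) {
    double p1 = sigmoid((delta_v(p, role) + bias) / beta);
    ll += ll_term(p1, a_self[t]);
    double infl = w * p * (1.0 - p) *
      (1.0 - 2.0 * a_self[t] - beta * std::log(p / (1.0 - p)));
    p = p + eta * (a_op[t] - p) + infl;
    p = std::min(1.0 - clip_eps, std::max(clip_eps, p));
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_tom_debug(SEXP ptr) {
  KTomPtr p(ptr);
  if (p->k == 0) stop("debug info only for k >= 1");
  p->predict();
  return List::create(_["v"] = wrap(p->c_v), _["w1"] = wrap(p->c_w1),
                      _["w2"] = wrap(p->c_w2), _["pk"] = wrap(p->c_pk),
                      _["p_op"] = p->c_pop);
}

// Run a k-ToM agent through a whole observed session recording its
// trial-by-trial predictions and level posteriors (diagnostics / tests).
// [[Rcpp::export]]
List cpp_tom_trace(int k, double sigma, double beta, int role,
                   IntegerVector a_self, IntegerVector a_op) {
  KTom agent(k, role, sigma, beta);
  int n = a_self.size();
  NumericVector pred(n);
  NumericMatrix lam(n, std::max(k, 1));
  for (int t = 0; t < n; ++t) {
    pred[t] = agent.predict();
    if (k >= 1) for (int kap = 0; kap < k; ++kap) lam(t, kap) = agent.lambda[kap];
    else lam(t, 0) = 1.0;
    agent.update(a_self[t], a_op[t]);
  }
  return List::create(_["p_op"] = pred, _["level_posterior"] = lam,
                      _["repairs"] = (double)agent.repairs);
}
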