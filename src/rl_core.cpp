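#include <Rcpp.h>
using namespace Rcpp;

// Shared trial recursion for the nested Pearce-Hall hybrid model family.
//
// Per trial with stimulus j (all values tracked per stimulus):
//   p_play = logistic(beta * (play_bias + Q[j]))        (V_pass = 0)
//   action: given (scoring) or sampled (simulation)
//   modality     = factual iff play
//   confirmatory = (factual & win) | (counterfactual & loss)
//   kappa_t = logistic(w0 [+ w1*conf_code] [+ w2*mod_code]),  codes +/-0.5
//   alpha_t = kappa_t * A[j]   (A[j] fixed at 1 when associability unused)
//   delta_t = R - Q[j],  R = +1 win / -1 loss   (shown points are +/-10)
//   Q[j]   += alpha_t * delta_t
//   A[j]    = eta * |delta_t| + (1 - eta) * A[j]   (hybrid only)
//
// Initial values: Q0 = 0, A0 = 1 per stimulus, so the first update of a
// stimulus uses alpha = kappa (kappa is the initial learning rate).
//
// The associability recursion is not artificially bounded: with a large
// kappa and step size, alpha = kappa * A can exceed 1 and the value
// recursion destabilizes (overshooting Q, growing |delta|) — the regime
// in which very flexible learners perform poorly. Q and A are clamped to
// |Q| <= 8, A <= 8, far outside the ordinary [-1, 1] operating range, so
// the divergent regime stays finite in floating point without altering
// behaviour near it.

static const double Q_CLAMP = 8.0, A_CLAMP = 8.0;
static inline double clampQ(double q) {
  return std::max(-Q_CLAMP, std::min(Q_CLAMP, q));
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List rl_engine_cpp(double beta, double play_bias, NumericVector kappa_w,
                   double eta, bool uses_assoc, int n_kappa, int n_stimuli,
                   IntegerVector stimulus, IntegerVector valence,
                   IntegerVector action, bool simulate) {
  const int T = stimulus.size();
  std::vector<double> Q(n_stimuli, 0.0), A(n_stimuli, 1.0);

  NumericVector q_out(T), delta_out(T), a_out(T), alpha_out(T), p_out(T);
  IntegerVector act_out(T), modality(T), confirm(T);
  double nll = 0.0;
  const double floor_p = 1e-12;

  for (int t = 0; t < T; ++t) {
    const int j = stimulus[t] - 1;
    const double p_play = logistic(beta * (play_bias + Q[j]));

    int a;
    if (simulate) {
      a = (unif_rand() < p_play) ? 1 : 0;
    } else {
      a = action[t];
      const double p_a = a == 1 ? p_play : 1.0 - p_play;
      nll -= std::log(std::max(p_a, floor_p));
    }

    const int win = valence[t];                       // 1 win, 0 loss
    const int fac = a;                                // factual iff play
    const int conf = (fac == 1) ? win : 1 - win;      // factual win / cf loss

    double lin = kappa_w[0];
    if (n_kappa >= 2) lin += kappa_w[1] * (conf == 1 ? 0.5 : -0.5);
    if (n_kappa >= 3) lin += kappa_w[2] * (fac == 1 ? 0.5 : -0.5);
    const double kappa = logistic(lin);

    const double a_cur = uses_assoc ? A[j] : 1.0;
    const double alpha = kappa * a_cur;
    const double R = win == 1 ? 1.0 : -1.0;
    const double delta = R - Q[j];

    q_out[t] = Q[j];
    delta_out[t] = delta;
    a_out[t] = a_cur;
    alpha_out[t] = alpha;
    p_out[t] = p_play;
    act_out[t] = a;
    modality[t] = fac;
    confirm[t] = conf;

    Q[j] = clampQ(Q[j] + alpha * delta);
    if (uses_assoc)
      A[j] = std::min(eta * std::fabs(delta) + (1.0 - eta) * A[j],
                      A_CLAMP);
  }

  return List::create(_["nll"] = nll, _["q"] = q_out, _["delta"] = delta_out,
                      _["assoc"] = a_out, _["alpha"] = alpha_out,
                      _["p_play"] = p_out, _["action"] = act_out,
                      _["modality"] = modality, _["confirmatory"] = confirm);
}

// Choice negative log-likelihood only (objective hot path for fitting).
// [[Rcpp::export]]
double rl_nll_cpp(double beta, double play_bias, NumericVector kappa_w,
                  double eta, bool uses_assoc, int n_kappa, int n_stimuli,
                  IntegerVector stimulus, IntegerVector valence,
                  IntegerVector action) {
  const int T = stimulus.size();
  std::vector<double> Q(n_stimuli, 0.0), A(n_stimuli, 1.0);
  double nll = 0.0;
  const double floor_p = 1e-12;

  for (int t = 0; t < T; ++t) {
    const int j = stimulus[t] - 1;
    const double p_play = logistic(beta * (play_bias + Q[j]));
    const int a = action[t];
    const double p_a = a == 1 ? p_play : 1.0 - p_play;
    nll -= std::log(std::max(p_a, floor_p));

    const int win = valence[t];
    const int conf = (a == 1) ? win : 1 - win;

    double lin = kappa_w[0];
    if (n_kappa >= 2) lin += kappa_w[1] * (conf == 1 ? 0.5 : -0.5);
    if (n_kappa >= 3) lin += kappa_w[2] * (a == 1 ? 0.5 : -0.5);
    const double kappa = logistic(lin);

    const double alpha = kappa * (uses_assoc ? A[j] : 1.0);
    const double R = win == 1 ? 1.0 : -1.0;
    const double delta = R - Q[j];
    Q[j] = clampQ(Q[j] + alpha * delta);
    if (uses_assoc)
      A[j] = std::min(eta * std::fabs(delta) + (1.0 - eta) * A[j],
                      A_CLAMP);
  }
  return nll;
}
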