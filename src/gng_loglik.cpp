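#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood for the go/no-go Rescorla-Wagner family.
//
// Stimuli are coded 1 = GW, 2 = GA, 3 = NGW, 4 = NGAL; actions 1 = go,
// 0 = nogo; reinforcement in {-1, 0, +1}.  `theta` is the full natural-space
// parameter vector in canonical order:
//   [0] reward_sensitivity  [1] punishment_sensitivity
//   [2] learning_rate_reward [3] learning_rate_punishment
//   [4] lapse [5] action_bias [6] approach_bias [7] avoidance_bias
// Tied parameters are expanded before the call; absent components are
// switched off by the flags, not by magic values.
//
// Q values and stimulus values start at exactly 0.  Learning rate and
// sensitivity follow trial valence (win stimuli use the reward pair, avoid
// stimuli the punishment pair); the Pavlovian term multiplies the stimulus
// value by the approach bias on win stimuli and the avoidance bias on avoid
// stimuli.  Choice probabilities are a softmax squashed by the lapse:
// p = softmax * (1 - lapse) + lapse / 2.

// [[Rcpp::export]]
double gng_session_loglik_cpp(IntegerVector stimulus,
                              IntegerVector action,
                              IntegerVector reinforcement,
                              NumericVector theta,
                              bool has_action_bias,
                              bool has_appavo) {
  const int n = stimulus.size();
  if (action.size() != n || reinforcement.size() != n)
    stop("stimulus, action and reinforcement must have equal length");
  if (theta.size() != 8) stop("theta must have length 8");

  const double rho_rew = theta[0], rho_pun = theta[1];
  const double lr_rew = theta[2], lr_pun = theta[3];
  const double lapse = theta[4], ab = theta[5];
  const double app = theta[6], avo = theta[7];

  double qgo[5] = {0, 0, 0, 0, 0};   // index by stimulus code, slot 0 unused
  double qng[5] = {0, 0, 0, 0, 0};
  double val[5] = {0, 0, 0, 0, 0};

  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int s = stimulus[t];
    if (s < 1 || s > 4) stop("stimulus codes must be in 1..4");
    const int a = action[t];
    const int r = reinforcement[t];
    const bool win = (s == 1 || s == 3);
    const double sens = win ? rho_rew : rho_pun;
    const double lr = win ? lr_rew : lr_pun;

    double wgo = qgo[s];
    if (has_action_bias) wgo += ab;
    if (has_appavo) wgo += (win ? app : avo) * val[s];
    const double wng = qng[s];

    // log softmax probability of the chosen action, computed in log space
    // so extreme weights (large sensitivities under wide priors) cannot
    // underflow the lapse mixture
    const double margin = (a == 1) ? (wng - wgo) : (wgo - wng);
    if (std::isnan(margin)) return R_NegInf;  // overflowed action weights
    const double log_sm = -R::log1pexp(margin);
    const double la = log_sm + std::log1p(-lapse);      // -Inf at lapse = 1
    const double lb = std::log(lapse / 2.0);            // -Inf at lapse = 0
    const double m = std::max(la, lb);
    ll += std::isinf(m) ? m : m + std::log1p(std::exp(std::min(la, lb) - m));

    const double target = sens * r;
    if (a == 1) qgo[s] += lr * (target - qgo[s]);
    else        qng[s] += lr * (target - qng[s]);
    val[s] += lr * (target - val[s]);
  }
  return ll;
}
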