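#include <Rcpp.h>
using namespace Rcpp;

// Per-trial forward pass of the standard Q-learning family.
// choice: 1 = left, 0 = right; reward: 0/1.
// Emits the left-choice probability computed from the state BEFORE the
// trial's update, plus the pre-update action values.
// [[Rcpp::export]]
List q_forward_cpp(IntegerVector choice, IntegerVector reward,
                   double alpha1, double alpha2, double k1, double k2,
                   double beta) {
  const int n = choice.size();
  NumericVector p(n), qLv(n), qRv(n);
  double qL = 0.5, qR = 0.5;  // average reward probability of the settings
  for (int t = 0; t < n; ++t) {
    qLv[t] = qL;
    qRv[t] = qR;
    p[t] = 1.0 / (1.0 + std::exp(-beta * (qL - qR)));
    const double target = k1 * reward[t] - k2 * (1 - reward[t]);
    if (choice[t] == 1) {
      qL = (1.0 - alpha1) * qL + alpha1 * target;
      qR = (1.0 - alpha2) * qR;
    } else {
      qR = (1.0 - alpha1) * qR + alpha1 * target;
      qL = (1.0 - alpha2) * qL;
    }
  }
  return List::create(_["p_left"] = p, _["q_left"] = qLv, _["q_right"] = qRv);
}

static inline void bq_predict_inplace(double &x, double &y, double G) {
  if (!std::isfinite(G)) return;  // point-mass kernel: prior unchanged
  const double s = x + y;
  const double m = x / s;
  const double m2 = x * (x + 1.0) / (s * (s + 1.0));
  const double nm = (1.0 + G * m) / (2.0 + G);
  const double nm2 = (2.0 + 3.0 * G * m + G * G * m2) / ((2.0 + G) * (3.0 + G));
  const double v = nm2 - nm * nm;
  const double conc = nm * (1.0 - nm) / v - 1.0;
  x = std::max(nm * conc, 1e-6);
  y = std::max((1.0 - nm) * conc, 1e-6);
}

// Per-trial forward pass of the Bayesian Q-learning family.
// Order within a trial: prediction step on BOTH actions, choice probability,
// effective learning rate of the chosen action (on its post-prediction
// pair), conjugate update of the chosen action only.
// [[Rcpp::export]]
List bq_forward_cpp(IntegerVector choice, IntegerVector reward,
                    double G, double k, double beta, double phi) {
  const int n = choice.size();
  NumericVector p(n), ea(n), eac(n);
  NumericVector muL(n), sdL(n), muR(n), sdR(n);
  double xL = 1.0, yL = 1.0, xR = 1.0, yR = 1.0;  // Beta(1,1) priors
  for (int t = 0; t < n; ++t) {
    bq_predict_inplace(xL, yL, G);
    bq_predict_inplace(xR, yR, G);
    const double sL = xL + yL, sR = xR + yR;
    muL[t] = xL / sL;
    muR[t] = xR / sR;
    sdL[t] = std::sqrt(xL * yL / (sL * sL * (sL + 1.0)));
    sdR[t] = std::sqrt(xR * yR / (sR * sR * (sR + 1.0)));
    const double uL = muL[t] + phi * sdL[t];
    const double uR = muR[t] + phi * sdR[t];
    p[t] = 1.0 / (1.0 + std::exp(-beta * (uL - uR)));
    const double sc = (choice[t] == 1) ? sL : sR;
    ea[t] = (reward[t] == 1) ? 1.0 / (sc + 1.0) : k / (sc + k);
    eac[t] = 1.0 / (sc + 1.0);  // concentration-driven rate, outcome-free
    if (choice[t] == 1) {
      if (reward[t] == 1) xL += 1.0; else yL += k;
    } else {
      if (reward[t] == 1) xR += 1.0; else yR += k;
    }
  }
  return List::create(_["p_left"] = p, _["ea"] = ea, _["ea_conc"] = eac,
                      _["mu_left"] = muL, _["sd_left"] = sdL,
                      _["mu_right"] = muR, _["sd_right"] = sdR,
                      _["x_left"] = xL, _["y_left"] = yL,
                      _["x_right"] = xR, _["y_right"] = yR);
}
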