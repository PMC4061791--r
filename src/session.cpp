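#include <Rcpp.h>
using namespace Rcpp;

// Four-constant polynomial approximation of the standard normal CDF,
// identical to the R-level std_normal_cdf(); the model's Eq.-level
// probability primitive, kept deliberately distinct from exact CDFs.
static inline double acdf(double z) {
  const double a1 = 0.196854, a2 = 0.115194, a3 = 0.000344, a4 = 0.019527;
  double za = std::fabs(z);
  double q = 1.0 + za * (a1 + za * (a2 + za * (a3 + za * a4)));
  q = q * q;
  q = q * q; // q^4
  double upper = 1.0 - 0.5 / q;
  return z >= 0.0 ? upper : 1.0 - upper;
}

// categories are coded 1 = A, 2 = B throughout
static inline int predicted_cat(double p_a) { return p_a > 0.5 ? 1 : 2; }

// feedback routing truth table; winner: 1 = RB, 2 = II
static inline void route(int policy, int winner, bool correct,
                         bool &fb_rb, bool &fb_ii) {
  bool win_rb = (winner == 1);
  fb_rb = false;
  fb_ii = false;
  switch (policy) {
  case 1: fb_rb = win_rb; fb_ii = !win_rb; break;
  case 2: fb_rb = fb_ii = true; break;
  case 3: fb_rb = fb_ii = correct; break;
  case 4: fb_rb = fb_ii = !correct; break;
  case 5: fb_rb = win_rb; fb_ii = true; break;
  case 6: fb_rb = true; fb_ii = !win_rb; break;
  case 7: fb_rb = (win_rb && !correct); fb_ii = true; break;
  case 8: fb_rb = true; fb_ii = (!win_rb && !correct); break;
  case 9: fb_rb = (win_rb && correct); fb_ii = (!win_rb && !correct); break;
  case 10: fb_rb = (win_rb && !correct); fb_ii = (!win_rb && correct); break;
  case 11: if (correct) { fb_rb = win_rb; fb_ii = !win_rb; } break;
  case 12: if (!correct) { fb_rb = win_rb; fb_ii = !win_rb; } break;
  default: stop("unknown feedback model number");
  }
}

struct Learner {
  double rb_b, ii_b, ps_rb, ps_ii;
  double rb_lr, ii_lr, ps_lr;

  double dist_rb(double x) const { return x - rb_b; }
  double dist_ii(double x, double y) const {
    return (y - x - ii_b) / M_SQRT2;
  }
  double p_a_rb(double x) const { return acdf(-dist_rb(x) / ps_rb); }
  double p_a_ii(double x, double y) const {
    return acdf(-dist_ii(x, y) / ps_ii);
  }
  // sys: 1 = RB, 2 = II; true_cat in {1, 2}
  void feed(int sys, double x, double y, int true_cat) {
    double d = (sys == 1) ? dist_rb(x) : dist_ii(x, y);
    double p_a = (sys == 1) ? p_a_rb(x) : p_a_ii(x, y);
    bool own_correct = (predicted_cat(p_a) == true_cat);
    double &ps = (sys == 1) ? ps_rb : ps_ii;
    if (own_correct) {
      ps *= (1.0 - ps_lr);
      if (ps < 1e-300) ps = 1e-300; // numerical floor, keeps ps > 0
    } else {
      double step = ((sys == 1) ? rb_lr : ii_lr) * std::fabs(d);
      double &b = (sys == 1) ? rb_b : ii_b;
      b += (true_cat == 1) ? step : -step;
      ps *= (1.0 + ps_lr);
    }
  }
};

static inline double clamp_conf(double c) {
  double hi = 1.0 - 1e-12;
  return c > hi ? hi : c;
}

// Run one closed-loop session. Uses R's global RNG (seed from R side).
// Draw order per trial: selection noise, (uniform tie-break if needed),
// response draw.
// [[Rcpp::export]]
List cpp_run_session(NumericVector x, NumericVector y, IntegerVector true_cat,
                     int block_size,
                     double rb_lr, double ii_lr, double ps_lr,
                     double ps_init_rb, double ps_init_ii,
                     double dm_noise, int policy, bool return_trace) {
  int n = x.size();
  if (n < 2) stop("need at least two trials");
  if (n % block_size != 0) stop("n_trials must be divisible by block_size");
  int n_blocks = n / block_size;

  Learner L;
  L.rb_b = 0.5 * (x[0] + x[1]);
  L.ii_b = 0.5 * ((y[0] - x[0]) + (y[1] - x[1]));
  L.ps_rb = ps_init_rb;
  L.ps_ii = ps_init_ii;
  L.rb_lr = rb_lr;
  L.ii_lr = ii_lr;
  L.ps_lr = ps_lr;

  NumericVector block_acc(n_blocks), rb_win_frac(n_blocks);
  NumericVector p_rb_v, p_ii_v, odds_rb_v, odds_ii_v, eps_v;
  IntegerVector winner_v, response_v;
  LogicalVector correct_v, fb_rb_v, fb_ii_v;
  if (return_trace) {
    p_rb_v = NumericVector(n); p_ii_v = NumericVector(n);
    odds_rb_v = NumericVector(n); odds_ii_v = NumericVector(n);
    eps_v = NumericVector(n);
    winner_v = IntegerVector(n); response_v = IntegerVector(n);
    correct_v = LogicalVector(n); fb_rb_v = LogicalVector(n);
    fb_ii_v = LogicalVector(n);
  }

  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double p_rb = L.p_a_rb(x[i]);
    double p_ii = L.p_a_ii(x[i], y[i]);
    double conf_rb = clamp_conf(std::max(p_rb, 1.0 - p_rb));
    double conf_ii = clamp_conf(std::max(p_ii, 1.0 - p_ii));
    double odds_rb = conf_rb / (1.0 - conf_rb);
    double odds_ii = conf_ii / (1.0 - conf_ii);

    double eps = norm_rand() * dm_noise;
    int winner;
    double noisy_rb = odds_rb + eps;
    if (noisy_rb > odds_ii) winner = 1;
    else if (noisy_rb < odds_ii) winner = 2;
    else winner = (unif_rand() < 0.5) ? 1 : 2;

    double p_sel = (winner == 1) ? p_rb : p_ii;
    int response = (unif_rand() < p_sel) ? 1 : 2;
    bool correct = (response == true_cat[i]);

    bool fb_rb, fb_ii;
    route(policy, winner, correct, fb_rb, fb_ii);
    // both systems read the pre-update state; apply afterwards
    if (fb_rb) L.feed(1, x[i], y[i], true_cat[i]);
    if (fb_ii) L.feed(2, x[i], y[i], true_cat[i]);

    int b = i / block_size;
    if (correct) block_acc[b] += 1.0;
    if (winner == 1) rb_win_frac[b] += 1.0;

    if (return_trace) {
      p_rb_v[i] = p_rb; p_ii_v[i] = p_ii;
      odds_rb_v[i] = odds_rb; odds_ii_v[i] = odds_ii;
      eps_v[i] = eps;
      winner_v[i] = winner; response_v[i] = response;
      correct_v[i] = correct; fb_rb_v[i] = fb_rb; fb_ii_v[i] = fb_ii;
    }
  }
  for (int b = 0; b < n_blocks; ++b) {
    block_acc[b] /= block_size;
    rb_win_frac[b] /= block_size;
  }

  List out = List::create(
    _["block_accuracy"] = block_acc,
    _["rb_win_fraction"] = rb_win_frac,
    _["final_rb_boundary"] = L.rb_b,
    _["final_ii_boundary"] = L.ii_b,
    _["final_rb_ps"] = L.ps_rb,
    _["final_ii_ps"] = L.ps_ii);
  if (return_trace) {
    out["p_a_rb"] = p_rb_v; out["p_a_ii"] = p_ii_v;
    out["odds_rb"] = odds_rb_v; out["odds_ii"] = odds_ii_v;
    out["epsilon"] = eps_v;
    out["winner"] = winner_v; out["response"] = response_v;
    out["correct"] = correct_v;
    out["fb_rb"] = fb_rb_v; out["fb_ii"] = fb_ii_v;
  }
  return out;
}

// Deterministic likelihood replay of an observed trial table: on each
// trial the system whose prediction best matches the observed choice is
// imputed as responsible, the trial likelihood is that matched probability
// (floored), and feedback routes by (responsible system, observed
// correctness) with each routed system updating against its own
// prediction versus the true category. response 0 marks a missing
// response: no likelihood, no update.
// [[Rcpp::export]]
List cpp_replay(NumericVector x, NumericVector y, IntegerVector true_cat,
                IntegerVector response,
                double rb_lr, double ii_lr, double ps_lr,
                double ps_init_rb, double ps_init_ii, int policy,
                double lik_floor) {
  int n = x.size();
  if (n < 2) stop("need at least two trials");

  Learner L;
  L.rb_b = 0.5 * (x[0] + x[1]);
  L.ii_b = 0.5 * ((y[0] - x[0]) + (y[1] - x[1]));
  L.ps_rb = ps_init_rb;
  L.ps_ii = ps_init_ii;
  L.rb_lr = rb_lr;
  L.ii_lr = ii_lr;
  L.ps_lr = ps_lr;

  NumericVector lik(n), p_rb_v(n), p_ii_v(n);
  IntegerVector responsible(n);

  for (int i = 0; i < n; ++i) {
    double p_rb = L.p_a_rb(x[i]);
    double p_ii = L.p_a_ii(x[i], y[i]);
    p_rb_v[i] = p_rb;
    p_ii_v[i] = p_ii;
    if (response[i] == NA_INTEGER || response[i] == 0) {
      lik[i] = NA_REAL;
      responsible[i] = NA_INTEGER;
      continue;
    }
    double lik_rb = (response[i] == 1) ? p_rb : 1.0 - p_rb;
    double lik_ii = (response[i] == 1) ? p_ii : 1.0 - p_ii;
    int resp_sys = (lik_rb >= lik_ii) ? 1 : 2; // tie -> RB
    double l = std::max(lik_rb, lik_ii);
    lik[i] = std::max(l, lik_floor);
    responsible[i] = resp_sys;

    bool correct = (response[i] == true_cat[i]);
    bool fb_rb, fb_ii;
    route(policy, resp_sys, correct, fb_rb, fb_ii);
    if (fb_rb) L.feed(1, x[i], y[i], true_cat[i]);
    if (fb_ii) L.feed(2, x[i], y[i], true_cat[i]);
  }

  return List::create(
    _["likelihood"] = lik,
    _["responsible"] = responsible,
    _["p_a_rb"] = p_rb_v,
    _["p_a_ii"] = p_ii_v,
    _["final_rb_boundary"] = L.rb_b,
    _["final_ii_boundary"] = L.ii_b,
    _["final_rb_ps"] = L.ps_rb,
    _["final_ii_ps"] = L.ps_ii);
}
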