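// Introspection-dynamics Monte Carlo core for two-player public goods games.
//
// Each time step the current strategy pair plays a deterministic block of
// rounds; one randomly chosen player draws a random alternative strategy,
// compares the block utility it would have realized against the coplayer's
// unchanged strategy, and switches with the logistic (Fermi) probability
// phi = 1 / (1 + exp(-s * (u_alt - u_cur))).
//
// Uses R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct GameParams {
  int e1, e2;
  double a1, a2, pden;   // productivities p_i = a_i / pden (exact rationals)
  bool threshold;
  double th_num, th_den; // theta = th_num / th_den
  double reward_r;
  double beta, gamma_;
  double emax;
};

struct BlockResult {
  double u1, u2;          // block utilities (sum over rounds)
  double c1_sum, c2_sum;  // contributions
  double pi1_sum, pi2_sum;
  int success, full;      // rounds meeting threshold / full contribution
};

inline void round_outcome(const GameParams& g, int c1, int c2,
                          double& pi1, double& pi2, bool& met) {
  double Ck = g.a1 * c1 + g.a2 * c2; // = C * pden, exact
  double r1, r2;
  met = false;
  if (g.threshold) {
    met = Ck * g.th_den >= g.th_num * g.pden;
    r1 = r2 = met ? g.reward_r : 0.0;
  } else {
    r1 = r2 = Ck / (g.pden * 2.0);
  }
  pi1 = (g.e1 - c1) + r1;
  pi2 = (g.e2 - c2) + r2;
}

inline void round_utility(const GameParams& g, int c1, int c2,
                          double pi1, double pi2, double& u1, double& u2) {
  double pen_abs = g.beta * std::abs(c1 - c2) / g.emax;
  double pen_rel = g.gamma_ *
    std::abs((double)c1 / g.e1 - (double)c2 / g.e2);
  u1 = pi1 - pen_abs - pen_rel;
  u2 = pi2 - pen_abs - pen_rel;
}

// Deterministic rollout of one block. s1 has length e2 + 2 (initial then
// responses to coplayer contributions 0..e2); s2 analogously.
BlockResult play_block(const GameParams& g, const std::vector<int>& s1,
                       const std::vector<int>& s2, int rounds,
                       int* rec_c = nullptr) {
  BlockResult b{0, 0, 0, 0, 0, 0, 0, 0};
  int c1 = s1[0], c2 = s2[0];
  for (int t = 0; t < rounds; ++t) {
    if (t > 0) {
      int n1 = s1[1 + c2];
      int n2 = s2[1 + c1];
      c1 = n1; c2 = n2;
    }
    double pi1, pi2, u1, u2;
    bool met;
    round_outcome(g, c1, c2, pi1, pi2, met);
    round_utility(g, c1, c2, pi1, pi2, u1, u2);
    b.u1 += u1; b.u2 += u2;
    b.c1_sum += c1; b.c2_sum += c2;
    b.pi1_sum += pi1; b.pi2_sum += pi2;
    if (met) ++b.success;
    if (c1 == g.e1 && c2 == g.e2) ++b.full;
    if (rec_c) { rec_c[2 * t] = c1; rec_c[2 * t + 1] = c2; }
  }
  return b;
}

inline int runif_int(int k) { // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

inline double fermi(double delta, double s) {
  double x = s * delta;
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double ex = std::exp(x);
  return ex / (1.0 + ex);
}

void draw_strategy(std::vector<int>& out, int own_e, bool constant_mode) {
  if (constant_mode) {
    int c = runif_int(own_e + 1);
    std::fill(out.begin(), out.end(), c);
  } else {
    for (size_t k = 0; k < out.size(); ++k) out[k] = runif_int(own_e + 1);
  }
}

// Encode a strategy as an index in 0..(own_e+1)^len - 1 (for occupancy).
inline double strat_index(const std::vector<int>& s, int own_e) {
  double idx = 0, base = own_e + 1;
  for (int k = (int)s.size() - 1; k >= 0; --k) idx = idx * base + s[k];
  return idx;
}

} // namespace

// [[Rcpp::export]]
List introspection_run_cpp(int e1, int e2, NumericVector p_num, double p_den,
                           bool is_threshold, double th_num, double th_den,
                           double reward_r, double beta, double gamma_,
                           double s, int steps, int rounds, bool agg_mean,
                           bool constant_mode, bool record_steps,
                           bool record_rounds, bool record_occupancy,
                           int burn_in) {
  GameParams g;
  g.e1 = e1; g.e2 = e2;
  g.a1 = p_num[0]; g.a2 = p_num[1]; g.pden = p_den;
  g.threshold = is_threshold;
  g.th_num = th_num; g.th_den = th_den; g.reward_r = reward_r;
  g.beta = beta; g.gamma_ = gamma_;
  g.emax = std::max(e1, e2);

  std::vector<int> s1(e2 + 2), s2(e1 + 2), alt;
  draw_strategy(s1, e1, constant_mode);
  draw_strategy(s2, e2, constant_mode);

  NumericMatrix step_mat = record_steps ? NumericMatrix(steps, 6)
                                        : NumericMatrix(0, 0);
  IntegerMatrix round_mat = record_rounds ? IntegerMatrix(steps * rounds, 2)
                                          : IntegerMatrix(0, 0);
  double m2_states = std::pow((double)(e2 + 1), (double)(e1 + 2));
  std::vector<double> occ;
  if (record_occupancy) {
    double m_tot = std::pow((double)(e1 + 1), (double)(e2 + 2)) * m2_states;
    occ.assign((size_t)m_tot, 0.0);
  }

  double tot_c1 = 0, tot_c2 = 0, tot_pi1 = 0, tot_pi2 = 0;
  double tot_success = 0, tot_full = 0, tot_rounds = 0;

  bool stale = true; // current block outcome needs recomputing
  BlockResult cur{};
  std::vector<int> rec_buf;
  if (record_rounds) rec_buf.resize(2 * rounds);

  for (int t = 0; t < steps; ++t) {
    if (stale || record_rounds) {
      cur = play_block(g, s1, s2, rounds,
                       record_rounds ? rec_buf.data() : nullptr);
      stale = false;
    }
    if (record_rounds)
      for (int k = 0; k < rounds; ++k) {
        round_mat((size_t)t * rounds + k, 0) = rec_buf[2 * k];
        round_mat((size_t)t * rounds + k, 1) = rec_buf[2 * k + 1];
      }
    if (record_steps) {
      step_mat(t, 0) = cur.c1_sum;  step_mat(t, 1) = cur.c2_sum;
      step_mat(t, 2) = cur.pi1_sum; step_mat(t, 3) = cur.pi2_sum;
      step_mat(t, 4) = cur.success; step_mat(t, 5) = cur.full;
    }
    if (t >= burn_in) {
      tot_c1 += cur.c1_sum; tot_c2 += cur.c2_sum;
      tot_pi1 += cur.pi1_sum; tot_pi2 += cur.pi2_sum;
      tot_success += cur.success; tot_full += cur.full;
      tot_rounds += rounds;
    }
    if (record_occupancy) {
      size_t idx = (size_t)(strat_index(s1, e1) * m2_states +
                            strat_index(s2, e2));
      occ[idx] += 1.0;
    }

    int focal = unif_rand() < 0.5 ? 1 : 2;
    if (focal == 1) {
      alt.assign(e2 + 2, 0);
      draw_strategy(alt, e1, constant_mode);
      BlockResult cf = play_block(g, alt, s2, rounds);
      double u_cur = agg_mean ? cur.u1 / rounds : cur.u1;
      double u_alt = agg_mean ? cf.u1 / rounds : cf.u1;
      if (unif_rand() < fermi(u_alt - u_cur, s)) { s1 = alt; stale = true; }
    } else {
      alt.assign(e1 + 2, 0);
      draw_strategy(alt, e2, constant_mode);
      BlockResult cf = play_block(g, s1, alt, rounds);
      double u_cur = agg_mean ? cur.u2 / rounds : cur.u2;
      double u_alt = agg_mean ? cf.u2 / rounds : cf.u2;
      if (unif_rand() < fermi(u_alt - u_cur, s)) { s2 = alt; stale = true; }
    }
  }

  List out = List::create(
    _["totals"] = NumericVector::create(
      _["c1"] = tot_c1, _["c2"] = tot_c2, _["pi1"] = tot_pi1,
      _["pi2"] = tot_pi2, _["success"] = tot_success, _["full"] = tot_full,
      _["rounds"] = tot_rounds),
    _["final_R1"] = IntegerVector(s1.begin(), s1.end()),
    _["final_R2"] = IntegerVector(s2.begin(), s2.end()));
  if (record_steps) out["steps"] = step_mat;
  if (record_rounds) out["rounds"] = round_mat;
  if (record_occupancy) out["occupancy"] = NumericVector(occ.begin(), occ.end());
  return out;
}
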