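// Exhaustive enumeration cores: look-ahead cost (depth-first minimum over
// ordered continuations), session log-likelihood, and the rate-maximising
// planner. Target ids are 0-based; id 15 is the start position. Distance
// matrices are 16x16; time/reward-rate matrices 16 origins x 15 targets.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int NT = 15;    // targets per display
static const int NO = 16;    // origins (targets + start)

// One-step cost matrix c(i,j) for fixed parameters, plus each origin row's
// target order sorted by ascending cost (used to resolve the innermost
// enumeration level by a first-free scan instead of a full loop).
struct CostCtx {
  std::vector<double> cmat;  // NO x NT, index i + NO*j
  std::vector<int> order;    // row-major: order[i*NT + t] = t-th cheapest j
};

static void build_cost_matrix(const NumericMatrix& d, const NumericMatrix& r,
                              const NumericVector& s,
                              double w1, double gamma, double w2,
                              bool fR, bool fD, bool fS, CostCtx& cc) {
  cc.cmat.assign(NO * NT, 0.0);
  for (int j = 0; j < NT; ++j) {
    double sz = fS ? w2 * s[j] : 0.0;
    for (int i = 0; i < NO; ++i) {
      double c = -sz;
      if (fR) c -= r(i, j);
      if (fD) c += w1 * std::pow(d(i, j), gamma);
      cc.cmat[i + NO * j] = c;
    }
  }
  cc.order.resize(NO * NT);
  for (int i = 0; i < NO; ++i) {
    int* ord = &cc.order[i * NT];
    for (int j = 0; j < NT; ++j) ord[j] = j;
    const double* row = cc.cmat.data() + i;
    std::sort(ord, ord + NT,
              [row](int a, int b) { return row[NO * a] < row[NO * b]; });
  }
}

// Minimum lambda-weighted continuation cost: ordered sequences of `steps`
// distinct free targets starting from `prev`. `used` marks the committed
// path; `inAvail` marks the unharvested set.
static double best_continuation(const CostCtx& cc,
                                const int* avail, int navail,
                                std::vector<char>& used,
                                const std::vector<char>& inAvail,
                                int prev, const double* lam, int steps) {
  if (steps <= 0) return 0.0;
  if (steps == 1) {
    // extremal single step from the presorted row; a negative weight turns
    // the minimum of lam*c into lam*max(c), so scan from the other end
    const int* ord = &cc.order[prev * NT];
    if (lam[0] >= 0) {
      for (int t = 0; t < NT; ++t) {
        int k = ord[t];
        if (inAvail[k] && !used[k]) return lam[0] * cc.cmat[prev + NO * k];
      }
    } else {
      for (int t = NT - 1; t >= 0; --t) {
        int k = ord[t];
        if (inAvail[k] && !used[k]) return lam[0] * cc.cmat[prev + NO * k];
      }
    }
    return 0.0;
  }
  double best = R_PosInf;
  for (int a = 0; a < navail; ++a) {
    int k = avail[a];
    if (used[k]) continue;
    used[k] = 1;
    double c = lam[0] * cc.cmat[prev + NO * k] +
      best_continuation(cc, avail, navail, used, inAvail, k, lam + 1,
                        steps - 1);
    used[k] = 0;
    if (c < best) best = c;
  }
  return best == R_PosInf ? 0.0 : best;
}

// C_j for each candidate; scratch buffers are supplied by the caller so the
// likelihood loop does not allocate.
static void lookahead_costs_core(const CostCtx& cc, int origin,
                                 const int* cand, int ncand,
                                 const int* avail, int navail,
                                 const std::vector<double>& lam, int depth,
                                 std::vector<char>& used,
                                 std::vector<char>& inAvail, double* out) {
  int horizon = std::min<int>(depth, navail);
  int steps = horizon - 1;
  std::fill(used.begin(), used.end(), 0);
  std::fill(inAvail.begin(), inAvail.end(), 0);
  for (int a = 0; a < navail; ++a) inAvail[avail[a]] = 1;
  for (int a = 0; a < ncand; ++a) {
    int j = cand[a];
    double c = cc.cmat[origin + NO * j];
    if (steps > 0) {
      used[j] = 1;
      c += best_continuation(cc, avail, navail, used, inAvail, j, lam.data(),
                             steps);
      used[j] = 0;
    }
    out[a] = c;
  }
}

// [[Rcpp::export]]
NumericVector cpp_lookahead_costs(NumericMatrix d, NumericMatrix r,
                                  NumericVector s, int origin,
                                  IntegerVector candidates,
                                  IntegerVector avail,
                                  double w1, double gamma, double w2,
                                  bool fR, bool fD, bool fS,
                                  NumericVector lambdas, int depth) {
  CostCtx cc;
  build_cost_matrix(d, r, s, w1, gamma, w2, fR, fD, fS, cc);
  std::vector<double> lam(lambdas.begin(), lambdas.end());
  std::vector<char> used(NT), inAvail(NT);
  NumericVector out(candidates.size());
  lookahead_costs_core(cc, origin, candidates.begin(), candidates.size(),
                       avail.begin(), avail.size(), lam, depth,
                       used, inAvail, REAL(out));
  return out;
}

// Choices are passed flat: per choice q, displays index disp[q] (1-based),
// origin and chosen ids, and slices avail_v[avail_p[q]..avail_p[q+1]) /
// cand_v[cand_p[q]..cand_p[q+1]) (0-based offsets). Choices must be grouped
// by display so the cost matrix is rebuilt only on display changes.
// [[Rcpp::export]]
double cpp_session_loglik(List displays, IntegerVector disp,
                          IntegerVector origin, IntegerVector chosen,
                          IntegerVector avail_v, IntegerVector avail_p,
                          IntegerVector cand_v, IntegerVector cand_p,
                          double beta, double w1, double gamma, double w2,
                          bool fR, bool fD, bool fS,
                          NumericVector lambdas, int depth) {
  std::vector<double> lam(lambdas.begin(), lambdas.end());
  CostCtx cc;
  int cur_disp = -1;
  double ll = 0.0;
  std::vector<char> used(NT), inAvail(NT);
  std::vector<double> C(NT);
  const int* av = avail_v.begin();
  const int* cv = cand_v.begin();
  for (int q = 0; q < disp.size(); ++q) {
    if (disp[q] != cur_disp) {
      List dsp = displays[disp[q] - 1];
      build_cost_matrix(as<NumericMatrix>(dsp["d"]),
                        as<NumericMatrix>(dsp["r"]),
                        as<NumericVector>(dsp["s"]),
                        w1, gamma, w2, fR, fD, fS, cc);
      cur_disp = disp[q];
    }
    int ncand = cand_p[q + 1] - cand_p[q];
    lookahead_costs_core(cc, origin[q], cv + cand_p[q], ncand,
                         av + avail_p[q], avail_p[q + 1] - avail_p[q],
                         lam, depth, used, inAvail, C.data());
    // log softmax probability of the chosen candidate, with max-subtraction
    int pos = -1;
    double zmax = R_NegInf;
    for (int a = 0; a < ncand; ++a) {
      double z = -beta * C[a];
      if (z > zmax) zmax = z;
      if (cv[cand_p[q] + a] == chosen[q]) pos = a;
    }
    if (pos < 0) return R_NegInf; // chosen target not legal
    double denom = 0.0;
    for (int a = 0; a < ncand; ++a)
      denom += std::exp(-beta * C[a] - zmax);
    ll += (-beta * C[pos] - zmax) - std::log(denom);
  }
  return ll;
}

// Rate-maximising planner: enumerate ordered prefixes of unharvested targets
// up to `depth` long whose cumulative predicted time fits the remaining
// budget. The remaining trial time is fixed, so maximising the rate of
// reward given that time means maximising the points of the feasible
// prefix; ties go to the shorter predicted duration, then fewer targets,
// then lowest first id. tmat is 16x15 predicted times.
struct PlanBest {
  double pts; double time; int len; int first;
  std::vector<int> seq;
  PlanBest() : pts(-1.0), time(R_PosInf), len(INT_MAX), first(INT_MAX) {}
};

static void plan_dfs(const NumericMatrix& tmat, const NumericVector& v,
                     const std::vector<int>& avail, std::vector<char>& used,
                     std::vector<int>& path, int prev,
                     double t_acc, double p_acc,
                     double remaining, int depth, PlanBest& best) {
  if ((int)path.size() >= depth) return;
  for (size_t a = 0; a < avail.size(); ++a) {
    int k = avail[a];
    if (used[k]) continue;
    double t2 = t_acc + tmat(prev, k);
    if (t2 > remaining) continue; // harvest would not complete in time
    double p2 = p_acc + v[k];
    path.push_back(k);
    int first = path[0];
    int len = (int)path.size();
    if (p2 > best.pts ||
        (p2 == best.pts &&
         (t2 < best.time - 1e-12 ||
          (t2 <= best.time + 1e-12 &&
           (len < best.len || (len == best.len && first < best.first)))))) {
      best.pts = p2; best.time = t2; best.len = len; best.first = first;
      best.seq = path;
    }
    used[k] = 1;
    plan_dfs(tmat, v, avail, used, path, k, t2, p2, remaining, depth, best);
    used[k] = 0;
    path.pop_back();
  }
}

// [[Rcpp::export]]
List cpp_planner_choice(NumericMatrix tmat, NumericVector v,
                        IntegerVector avail, int origin,
                        double remaining, int depth) {
  std::vector<int> av(avail.begin(), avail.end());
  std::vector<char> used(NT, 0);
  std::vector<int> path;
  PlanBest best;
  plan_dfs(tmat, v, av, used, path, origin, 0.0, 0.0, remaining, depth, best);
  if (best.pts < 0) {
    return List::create(_["sequence"] = IntegerVector(0),
                        _["points"] = 0.0, _["time"] = 0.0,
                        _["rate"] = NA_REAL);
  }
  return List::create(
    _["sequence"] = IntegerVector(best.seq.begin(), best.seq.end()),
    _["points"] = best.pts, _["time"] = best.time,
    _["rate"] = best.pts / best.time);
}
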