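// Modified dynamic program for significance-restricted segmentation.
//
// State per time point t: a set of triplets (link, index, score), one per
// admissible predecessor, kept sorted by accumulated objective.  "link" is
// the time point right before the current last block (0 = the last block
// starts at 1), "index" the 0-based position of the predecessor triplet in
// the link's set, "score" the accumulated SSE / negative log-likelihood.
//
// The feasibility screen: a predecessor triplet of S_s is admissible for the
// new block (s+1..t) iff its own last block (link+1..s) differs from
// (s+1..t) significantly at level alpha.  Future feasibility depends on the
// last block only through (s, t), so the first feasible triplet in score
// order is the only one worth keeping per link value.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

namespace {

enum Alt { TWO_SIDED = 0, GREATER = 1, LESS = 2 };   // right block vs left
enum Fam { AUTO_BINARY = 0, PROP_Z = 1, FISHER = 2 };

struct Course {
  const double *cm, *cs, *css;
  int n;
  bool binary;
  double cnt(int a, int b) const { return cm[b] - cm[a - 1]; }
  double sum(int a, int b) const { return cs[b] - cs[a - 1]; }
  double ssq(int a, int b) const { return css[b] - css[a - 1]; }
  // block objective: SSE, or binomial negative log-likelihood
  double obj(int a, int b) const {
    double c = cnt(a, b), s = sum(a, b);
    if (binary) {
      double k = s, r = 0.0;
      if (k > 0) r += k * std::log(k / c);
      if (c - k > 0) r += (c - k) * std::log(1.0 - k / c);
      return std::max(-r, 0.0);
    }
    double mu = s / c;
    double v = ssq(a, b) - c * mu * mu;
    return v > 0 ? v : 0.0;
  }
};

double junction_p(const Course &d, int a, int s, int b, double alpha_unused,
                  int alt, int fam) {
  (void)alpha_unused;
  double n1 = d.cnt(a, s), n2 = d.cnt(s + 1, b);
  if (n1 < 2 || n2 < 2) return 1.0;      // small-sample rule
  double s1 = d.sum(a, s), s2 = d.sum(s + 1, b);
  double m1 = s1 / n1, m2 = s2 / n2;
  if (!d.binary) {
    double ss1 = std::max(d.ssq(a, s) - n1 * m1 * m1, 0.0);
    double ss2 = std::max(d.ssq(s + 1, b) - n2 * m2 * m2, 0.0);
    double df = n1 + n2 - 2.0;
    double pooled = (ss1 + ss2) / df;
    if (pooled <= 0.0) {
      if (m1 == m2) return 1.0;
      if (alt == TWO_SIDED) return 0.0;
      if (alt == GREATER) return m2 > m1 ? 0.0 : 1.0;
      return m2 < m1 ? 0.0 : 1.0;
    }
    double t = (m1 - m2) / std::sqrt(pooled * (1.0 / n1 + 1.0 / n2));
    if (alt == TWO_SIDED) return std::min(2.0 * R::pt(-std::fabs(t), df, 1, 0), 1.0);
    if (alt == GREATER) return R::pt(t, df, 1, 0);      // right > left: t small
    return R::pt(t, df, 0, 0);                          // right < left: t large
  }
  // binary: proportion z or Fisher exact, with the any-cell-below-6 rule
  double k1 = s1, k2 = s2;
  int f = fam;
  if (f == AUTO_BINARY)
    f = (std::min(std::min(k1, n1 - k1), std::min(k2, n2 - k2)) < 6)
        ? FISHER : PROP_Z;
  if (f == PROP_Z) {
    double pbar = (k1 + k2) / (n1 + n2);
    if (pbar <= 0.0 || pbar >= 1.0) return 1.0;
    double z = (m1 - m2) / std::sqrt(pbar * (1.0 - pbar) * (1.0 / n1 + 1.0 / n2));
    if (alt == TWO_SIDED) return std::min(2.0 * R::pnorm(-std::fabs(z), 0, 1, 1, 0), 1.0);
    if (alt == GREATER) return R::pnorm(z, 0, 1, 1, 0);
    return R::pnorm(z, 0, 1, 0, 0);
  }
  // Fisher exact on (k1 of n1) vs (k2 of n2); hypergeometric in k1
  double K = k1 + k2, Nt = n1 + n2;
  if (alt == GREATER)          // right > left <=> left proportion small
    return R::phyper(k1, K, Nt - K, n1, 1, 0);
  if (alt == LESS)
    return R::phyper(k1 - 1, K, Nt - K, n1, 0, 0);
  double lo = std::max(0.0, K - n2), hi = std::min(K, n1);
  double dobs = R::dhyper(k1, K, Nt - K, n1, 0), p = 0.0;
  for (double x = lo; x <= hi; x += 1.0) {
    double dx = R::dhyper(x, K, Nt - K, n1, 0);
    if (dx <= dobs * (1.0 + 1e-7)) p += dx;
  }
  return std::min(p, 1.0);
}

} // namespace

// [[Rcpp::export]]
double junction_p_cpp(NumericVector cm, NumericVector cs, NumericVector css,
                      int a, int s, int b, int binary, int alt, int fam) {
  Course d{cm.begin(), cs.begin(), css.begin(), (int)cm.size() - 1,
           binary != 0};
  return junction_p(d, a, s, b, 0.0, alt, fam);
}

// [[Rcpp::export]]
List dp_fit_cpp(NumericVector cm, NumericVector cs, NumericVector css,
                double alpha, int binary, int alt, int fam,
                bool keep_sets = false) {
  Course d{cm.begin(), cs.begin(), css.begin(), (int)cm.size() - 1,
           binary != 0};
  int n = d.n;
  std::vector<std::vector<int>> link(n + 1), idx(n + 1);
  std::vector<std::vector<double>> score(n + 1);

  link[1] = {0}; idx[1] = {0}; score[1] = {d.obj(1, 1)};
  for (int t = 2; t <= n; ++t) {
    std::vector<int> L, I;
    std::vector<double> S;
    for (int s = t - 1; s >= 1; --s) {
      const std::vector<int> &Ls = link[s];
      const std::vector<double> &Ss = score[s];
      double obj_new = -1.0;
      for (size_t j = 0; j < Ls.size(); ++j) {   // stored order = score order
        double p = junction_p(d, Ls[j] + 1, s, t, alpha, alt, fam);
        if (p <= alpha) {
          if (obj_new < 0) obj_new = d.obj(s + 1, t);
          L.push_back(s); I.push_back((int)j); S.push_back(Ss[j] + obj_new);
          break;
        }
      }
    }
    L.push_back(0); I.push_back(0); S.push_back(d.obj(1, t));
    // stable sort by score; insertion order (s = t-1, ..., 1, then the
    // single-block triplet) breaks ties, so among equal-objective optima
    // the finer partition wins -- alpha = 1 then yields all singletons
    // even on exact-tie data, matching the stated limit behaviour
    std::vector<int> ord(L.size());
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&S](int x, int y) { return S[x] < S[y]; });
    link[t].resize(ord.size()); idx[t].resize(ord.size());
    score[t].resize(ord.size());
    for (size_t k = 0; k < ord.size(); ++k) {
      link[t][k] = L[ord[k]]; idx[t][k] = I[ord[k]]; score[t][k] = S[ord[k]];
    }
  }

  // backtrack from the first element of S_n
  std::vector<int> ends;
  int t = n, pos = 0;
  while (true) {
    ends.push_back(t);
    int lk = link[t][pos], ix = idx[t][pos];
    if (lk == 0) break;
    t = lk; pos = ix;
  }
  std::reverse(ends.begin(), ends.end());

  List sets = R_NilValue;
  if (keep_sets) {
    List out(n);
    for (int tt = 1; tt <= n; ++tt) {
      out[tt - 1] = DataFrame::create(
        _["link"] = IntegerVector(link[tt].begin(), link[tt].end()),
        _["index"] = IntegerVector(idx[tt].begin(), idx[tt].end()),
        _["score"] = NumericVector(score[tt].begin(), score[tt].end()));
    }
    sets = out;
  }
  return List::create(_["ends"] = IntegerVector(ends.begin(), ends.end()),
                      _["objective"] = score[n][0],
                      _["sets"] = sets);
}
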