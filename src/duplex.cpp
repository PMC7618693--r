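#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Guide/target duplex evaluation under a simplified nearest-neighbor model:
// dG = init + sum of stacking terms over consecutive Watson-Crick paired
// positions + a flat penalty per internal mismatch and per G:U wobble.
// Sequences are DNA alphabet (T stands for U); the guide ("mature") is
// antisense, so mature position k (0-based) pairs with site position L-1-k.

static inline int code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// pairing status: 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
static inline int pair_status(int m, int s) {
  if (s == 3 - m) return 2;
  if ((m == 2 && s == 3) || (m == 3 && s == 2)) return 1;
  return 0;
}

struct EvalResult {
  double dg;
  double dg_perfect;
  std::vector<int> mm_pos;  // 1-based from mature 5'
  std::vector<int> gu_pos;
};

static void encode(const std::string& x, std::vector<int>& out) {
  out.resize(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    out[i] = code(x[i]);
    if (out[i] < 0) stop("non-ACGT character in sequence");
  }
}

// stacks: length-16 vector indexed by 4*first + second of the mature
// dinucleotide read 5'->3'
static EvalResult eval_codes(const std::vector<int>& m, const int* s, int L,
                             const double* stacks, double mm_pen,
                             double gu_pen, double init) {
  EvalResult r;
  std::vector<int> st(L);
  long double dg = init, dgp = init;
  for (int k = 0; k < L; ++k) st[k] = pair_status(m[k], s[L - 1 - k]);
  for (int k = 0; k + 1 < L; ++k) {
    double stack = stacks[4 * m[k] + m[k + 1]];
    dgp += stack;
    if (st[k] == 2 && st[k + 1] == 2) dg += stack;
  }
  for (int k = 0; k < L; ++k) {
    if (st[k] == 0) {
      dg += mm_pen;
      r.mm_pos.push_back(k + 1);
    } else if (st[k] == 1) {
      dg += gu_pen;
      r.gu_pos.push_back(k + 1);
    }
  }
  r.dg = (double)dg;
  r.dg_perfect = (double)dgp;
  return r;
}

static double clip_fraction(double dg, double dgp) {
  if (dgp >= 0) stop("perfect-match duplex energy is non-negative; pathological composition");
  double f = dg / dgp;
  if (f < 0) f = 0;
  if (f > 1) f = 1;
  return f;
}

// admissibility of the mismatch pattern (positions 1-based from mature 5'):
// no mismatch or G:U inside [central_lo, central_hi]; <= seed_max mismatches
// in [seed_lo, seed_hi]; <= tail_max mismatches in [tail_lo, tail_hi];
// weighted total (mismatch = 1, G:U = gu_weight, rounded up) <= total_max
static bool admissible_pattern(const std::vector<int>& mm,
                               const std::vector<int>& gu,
                               const IntegerVector& rules, double gu_weight) {
  int seed_lo = rules[0], seed_hi = rules[1], seed_max = rules[2];
  int central_lo = rules[3], central_hi = rules[4];
  int tail_lo = rules[5], tail_hi = rules[6], tail_max = rules[7];
  int total_max = rules[8];
  int seed_n = 0, tail_n = 0;
  for (size_t i = 0; i < mm.size(); ++i) {
    int p = mm[i];
    if (p >= central_lo && p <= central_hi) return false;
    if (p >= seed_lo && p <= seed_hi) ++seed_n;
    if (p >= tail_lo && p <= tail_hi) ++tail_n;
  }
  for (size_t i = 0; i < gu.size(); ++i) {
    int p = gu[i];
    if (p >= central_lo && p <= central_hi) return false;
  }
  if (seed_n > seed_max || tail_n > tail_max) return false;
  double tot = (double)mm.size() + gu_weight * (double)gu.size();
  if ((int)std::ceil(tot - 1e-9) > total_max) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_evaluate(std::string mature, std::string site, NumericVector stacks,
                  double mm_pen, double gu_pen, double init) {
  if (mature.size() != site.size()) stop("mature and site lengths differ");
  std::vector<int> m, s;
  encode(mature, m);
  encode(site, s);
  EvalResult r = eval_codes(m, s.data(), (int)m.size(), stacks.begin(),
                            mm_pen, gu_pen, init);
  return List::create(_["dg"] = r.dg, _["dg_perfect"] = r.dg_perfect,
                      _["fraction"] = clip_fraction(r.dg, r.dg_perfect),
                      _["mm_pos"] = wrap(r.mm_pos),
                      _["gu_pos"] = wrap(r.gu_pos));
}

// Scan every window of the sense-strand transcript; return the window with
// maximal fraction, ties broken by smallest 0-based start.
// [[Rcpp::export]]
List cpp_best_site(std::string mature, std::string transcript,
                   NumericVector stacks, double mm_pen, double gu_pen,
                   double init) {
  int L = (int)mature.size();
  int N = (int)transcript.size();
  if (N < L) stop("transcript shorter than mature length");
  std::vector<int> m, t;
  encode(mature, m);
  encode(transcript, t);
  int best_start = 0;
  double best_frac = -1;
  EvalResult best;
  for (int w = 0; w + L <= N; ++w) {
    EvalResult r = eval_codes(m, t.data() + w, L, stacks.begin(), mm_pen,
                              gu_pen, init);
    double f = clip_fraction(r.dg, r.dg_perfect);
    if (f > best_frac) {
      best_frac = f;
      best_start = w;
      best = r;
    }
  }
  return List::create(_["start"] = best_start, _["end"] = best_start + L,
                      _["dg"] = best.dg, _["dg_perfect"] = best.dg_perfect,
                      _["fraction"] = best_frac,
                      _["mm_pos"] = wrap(best.mm_pos),
                      _["gu_pos"] = wrap(best.gu_pos));
}

// Batch: best-site fraction and admissibility of each mature against one
// transcript. Returns parallel vectors over matures. Allocation-free inner
// loop; the perfect-match energy is constant per mature and computed once.
// [[Rcpp::export]]
List cpp_scan_table(CharacterVector matures, std::string transcript,
                    NumericVector stacks, double mm_pen, double gu_pen,
                    double init, IntegerVector rules, double gu_weight) {
  int M = matures.size();
  int N = (int)transcript.size();
  std::vector<int> t;
  encode(transcript, t);
  NumericVector frac(M), dg(M);
  IntegerVector start(M);
  LogicalVector adm(M);
  const double* st = stacks.begin();
  int seed_lo = rules[0], seed_hi = rules[1], seed_max = rules[2];
  int central_lo = rules[3], central_hi = rules[4];
  int tail_lo = rules[5], tail_hi = rules[6], tail_max = rules[7];
  int total_max = rules[8];
  std::vector<int> m;
  for (int i = 0; i < M; ++i) {
    std::string mat = as<std::string>(matures[i]);
    int L = (int)mat.size();
    if (N < L) stop("transcript shorter than mature length");
    encode(mat, m);
    long double dgp = init;
    for (int k = 0; k + 1 < L; ++k) dgp += st[4 * m[k] + m[k + 1]];
    if (dgp >= 0)
      stop("perfect-match duplex energy is non-negative; pathological composition");
    int best_start = 0;
    double best_frac = -1, best_dg = 0;
    bool best_adm = false;
    const int* td = t.data();
    for (int w = 0; w + L <= N; ++w) {
      long double d = init;
      int prev = -1;
      int n_mm = 0, n_gu = 0, seed_n = 0, tail_n = 0;
      bool central_ok = true;
      const int* site = td + w;  // site position L-1-k pairs mature k
      for (int k = 0; k < L; ++k) {
        int s = pair_status(m[k], site[L - 1 - k]);
        if (s == 2) {
          if (prev == 2) d += st[4 * m[k - 1] + m[k]];
        } else {
          int p = k + 1;
          if (s == 1) {
            d += gu_pen;
            ++n_gu;
            if (p >= central_lo && p <= central_hi) central_ok = false;
          } else {
            d += mm_pen;
            ++n_mm;
            if (p >= central_lo && p <= central_hi) central_ok = false;
            if (p >= seed_lo && p <= seed_hi) ++seed_n;
            if (p >= tail_lo && p <= tail_hi) ++tail_n;
          }
        }
        prev = s;
      }
      double f = (double)(d / dgp);
      if (f < 0) f = 0;
      if (f > 1) f = 1;
      if (f > best_frac) {
        best_frac = f;
        best_start = w;
        best_dg = (double)d;
        double tot = (double)n_mm + gu_weight * (double)n_gu;
        best_adm = central_ok && seed_n <= seed_max && tail_n <= tail_max &&
          (int)std::ceil(tot - 1e-9) <= total_max;
      }
    }
    frac[i] = best_frac;
    dg[i] = best_dg;
    start[i] = best_start;
    adm[i] = best_adm;
  }
  return List::create(_["fraction"] = frac, _["dg"] = dg, _["start"] = start,
                      _["admissible"] = adm);
}
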