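#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Naive full-scan of an integer-encoded sequence (codes 0..3 = A,C,G,T;
// negative = ambiguous, never matches) with a 4 x L integer score matrix.
// No lookahead or filtration: every window's full column sum is formed, via
// a column-outer accumulation that keeps memory access sequential.
// Ambiguous bases contribute a large negative constant so any window
// containing one scores far below every attainable threshold.

static const int AMBIG = -10000000;

static void accumulate(const int *s, R_xlen_t nwin, const IntegerMatrix &sc,
                       std::vector<int> &acc) {
  const int L = sc.ncol();
  std::fill(acc.begin(), acc.end(), 0);
  for (int j = 0; j < L; ++j) {
    int tab[5];
    for (int b = 0; b < 4; ++b) tab[b] = sc(b, j);
    tab[4] = AMBIG;
    const int *sj = s + j;
    for (R_xlen_t i = 0; i < nwin; ++i) {
      const int b = sj[i];
      acc[i] += tab[b < 0 ? 4 : b];
    }
  }
}

// [[Rcpp::export]]
List cpp_scan_int(IntegerVector seq, IntegerMatrix sc, double thr) {
  const int L = sc.ncol();
  const R_xlen_t n = seq.size();
  std::vector<int> pos;
  std::vector<double> score;
  if (n >= L) {
    const R_xlen_t nwin = n - L + 1;
    std::vector<int> acc(nwin);
    accumulate(INTEGER(seq), nwin, sc, acc);
    const double t = thr;
    for (R_xlen_t i = 0; i < nwin; ++i) {
      if (acc[i] >= t) {
        pos.push_back((int) i);
        score.push_back((double) acc[i]);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(score));
}

// [[Rcpp::export]]
int cpp_count_int(IntegerVector seq, IntegerMatrix sc, double thr) {
  const int L = sc.ncol();
  const R_xlen_t n = seq.size();
  if (n < L) return 0;
  const R_xlen_t nwin = n - L + 1;
  std::vector<int> acc(nwin);
  accumulate(INTEGER(seq), nwin, sc, acc);
  const double t = thr;
  int cnt = 0;
  for (R_xlen_t i = 0; i < nwin; ++i)
    if (acc[i] >= t) ++cnt;
  return cnt;
}
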