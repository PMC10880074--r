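#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Motif score at every start position of an encoded sequence.
// codes are 1-based (A=1, C=2, G=3, T=4); logprob is 4 x L, rows A,C,G,T.
// [[Rcpp::export]]
NumericVector box_scores_cpp(const NumericMatrix& logprob,
                             const IntegerVector& codes) {
  const int L = logprob.ncol();
  const int n = codes.size() - L + 1;
  if (n < 1) return NumericVector(0);
  const double* lp = logprob.begin();  // column-major 4 x L
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < L; ++j) s += lp[4 * j + codes[i + j] - 1];
    out[i] = s;
  }
  return out;
}

static double best_total(const std::vector<int>& codes,
                         const double* lp35, int L35,
                         const double* lp10, int L10,
                         int spacer_min, int spacer_max,
                         bool anchored, int tss_index, int dmin, int dmax,
                         std::vector<double>& s10buf) {
  const int n = (int) codes.size();
  double best = R_NegInf;
  const int n10 = n - L10 + 1;
  if (n10 > 0) {
    s10buf.resize(n10);
    for (int i = 0; i < n10; ++i) {
      double s = 0.0;
      for (int j = 0; j < L10; ++j) s += lp10[4 * j + codes[i + j] - 1];
      s10buf[i] = s;
    }
  }
  const int n35 = n - L35 + 1;
  for (int p35 = 0; p35 < n35; ++p35) {
    double s35 = 0.0;
    for (int j = 0; j < L35; ++j) s35 += lp35[4 * j + codes[p35 + j] - 1];
    for (int sp = spacer_min; sp <= spacer_max; ++sp) {
      const int p10 = p35 + L35 + sp;          // 0-based start of -10 box
      if (p10 + L10 > n) continue;
      if (anchored) {
        const int d = tss_index - (p10 + L10 - 1) - 1;  // intervening bases
        if (d < dmin || d > dmax) continue;
      }
      const double tot = s35 + s10buf[p10];
      if (tot > best) best = tot;
    }
  }
  return best;
}

// Best bipartite total of one encoded window (0-based tss_index, or -1
// for an unanchored scan). Returns -Inf when no placement fits.
// [[Rcpp::export]]
double best_total_cpp(const IntegerVector& codes,
                      const NumericMatrix& lp35, const NumericMatrix& lp10,
                      int spacer_min, int spacer_max,
                      bool anchored, int tss_index, int dmin, int dmax) {
  std::vector<int> v(codes.begin(), codes.end());
  std::vector<double> buf;
  return best_total(v, lp35.begin(), lp35.ncol(), lp10.begin(), lp10.ncol(),
                    spacer_min, spacer_max, anchored, tss_index, dmin, dmax,
                    buf);
}

// Null distribution of the best bipartite total: n exact shuffles of the
// window's bases (mononucleotide counts preserved) scored under the same
// scan mode as the observed window. Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericVector null_best_totals_cpp(const IntegerVector& codes,
                                   const NumericMatrix& lp35,
                                   const NumericMatrix& lp10,
                                   int spacer_min, int spacer_max,
                                   bool anchored, int tss_index,
                                   int dmin, int dmax, int n) {
  std::vector<int> v(codes.begin(), codes.end());
  const int len = (int) v.size();
  NumericVector out(n);
  std::vector<double> buf;
  RNGScope scope;
  for (int r = 0; r < n; ++r) {
    // Fisher-Yates shuffle driven by R's uniform RNG
    for (int i = len - 1; i > 0; --i) {
      int j = (int) (unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    out[r] = best_total(v, lp35.begin(), lp35.ncol(), lp10.begin(),
                        lp10.ncol(), spacer_min, spacer_max,
                        anchored, tss_index, dmin, dmax, buf);
  }
  return out;
}
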