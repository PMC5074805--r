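#include <Rcpp.h>
using namespace Rcpp;

// Additive log-odds score of every length-w window of an encoded sequence.
// codes: integer codes 1..20 (0 = non-standard, contributes 0 by design).
// lo: w x 20 matrix of per-position log-odds (bits).
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector codes, NumericMatrix lo) {
  const int L = codes.size();
  const int w = lo.nrow();
  if (L < w) return NumericVector(0);
  const int n = L - w + 1;
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int k = 0; k < w; ++k) {
      const int c = codes[j + k];
      if (c > 0) s += lo(k, c - 1);
    }
    out[j] = s;
  }
  return out;
}

// Per-sequence maximum window score over a concatenated code vector.
// starts: 0-based offsets of each sequence; lens: sequence lengths.
// Sequences shorter than w yield -Inf.
// [[Rcpp::export]]
NumericVector cpp_db_max_scores(IntegerVector codes, IntegerVector starts,
                                IntegerVector lens, NumericMatrix lo) {
  const int w = lo.nrow();
  const int nseq = starts.size();
  NumericVector out(nseq);
  for (int i = 0; i < nseq; ++i) {
    const int L = lens[i];
    if (L < w) { out[i] = R_NegInf; continue; }
    const int off = starts[i];
    double best = R_NegInf;
    for (int j = 0; j <= L - w; ++j) {
      double s = 0.0;
      for (int k = 0; k < w; ++k) {
        const int c = codes[off + j + k];
        if (c > 0) s += lo(k, c - 1);
      }
      if (s > best) best = s;
    }
    out[i] = best;
  }
  return out;
}
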