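#include <Rcpp.h>
using namespace Rcpp;

// pos: n_samples x m matrix, pos(s, j) = position of marker j in sample s.
// Returns q with q(i, j) = fraction of samples where i precedes j.
// [[Rcpp::export]]
NumericMatrix cpp_pair_agreement(IntegerMatrix pos) {
  int ns = pos.nrow(), m = pos.ncol();
  NumericMatrix q(m, m);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < m; ++i) {
      int pi = pos(s, i);
      for (int j = i + 1; j < m; ++j) {
        if (pi < pos(s, j)) q(i, j) += 1.0; else q(j, i) += 1.0;
      }
    }
  }
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i != j) q(i, j) /= ns;
    }
    q(i, i) = NA_REAL;
  }
  return q;
}
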