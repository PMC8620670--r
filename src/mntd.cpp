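#include <Rcpp.h>
using namespace Rcpp;

// Mean nearest-taxon distance over the rows/columns of dm indexed by idx
// (1-based). Inner loop of every null draw, hence C++.
// [[Rcpp::export]]
double cpp_mntd(NumericMatrix dm, IntegerVector idx) {
  const int k = idx.size();
  if (k < 2) stop("need at least 2 taxa");
  double total = 0.0;
  for (int i = 0; i < k; ++i) {
    const int ri = idx[i] - 1;
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      const double d = dm(ri, idx[j] - 1);
      if (d < best) best = d;
    }
    total += best;
  }
  return total / k;
}

// MNTD of each column of `draws` (a k x ndraws matrix of 1-based tip
// indices): the null distribution for NTI.
// [[Rcpp::export]]
NumericVector cpp_null_mntd(NumericMatrix dm, IntegerMatrix draws) {
  const int k = draws.nrow(), n = draws.ncol();
  NumericVector out(n);
  for (int c = 0; c < n; ++c) {
    double total = 0.0;
    for (int i = 0; i < k; ++i) {
      const int ri = draws(i, c) - 1;
      double best = R_PosInf;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        const double d = dm(ri, draws(j, c) - 1);
        if (d < best) best = d;
      }
      total += best;
    }
    out[c] = total / k;
  }
  return out;
}
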