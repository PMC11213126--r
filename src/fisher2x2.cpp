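#include <Rcpp.h>
using namespace Rcpp;

// Two-sided Fisher exact p for the 2x2 table
//   [[ c1, b1 - c1 ],
//    [ c2, b2 - c2 ]]
// conditioning on both margins: the top-left entry is hypergeometric with
// r = b1 white, b = b2 black, n = c1 + c2 drawn.  The two-sided p sums
// P(X = k) over all k in the support with P(X = k) <= P(X = obs), using the
// same relative tie tolerance as stats::fisher.test so that mathematically
// equal tail masses computed through lgamma are not dropped.
static double fisher_one(int c1, int b1, int c2, int b2) {
  if (b1 < 0 || b2 < 0 || c1 < 0 || c2 < 0 || c1 > b1 || c2 > b2)
    return NA_REAL;
  if (b1 == 0 || b2 == 0) return NA_REAL;
  const int s = c1 + c2;
  const int lo = std::max(0, s - b2);
  const int hi = std::min(s, b1);
  const double dobs = R::dhyper((double)c1, (double)b1, (double)b2,
                                (double)s, 0);
  const double relErr = 1.0 + 1e-7;
  double p = 0.0;
  for (int k = lo; k <= hi; ++k) {
    double d = R::dhyper((double)k, (double)b1, (double)b2, (double)s, 0);
    if (d <= dobs * relErr) p += d;
  }
  return std::min(p, 1.0);
}

// [[Rcpp::export(name = ".fisher2x2")]]
NumericVector fisher2x2_cpp(IntegerVector c1, IntegerVector b1,
                            IntegerVector c2, IntegerVector b2) {
  R_xlen_t n = c1.size();
  if (b1.size() != n || c2.size() != n || b2.size() != n)
    stop("all four count vectors must have the same length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (c1[i] == NA_INTEGER || b1[i] == NA_INTEGER ||
        c2[i] == NA_INTEGER || b2[i] == NA_INTEGER) {
      out[i] = NA_REAL;
    } else {
      out[i] = fisher_one(c1[i], b1[i], c2[i], b2[i]);
    }
  }
  return out;
}
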