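#include <Rcpp.h>
using namespace Rcpp;

// Two-sided Fisher exact p for a vector of 2x2 tables
//   [[a, b], [c, d]]  with rows = (case, control), cols = (meth, unmeth).
// Two-sided rule: sum hypergeometric point probabilities <= observed
// (relative tolerance 1 + 1e-7, the standard exact-test convention).
// Tables with an empty row are undefined (NA); degenerate margins give p = 1.
// [[Rcpp::export]]
NumericVector fisher2x2_p_cpp(IntegerVector a, IntegerVector b,
                              IntegerVector c, IntegerVector d) {
  const R_xlen_t n = a.size();
  if (b.size() != n || c.size() != n || d.size() != n)
    stop("count vectors must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_INTEGER || b[i] == NA_INTEGER ||
        c[i] == NA_INTEGER || d[i] == NA_INTEGER) { out[i] = NA_REAL; continue; }
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("negative count in 2x2 table at position %d", (int)(i + 1));
    const double n1 = a[i] + b[i];   // case total
    const double n2 = c[i] + d[i];   // control total
    const double k  = a[i] + c[i];   // methylated total
    if (n1 == 0 || n2 == 0) { out[i] = NA_REAL; continue; }
    if (k == 0 || k == n1 + n2) { out[i] = 1.0; continue; }
    const double dobs = ::Rf_dhyper(a[i], n1, n2, k, 0);
    const double thr  = dobs * (1.0 + 1e-7);
    const int lo = (int)std::max(0.0, k - n2);
    const int hi = (int)std::min(k, n1);
    double p = 0.0;
    for (int x = lo; x <= hi; ++x) {
      const double dx = ::Rf_dhyper(x, n1, n2, k, 0);
      if (dx <= thr) p += dx;
    }
    out[i] = std::min(1.0, p);
  }
  return out;
}
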