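#include <Rcpp.h>
using namespace Rcpp;

// Pentamer-difference score for many candidate breakpoint pairs.
//
// tPp, tPm: 3072 x (n_genes + 1) transposed prefix-sum matrices of
// frame-specific pentamer counts for plus- and minus-strand genes
// (column g = totals over the first g genes in midpoint order).
// totp, totm: length-3072 genome-wide class totals.
// a, b: 0-based gene-index bounds per pair (arm I = genes a..b-1).
// Conditionals use a pseudocount of 1 per pentamer per frame.
// [[Rcpp::export]]
NumericVector delta_pairs_cpp(NumericMatrix tPp, NumericMatrix tPm,
                              NumericVector totp, NumericVector totm,
                              IntegerVector a, IntegerVector b) {
  const int npairs = a.size();
  const int ncell = tPp.nrow();          // 3072 = 768 tetramer-frames x 4
  NumericVector out(npairs);
  for (int p = 0; p < npairs; ++p) {
    const double *pa = &tPp(0, a[p]), *pb = &tPp(0, b[p]);
    const double *ma = &tPm(0, a[p]), *mb = &tPm(0, b[p]);
    double d = 0.0, n1tot = 0.0, n2tot = 0.0;
    double c1[4], c2[4];
    for (int t = 0; t < ncell; t += 4) {
      double s1 = 0.0, s2 = 0.0;
      for (int k = 0; k < 4; ++k) {
        const int i = t + k;
        const double in1p = pb[i] - pa[i];
        const double in1m = mb[i] - ma[i];
        c1[k] = in1p + (totm[i] - in1m) + 1.0;
        c2[k] = in1m + (totp[i] - in1p) + 1.0;
        s1 += c1[k];
        s2 += c2[k];
        n1tot += c1[k] - 1.0;
        n2tot += c2[k] - 1.0;
      }
      for (int k = 0; k < 4; ++k) {
        const double diff = c1[k] / s1 - c2[k] / s2;
        d += diff * diff;
      }
    }
    out[p] = (n1tot <= 0.0 || n2tot <= 0.0) ? NA_REAL : d;
  }
  return out;
}
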