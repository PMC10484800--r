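#include <Rcpp.h>
using namespace Rcpp;

// Gather columns of an im2col matrix from a flat (unpadded) activation.
// idx holds 1-based linear indices into x; 0 marks a zero-padding position.
// [[Rcpp::export(rng = false)]]
NumericMatrix gather_cols(NumericVector x, IntegerMatrix idx) {
  const R_xlen_t n = idx.nrow(), m = idx.ncol();
  NumericMatrix out(n, m);
  const double* xp = x.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const int* ip = &idx(0, 0) + j * n;
    double* op = &out(0, 0) + j * n;
    for (R_xlen_t i = 0; i < n; ++i) op[i] = ip[i] ? xp[ip[i] - 1] : 0.0;
  }
  return out;
}

// Adjoint: scatter-add im2col columns back into a flat activation of
// length out_len. Index 0 (padding) is dropped; overlaps accumulate.
// [[Rcpp::export(rng = false)]]
NumericVector scatter_add_cols(NumericMatrix cols, IntegerMatrix idx,
                               double out_len) {
  const R_xlen_t n = idx.nrow(), m = idx.ncol();
  NumericVector out((R_xlen_t) out_len);
  double* op = out.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const int* ip = &idx(0, 0) + j * n;
    const double* cp = &cols(0, 0) + j * n;
    for (R_xlen_t i = 0; i < n; ++i)
      if (ip[i]) op[ip[i] - 1] += cp[i];
  }
  return out;
}
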