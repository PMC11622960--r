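#include <Rcpp.h>
using namespace Rcpp;

// Gather x[idx] for the im2col lowering of a convolution. idx is 1-based and
// precomputed once per (layer geometry, batch size), so the hot loop is a
// plain copy.
// [[Rcpp::export]]
NumericVector lh_gather(const NumericVector& x, const IntegerVector& idx) {
  R_xlen_t n = idx.size();
  NumericVector out(no_init(n));
  const double* px = x.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[pi[i] - 1];
  return out;
}

// Scatter-add vals into a zero vector of length n (the col2im adjoint of
// lh_gather). Overlapping patch positions accumulate.
// [[Rcpp::export]]
NumericVector lh_scatter_add(int n, const IntegerVector& idx,
                             const NumericVector& vals) {
  NumericVector out(n);  // zero-initialised
  R_xlen_t m = idx.size();
  const int* pi = idx.begin();
  const double* pv = vals.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < m; ++i) po[pi[i] - 1] += pv[i];
  return out;
}

// Hamming distances between packed codes. q and db hold one code per column,
// packed 32 bits per integer word; distances are popcounts of the XOR.
// [[Rcpp::export]]
IntegerMatrix lh_hamming_packed(const IntegerMatrix& q, const IntegerMatrix& db) {
  int words = q.nrow();
  if (db.nrow() != words) stop("packed codes have different word counts");
  int nq = q.ncol(), nd = db.ncol();
  IntegerMatrix out(nq, nd);
  for (int j = 0; j < nd; ++j) {
    const int* pd = &db(0, j);
    for (int i = 0; i < nq; ++i) {
      const int* pq = &q(0, i);
      unsigned int acc = 0;
      for (int w = 0; w < words; ++w) {
        unsigned int x = (unsigned int)pq[w] ^ (unsigned int)pd[w];
#if defined(__GNUC__) || defined(__clang__)
        acc += __builtin_popcount(x);
#else
        while (x) { acc += x & 1u; x >>= 1; }
#endif
      }
      out(i, j) = (int)acc;
    }
  }
  return out;
}
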