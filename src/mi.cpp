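#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Plug-in mutual information (bits) for all gene pairs on pre-discretized
// data. D is an n_samples x n_genes matrix of bin codes in 1..B.
// Diagonal is left at 0 (self-information is excluded downstream).
// [[Rcpp::export]]
NumericMatrix mi_all_pairs_cpp(IntegerMatrix D, int B) {
  const int n = D.nrow();
  const int G = D.ncol();
  const double ln2 = std::log(2.0);
  std::vector<std::vector<int> > marg(G, std::vector<int>(B, 0));
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < n; ++i)
      marg[g][D(i, g) - 1]++;
  NumericMatrix M(G, G);
  std::vector<int> joint(B * B);
  for (int a = 0; a < G; ++a) {
    const int *ca = &D(0, a);
    for (int b = a + 1; b < G; ++b) {
      const int *cb = &D(0, b);
      std::fill(joint.begin(), joint.end(), 0);
      for (int i = 0; i < n; ++i)
        joint[(ca[i] - 1) * B + (cb[i] - 1)]++;
      double mi = 0.0;
      for (int x = 0; x < B; ++x) {
        const int mx = marg[a][x];
        if (!mx) continue;
        const int *row = &joint[x * B];
        for (int y = 0; y < B; ++y) {
          const int c = row[y];
          if (c)
            mi += (double)c / n *
                  std::log((double)c * n / ((double)mx * marg[b][y]));
        }
      }
      mi /= ln2;
      M(a, b) = mi;
      M(b, a) = mi;
    }
    if ((a & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return M;
}

// MI (bits) between matched column pairs of two discretized matrices;
// used for scoring sampled null pairs.
// [[Rcpp::export]]
NumericVector mi_paired_cols_cpp(IntegerMatrix Da, IntegerMatrix Db, int B) {
  const int n = Da.nrow();
  const int K = Da.ncol();
  if (Db.nrow() != n || Db.ncol() != K)
    stop("Da and Db must have identical dimensions");
  const double ln2 = std::log(2.0);
  NumericVector out(K);
  std::vector<int> joint(B * B), ma(B), mb(B);
  for (int k = 0; k < K; ++k) {
    const int *ca = &Da(0, k);
    const int *cb = &Db(0, k);
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(ma.begin(), ma.end(), 0);
    std::fill(mb.begin(), mb.end(), 0);
    for (int i = 0; i < n; ++i) {
      joint[(ca[i] - 1) * B + (cb[i] - 1)]++;
      ma[ca[i] - 1]++;
      mb[cb[i] - 1]++;
    }
    double mi = 0.0;
    for (int x = 0; x < B; ++x) {
      if (!ma[x]) continue;
      const int *row = &joint[x * B];
      for (int y = 0; y < B; ++y) {
        const int c = row[y];
        if (c)
          mi += (double)c / n *
                std::log((double)c * n / ((double)ma[x] * mb[y]));
      }
    }
    out[k] = mi / ln2;
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
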