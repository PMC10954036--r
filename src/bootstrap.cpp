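// Bootstrap resampling engine for the smoothed-FST outlier null.
//
// A window's null statistic is the Gaussian-weighted mean of |window| values
// drawn with replacement from the genome-wide pool of per-site values. Two
// execution paths compute the exceedance count k = #{resample >= observed}:
//
//  * indep: each window draws its own replicates (exact independence across
//    windows; used whenever the level's total draw count is small).
//  * shared: one replicate draw matrix per chunk is shared by all windows at
//    the same escalation level and combined with each window's weights by a
//    BLAS matrix product. Marginally each window still receives an exact
//    B-replicate bootstrap p-value; only independence *between* windows is
//    relaxed. This is what makes 1e6-1e7 replicate levels tractable.
//
// All randomness flows through R's RNG so set.seed() governs both paths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int draw_index(int n) {
  int i;
  do {
    i = (int)(unif_rand() * n);
  } while (i >= n); // guard against unif_rand() returning 1.0
  return i;
}

// [[Rcpp::export]]
IntegerVector boot_indep_cpp(NumericVector pool, List weights,
                             NumericVector obs, int B, double tol) {
  const int n = pool.size();
  const int nwin = weights.size();
  IntegerVector k(nwin);
  for (int w = 0; w < nwin; ++w) {
    NumericVector wv = weights[w];
    const int m = wv.size();
    const double thr = obs[w] - tol * std::max(1.0, std::fabs(obs[w]));
    int cnt = 0;
    for (int b = 0; b < B; ++b) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += wv[j] * pool[draw_index(n)];
      if (s >= thr) ++cnt;
    }
    k[w] = cnt;
  }
  return k;
}

// [[Rcpp::export]]
IntegerVector boot_shared_cpp(NumericVector pool, arma::mat W,
                              NumericVector obs, double B, int chunk,
                              double tol) {
  const int n = pool.size();
  const int mmax = W.n_rows;
  const int nwin = W.n_cols;
  IntegerVector k(nwin);
  arma::vec thr(nwin);
  for (int w = 0; w < nwin; ++w)
    thr[w] = obs[w] - tol * std::max(1.0, std::fabs(obs[w]));
  double done = 0.0;
  while (done < B) {
    int r = (int)std::min((double)chunk, B - done);
    arma::mat D(r, mmax);
    double* d = D.memptr();
    const R_xlen_t total = (R_xlen_t)r * mmax;
    for (R_xlen_t i = 0; i < total; ++i) d[i] = pool[draw_index(n)];
    arma::mat S = D * W; // r x nwin weighted means (weights pre-normalized)
    for (int w = 0; w < nwin; ++w) {
      const double* col = S.colptr(w);
      int cnt = 0;
      for (int i = 0; i < r; ++i)
        if (col[i] >= thr[w]) ++cnt;
      k[w] += cnt;
    }
    done += r;
  }
  return k;
}
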