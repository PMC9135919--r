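// Resampling kernel for PCLRC network inference: for each pre-drawn row
// subsample, compute column average-ranks, the Spearman correlation matrix,
// CLR background-corrected scores, and accumulate how often each edge falls
// in the top keepFraction of scores (ties at the cutoff included).
// Subsample indices are drawn in R so that results are reproducible from the
// R random number generator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column-wise average ranks (ties get the mean rank)
static void colRanksAvg(const mat& X, mat& out) {
  const uword n = X.n_rows, P = X.n_cols;
  uvec ord(n);
  for (uword j = 0; j < P; ++j) {
    ord = stable_sort_index(X.col(j));
    uword i = 0;
    while (i < n) {
      uword k = i;
      const double v = X(ord(i), j);
      while (k + 1 < n && X(ord(k + 1), j) == v) ++k;
      const double r = 0.5 * (static_cast<double>(i) +
                              static_cast<double>(k)) + 1.0;
      for (uword t = i; t <= k; ++t) out(ord(t), j) = r;
      i = k + 1;
    }
  }
}

// Pearson correlation of (rank) columns; constant columns get zero rows
static void corFromRanks(const mat& rk, mat& R) {
  const uword n = rk.n_rows, P = rk.n_cols;
  mat Z = rk;
  rowvec mu = mean(Z, 0);
  Z.each_row() -= mu;
  rowvec sd = sqrt(sum(square(Z), 0) / static_cast<double>(n - 1));
  uvec constCol = find(sd <= 0);
  rowvec sdSafe = sd;
  sdSafe.elem(constCol).fill(1.0);
  Z.each_row() /= (sdSafe * std::sqrt(static_cast<double>(n - 1)));
  R = Z.t() * Z;
  for (uword c = 0; c < constCol.n_elem; ++c) {
    R.row(constCol(c)).zeros();
    R.col(constCol(c)).zeros();
  }
  R.diag().ones();
}

// CLR scores: row-background z-scores of |R|, clipped at 0, symmetrised
static void clrFromCor(const mat& R, mat& S) {
  const uword P = R.n_cols;
  mat s = abs(R);
  s.diag().zeros();
  vec mu = sum(s, 1) / static_cast<double>(P - 1);
  vec ex2 = sum(square(s), 1) / static_cast<double>(P - 1);
  vec var = ex2 - square(mu);
  var.transform([](double v) { return v > 0 ? v : 0.0; });
  vec sd = sqrt(var);
  mat z(P, P, fill::zeros);
  for (uword i = 0; i < P; ++i) {
    if (sd(i) <= 0) continue;
    for (uword j = 0; j < P; ++j) {
      if (i == j) continue;
      double v = (s(i, j) - mu(i)) / sd(i);
      z(i, j) = v > 0 ? v : 0.0;
    }
  }
  S = sqrt(square(z) + square(z.t()));
  S.diag().zeros();
}

// [[Rcpp::export(name = ".pclrcCounts")]]
arma::mat pclrcCounts(const arma::mat& X, const arma::umat& idx,
                      double keepFraction) {
  const uword P = X.n_cols;
  const uword m = idx.n_rows, nIter = idx.n_cols;
  const uword nEdges = P * (P - 1) / 2;
  uword nKeep = static_cast<uword>(std::ceil(keepFraction *
                                             static_cast<double>(nEdges)));
  if (nKeep < 1) nKeep = 1;
  mat counts(P, P, fill::zeros);
  mat sub(m, P), rk(m, P), R(P, P), S(P, P);
  vec ut(nEdges);
  for (uword it = 0; it < nIter; ++it) {
    for (uword r = 0; r < m; ++r) sub.row(r) = X.row(idx(r, it) - 1);
    colRanksAvg(sub, rk);
    corFromRanks(rk, R);
    clrFromCor(R, S);
    uword e = 0;
    for (uword j = 1; j < P; ++j)
      for (uword i = 0; i < j; ++i) ut(e++) = S(i, j);
    vec sorted = sort(ut, "descend");
    const double cut = sorted(nKeep - 1);
    for (uword j = 1; j < P; ++j)
      for (uword i = 0; i < j; ++i)
        if (S(i, j) >= cut) counts(i, j) += 1.0;
  }
  return counts;
}
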