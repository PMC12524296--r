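// PLS1 engines.
//
// Two routes are implemented:
//  - cpp_pls1_fit: plain NIPALS in sample space (exported model fitting).
//  - Gram-matrix cross-validation engines used by the wavelength selectors,
//    which must evaluate thousands of band subsets. For a univariate
//    response, NIPALS needs no inner iteration and the whole extraction can
//    be run on X'X / X'y, so a per-fold Gram matrix is computed once and
//    each subset evaluation touches only a k x k block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// NIPALS PLS1 on centered data; returns everything needed for a model object.
// [[Rcpp::export]]
List cpp_pls1_fit(const arma::mat& X, const arma::vec& y, int ncomp) {
  const int n = X.n_rows, p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;

  mat W(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros), T(n, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros);
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = Xc.t() * yc;
    double wn = norm(w);
    if (wn < 1e-12) break;
    w /= wn;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pl = Xc.t() * t / tt;
    double qa = dot(t, yc) / tt;
    W.col(a) = w; P.col(a) = pl; T.col(a) = t; q(a) = qa;
    Xc -= t * pl.t();
    yc -= qa * t;
    ++used;
  }
  if (used == 0) stop("PLS extraction failed: X'y is numerically zero");
  W = W.cols(0, used - 1); P = P.cols(0, used - 1);
  T = T.cols(0, used - 1); q = q.subvec(0, used - 1);

  // collapsed regression coefficients for every truncation 1..used
  mat B(p, used, fill::zeros);
  mat PtW = P.t() * W; // upper triangular with unit diagonal
  for (int a = 1; a <= used; ++a) {
    vec z = solve(trimatu(PtW.submat(0, 0, a - 1, a - 1)), q.subvec(0, a - 1));
    B.col(a - 1) = W.cols(0, a - 1) * z;
  }
  return List::create(_["weights"] = W, _["loadings"] = P, _["scores"] = T,
                      _["yloadings"] = q, _["coef"] = B,
                      _["xmeans"] = vec(xm.t()), _["ymean"] = ym,
                      _["ncomp"] = used);
}

// Gram-space PLS1 path: accumulate test-set squared errors for LV = 1..A.
// C = Xtr_c' Xtr_c and s = Xtr_c' ytr_c restricted to a band subset;
// Xte is test data centered by the training means (same subset), yte raw.
//
// Uses the Krylov characterization of PLS1: the a-component coefficient
// vector minimizes the training residual over span{s, Cs, ..., C^(a-1)s},
// so the whole path needs only A matvecs with C (Lanczos with full
// reorthogonalization) instead of A rank-one deflations of C.
static void gram_pls_sse(const mat& C, const vec& s, int A, const mat& Xte,
                         const vec& yte, double ymean, vec& sse) {
  const int k = C.n_rows;
  const int m = Xte.n_rows;
  if (A > k) A = k;
  double snorm = norm(s);
  if (snorm < 1e-12) { // no usable signal: intercept-only predictions
    double tail = accu(square(yte - ymean));
    sse += tail;
    return;
  }
  mat V(k, A);
  mat T(A, A, fill::zeros); // projected C, symmetric
  V.col(0) = s / snorm;
  int used = 0;
  for (int a = 0; a < A; ++a) {
    vec u = C * V.col(a);
    for (int b = 0; b <= a; ++b) {
      double c = dot(V.col(b), u);
      T(b, a) = c; T(a, b) = c;
    }
    used = a + 1;
    if (a + 1 < A) {
      u -= V.cols(0, a) * T.col(a).head(a + 1);
      // second orthogonalization pass for numerical safety
      u -= V.cols(0, a) * (V.cols(0, a).t() * u);
      double h = norm(u);
      if (h < 1e-9 * snorm) break; // Krylov space exhausted
      V.col(a + 1) = u / h;
    }
  }
  mat Z = Xte * V.cols(0, used - 1); // m x used test scores basis
  vec g(used, fill::zeros);
  g(0) = snorm; // V' s
  vec pred(m);
  double tail = accu(square(yte - ymean));
  for (int a = 1; a <= A; ++a) {
    int ua = std::min(a, used);
    if (a <= used) {
      vec coef;
      bool ok = solve(coef, T.submat(0, 0, ua - 1, ua - 1),
                      g.head(ua), solve_opts::no_approx);
      if (!ok) { sse(a - 1) += tail; continue; }
      pred = Z.cols(0, ua - 1) * coef + ymean;
      tail = accu(square(yte - pred));
    }
    sse(a - 1) += tail;
  }
}

struct FoldData {
  uvec tr, te;
  rowvec xm;
  double ym;
  mat C;    // p x p Gram of centered training block
  mat S;    // p x 1 cross-covariance
  mat Xte;  // centered test block
  vec yte;
};

static std::vector<FoldData> make_folds(const mat& X, const vec& y,
                                        const ivec& foldid, bool full_gram) {
  int K = foldid.max();
  std::vector<FoldData> out(K);
  for (int f = 1; f <= K; ++f) {
    FoldData fd;
    fd.tr = find(foldid != f);
    fd.te = find(foldid == f);
    mat Xtr = X.rows(fd.tr);
    vec ytr = y(fd.tr);
    fd.xm = mean(Xtr, 0);
    fd.ym = mean(ytr);
    Xtr.each_row() -= fd.xm;
    vec yc = ytr - fd.ym;
    if (full_gram) fd.C = Xtr.t() * Xtr;
    fd.S = Xtr.t() * yc;
    fd.Xte = X.rows(fd.te);
    fd.Xte.each_row() -= fd.xm;
    fd.yte = y(fd.te);
    out[f - 1] = std::move(fd);
  }
  return out;
}

// Pooled K-fold RMSECV for LV = 1..maxlv on the full matrix.
// [[Rcpp::export]]
arma::vec cpp_cv_rmse_path(const arma::mat& X, const arma::vec& y,
                           const arma::ivec& foldid, int maxlv) {
  auto folds = make_folds(X, y, foldid, true);
  vec sse(maxlv, fill::zeros);
  for (auto& fd : folds)
    gram_pls_sse(fd.C, fd.S.col(0), maxlv, fd.Xte, fd.yte, fd.ym, sse);
  return sqrt(sse / X.n_rows);
}

// Minimum-over-LV pooled RMSECV for each band subset (1-based indices).
// [[Rcpp::export]]
List cpp_subsets_cv_rmse(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& foldid, int maxlv,
                         const List& subsets) {
  auto folds = make_folds(X, y, foldid, true);
  int ns = subsets.size();
  vec best(ns);
  ivec bestlv(ns);
  for (int i = 0; i < ns; ++i) {
    uvec S = as<uvec>(subsets[i]) - 1;
    int A = std::min<int>(maxlv, S.n_elem);
    vec sse(A, fill::zeros);
    for (auto& fd : folds)
      gram_pls_sse(fd.C.submat(S, S), fd.S.rows(S), A, fd.Xte.cols(S),
                   fd.yte, fd.ym, sse);
    vec rmse = sqrt(sse / X.n_rows);
    uword a = rmse.index_min();
    best(i) = rmse(a);
    bestlv(i) = a + 1;
  }
  return List::create(_["rmse"] = best, _["best_lv"] = bestlv);
}

// One IRIV round: RMSECV of every row-subset of the binary inclusion matrix
// M (n_rows x p, entries 0/1) and of every single-column flip of every row.
// [[Rcpp::export]]
List cpp_iriv_round(const arma::mat& X, const arma::vec& y,
                    const arma::ivec& foldid, int maxlv,
                    const arma::imat& M) {
  auto folds = make_folds(X, y, foldid, true);
  const int nr = M.n_rows, p = M.n_cols;
  vec rmse0(nr);
  mat rflip(nr, p);
  const double n = X.n_rows;

  auto eval = [&](const uvec& S) -> double {
    int A = std::min<int>(maxlv, S.n_elem);
    if (A == 0) { // empty subset: intercept-only model
      double sse = 0;
      for (auto& fd : folds) sse += accu(square(fd.yte - fd.ym));
      return std::sqrt(sse / n);
    }
    vec sse(A, fill::zeros);
    for (auto& fd : folds)
      gram_pls_sse(fd.C.submat(S, S), fd.S.rows(S), A, fd.Xte.cols(S),
                   fd.yte, fd.ym, sse);
    return sqrt(sse / n).min();
  };

  for (int r = 0; r < nr; ++r) {
    irowvec row = M.row(r);
    uvec S = find(conv_to<ivec>::from(row.t()) == 1);
    rmse0(r) = eval(S);
    for (int j = 0; j < p; ++j) {
      irowvec rr = row;
      rr(j) = 1 - rr(j);
      uvec Sj = find(conv_to<ivec>::from(rr.t()) == 1);
      rflip(r, j) = eval(Sj);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["rmse0"] = rmse0, _["rmse_flip"] = rflip);
}
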