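// Penalized alternating least squares for sparse common/distinctive SCA.
//
// Criterion: ||X - X W P'||_F^2 + sum_q lam1_q ||w_q||_1 + lam2 ||W||_F^2
// with P'P = I and W zero outside a binary constraint mask. Only X'X (and
// ||X||^2) are needed: the Frobenius term expands to
//   ||X||^2 - 2 tr(P' X'X W) + tr(W' X'X W).
//
// The W update is coordinate descent: with all other weights fixed, the
// exact univariate minimizer for a free cell (j,q) is
//   w_jq = S(r_jq, lam1_q / 2) / ((X'X)_jj + lam2),
//   r_jq = (X'X P)_jq - sum_{j' != j} (X'X)_{jj'} w_{j'q},
// S the soft-threshold. Masked cells are never touched. The P update is
// the reduced-rank Procrustes solution P = U V' from svd(X'X W).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double a, double t) {
  if (a > t) return a - t;
  if (a < -t) return a + t;
  return 0.0;
}

// One full sweep, components in order, variables in natural order within
// each component. R = XtX * W is maintained incrementally. W and R are
// modified in place.
static void sweep_inplace(const mat& XtX, const mat& XtXP, mat& W, mat& R,
                          const mat& mask, const vec& lam1, double lam2) {
  const uword J = W.n_rows, Q = W.n_cols;
  for (uword q = 0; q < Q; ++q) {
    const double thr = lam1(q) / 2.0;
    for (uword j = 0; j < J; ++j) {
      if (mask(j, q) == 0.0) continue;
      const double d = XtX(j, j);
      const double wold = W(j, q);
      const double r = XtXP(j, q) - (R(j, q) - d * wold);
      const double denom = d + lam2;
      const double wnew = (denom > 0.0) ? soft(r, thr) / denom : 0.0;
      if (wnew != wold) {
        R.col(q) += XtX.col(j) * (wnew - wold);
        W(j, q) = wnew;
      }
    }
  }
}

static double objective_val(double ssqX, const mat& W, const mat& P,
                            const mat& R, const vec& lam1, double lam2) {
  double obj = ssqX - 2.0 * accu(P % R) + accu(W % R) + lam2 * accu(W % W);
  for (uword q = 0; q < W.n_cols; ++q)
    obj += lam1(q) * accu(abs(W.col(q)));
  return obj;
}

// [[Rcpp::export(name = ".cd_sweep_cpp")]]
arma::mat cd_sweep_cpp(const arma::mat& XtX, const arma::mat& XtXP,
                       arma::mat W, const arma::mat& mask,
                       const arma::vec& lam1, double lam2) {
  mat R = XtX * W;
  sweep_inplace(XtX, XtXP, W, R, mask, lam1, lam2);
  return W;
}

// [[Rcpp::export(name = ".scads_cd_fit_cpp")]]
Rcpp::List scads_cd_fit_cpp(const arma::mat& XtX, double ssqX,
                            arma::mat W, const arma::mat& mask,
                            const arma::vec& lam1, double lam2,
                            double tol, int max_iter) {
  const uword Q = W.n_cols;
  std::vector<double> trace;
  trace.reserve(2 * max_iter + 2);

  mat P(W.n_rows, Q, fill::zeros);
  bool converged = false;
  int iter = 0;
  double prev = datum::inf;

  for (iter = 1; iter <= max_iter; ++iter) {
    mat R = XtX * W;
    if (norm(W, "fro") == 0.0) {  // empty model: loadings undefined, loss fixed
      if (P.n_elem == 0 || accu(abs(P)) == 0.0) P.eye(W.n_rows, Q);
      converged = true;
      double obj = objective_val(ssqX, W, P, R, lam1, lam2);
      trace.push_back(obj);
      break;
    }
    mat U, V; vec s;
    svd_econ(U, s, V, R);
    P = U.cols(0, Q - 1) * V.t();
    trace.push_back(objective_val(ssqX, W, P, R, lam1, lam2));

    mat XtXP = XtX * P;
    sweep_inplace(XtX, XtXP, W, R, mask, lam1, lam2);
    double obj = objective_val(ssqX, W, P, R, lam1, lam2);
    trace.push_back(obj);

    if (std::isfinite(prev)) {
      double denom = std::max(std::abs(prev), 1e-300);
      if ((prev - obj) / denom < tol) { converged = true; break; }
    }
    prev = obj;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("P") = P,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iter);
}

// Exact alternating fit for lam1 = 0. The weights update per component is
// (ridge) least squares X_S w ~ X p_q on the component's support S, solved
// through the I x I dual system X_S X_S' + lam2 I with factorizations
// cached per distinct support; with lam2 = 0 the minimum-norm solution via
// the pseudo-inverse is used. Exact conditional minimizers keep the loss
// monotone. Objectives are evaluated in I x Q space:
// tr(P'X'XW) = accu((XP) % (XW)), tr(W'X'XW) = ||XW||^2.
// [[Rcpp::export(name = ".scads_exact_fit_cpp")]]
Rcpp::List scads_exact_fit_cpp(const arma::mat& X, double ssqX,
                               arma::mat W, const arma::mat& mask,
                               double lambda2, double tol, int max_iter) {
  const uword J = X.n_cols, Q = W.n_cols;

  // distinct supports
  std::vector<uvec> supports;
  std::vector<uword> sup_of(Q);
  for (uword q = 0; q < Q; ++q) {
    uvec S = find(mask.col(q) != 0.0);
    uword hit = supports.size();
    for (uword k = 0; k < supports.size(); ++k)
      if (supports[k].n_elem == S.n_elem &&
          all(supports[k] == S)) { hit = k; break; }
    if (hit == supports.size()) supports.push_back(S);
    sup_of[q] = hit;
  }
  // factorizations per support
  std::vector<mat> cholG(supports.size());   // lambda2 > 0
  std::vector<mat> pinvS(supports.size());   // lambda2 == 0
  for (uword k = 0; k < supports.size(); ++k) {
    mat XS = X.cols(supports[k]);
    if (lambda2 > 0.0) {
      mat G = XS * XS.t();
      G.diag() += lambda2;
      cholG[k] = chol(G);
    } else {
      pinvS[k] = pinv(XS);
    }
  }

  std::vector<double> trace;
  trace.reserve(2 * max_iter + 2);
  mat P(J, Q, fill::zeros);
  bool converged = false;
  double prev = datum::inf;
  int iter = 0;

  mat XW = X * W;
  for (iter = 1; iter <= max_iter; ++iter) {
    if (norm(W, "fro") == 0.0) {
      if (accu(abs(P)) == 0.0) P.eye(J, Q);
      trace.push_back(ssqX);
      converged = true;
      break;
    }
    mat M = X.t() * XW;
    mat U, V; vec s;
    svd_econ(U, s, V, M);
    P = U.cols(0, Q - 1) * V.t();
    trace.push_back(ssqX - 2.0 * accu(P % M) + accu(square(XW)) +
                    lambda2 * accu(square(W)));

    mat C = X * P;
    for (uword q = 0; q < Q; ++q) {
      const uvec& S = supports[sup_of[q]];
      vec w;
      if (lambda2 > 0.0) {
        vec y = solve(trimatu(cholG[sup_of[q]]),
                      solve(trimatl(cholG[sup_of[q]].t()), C.col(q)));
        w = X.cols(S).t() * y;
      } else {
        w = pinvS[sup_of[q]] * C.col(q);
      }
      W.col(q).zeros();
      W.elem(S + q * J) = w;
    }
    XW = X * W;
    double obj = ssqX - 2.0 * accu(C % XW) + accu(square(XW)) +
                 lambda2 * accu(square(W));
    trace.push_back(obj);

    if (std::isfinite(prev)) {
      double denom = std::max(std::abs(prev), 1e-300);
      if ((prev - obj) / denom < tol) { converged = true; break; }
    }
    prev = obj;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("P") = P,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iter);
}
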