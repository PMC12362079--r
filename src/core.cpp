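// Compiled numerical core: ridge-penalized logistic regression (IRLS,
// primal for n >= p, dual/kernel form for p > n), the per-timepoint
// cross-validated decoding loop, and the sign-flip permutation null for
// the cluster tests. These run ~10^5-10^6 times in the recovery and
// calibration simulations, hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigmoid(const vec& eta) {
  return 1.0 / (1.0 + exp(-clamp(eta, -35.0, 35.0)));
}

// Primal IRLS for: sum_i log(1 + exp(-s_i (x_i'w + b))) + lambda/2 ||w||^2
// (intercept unpenalized). y in {0,1}. Returns (w, b).
static vec ridge_logit_primal(const mat& X, const vec& y, double lambda,
                              int max_iter = 30, double tol = 1e-9) {
  const uword n = X.n_rows, p = X.n_cols;
  mat Z(n, p + 1);
  Z.cols(0, p - 1) = X;
  Z.col(p).ones();
  vec beta(p + 1, fill::zeros);
  vec pen(p + 1, fill::value(lambda));
  pen(p) = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    vec eta = Z * beta;
    vec mu = sigmoid(eta);
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-9, 0.25);
    vec grad = Z.t() * (mu - y) + pen % beta;
    mat H = Z.t() * (Z.each_col() % w);
    H.diag() += pen;
    vec step;
    if (!solve(step, H, grad, solve_opts::likely_sympd)) break;
    beta -= step;
    if (norm(step, 2) < tol * (1.0 + norm(beta, 2))) break;
  }
  return beta;
}

// Dual (kernel) IRLS for p > n, no intercept, columns of X assumed
// centered. Solves for alpha with w = X' alpha via Newton steps in the
// n-dimensional space: (W K + lambda I) d = (mu - y + lambda a).
static vec ridge_logit_dual_alpha(const mat& K, const vec& y, double lambda,
                                  int max_iter = 30, double tol = 1e-9) {
  const uword n = K.n_rows;
  vec a(n, fill::zeros);
  for (int it = 0; it < max_iter; ++it) {
    vec f = K * a;
    vec mu = sigmoid(f);
    vec w = clamp(mu % (1.0 - mu), 1e-9, 0.25);
    vec rhs = (mu - y) + lambda * a;
    mat M = K.each_col() % w;
    M.diag() += lambda;
    vec step;
    if (!solve(step, M, rhs)) break;
    a -= step;
    if (norm(step, 2) < tol * (1.0 + norm(a, 2))) break;
  }
  return a;
}

// [[Rcpp::export(name = ".ridge_logit_fit")]]
Rcpp::List ridge_logit_fit(const arma::mat& X, const arma::vec& y,
                           double lambda) {
  vec beta = ridge_logit_primal(X, y, lambda);
  const uword p = X.n_cols;
  return Rcpp::List::create(
    Rcpp::Named("w") = beta.subvec(0, p - 1),
    Rcpp::Named("b") = beta(p));
}

// Standardize train columns; apply the same transform to test. Zero-variance
// features are left centered (divisor 1).
static void standardize_cols(mat& Xtr, mat& Xte) {
  rowvec m = mean(Xtr, 0);
  rowvec s = stddev(Xtr, 0, 0);
  s.elem(find(s < 1e-12)).ones();
  Xtr.each_row() -= m;  Xtr.each_row() /= s;
  Xte.each_row() -= m;  Xte.each_row() /= s;
}

// Per-timepoint stratified-CV decoding.
// data: cube [trials x channels x times]; y in {0,1}; fold: 1-based fold id
// per trial; global_standardize replicates standardization across all
// epochs before CV (leaks test statistics; provided for replication).
// Returns fold-mean test accuracy per timepoint.
// [[Rcpp::export(name = ".decode_timecourse_core")]]
arma::vec decode_timecourse_core(const arma::cube& data, const arma::vec& y,
                                 const arma::ivec& fold, double lambda,
                                 bool global_standardize) {
  const uword n_times = data.n_slices;
  const int k = fold.max();
  vec acc(n_times, fill::zeros);
  for (uword t = 0; t < n_times; ++t) {
    mat Xt = data.slice(t);  // trials x channels
    if (global_standardize) {
      rowvec m = mean(Xt, 0);
      rowvec s = stddev(Xt, 0, 0);
      s.elem(find(s < 1e-12)).ones();
      Xt.each_row() -= m;
      Xt.each_row() /= s;
    }
    double fold_acc_sum = 0.0;
    for (int f = 1; f <= k; ++f) {
      uvec te = find(fold == f);
      uvec tr = find(fold != f);
      mat Xtr = Xt.rows(tr), Xte = Xt.rows(te);
      if (!global_standardize) standardize_cols(Xtr, Xte);
      vec beta = ridge_logit_primal(Xtr, y.elem(tr), lambda);
      vec eta = Xte * beta.subvec(0, Xte.n_cols - 1) + beta(Xte.n_cols);
      vec pred = conv_to<vec>::from(eta > 0);
      fold_acc_sum += mean(conv_to<vec>::from(pred == y.elem(te)));
    }
    acc(t) = fold_acc_sum / k;
  }
  return acc;
}

// Cross-validated accuracy of a ridge-logistic decoder on flattened trials
// (dual form when p > n). Columns are centered on training means only.
// [[Rcpp::export(name = ".flat_cv_accuracy_core")]]
double flat_cv_accuracy_core(const arma::mat& X, const arma::vec& y,
                             const arma::ivec& fold, double lambda) {
  const int k = fold.max();
  double fold_acc_sum = 0.0;
  for (int f = 1; f <= k; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    rowvec m = mean(Xtr, 0);
    Xtr.each_row() -= m;
    Xte.each_row() -= m;
    vec pred;
    if (Xtr.n_cols > Xtr.n_rows) {
      mat K = Xtr * Xtr.t();
      vec a = ridge_logit_dual_alpha(K, y.elem(tr), lambda);
      vec eta = Xte * (Xtr.t() * a);
      pred = conv_to<vec>::from(eta > 0);
    } else {
      vec beta = ridge_logit_primal(Xtr, y.elem(tr), lambda);
      vec eta = Xte * beta.subvec(0, Xte.n_cols - 1) + beta(Xte.n_cols);
      pred = conv_to<vec>::from(eta > 0);
    }
    fold_acc_sum += mean(conv_to<vec>::from(pred == y.elem(te)));
  }
  return fold_acc_sum / k;
}

// Shuffled-label CV accuracies for the flat linear decoder. The fold
// geometry and hence the centered Gram matrices do not depend on the
// labels, so they are computed once and reused across all label rows
// (row 0 of Y is the observed labeling, the rest are shuffles).
// [[Rcpp::export(name = ".flat_cv_perm_core")]]
arma::vec flat_cv_perm_core(const arma::mat& X, const arma::imat& Y,
                            const arma::ivec& fold, double lambda) {
  const int k = fold.max();
  const uword n_rows = Y.n_rows;
  const bool dual = X.n_cols > X.n_rows;
  std::vector<mat> Ktr(k), Cte(k), Xtr_s(k), Xte_s(k);
  std::vector<uvec> tr_idx(k), te_idx(k);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    rowvec m = mean(Xtr, 0);
    Xtr.each_row() -= m;
    Xte.each_row() -= m;
    if (dual) {
      Ktr[f - 1] = Xtr * Xtr.t();
      Cte[f - 1] = Xte * Xtr.t();
    } else {
      Xtr_s[f - 1] = Xtr;
      Xte_s[f - 1] = Xte;
    }
    tr_idx[f - 1] = tr;
    te_idx[f - 1] = te;
  }
  vec out(n_rows);
  for (uword r = 0; r < n_rows; ++r) {
    vec y = conv_to<vec>::from(Y.row(r).t());
    double fold_acc_sum = 0.0;
    for (int f = 0; f < k; ++f) {
      vec ytr = y.elem(tr_idx[f]);
      vec yte = y.elem(te_idx[f]);
      vec eta;
      if (dual) {
        vec a = ridge_logit_dual_alpha(Ktr[f], ytr, lambda);
        eta = Cte[f] * a;
      } else {
        vec beta = ridge_logit_primal(Xtr_s[f], ytr, lambda);
        eta = Xte_s[f] * beta.subvec(0, Xte_s[f].n_cols - 1) +
          beta(Xte_s[f].n_cols);
      }
      vec pred = conv_to<vec>::from(eta > 0);
      fold_acc_sum += mean(conv_to<vec>::from(pred == yte));
    }
    out(r) = fold_acc_sum / k;
  }
  return out;
}

// Sign-flip permutation null for the cluster tests.
// A: subjects x times matrix of (accuracy - chance); signs: n_perm x
// n_subjects of +/-1. For each permutation the group statistic is the
// subject mean of the flipped series; clusters are maximal runs strictly
// above `threshold`. Returns the max cluster mass per permutation and the
// head/tail depth-indexed maxima (n_perm x n_times; depth d column holds
// the largest statistic observed at depth d+1 into any cluster).
// [[Rcpp::export(name = ".cluster_perm_null_core")]]
Rcpp::List cluster_perm_null_core(const arma::mat& A, const arma::mat& signs,
                                  double threshold, bool want_depth) {
  const uword n_perm = signs.n_rows;
  const uword n_sub = A.n_rows;
  const uword n_times = A.n_cols;
  vec max_mass(n_perm, fill::zeros);
  mat Dh, Dt;
  if (want_depth) {
    Dh.zeros(n_perm, n_times);
    Dt.zeros(n_perm, n_times);
  }
  mat S = (signs * A) / double(n_sub);  // n_perm x n_times group statistics
  for (uword pm = 0; pm < n_perm; ++pm) {
    double best = 0.0;
    uword t = 0;
    while (t < n_times) {
      if (S(pm, t) > threshold) {
        uword start = t;
        double mass = 0.0;
        while (t < n_times && S(pm, t) > threshold) {
          mass += S(pm, t);
          ++t;
        }
        uword len = t - start;
        if (mass > best) best = mass;
        if (want_depth) {
          for (uword j = 0; j < len; ++j) {
            double v = S(pm, start + j);
            if (v > Dh(pm, j)) Dh(pm, j) = v;
            double vt = S(pm, t - 1 - j);
            if (vt > Dt(pm, j)) Dt(pm, j) = vt;
          }
        }
      } else {
        ++t;
      }
    }
    max_mass(pm) = best;
  }
  if (want_depth) {
    return Rcpp::List::create(
      Rcpp::Named("max_mass") = max_mass,
      Rcpp::Named("depth_head") = Dh,
      Rcpp::Named("depth_tail") = Dt);
  }
  return Rcpp::List::create(Rcpp::Named("max_mass") = max_mass);
}
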