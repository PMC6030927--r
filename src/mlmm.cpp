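// Marginal-likelihood machinery for the multivariate linear mixed model with
// correlated random intercepts (one intercept per marker), and the pairwise
// concordance index used by the validation module.
//
// The model for patient i: y_i = X_i beta + Z_i b_i + e_i, with
// b_i ~ MVN(0, G) (K x K, one random intercept per marker), e_i diagonal
// with residual variance sigma2[marker(row)].  Z_i is the 0/1 matrix mapping
// the K intercepts to rows by marker, so V_i = Z_i G Z_i' + R_i has entries
// V[r,c] = G[m_r, m_c] + (r == c) * sigma2[m_r].
//
// beta is profiled out by GLS, so the objective passed to the optimizer is a
// function of (L, log sigma2) only, where G = L L'.  The gradient uses the
// envelope theorem: at beta = beta_hat(theta) the derivative of the profile
// deviance w.r.t. a variance parameter needs only
//   d(-l)/dG    = 0.5 * sum_i (A_i - u_i u_i')          (then chain onto L)
//   d(-l)/ds2_k = 0.5 * (tr_k(Vinv) - sum_k (Vinv r)^2)
// with A_i = Z_i' Vinv_i Z_i (K x K) and u_i = Z_i' Vinv_i r_i.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Build V_i for one patient block given marker indices (0-based).
static arma::mat build_V(const arma::uvec& m, const arma::mat& G,
                         const arma::vec& sigma2) {
  const arma::uword ni = m.n_elem;
  arma::mat V(ni, ni);
  for (arma::uword r = 0; r < ni; ++r) {
    for (arma::uword c = 0; c <= r; ++c) {
      double v = G(m[r], m[c]);
      V(r, c) = v;
      V(c, r) = v;
    }
    V(r, r) += sigma2[m[r]];
  }
  return V;
}

// [[Rcpp::export]]
List mlmm_nll_cpp(const arma::vec& y, const arma::mat& X,
                  const arma::uvec& marker, const arma::uvec& pstart,
                  const arma::mat& L, const arma::vec& sigma2,
                  const bool want_grad, const bool reml) {
  const arma::uword K = L.n_rows;
  const arma::uword p = X.n_cols;
  const arma::uword npat = pstart.n_elem - 1;
  const arma::uword N = y.n_elem;

  arma::mat G = L * L.t();

  double logdet = 0.0, ytVy = 0.0;
  arma::mat XtVX(p, p, arma::fill::zeros);
  arma::vec XtVy(p, arma::fill::zeros);
  std::vector<arma::mat> Vinv_store;
  if (want_grad) Vinv_store.resize(npat);

  for (arma::uword i = 0; i < npat; ++i) {
    const arma::uword a = pstart[i], b = pstart[i + 1];
    if (b <= a) continue;
    arma::uvec rows = arma::regspace<arma::uvec>(a, b - 1);
    arma::uvec m = marker.elem(rows);
    arma::mat V = build_V(m, G, sigma2);
    arma::mat C;
    if (!arma::chol(C, V, "lower")) {
      return List::create(_["nll"] = R_PosInf, _["ok"] = false);
    }
    logdet += 2.0 * arma::accu(arma::log(C.diag()));
    arma::mat Ci = arma::inv(arma::trimatl(C));
    arma::mat Vinv = Ci.t() * Ci;
    if (want_grad) Vinv_store[i] = Vinv;
    arma::mat Xi = X.rows(rows);
    arma::vec yi = y.elem(rows);
    arma::mat VX = Vinv * Xi;
    XtVX += Xi.t() * VX;
    XtVy += VX.t() * yi;
    ytVy += arma::as_scalar(yi.t() * Vinv * yi);
  }

  arma::vec beta;
  if (!arma::solve(beta, XtVX, XtVy,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
    return List::create(_["nll"] = R_PosInf, _["ok"] = false);
  }
  double quad = ytVy - arma::dot(beta, XtVy);
  double nll = 0.5 * (logdet + quad + (double)N * LOG2PI);
  if (reml) {
    double ldX, sgn;
    arma::log_det(ldX, sgn, XtVX);
    nll += 0.5 * ldX - 0.5 * (double)p * LOG2PI;
  }

  List out = List::create(_["nll"] = nll, _["beta"] = beta,
                          _["XtVX"] = XtVX, _["ok"] = true);
  if (!want_grad) return out;

  // gradient pass (ML objective; REML uses numeric differentiation upstream)
  arma::mat S1(K, K, arma::fill::zeros);
  arma::vec tr_k(K, arma::fill::zeros), qd_k(K, arma::fill::zeros);
  for (arma::uword i = 0; i < npat; ++i) {
    const arma::uword a = pstart[i], b = pstart[i + 1];
    if (b <= a) continue;
    arma::uvec rows = arma::regspace<arma::uvec>(a, b - 1);
    arma::uvec m = marker.elem(rows);
    const arma::mat& Vinv = Vinv_store[i];
    arma::vec r = y.elem(rows) - X.rows(rows) * beta;
    arma::vec w = Vinv * r;
    arma::vec u(K, arma::fill::zeros);
    arma::mat A(K, K, arma::fill::zeros);
    const arma::uword ni = m.n_elem;
    for (arma::uword rr = 0; rr < ni; ++rr) {
      u[m[rr]] += w[rr];
      tr_k[m[rr]] += Vinv(rr, rr);
      qd_k[m[rr]] += w[rr] * w[rr];
      for (arma::uword cc = 0; cc < ni; ++cc) A(m[rr], m[cc]) += Vinv(rr, cc);
    }
    S1 += A - u * u.t();
  }
  arma::mat grad_L = S1 * L;                 // d(-l)/dL (lower triangle used)
  arma::vec grad_s2 = 0.5 * (tr_k - qd_k);   // d(-l)/d sigma2_k
  out["grad_L"] = grad_L;
  out["grad_sigma2"] = grad_s2;
  return out;
}

// Batch empirical-Bayes BLUP of the random intercepts:
// bhat_i = G Z_i' V_i^{-1} (y_i - X_i beta).  Returns an npat x K matrix;
// rows with no observations are zero (the prior mean).
// [[Rcpp::export]]
arma::mat mlmm_blup_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::uvec& marker, const arma::uvec& pstart,
                        const arma::mat& G, const arma::vec& sigma2,
                        const arma::vec& beta) {
  const arma::uword K = G.n_rows;
  const arma::uword npat = pstart.n_elem - 1;
  arma::mat bhat(npat, K, arma::fill::zeros);
  for (arma::uword i = 0; i < npat; ++i) {
    const arma::uword a = pstart[i], b = pstart[i + 1];
    if (b <= a) continue;
    arma::uvec rows = arma::regspace<arma::uvec>(a, b - 1);
    arma::uvec m = marker.elem(rows);
    arma::mat V = build_V(m, G, sigma2);
    arma::vec r = y.elem(rows) - X.rows(rows) * beta;
    arma::vec w = arma::solve(V, r, arma::solve_opts::likely_sympd);
    arma::vec u(K, arma::fill::zeros);
    for (arma::uword rr = 0; rr < m.n_elem; ++rr) u[m[rr]] += w[rr];
    bhat.row(i) = (G * u).t();
  }
  return bhat;
}

// Harrell concordance over pairs of rows, with landmark-stacking rules:
// pairs sharing a patient id are never compared, and when groups are
// supplied (age-adjusted mode) only within-group pairs count.  A pair is
// comparable when the smaller time is an event time and the ordering is
// determinable; equal event times are not orderable.  Score ties add 1/2.
// [[Rcpp::export]]
List cindex_pairs_cpp(const arma::vec& score, const arma::vec& time,
                      const arma::ivec& event, const arma::ivec& id,
                      const arma::ivec& group, const bool use_id,
                      const bool use_group) {
  const arma::uword n = score.n_elem;
  double conc = 0.0;
  double ncomp = 0.0;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      if (use_id && id[i] == id[j]) continue;
      if (use_group && group[i] != group[j]) continue;
      int cas = -1, oth = -1;
      if (time[i] < time[j]) {
        if (event[i] == 1) { cas = i; oth = j; }
      } else if (time[j] < time[i]) {
        if (event[j] == 1) { cas = j; oth = i; }
      } else {  // tied times: orderable only when exactly one is an event
        if (event[i] == 1 && event[j] == 0) { cas = i; oth = j; }
        else if (event[j] == 1 && event[i] == 0) { cas = j; oth = i; }
      }
      if (cas < 0) continue;
      ncomp += 1.0;
      if (score[cas] > score[oth]) conc += 1.0;
      else if (score[cas] == score[oth]) conc += 0.5;
    }
  }
  return List::create(_["concordant"] = conc, _["comparable"] = ncomp);
}
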