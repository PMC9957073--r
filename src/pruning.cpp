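// Post-order pruning likelihood for a dense rate matrix on a rooted tree.
//
// The transition matrix exp(Q t) is applied to conditional-likelihood
// vectors through an eigendecomposition of Q computed once per call
// (cheap: per branch cost is O(K^2) instead of O(K^3)).  When the
// eigenbasis is ill-conditioned or Q is defective the code falls back to
// a Pade matrix exponential per unique branch length.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

// root_type: 0 = weighted_by_partials (FitzJohn), 1 = flat,
//            2 = fixed at state root_state (0-based row index)
// dgr: the (delta, gamma, rho) rates behind Q -- used to pick the
// symmetrized path for the pure fusion/fission chain.
// edge must be in postorder (every child row before its parent's row),
// 1-based ape node ids: tips 1..n_tip, root n_tip + 1.
// [[Rcpp::export]]
double prune_loglik_cpp(const arma::mat& Q,
                        const arma::vec& dgr,
                        const arma::imat& edge,
                        const arma::vec& elen,
                        const int n_tip,
                        const int n_node,
                        const arma::mat& tip_partials,
                        const int root_type,
                        const int root_state) {
  const int K = Q.n_rows;
  const int E = edge.n_rows;

  // With rho = 0 the generator is a birth-death chain: D^{1/2} Q D^{-1/2}
  // is symmetric for D = diag((gamma/delta)^i), so a symmetric
  // eigendecomposition is available and stable for any positive rates
  // (the general eigenbasis degenerates when gamma/delta is far from 1).
  bool sym_path = false;
  vec sym_lam, svec;
  mat U;
  if (K > 1 && dgr(2) == 0.0 && dgr(0) > 0.0 && dgr(1) > 0.0) {
    const double lr = std::log(dgr(1) / dgr(0));
    if (std::abs(lr) * 0.5 * (K - 1) < 500.0) {
      svec.set_size(K);
      for (int i = 0; i < K; ++i) svec(i) = std::exp(0.5 * lr * i);
      mat S = Q;
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j) S(i, j) *= svec(i) / svec(j);
      S = 0.5 * (S + S.t());
      sym_path = eig_sym(sym_lam, U, S);
    }
  }

  cx_vec eval;
  cx_mat evec, evec_inv;
  bool use_eigen = false;
  bool real_path = false;
  vec evalr;
  mat evr, evr_inv;
  if (!sym_path) {
    use_eigen = eig_gen(eval, evec, Q);
    if (use_eigen) use_eigen = inv(evec_inv, evec);
    if (use_eigen) {
      mat recon = real(evec * diagmat(eval) * evec_inv);
      double qn = norm(Q, "fro");
      if (qn < 1e-300) qn = 1.0;
      if (norm(recon - Q, "fro") / qn > 1e-9) use_eigen = false;
    }
    // all-real spectrum: 4x cheaper than the complex path
    if (use_eigen &&
        norm(imag(eval), "inf") < 1e-12 * (1.0 + norm(real(eval), "inf")) &&
        norm(imag(evec), "inf") < 1e-9) {
      real_path = true;
      evalr = real(eval);
      evr = real(evec);
      evr_inv = real(evec_inv);
    }
  }

  std::map<double, mat> pcache;  // fallback: exp(Q t) per unique t

  mat partial(K, n_tip + n_node, fill::ones);
  partial.cols(0, n_tip - 1) = tip_partials;
  double logscale = 0.0;

  for (int i = 0; i < E; ++i) {
    const int parent = edge(i, 0) - 1;
    const int child = edge(i, 1) - 1;
    const double t = elen(i);
    vec x = partial.col(child);
    vec y(K);
    bool need_pade = false;
    if (t == 0.0) {
      y = x;
    } else if (sym_path) {
      vec sx = svec % x;
      const double big = sx.max();
      vec w = U.t() * sx;
      w %= exp(sym_lam * t);
      y = (U * w) / svec;
      // entries below the round-off noise floor of the scaled transform
      // (noise ~ eps * max(s x) amplified by 1/s_i) are unreliable
      const double noise = 64.0 * K * datum::eps * big;
      for (int ii = 0; ii < K; ++ii)
        if (!(y(ii) > noise / svec(ii))) y(ii) = 0.0;
      // a stochastic propagation of partials scaled to max 1 cannot
      // exceed 1; if it does the transform lost precision entirely
      if (y.max() > 1.0 + 1e-8) need_pade = true;
    } else if (real_path) {
      vec w = evr_inv * x;
      w %= exp(evalr * t);
      y = evr * w;
    } else if (use_eigen) {
      cx_vec w = evec_inv * conv_to<cx_vec>::from(x);
      w %= exp(eval * t);
      y = real(evec * w);
    } else {
      need_pade = true;
    }
    if (need_pade) {
      std::map<double, mat>::iterator it = pcache.find(t);
      if (it == pcache.end()) it = pcache.insert(std::make_pair(t, expmat(Q * t))).first;
      y = it->second * x;
    }
    y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    const double m = y.max();
    // partials enter scaled to max 1; a conditional factor at or below the
    // round-off noise floor of the propagation means the data are
    // (numerically) impossible under these parameters
    if (!(m > 1e-12)) return R_NegInf;
    y /= m;
    logscale += std::log(m);
    partial.col(parent) %= y;
  }

  const vec r = partial.col(n_tip);  // root node, 0-based index n_tip
  const double s = accu(r);
  if (!(s > 0.0)) return R_NegInf;
  double ll;
  if (root_type == 0) {
    ll = std::log(accu(r % r) / s);
  } else if (root_type == 1) {
    ll = std::log(s / static_cast<double>(K));
  } else {
    if (!(r(root_state) > 0.0)) return R_NegInf;
    ll = std::log(r(root_state));
  }
  return ll + logscale;
}
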