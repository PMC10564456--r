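// Blocked Gibbs sampler for the multivariate mixed model
//   y_i = B' x_i + u_line(i) + v_block(i) + e_i
// with u ~ N(0, Su), v ~ N(0, Sv), e ~ N(0, Se) and conditionally
// conjugate inverse-Wishart updates for the three covariance components.
// All randomness goes through R's RNG so set.seed() in R governs the draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rnorm_mat(int r, int c) {
  mat M(r, c);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i)
      M(i, j) = norm_rand();
  return M;
}

static mat safe_inv(const mat& S) {
  mat R;
  if (inv_sympd(R, S)) return R;
  mat S2 = S + eye(S.n_rows, S.n_cols) * (1e-10 * (1.0 + trace(S)));
  if (inv_sympd(R, S2)) return R;
  return pinv(S);
}

static mat chol_lower_safe(const mat& S) {
  mat L;
  if (chol(L, S, "lower")) return L;
  mat S2 = S + eye(S.n_rows, S.n_cols) * (1e-10 * (1.0 + trace(S)));
  if (chol(L, S2, "lower")) return L;
  // last resort: eigen square root (lower-triangular property lost but
  // still a valid covariance factor)
  vec ev; mat V;
  eig_sym(ev, V, (S + S.t()) / 2.0);
  ev.for_each([](double& x) { x = x > 0 ? std::sqrt(x) : 0.0; });
  return V * diagmat(ev);
}

// Eigenvalue floor keeping covariance draws away from numerical
// singularity: the improper flat prior puts real mass near zero variance
// for weakly identified components, and an unfloored chain underflows
// into an absorbing state there.
static mat floor_psd(const mat& S, double rel = 1e-6) {
  vec ev; mat V;
  eig_sym(ev, V, (S + S.t()) / 2.0);
  double flr = std::max(rel * mean(ev), 1e-12);
  ev.for_each([flr](double& x) { if (x < flr) x = flr; });
  mat R = V * diagmat(ev) * V.t();
  return (R + R.t()) / 2.0;
}

// Sigma ~ InvWishart(scale, df) via the Bartlett decomposition of the
// Wishart draw of Sigma^{-1} ~ W(scale^{-1}, df).
static mat rinvwishart(double df, const mat& scale) {
  const int t = scale.n_rows;
  mat Ls = chol_lower_safe(safe_inv(floor_psd(scale)));
  mat A(t, t, fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  mat LA = Ls * A;
  mat W = LA * LA.t();
  return floor_psd(safe_inv(W));
}

// [[Rcpp::export]]
Rcpp::List gibbs_mvlmm_cpp(const arma::mat& Y, const arma::mat& X,
                           const arma::uvec& line, const arma::uvec& block,
                           int n_iter, int burn_in, int thin,
                           double prior_nu, const arma::mat& prior_V,
                           bool flat) {
  const int n = Y.n_rows, t = Y.n_cols, p = X.n_cols;
  const int nl = line.max() + 1, nb = block.max() + 1;
  const int n_keep = (n_iter - burn_in) / thin;

  mat XtXinv = safe_inv(X.t() * X);
  mat Lx = chol_lower_safe(XtXinv);
  mat XtXinvXt = XtXinv * X.t();

  std::vector<uvec> line_rows(nl), block_rows(nb);
  for (int l = 0; l < nl; ++l) line_rows[l] = find(line == (unsigned) l);
  for (int b = 0; b < nb; ++b) block_rows[b] = find(block == (unsigned) b);

  mat V0 = flat ? mat(t, t, fill::zeros) : prior_V;
  double nu0 = flat ? 0.0 : prior_nu;

  // initial values
  mat B = XtXinvXt * Y;
  mat E0 = Y - X * B;
  mat Se = (E0.t() * E0) / std::max(n - p, 1);
  Se = (Se + Se.t()) / 2.0;
  mat Su = Se * 0.5, Sv = Se * 0.1;
  mat U = rnorm_mat(nl, t) * chol_lower_safe(Su).t();
  mat V = rnorm_mat(nb, t) * chol_lower_safe(Sv).t();

  cube keep_G(t, t, n_keep), keep_Sv(t, t, n_keep), keep_Se(t, t, n_keep);
  mat keep_B_mean(p, t, fill::zeros);
  int k = 0;

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects | rest
    mat R1 = Y;
    for (int i = 0; i < n; ++i) R1.row(i) -= U.row(line(i)) + V.row(block(i));
    mat Bhat = XtXinvXt * R1;
    mat Le = chol_lower_safe(Se);
    B = Bhat + Lx * rnorm_mat(p, t) * Le.t();
    mat XB = X * B;

    mat Sei = safe_inv(Se);
    mat Sui = safe_inv(Su);
    mat Svi = safe_inv(Sv);

    // line effects | rest
    mat R2 = Y - XB;
    for (int i = 0; i < n; ++i) R2.row(i) -= V.row(block(i));
    for (int l = 0; l < nl; ++l) {
      const uvec& rws = line_rows[l];
      vec rsum = sum(R2.rows(rws), 0).t();
      mat P = ((double) rws.n_elem) * Sei + Sui;
      mat Lp = chol_lower_safe(P);
      vec mean_l = solve(trimatu(Lp.t()), solve(trimatl(Lp), Sei * rsum));
      vec z = rnorm_mat(t, 1).col(0);
      U.row(l) = (mean_l + solve(trimatu(Lp.t()), z)).t();
    }

    // block effects | rest
    mat R3 = Y - XB;
    for (int i = 0; i < n; ++i) R3.row(i) -= U.row(line(i));
    for (int b = 0; b < nb; ++b) {
      const uvec& rws = block_rows[b];
      vec rsum = sum(R3.rows(rws), 0).t();
      mat P = ((double) rws.n_elem) * Sei + Svi;
      mat Lp = chol_lower_safe(P);
      vec mean_b = solve(trimatu(Lp.t()), solve(trimatl(Lp), Sei * rsum));
      vec z = rnorm_mat(t, 1).col(0);
      V.row(b) = (mean_b + solve(trimatu(Lp.t()), z)).t();
    }

    // covariance components | effects
    Su = rinvwishart(nl + nu0, U.t() * U + V0);
    Sv = rinvwishart(nb + nu0, V.t() * V + V0);
    mat E = Y - XB;
    for (int i = 0; i < n; ++i) E.row(i) -= U.row(line(i)) + V.row(block(i));
    Se = rinvwishart(n + nu0, E.t() * E + V0);

    if (it >= burn_in && (it - burn_in + 1) % thin == 0 && k < n_keep) {
      keep_G.slice(k) = Su / 2.0;  // G = half the among-line covariance
      keep_Sv.slice(k) = Sv;
      keep_Se.slice(k) = Se;
      keep_B_mean += B;
      ++k;
    }
  }
  if (k > 0) keep_B_mean /= k;
  cube Gk = keep_G.slices(0, std::max(k - 1, 0));
  cube Svk = keep_Sv.slices(0, std::max(k - 1, 0));
  cube Sek = keep_Se.slices(0, std::max(k - 1, 0));

  return Rcpp::List::create(
    Rcpp::Named("G") = Gk,
    Rcpp::Named("blockCov") = Svk,
    Rcpp::Named("residCov") = Sek,
    Rcpp::Named("fixedMean") = keep_B_mean,
    Rcpp::Named("nKept") = k);
}
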