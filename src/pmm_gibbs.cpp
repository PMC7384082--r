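// Blocked Gibbs sampler for the multi-response phylogenetic mixed model
// ("animal model"):
//
//   w_i = y_i + m_i,        m_i ~ N(0, diag(V_i))   (known measurement error)
//   y_i = B' x_i + H_i v_{s(i)} + e_i,  e_i ~ N(0, R)
//   vec(v) ~ N(0, G (x) A)  over species, A the relatedness matrix
//
// with k responses, p fixed-effect columns shared across responses (each
// with a per-response coefficient), and a q-column random-effect design Zr
// (q = 1 column of ones for a random intercept; q = 2 for intercept +
// slope in the single-response size-scaling models).  The per-species
// effect v_s has dimension d = q*k, laid out term-major: [term t][trait j].
// G and R get conjugate inverse-Wishart updates; missing responses are
// imputed from their conditional normals (Missing At Random).
//
// All randomness comes from R's RNG so set.seed() makes chains bit-identical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double rnorm1() { return R::norm_rand(); }

static vec rnorm_vec(unsigned int m) {
  vec z(m);
  for (unsigned int i = 0; i < m; ++i) z(i) = rnorm1();
  return z;
}

static mat rnorm_mat(unsigned int r, unsigned int c) {
  mat z(r, c);
  // column-major fill, matches R's matrix(rnorm(r*c), r, c)
  for (unsigned int j = 0; j < c; ++j)
    for (unsigned int i = 0; i < r; ++i) z(i, j) = rnorm1();
  return z;
}

// Draw from the inverse-Wishart IW(S, df) via the Bartlett decomposition of
// the companion Wishart(S^{-1}, df) draw.
static mat rinvwishart(const mat& S, double df) {
  const unsigned int k = S.n_rows;
  mat Sinv = inv_sympd(symmatu(S));
  mat L = chol(Sinv, "lower");
  mat Abar(k, k, fill::zeros);
  for (unsigned int i = 0; i < k; ++i) {
    Abar(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (unsigned int j = 0; j < i; ++j) Abar(i, j) = rnorm1();
  }
  mat LA = L * Abar;
  return inv_sympd(symmatu(LA * LA.t()));
}

static mat safe_inv_sympd(const mat& M) {
  mat out;
  if (!inv_sympd(out, symmatu(M))) {
    // one jittered retry, then give up loudly
    mat Mj = symmatu(M) + 1e-8 * eye(M.n_rows, M.n_cols);
    if (!inv_sympd(out, Mj))
      Rcpp::stop("non-positive-definite conditional covariance (after jitter)");
  }
  return out;
}

static mat safe_chol_lower(const mat& M) {
  mat out;
  if (!chol(out, symmatu(M), "lower")) {
    mat Mj = symmatu(M) + 1e-10 * eye(M.n_rows, M.n_cols);
    if (!chol(out, Mj, "lower"))
      Rcpp::stop("non-positive-definite covariance in Cholesky (after jitter)");
  }
  return out;
}

// random-effect contribution for observation i: (z_i' (x) I_k) v_s
static vec rand_contrib(const rowvec& z, const rowvec& v, unsigned int k) {
  const unsigned int q = z.n_elem;
  vec out(k, fill::zeros);
  for (unsigned int t = 0; t < q; ++t)
    for (unsigned int j = 0; j < k; ++j)
      out(j) += z(t) * v(t * k + j);
  return out;
}

// [[Rcpp::export]]
Rcpp::List pmm_gibbs_cpp(const arma::mat& W,      // n x k observed, NaN = missing
                         const arma::mat& X,      // n x p fixed design
                         const arma::uvec& sp,    // n, 0-based species index
                         const arma::mat& Zr,     // n x q random design
                         const arma::mat& Ainv,   // N x N
                         const arma::mat& V,      // n x k known error variances
                         const arma::mat& PsiG, double nuG,
                         const arma::mat& PsiR, double nuR,
                         int n_iter, int burn_in, int thin,
                         bool fix_g_zero) {
  const unsigned int n = W.n_rows, k = W.n_cols, p = X.n_cols,
    q = Zr.n_cols, N = Ainv.n_rows, d = q * k;
  if (burn_in >= n_iter) Rcpp::stop("burn_in must be smaller than n_iter");

  // missingness bookkeeping
  umat is_miss(n, k);
  for (unsigned int i = 0; i < n; ++i)
    for (unsigned int j = 0; j < k; ++j)
      is_miss(i, j) = std::isnan(W(i, j)) ? 1u : 0u;
  uvec miss_idx = find(vectorise(is_miss) == 1u); // column-major into (n x k)
  const unsigned int n_miss = miss_idx.n_elem;

  bool any_latent = n_miss > 0;
  for (unsigned int i = 0; i < n && !any_latent; ++i)
    for (unsigned int j = 0; j < k; ++j)
      if (!is_miss(i, j) && V(i, j) > 0) { any_latent = true; break; }

  // initial latent Y: observed values, missing filled with column means
  mat Y = W;
  for (unsigned int j = 0; j < k; ++j) {
    double s = 0; unsigned int m = 0;
    for (unsigned int i = 0; i < n; ++i)
      if (!is_miss(i, j)) { s += W(i, j); ++m; }
    double fill = m > 0 ? s / m : 0.0;
    for (unsigned int i = 0; i < n; ++i)
      if (is_miss(i, j)) Y(i, j) = fill;
  }

  // fixed-design precomputations (flat prior on B)
  mat XtX = X.t() * X;
  mat XtX_inv = safe_inv_sympd(XtX);
  mat CX = safe_chol_lower(XtX_inv);

  // per-species observation lists
  std::vector<uvec> sp_obs(N);
  {
    std::vector<std::vector<unsigned int> > tmp(N);
    for (unsigned int i = 0; i < n; ++i) tmp[sp(i)].push_back(i);
    for (unsigned int s = 0; s < N; ++s)
      sp_obs[s] = conv_to<uvec>::from(tmp[s]);
  }

  // initial values
  // start from an even split of the empirical residual covariance between
  // the heritable and residual blocks (burn-in insensitive for either truth)
  mat B = XtX_inv * (X.t() * Y);
  mat E0 = Y - X * B;
  mat S0 = symmatu(E0.t() * E0 / std::max(1u, n - 1)) + 1e-6 * eye(k, k);
  mat R = fix_g_zero ? S0 : mat(0.5 * S0);
  mat G(d, d, fill::zeros);
  if (!fix_g_zero) {
    if (q == 1) G = 0.5 * S0;
    else G = 0.5 * mean(S0.diag()) * eye(d, d);
  }
  mat U(N, d, fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  mat beta_draws(n_keep, p * k);
  mat g_draws(n_keep, d * d);
  mat r_draws(n_keep, k * k);
  mat u_draws(n_keep, N * d);
  mat ymiss_draws(n_keep, n_miss);
  vec dev_draws(n_keep);
  mat Ysum(n, k, fill::zeros), Bsum(p, k, fill::zeros),
    Usum(N, d, fill::zeros), Rsum(k, k, fill::zeros);

  const double l2pi = std::log(2.0 * M_PI);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    mat Rinv = safe_inv_sympd(R);

    // random-effect contribution per observation
    mat RU(n, k, fill::zeros);
    if (!fix_g_zero)
      for (unsigned int i = 0; i < n; ++i)
        RU.row(i) = rand_contrib(Zr.row(i), U.row(sp(i)), k).t();

    // (5)-(6) latent true values & MAR imputation
    if (any_latent) {
      mat Mu = X * B + RU;
      for (unsigned int i = 0; i < n; ++i) {
        std::vector<unsigned int> fixed, free_;
        for (unsigned int j = 0; j < k; ++j) {
          if (!is_miss(i, j) && V(i, j) <= 0) fixed.push_back(j);
          else free_.push_back(j);
        }
        if (free_.empty()) { Y.row(i) = W.row(i); continue; }
        uvec iF = conv_to<uvec>::from(fixed);
        uvec iS = conv_to<uvec>::from(free_);
        vec mu_i = Mu.row(i).t();
        vec priorMean; mat priorCov;
        if (iF.is_empty()) {
          priorMean = mu_i; priorCov = R;
        } else {
          // set the exactly-observed components, condition the rest on them
          for (unsigned int a = 0; a < iF.n_elem; ++a)
            Y(i, iF(a)) = W(i, iF(a));
          mat RFF = R.submat(iF, iF);
          mat RSF = R.submat(iS, iF);
          vec wF = W.row(i).t();
          vec devF = wF(iF) - mu_i(iF);
          mat K = RSF * safe_inv_sympd(RFF);
          priorMean = mu_i(iS) + K * devF;
          priorCov = symmatu(R.submat(iS, iS) - K * RSF.t());
        }
        mat P0 = safe_inv_sympd(priorCov);
        vec rhs = P0 * priorMean;
        mat Om = P0;
        for (unsigned int a = 0; a < iS.n_elem; ++a) {
          unsigned int j = iS(a);
          if (!is_miss(i, j) && V(i, j) > 0) {
            Om(a, a) += 1.0 / V(i, j);
            rhs(a) += W(i, j) / V(i, j);
          }
        }
        mat Sig = safe_inv_sympd(Om);
        vec ys = Sig * rhs + safe_chol_lower(Sig) * rnorm_vec(iS.n_elem);
        for (unsigned int a = 0; a < iS.n_elem; ++a) Y(i, iS(a)) = ys(a);
      }
    }

    // (1) fixed effects: flat prior; with shared X the conditional mean is
    // the per-response OLS fit and vec(B) ~ N(vec(Bhat), R (x) (X'X)^{-1})
    mat Bhat = XtX_inv * (X.t() * (Y - RU));
    mat LR = safe_chol_lower(R);
    B = Bhat + CX * rnorm_mat(p, k) * LR.t();

    // (2) species effects, single-site over species
    if (!fix_g_zero) {
      mat Ginv = safe_inv_sympd(G);
      mat Resid = Y - X * B;
      for (unsigned int s = 0; s < N; ++s) {
        // prior: v_s | v_-s with precision Ainv(s,s) * Ginv and linear term
        // -Ginv * sum_{t != s} Ainv(s,t) v_t
        vec wsum(d, fill::zeros);
        for (unsigned int t = 0; t < N; ++t)
          if (t != s && Ainv(s, t) != 0.0) wsum += Ainv(s, t) * U.row(t).t();
        vec lin = -(Ginv * wsum);
        mat P = Ainv(s, s) * Ginv;
        const uvec& obs = sp_obs[s];
        for (unsigned int a = 0; a < obs.n_elem; ++a) {
          unsigned int i = obs(a);
          rowvec z = Zr.row(i);
          vec ri = Resid.row(i).t();
          vec Rr = Rinv * ri;
          for (unsigned int t = 0; t < q; ++t) {
            lin.subvec(t * k, t * k + k - 1) += z(t) * Rr;
            for (unsigned int t2 = 0; t2 < q; ++t2)
              P.submat(t * k, t2 * k, t * k + k - 1, t2 * k + k - 1) +=
                z(t) * z(t2) * Rinv;
          }
        }
        mat Sig = safe_inv_sympd(P);
        vec vs = Sig * lin + safe_chol_lower(Sig) * rnorm_vec(d);
        U.row(s) = vs.t();
      }
      // (3) heritable covariance
      mat SG = symmatu(PsiG + U.t() * Ainv * U);
      G = rinvwishart(SG, nuG + (double)N);
      // refresh the random contributions with the new species effects
      for (unsigned int i = 0; i < n; ++i)
        RU.row(i) = rand_contrib(Zr.row(i), U.row(sp(i)), k).t();
    }

    // (4) residual covariance
    mat E = Y - X * B - RU;
    mat SR = symmatu(PsiR + E.t() * E);
    R = rinvwishart(SR, nuR + (double)n);

    // conditional deviance of the latent responses given (B, U, R)
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      mat Rinv2 = safe_inv_sympd(R);
      double ldR; double sign;
      log_det(ldR, sign, R);
      double dev = n * k * l2pi + n * ldR + accu((E * Rinv2) % E);

      beta_draws.row(kept) = vectorise(B).t();
      g_draws.row(kept) = vectorise(G).t();
      r_draws.row(kept) = vectorise(R).t();
      u_draws.row(kept) = vectorise(U).t();
      dev_draws(kept) = dev;
      if (n_miss > 0) {
        vec yv = vectorise(Y);
        ymiss_draws.row(kept) = yv(miss_idx).t();
      }
      Ysum += Y; Bsum += B; Usum += U; Rsum += R;
      ++kept;
    }
  }

  // plug-in deviance at posterior means of (B, U, latent Y), R at its mean
  mat Ybar = Ysum / std::max(1, kept);
  mat Bbar = Bsum / std::max(1, kept);
  mat Ubar = Usum / std::max(1, kept);
  mat Rbar = symmatu(Rsum / std::max(1, kept));
  mat RUbar(n, k, fill::zeros);
  if (!fix_g_zero)
    for (unsigned int i = 0; i < n; ++i)
      RUbar.row(i) = rand_contrib(Zr.row(i), Ubar.row(sp(i)), k).t();
  mat Ehat = Ybar - X * Bbar - RUbar;
  double ldRb, signb;
  log_det(ldRb, signb, Rbar);
  double dev_hat = n * k * l2pi + n * ldRb +
    accu((Ehat * safe_inv_sympd(Rbar)) % Ehat);

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_draws,
    Rcpp::Named("G") = g_draws,
    Rcpp::Named("R") = r_draws,
    Rcpp::Named("U") = u_draws,
    Rcpp::Named("deviance") = dev_draws,
    Rcpp::Named("dev_hat") = dev_hat,
    Rcpp::Named("y_missing") = ymiss_draws,
    Rcpp::Named("miss_index") = conv_to<std::vector<double> >::from(
      conv_to<vec>::from(miss_idx) + 1.0),
    Rcpp::Named("y_mean") = Ybar,
    Rcpp::Named("beta_mean") = Bbar,
    Rcpp::Named("u_mean") = Ubar);
}
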