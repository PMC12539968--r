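// Blocked Gibbs sampler for the five-response multivariate social-bond model.
//
// Seven linear components share one design matrix and correlated ego/alter
// random effects:
//   0 aggression (Bernoulli-logit)   1 groom (Bernoulli-logit)
//   2 play (Bernoulli-logit)         3 contact hurdle  (logit, P(zero))
//   4 contact location (Gaussian on log scale, positives only)
//   5 proximity hurdle (logit)       6 proximity location (Gaussian, positives)
//
// All logit components are augmented with Polya-Gamma latent variables
// (Devroye-type exact sampler), which makes every conditional Gaussian /
// Wishart / slice and the sweep an exact Gibbs kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// alternating-series coefficients for the Jacobi J*(1,.) density
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np5 * np5 / x);
}

// CDF at t of inverse-Gaussian(mu = 1/z, lambda = 1)
static double pigauss(double t, double z) {
  double s = std::sqrt(1.0 / t);
  return R::pnorm(s * (t * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-s * (t * z + 1.0), 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, PG_TRUNC)
static double rtigauss(double z) {
  z = std::fabs(z);
  const double t = PG_TRUNC;
  double X = t + 1.0;
  if (z < 1.0 / t) { // mu > t: rejection sampler targeting the tail shape
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      X = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * X)) break;
    }
  } else {
    double mu = 1.0 / z;
    while (X > t) {
      double Y = norm_rand();
      Y *= Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// exact draw from Polya-Gamma PG(1, z)
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * PG_TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(PG_TRUNC, z);
  while (true) {
    double X;
    if (p + q > 0.0 && unif_rand() < p / (p + q))
      X = PG_TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(z);
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    bool accept = false;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) { accept = true; break; }
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
    if (accept) return X / 4.0;
  }
}

//' @title Draw Polya-Gamma PG(1, z) variates
//' @description Exact Devroye-type sampler used by the Gibbs kernel;
//'   exported for validation against the closed-form moments.
//' @param z numeric vector of tilting parameters.
//' @return numeric vector of PG(1, z) draws.
//' @keywords internal
// [[Rcpp::export]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// Wishart(df, S) draw via Bartlett decomposition
static arma::mat rwishart_c(double df, const arma::mat& S) {
  int d = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// draw x ~ N(Prec^{-1} m, Prec^{-1})
static arma::vec rmvnorm_prec(const arma::vec& m, const arma::mat& Prec) {
  arma::mat R = arma::chol(Prec); // upper
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), m));
  arma::vec zdraw(m.n_elem);
  for (arma::uword i = 0; i < m.n_elem; ++i) zdraw(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), zdraw);
}

// slice sampler for a residual scale with half-Normal(0, prior_sd) prior
static double slice_sigma(double sig, double n, double ssr, double prior_sd) {
  auto logpost = [&](double s) {
    return -n * std::log(s) - ssr / (2.0 * s * s) -
           s * s / (2.0 * prior_sd * prior_sd);
  };
  double ly = logpost(sig) - R::exp_rand();
  double w = 0.1 * sig + 0.01;
  double L = sig - w * unif_rand();
  double Rr = L + w;
  if (L < 1e-8) L = 1e-8;
  while (L > 1e-8 && logpost(L) > ly) {
    L -= w;
    if (L < 1e-8) { L = 1e-8; break; }
  }
  while (logpost(Rr) > ly) Rr += w;
  while (true) {
    double s1 = L + unif_rand() * (Rr - L);
    if (logpost(s1) > ly) return s1;
    if (s1 < sig) L = s1; else Rr = s1;
  }
}

//' @title Gibbs kernel for the multivariate social-bond model (one chain)
//' @description Internal workhorse behind [fit_social_model()]. Uses R's RNG,
//'   so results are reproducible under `set.seed()`.
//' @param X design matrix (n rows, p columns, including the intercept).
//' @param ego,alter 1-based grouping indices per row.
//' @param ybin n x 5 0/1 matrix: aggression, groom, play, contact-is-zero,
//'   proximity-is-zero indicators.
//' @param pos_c,pos_p 1-based row indices with positive contact / proximity
//'   versatility; `logy_c`, `logy_p` the matching log responses.
//' @param n_ego,n_alter numbers of grouping levels.
//' @param beta0 p x 7 matrix of initial fixed effects.
//' @param b_prior_sd prior sd of fixed effects.
//' @param wish_df,wish_scale Wishart prior degrees of freedom and scale
//'   (`V = wish_scale * I`) for the RE precisions.
//' @param sigma_prior_sd half-Normal prior sd for the residual scales.
//' @param n_iter,warmup,thin MCMC schedule for this chain.
//' @param store_re keep random-effect draws (needed for conditional R2).
//' @param hurdle_intercept_only if TRUE the two hurdle components use only
//'   the intercept column of `X` as fixed effects.
//' @param ego_cols,ego_xval 1-based design columns constant within ego and
//'   their per-ego values (levels x columns), used for the
//'   ancillarity-sufficiency translation moves; likewise
//'   `alter_cols`/`alter_xval` for the alter grouping.
//' @return list of flattened draw matrices.
//' @keywords internal
// [[Rcpp::export]]
List gibbs_social(const arma::mat& X,
                  const arma::ivec& ego,
                  const arma::ivec& alter,
                  const arma::imat& ybin,
                  const arma::ivec& pos_c, const arma::vec& logy_c,
                  const arma::ivec& pos_p, const arma::vec& logy_p,
                  int n_ego, int n_alter,
                  const arma::mat& beta0,
                  double b_prior_sd,
                  double wish_df, double wish_scale,
                  double sigma_prior_sd,
                  int n_iter, int warmup, int thin,
                  bool store_re,
                  bool hurdle_intercept_only,
                  const arma::ivec& ego_cols, const arma::mat& ego_xval,
                  const arma::ivec& alter_cols,
                  const arma::mat& alter_xval) {
  const int N = X.n_rows, P = X.n_cols, C = 7;
  const int bin_comp[5] = {0, 1, 2, 3, 5};   // logit components
  const int gau_comp[2] = {4, 6};            // Gaussian components
  const double b_prec = 1.0 / (b_prior_sd * b_prior_sd);

  arma::mat beta = beta0;                 // P x 7
  arma::mat u(n_ego, C, arma::fill::zeros);
  arma::mat v(n_alter, C, arma::fill::zeros);
  arma::mat Omega_u = arma::eye(C, C), Omega_v = arma::eye(C, C);
  double sigma_c = 1.0, sigma_p = 1.0;

  arma::uvec egoi(N), alti(N);
  for (int i = 0; i < N; ++i) { egoi(i) = ego(i) - 1; alti(i) = alter(i) - 1; }
  // positive-row bookkeeping for the Gaussian components
  std::vector<arma::uvec> gau_rows(2);
  std::vector<arma::vec> gau_y(2);
  gau_rows[0].set_size(pos_c.n_elem);
  for (arma::uword j = 0; j < pos_c.n_elem; ++j) gau_rows[0](j) = pos_c(j) - 1;
  gau_y[0] = logy_c;
  gau_rows[1].set_size(pos_p.n_elem);
  for (arma::uword j = 0; j < pos_p.n_elem; ++j) gau_rows[1](j) = pos_p(j) - 1;
  gau_y[1] = logy_p;

  const int n_keep = (n_iter - warmup) / thin;
  arma::mat keep_beta(n_keep, P * C);
  arma::mat keep_Su(n_keep, C * C), keep_Sv(n_keep, C * C);
  arma::mat keep_sigma(n_keep, 2);
  arma::mat keep_u, keep_v;
  if (store_re) {
    keep_u.set_size(n_keep, n_ego * C);
    keep_v.set_size(n_keep, n_alter * C);
  }

  arma::mat w(N, C), r(N, C);
  arma::mat Wsum(n_ego, C), Msum(n_ego, C), WsumA(n_alter, C), MsumA(n_alter, C);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // current linear predictors
    arma::mat etaF = X * beta;            // N x 7
    arma::mat eta = etaF;
    for (int i = 0; i < N; ++i) {
      eta.row(i) += u.row(egoi(i)) + v.row(alti(i));
    }

    // 1. latent precisions / working responses
    w.zeros();
    for (int k = 0; k < 5; ++k) {
      int c = bin_comp[k];
      for (int i = 0; i < N; ++i) {
        double om = rpg1(eta(i, c));
        w(i, c) = om;
        r(i, c) = (ybin(i, k) - 0.5) / om;
      }
    }
    for (int k = 0; k < 2; ++k) {
      int c = gau_comp[k];
      double prec = (k == 0) ? 1.0 / (sigma_c * sigma_c)
                             : 1.0 / (sigma_p * sigma_p);
      const arma::uvec& rows = gau_rows[k];
      for (arma::uword j = 0; j < rows.n_elem; ++j) {
        w(rows(j), c) = prec;
        r(rows(j), c) = gau_y[k](j);
      }
    }

    // 2. fixed effects, one component at a time
    for (int c = 0; c < C; ++c) {
      int Pc = (hurdle_intercept_only && (c == 3 || c == 5)) ? 1 : P;
      arma::vec wc = w.col(c);
      arma::vec resid = r.col(c);
      for (int i = 0; i < N; ++i)
        resid(i) -= u(egoi(i), c) + v(alti(i), c);
      arma::mat Xc = X.cols(0, Pc - 1);
      arma::mat Xw = Xc;
      Xw.each_col() %= wc;
      arma::mat Prec = Xc.t() * Xw + b_prec * arma::eye(Pc, Pc);
      arma::vec m = Xc.t() * (wc % resid);
      arma::vec bc = rmvnorm_prec(m, Prec);
      beta.col(c).zeros();
      beta.col(c).head(Pc) = bc;
    }
    etaF = X * beta;

    // 3. ego random effects (likelihood contribution is diagonal in c)
    Wsum.zeros(); Msum.zeros();
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) {
        double wi = w(i, c);
        if (wi > 0.0) {
          Wsum(egoi(i), c) += wi;
          Msum(egoi(i), c) += wi * (r(i, c) - etaF(i, c) - v(alti(i), c));
        }
      }
    }
    for (int e = 0; e < n_ego; ++e) {
      arma::mat Prec = Omega_u + arma::diagmat(Wsum.row(e).t());
      u.row(e) = rmvnorm_prec(Msum.row(e).t(), Prec).t();
    }

    // 4. alter random effects
    WsumA.zeros(); MsumA.zeros();
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) {
        double wi = w(i, c);
        if (wi > 0.0) {
          WsumA(alti(i), c) += wi;
          MsumA(alti(i), c) += wi * (r(i, c) - etaF(i, c) - u(egoi(i), c));
        }
      }
    }
    for (int a = 0; a < n_alter; ++a) {
      arma::mat Prec = Omega_v + arma::diagmat(WsumA.row(a).t());
      v.row(a) = rmvnorm_prec(MsumA.row(a).t(), Prec).t();
    }

    // 4b. translation (ancillarity-sufficiency) moves. For any design
    // column that is constant within a grouping factor, shifting its
    // coefficient by delta while subtracting x_g * delta from that group's
    // random effects leaves the likelihood invariant; the conditional for
    // delta is Gaussian, so the joint move is a free Gibbs update that
    // breaks the posterior correlation between group-level covariates
    // (including the intercept) and the random-effect means.
    if (!hurdle_intercept_only) {
      for (arma::uword kk = 0; kk < ego_cols.n_elem; ++kk) {
        int k = ego_cols(kk) - 1;
        arma::vec xu(C, arma::fill::zeros);
        double xsum2 = 0.0;
        for (int e = 0; e < n_ego; ++e) {
          double xe = ego_xval(e, kk);
          xu += xe * u.row(e).t();
          xsum2 += xe * xe;
        }
        arma::mat Pd = b_prec * arma::eye(C, C) + xsum2 * Omega_u;
        arma::vec lin = Omega_u * xu - b_prec * beta.row(k).t();
        arma::vec delta = rmvnorm_prec(lin, Pd);
        beta.row(k) += delta.t();
        for (int e = 0; e < n_ego; ++e)
          u.row(e) -= ego_xval(e, kk) * delta.t();
        etaF += X.col(k) * delta.t();
      }
      for (arma::uword kk = 0; kk < alter_cols.n_elem; ++kk) {
        int k = alter_cols(kk) - 1;
        arma::vec xv(C, arma::fill::zeros);
        double xsum2 = 0.0;
        for (int a = 0; a < n_alter; ++a) {
          double xa = alter_xval(a, kk);
          xv += xa * v.row(a).t();
          xsum2 += xa * xa;
        }
        arma::mat Pd = b_prec * arma::eye(C, C) + xsum2 * Omega_v;
        arma::vec lin = Omega_v * xv - b_prec * beta.row(k).t();
        arma::vec delta = rmvnorm_prec(lin, Pd);
        beta.row(k) += delta.t();
        for (int a = 0; a < n_alter; ++a)
          v.row(a) -= alter_xval(a, kk) * delta.t();
        etaF += X.col(k) * delta.t();
      }
    } else {
      // intercept-only hurdles: restrict the move to the intercept, which
      // every component retains
      arma::vec usum = arma::sum(u, 0).t();
      arma::mat Pd = b_prec * arma::eye(C, C) + (double)n_ego * Omega_u;
      arma::vec delta = rmvnorm_prec(Omega_u * usum - b_prec * beta.row(0).t(), Pd);
      beta.row(0) += delta.t();
      u.each_row() -= delta.t();
      etaF.each_row() += delta.t();
      arma::vec vsum = arma::sum(v, 0).t();
      Pd = b_prec * arma::eye(C, C) + (double)n_alter * Omega_v;
      delta = rmvnorm_prec(Omega_v * vsum - b_prec * beta.row(0).t(), Pd);
      beta.row(0) += delta.t();
      v.each_row() -= delta.t();
      etaF.each_row() += delta.t();
    }

    // 5. RE precision matrices (conjugate Wishart)
    {
      arma::mat P0 = (1.0 / wish_scale) * arma::eye(C, C);
      arma::mat Su = arma::inv_sympd(P0 + u.t() * u);
      Omega_u = rwishart_c(wish_df + n_ego, Su);
      arma::mat Sv = arma::inv_sympd(P0 + v.t() * v);
      Omega_v = rwishart_c(wish_df + n_alter, Sv);
    }

    // 6. residual scales for the two Gaussian components
    for (int k = 0; k < 2; ++k) {
      int c = gau_comp[k];
      const arma::uvec& rows = gau_rows[k];
      if (rows.n_elem == 0) continue;
      double ssr = 0.0;
      for (arma::uword j = 0; j < rows.n_elem; ++j) {
        arma::uword i = rows(j);
        double res = gau_y[k](j) - etaF(i, c) - u(egoi(i), c) - v(alti(i), c);
        ssr += res * res;
      }
      if (k == 0)
        sigma_c = slice_sigma(sigma_c, (double)rows.n_elem, ssr, sigma_prior_sd);
      else
        sigma_p = slice_sigma(sigma_p, (double)rows.n_elem, ssr, sigma_prior_sd);
    }

    // 7. store
    if (it >= warmup && ((it - warmup) % thin == 0) && kept < n_keep) {
      keep_beta.row(kept) = arma::vectorise(beta).t();
      arma::mat Sig_u = arma::inv_sympd(Omega_u);
      arma::mat Sig_v = arma::inv_sympd(Omega_v);
      keep_Su.row(kept) = arma::vectorise(Sig_u).t();
      keep_Sv.row(kept) = arma::vectorise(Sig_v).t();
      keep_sigma(kept, 0) = sigma_c;
      keep_sigma(kept, 1) = sigma_p;
      if (store_re) {
        keep_u.row(kept) = arma::vectorise(u).t();
        keep_v.row(kept) = arma::vectorise(v).t();
      }
      ++kept;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      Named("beta") = keep_beta,
      Named("Sigma_u") = keep_Su,
      Named("Sigma_v") = keep_Sv,
      Named("sigma") = keep_sigma,
      Named("n_keep") = kept);
  if (store_re) {
    out["u"] = keep_u;
    out["v"] = keep_v;
  }
  return out;
}
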