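// Gibbs-with-data-augmentation drivers for the eight two-stage IV models.
// All randomness comes from R's RNG, consumed in the same call order as the
// R-level conditional samplers, so the pure-R reference driver reproduces
// these chains draw-for-draw under a common seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(const arma::uword k) {
  arma::vec z(k);
  for (arma::uword i = 0; i < k; ++i) z[i] = R::norm_rand();
  return z;
}

// Conjugate normal draw for a weighted linear regression block:
// precision = diag(prec) + X' diag(w) X / s2.
static arma::vec draw_coefs(const arma::mat& X, const arma::vec& y,
                            const arma::vec& w, const double s2,
                            const arma::vec& loc, const arma::vec& prec) {
  arma::mat Xw = X.each_col() % arma::sqrt(w);
  arma::mat P = arma::diagmat(prec) + (Xw.t() * Xw) / s2;
  arma::vec b = prec % loc + (X.t() * (w % y)) / s2;
  arma::mat R;
  if (!arma::chol(R, P))
    stop("conditional precision matrix is not positive definite");
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), b));
  arma::vec z = rnorm_vec(X.n_cols);
  return mu + arma::solve(arma::trimatu(R), z);
}

// Inverse-gamma draw: IG(sh0 + n/2, sc0 + sum(w r^2)/2).
static double draw_var(const arma::vec& r, const arma::vec& w,
                       const double sh0, const double sc0) {
  const double shape = sh0 + r.n_elem / 2.0;
  const double scale = sc0 + arma::dot(w, r % r) / 2.0;
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// Griddy-Gibbs draw of the t degrees of freedom on (lo, hi].
static double draw_df(const arma::vec& omega, const double lo,
                      const double hi, const int grid) {
  const double n = static_cast<double>(omega.n_elem);
  const double slw = arma::accu(arma::log(omega));
  const double sw = arma::accu(omega);
  const double width = (hi - lo) / grid;
  arma::vec lk(grid);
  for (int g = 0; g < grid; ++g) {
    const double a = (lo + (g + 0.5) * width) / 2.0;
    lk[g] = n * (a * std::log(a) - R::lgammafn(a)) + (a - 1.0) * slw - a * sw;
  }
  lk -= lk.max();
  arma::vec wgt = arma::exp(lk);
  const double total = arma::accu(wgt);
  if (!std::isfinite(total) || total <= 0.0)
    stop("degenerate df grid kernel");
  const double u = R::unif_rand() * total;
  double cum = 0.0;
  int cell = grid - 1;
  for (int g = 0; g < grid; ++g) {
    cum += wgt[g];
    if (u <= cum) { cell = g; break; }
  }
  return lo + cell * width + R::unif_rand() * width;
}

static double log1p_exp(const double eta) {
  return eta > 0.0 ? eta + std::log1p(std::exp(-eta))
                   : std::log1p(std::exp(eta));
}

static double logit_log_post(const arma::vec& pi1, const arma::mat& W1,
                             const arma::vec& x, const arma::vec& loc,
                             const arma::vec& prec) {
  arma::vec eta = W1 * pi1;
  double ll = 0.0;
  for (arma::uword i = 0; i < x.n_elem; ++i)
    ll += x[i] * eta[i] - log1p_exp(eta[i]);
  arma::vec d = pi1 - loc;
  return ll - 0.5 * arma::dot(prec, d % d);
}

// [[Rcpp::export]]
List gibbs_driver_cpp(List dat, List pr, List mod, List cfg, List init) {
  const arma::vec x = as<arma::vec>(dat["x"]);
  const arma::ivec m = as<arma::ivec>(dat["m"]);
  const arma::mat C = as<arma::mat>(dat["C"]);
  const arma::mat Z = as<arma::mat>(dat["Z"]);
  const arma::uword n = x.n_elem;
  const arma::uvec mis = arma::find(m == 1);
  const arma::uword nmis = mis.n_elem;

  const bool binary = as<bool>(mod["binary"]);
  const bool robust = as<bool>(mod["robust"]);
  const bool selection = as<bool>(mod["selection"]);
  const bool df_est = as<bool>(mod["df_est"]);

  const arma::vec b0 = as<arma::vec>(pr["b0"]), B0 = as<arma::vec>(pr["B0"]);
  const arma::vec g0 = as<arma::vec>(pr["g0"]), G0 = as<arma::vec>(pr["G0"]);
  const double u0 = as<double>(pr["u0"]), U0 = as<double>(pr["U0"]);
  const double e0 = as<double>(pr["e0"]), E0 = as<double>(pr["E0"]);
  const double df_lo = as<double>(pr["df_lower"]);
  const double df_hi = as<double>(pr["df_upper"]);
  const arma::vec sel_loc = as<arma::vec>(pr["sel_loc"]);
  const arma::vec sel_prec = as<arma::vec>(pr["sel_prec"]);
  const int grid_size = as<int>(pr["grid_size"]);

  const int n_iter = as<int>(cfg["n_iter"]);
  const int n_burnin = as<int>(cfg["n_burnin"]);
  const int thin = as<int>(cfg["thin"]);
  const bool debug = as<bool>(cfg["debug"]);

  arma::vec pi1 = as<arma::vec>(init["pi1"]);
  arma::vec pi2 = as<arma::vec>(init["pi2"]);
  double s21 = as<double>(init["s21"]);
  double s22 = as<double>(init["s22"]);
  double nu = as<double>(init["nu"]);
  arma::vec omega = as<arma::vec>(init["omega"]);
  arma::vec y = as<arma::vec>(init["y"]);
  arma::vec phi = as<arma::vec>(init["phi"]);
  double log_scale = as<double>(init["log_scale"]);
  const arma::mat prop_chol = as<arma::mat>(init["prop_chol"]);

  const arma::uword k1 = pi1.n_elem, k2 = pi2.n_elem;
  arma::mat W1(n, k1);
  W1.col(0).ones();
  if (Z.n_cols > 0) W1.cols(1, k1 - 1) = Z;
  arma::mat W2(n, k2);
  W2.col(0).ones();
  if (C.n_cols > 0) W2.cols(2, k2 - 1) = C;
  arma::mat S(n, 2);
  S.col(0).ones();
  const arma::vec ones_n(n, arma::fill::ones);

  const int n_ret = (n_iter - n_burnin) / thin;
  const int npar = k1 + k2 + (selection ? 2 : 0) + (binary ? 1 : 2) +
                   (robust ? 1 : 0);
  arma::mat draws(n_ret, npar);
  arma::vec devs(n_ret);
  int row = 0, acc_post = 0, post_iters = 0;

  for (int j = 1; j <= n_iter; ++j) {
    // 3.1 / 3.2: stage-1 coefficients (and variance, continuous only)
    if (!binary) {
      pi1 = draw_coefs(W1, x, ones_n, s21, b0, B0);
      arma::vec r1 = x - W1 * pi1;
      s21 = draw_var(r1, ones_n, u0, U0);
    } else {
      const double lp_cur = logit_log_post(pi1, W1, x, b0, B0);
      if (!std::isfinite(lp_cur))
        stop("non-finite stage-1 log posterior at iteration %d", j);
      arma::vec prop = pi1 +
        std::exp(log_scale) * (prop_chol * rnorm_vec(k1));
      const double lr = logit_log_post(prop, W1, x, b0, B0) - lp_cur;
      const double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr))
                                             : 0.0;
      const bool accepted = std::log(R::unif_rand()) < lr;
      if (accepted) pi1 = prop;
      if (j <= n_burnin)
        log_scale += (alpha - 0.234) / std::pow(j + 1.0, 0.6);
      else { post_iters++; if (accepted) acc_post++; }
    }

    // predicted treatment enters stage 2
    arma::vec eta1 = W1 * pi1;
    arma::vec xhat = binary ? arma::vec(1.0 / (1.0 + arma::exp(-eta1)))
                            : eta1;
    W2.col(1) = xhat;
    arma::vec mu = W2 * pi2;

    // 3.3: within-chain imputation of missing outcomes
    if (nmis > 0) {
      if (!selection) {
        arma::vec z = rnorm_vec(nmis);
        for (arma::uword i = 0; i < nmis; ++i) {
          const arma::uword r = mis[i];
          y[r] = mu[r] + z[i] * std::sqrt(s22 / omega[r]);
        }
      } else {
        const double prop_sd = arma::stddev(y - mu);
        arma::vec z = rnorm_vec(nmis), u(nmis);
        for (arma::uword i = 0; i < nmis; ++i) u[i] = R::unif_rand();
        for (arma::uword i = 0; i < nmis; ++i) {
          const arma::uword r = mis[i];
          const double sd_i = std::sqrt(s22 / omega[r]);
          const double prop = y[r] + z[i] * prop_sd;
          const double la =
            (R::dnorm(prop, mu[r], sd_i, 1) +
             R::pnorm(phi[0] + phi[1] * prop, 0.0, 1.0, 1, 1)) -
            (R::dnorm(y[r], mu[r], sd_i, 1) +
             R::pnorm(phi[0] + phi[1] * y[r], 0.0, 1.0, 1, 1));
          if (std::log(u[i]) < la) y[r] = prop;
        }
      }
    }

    // probit selection layer: truncated latents, then coefficients
    if (selection) {
      arma::vec u(n), lat(n);
      for (arma::uword i = 0; i < n; ++i) u[i] = R::unif_rand();
      for (arma::uword i = 0; i < n; ++i) {
        const double eta = phi[0] + phi[1] * y[i];
        double p = (m[i] == 1) ? u[i] * R::pnorm(eta, 0.0, 1.0, 1, 0)
                               : u[i] * R::pnorm(-eta, 0.0, 1.0, 1, 0);
        p = std::min(std::max(p, 1e-300), 1.0 - 1e-16);
        lat[i] = (m[i] == 1) ? eta - R::qnorm(p, 0.0, 1.0, 1, 0)
                             : eta + R::qnorm(p, 0.0, 1.0, 1, 0);
      }
      S.col(1) = y;
      phi = draw_coefs(S, lat, ones_n, 1.0, sel_loc, sel_prec);
    }

    // 3.4 stage-2 variance; 3.5 df; 3.6 t weights; 3.7 stage-2 coefficients
    arma::vec r2 = y - mu;
    s22 = draw_var(r2, omega, e0, E0);
    if (robust && df_est) nu = draw_df(omega, df_lo, df_hi, grid_size);
    if (robust) {
      for (arma::uword i = 0; i < n; ++i)
        omega[i] = R::rgamma((nu + 1.0) / 2.0,
                             2.0 / (nu + r2[i] * r2[i] / s22));
    }
    pi2 = draw_coefs(W2, y, omega, s22, g0, G0);

    if (!pi2.is_finite() || !std::isfinite(s22) || s22 <= 0.0) {
      if (debug)
        Rcout << "state at failure: s22=" << s22 << " pi2=" << pi2.t();
      stop("non-finite sampler state at iteration %d", j);
    }

    if (j > n_burnin && (j - n_burnin) % thin == 0) {
      arma::vec mu_dev = W2 * pi2;
      double ll = 0.0;
      if (!binary) {
        const double sd1 = std::sqrt(s21);
        for (arma::uword i = 0; i < n; ++i)
          ll += R::dnorm(x[i], xhat[i], sd1, 1);
      } else {
        for (arma::uword i = 0; i < n; ++i)
          ll += x[i] * eta1[i] - log1p_exp(eta1[i]);
      }
      const double sd2 = std::sqrt(s22);
      for (arma::uword i = 0; i < n; ++i) {
        if (m[i] == 1) continue;
        if (robust)
          ll += R::dt((y[i] - mu_dev[i]) / sd2, nu, 1) - std::log(sd2);
        else
          ll += R::dnorm(y[i], mu_dev[i], sd2, 1);
      }
      devs[row] = -2.0 * ll;

      int c = 0;
      for (arma::uword i = 0; i < k1; ++i) draws(row, c++) = pi1[i];
      for (arma::uword i = 0; i < k2; ++i) draws(row, c++) = pi2[i];
      if (selection) { draws(row, c++) = phi[0]; draws(row, c++) = phi[1]; }
      if (!binary) draws(row, c++) = s21;
      draws(row, c++) = s22;
      if (robust) draws(row, c++) = nu;
      ++row;
    }
  }

  return List::create(
    _["draws"] = draws, _["deviance"] = devs,
    _["accept_rate"] = post_iters > 0 ?
        static_cast<double>(acc_post) / post_iters : NA_REAL,
    _["log_scale"] = log_scale);
}
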