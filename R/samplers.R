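# Conditional-posterior building blocks of the Gibbs sampler with data
# augmentation.  Each function draws from one full conditional using R's
# global RNG; the compiled drivers in src/ replicate the same draws in the
# same RNG call order, so an R-level chain and a compiled chain agree
# draw-for-draw under a common seed.

#' Draw regression coefficients from their conjugate normal conditional
#'
#' Serves both stages of the model: stage one with unit weights, stage two
#' with the latent t weights (unit for normal-family models).  With
#' diagonal prior precision `prior_prec` at location `prior_loc`, the
#' conditional is multivariate normal with precision
#' `diag(prior_prec) + X' diag(w) X / sigma2` and mean
#' `P^{-1} (prior_prec * prior_loc + X' diag(w) y / sigma2)`.
#'
#' @param design n x k design matrix.
#' @param response Length-n response vector.
#' @param weights Length-n positive weights (row precisions scale as
#'   `weights / sigma2`).
#' @param sigma2 Error variance (positive scalar).
#' @param prior_loc,prior_prec Length-k prior location and precision.
#' @return One length-k draw.
#' @export
sample_linear_coefs <- function(design, response, weights, sigma2,
                                prior_loc, prior_prec) {
  k <- ncol(design)
  stopifnot(length(prior_loc) == k, length(prior_prec) == k,
            length(response) == nrow(design), sigma2 > 0)
  if (length(weights) == 1L) weights <- rep(weights, nrow(design))
  P <- diag(prior_prec, k) + crossprod(design * sqrt(weights)) / sigma2
  b <- prior_prec * prior_loc + crossprod(design, weights * response)[, 1] / sigma2
  R <- tryCatch(chol(P), error = function(e)
    stop("conditional precision matrix is not positive definite (",
         conditionMessage(e), ")", call. = FALSE))
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  drop(mu + backsolve(R, stats::rnorm(k)))
}

#' Draw an error variance from its inverse-gamma conditional
#'
#' With an IG(shape0, scale0) prior and (weighted) residuals, the
#' conditional is IG(shape0 + n/2, scale0 + sum(w * r^2) / 2).
#'
#' @param residuals Residual vector (may be empty: prior draw).
#' @param weights Positive weights aligned with `residuals`.
#' @param shape0,scale0 Inverse-gamma prior shape and scale (> 0).
#' @return One positive draw.
#' @export
sample_variance <- function(residuals, weights, shape0, scale0) {
  stopifnot(shape0 > 0, scale0 > 0)
  if (length(weights) == 1L) weights <- rep(weights, length(residuals))
  if (length(residuals) && any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  shape <- shape0 + length(residuals) / 2
  scale <- scale0 + sum(weights * residuals^2) / 2
  1 / stats::rgamma(1L, shape = shape, rate = scale)
}

#' Draw the latent t scale weights
#'
#' The Student-t stage-two error is represented as a scale mixture of
#' normals: `y_i | w_i ~ N(mu_i, sigma2 / w_i)` with
#' `w_i ~ Gamma(nu/2, rate = nu/2)` marginally giving a t with `nu` degrees
#' of freedom.  The conditional is
#' `w_i ~ Gamma((nu + 1)/2, rate = (nu + r_i^2 / sigma2)/2)`.
#'
#' @param residuals Stage-two residual vector.
#' @param sigma2 Stage-two error variance.
#' @param nu Degrees of freedom (> 0).
#' @return Positive weight vector, one per residual.
#' @export
sample_t_weights <- function(residuals, sigma2, nu) {
  if (!(nu > 0)) stop("nu must be positive", call. = FALSE)
  stopifnot(sigma2 > 0)
  stats::rgamma(length(residuals), shape = (nu + 1) / 2,
                rate = (nu + residuals^2 / sigma2) / 2)
}

# Log kernel of p(nu | w) up to a constant, via sufficient statistics:
# prod_i Gamma(w_i; nu/2, rate nu/2) on a uniform (lo, hi] prior.
.df_log_kernel <- function(nu, n, sum_log_w, sum_w) {
  a <- nu / 2
  n * (a * log(a) - lgamma(a)) + (a - 1) * sum_log_w - a * sum_w
}

#' Draw the t degrees of freedom by griddy Gibbs
#'
#' The conditional `p(nu | w) ∝ 1(lo < nu <= hi) prod_i Gamma(w_i; nu/2,
#' rate nu/2)` has bounded support under the uniform prior, so it is drawn
#' by grid inversion: evaluate the log kernel at the midpoints of
#' `grid_size` equal cells, normalize in log space, inverse-CDF sample a
#' cell, and jitter uniformly within it.
#'
#' @param omega Current latent weights (empty: prior draw).
#' @param df_lower,df_upper Prior support bounds.
#' @param grid_size Number of grid cells (default 512).
#' @return One draw in `(df_lower, df_upper]`.
#' @export
sample_df <- function(omega, df_lower, df_upper, grid_size = 512L) {
  stopifnot(df_lower >= 0, df_upper > df_lower, grid_size >= 8L)
  width <- (df_upper - df_lower) / grid_size
  mids <- df_lower + (seq_len(grid_size) - 0.5) * width
  lk <- .df_log_kernel(mids, length(omega), sum(log(omega)), sum(omega))
  lk <- lk - max(lk)
  w <- exp(lk)
  total <- sum(w)
  if (!is.finite(total) || total <= 0)
    stop("degenerate df grid kernel", call. = FALSE)
  cw <- cumsum(w)
  u <- stats::runif(1L) * total
  cell <- findInterval(u, cw) + 1L
  if (cell > grid_size) cell <- grid_size
  df_lower + (cell - 1L) * width + stats::runif(1L) * width
}

#' Impute missing outcomes within the chain
#'
#' For non-selection models each missing outcome is drawn from its normal
#' conditional `N(mu_i, sigma2 / w_i)` at the current parameter state.  For
#' selection models the conditional is proportional to
#' `N(y_i; mu_i, sigma2 / w_i) * Phi(phi0 + phi1 y_i)` and is updated by one
#' random-walk Metropolis step per missing entry, with proposal SD equal to
#' the SD of the current full-outcome residuals.
#'
#' @param y_mis Current imputations (one per missing row).
#' @param mu_mis Stage-two means at the missing rows.
#' @param sigma2 Stage-two error variance.
#' @param omega_mis Latent t weights at the missing rows (1 for normal).
#' @param selection Logical; use the Metropolis selection-aware update?
#' @param phi Length-2 selection coefficients (intercept, outcome slope).
#' @param prop_sd Metropolis proposal SD (selection models).
#' @return Updated imputation vector.
#' @export
impute_missing_y <- function(y_mis, mu_mis, sigma2, omega_mis,
                             selection = FALSE, phi = c(0, 0),
                             prop_sd = sqrt(sigma2)) {
  nm <- length(y_mis)
  if (nm == 0L) return(y_mis)
  sd_i <- sqrt(sigma2 / omega_mis)
  if (!selection)
    return(mu_mis + stats::rnorm(nm) * sd_i)
  prop <- y_mis + stats::rnorm(nm) * prop_sd
  log_acc <- (stats::dnorm(prop, mu_mis, sd_i, log = TRUE) +
              stats::pnorm(phi[1] + phi[2] * prop, log.p = TRUE)) -
             (stats::dnorm(y_mis, mu_mis, sd_i, log = TRUE) +
              stats::pnorm(phi[1] + phi[2] * y_mis, log.p = TRUE))
  accept <- log(stats::runif(nm)) < log_acc
  ifelse(accept, prop, y_mis)
}

#' Update the probit selection layer
#'
#' Latent-utility augmentation for the probit regression of the
#' missingness indicator on the (current, imputation-completed) outcome:
#' each latent utility is a unit-variance normal centred at
#' `phi0 + phi1 y_i`, truncated to `(0, Inf)` where the outcome is missing
#' and `(-Inf, 0]` where it is observed; the coefficients are then drawn
#' from their conjugate normal conditional given the latents.
#'
#' @param y Completed outcome vector (imputations filled in).
#' @param m 0/1 missingness indicator.
#' @param phi Current length-2 selection coefficients.
#' @param prior_loc,prior_prec Length-2 prior location and precision.
#' @return List with updated `phi` and `latents`.
#' @export
sample_selection <- function(y, m, phi, prior_loc, prior_prec) {
  eta <- phi[1] + phi[2] * y
  u <- stats::runif(length(y))
  clamp <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)
  lat <- ifelse(m == 1L,
                eta - stats::qnorm(clamp(u * stats::pnorm(eta))),
                eta + stats::qnorm(clamp(u * stats::pnorm(-eta))))
  if (any(lat[m == 1L] <= 0) || any(lat[m == 0L] > 0))
    stop("internal error: truncated latent utility on the wrong side",
         call. = FALSE)
  S <- cbind(1, y)
  phi_new <- sample_linear_coefs(S, lat, weights = 1, sigma2 = 1,
                                 prior_loc = prior_loc,
                                 prior_prec = prior_prec)
  list(phi = phi_new, latents = lat)
}

# log-likelihood of the Bernoulli-logit stage-1 block plus its normal prior
.logit_log_post <- function(pi1, W1, x, prior_loc, prior_prec) {
  eta <- drop(W1 %*% pi1)
  log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(x * eta - log1pe) - 0.5 * sum(prior_prec * (pi1 - prior_loc)^2)
}

#' Metropolis update of the logistic stage-1 coefficients
#'
#' One random-walk Metropolis step on the full stage-1 coefficient block of
#' the binary-treatment models, targeting the Bernoulli-logit likelihood
#' times the normal prior.  The proposal is `exp(log_scale) * L z` with `L`
#' a fixed Cholesky shape (from the ML information matrix); `log_scale` is
#' adapted during burn-in toward the multivariate optimum acceptance rate
#' 0.234 by a Robbins-Monro recursion and frozen afterwards.
#'
#' @param pi1 Current coefficient vector.
#' @param W1 Stage-one design `[1, Z]`.
#' @param x Binary treatment vector.
#' @param prior_loc,prior_prec Prior location and precision.
#' @param prop_chol Lower-triangular proposal shape matrix `L`.
#' @param log_scale Log of the scalar proposal scale.
#' @param adapt Logical; update `log_scale` (burn-in only)?
#' @param iter Iteration index used by the adaptation step size.
#' @return List with `pi1`, `log_scale`, `accepted`, and the acceptance
#'   probability `alpha`.
#' @export
mh_logistic_stage1 <- function(pi1, W1, x, prior_loc, prior_prec,
                               prop_chol, log_scale, adapt = FALSE,
                               iter = 1L) {
  lp_cur <- .logit_log_post(pi1, W1, x, prior_loc, prior_prec)
  if (!is.finite(lp_cur))
    stop("non-finite stage-1 log posterior at the current state",
         call. = FALSE)
  k <- length(pi1)
  prop <- pi1 + exp(log_scale) * drop(prop_chol %*% stats::rnorm(k))
  lp_prop <- .logit_log_post(prop, W1, x, prior_loc, prior_prec)
  lr <- lp_prop - lp_cur
  alpha <- if (is.finite(lr)) min(1, exp(lr)) else 0
  accepted <- log(stats::runif(1L)) < lr
  if (accepted) pi1 <- prop
  if (adapt)
    log_scale <- log_scale + (alpha - 0.234) / (iter + 1)^0.6
  list(pi1 = pi1, log_scale = log_scale, accepted = accepted, alpha = alpha)
}
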