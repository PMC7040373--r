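# Model drivers: assemble the conditional samplers into the eight Gibbs
# loops, manage chains, burn-in, thinning and initialization.

.par_names <- function(data, spec) {
  J <- ncol(data$Z); p <- ncol(data$C)
  s1 <- c("stage1.intercept",
          if (J == 1L) "stage1.slope" else paste0("stage1.slope", seq_len(J)))
  covs <- if (p > 0L) paste0(colnames(data$C), ".coefficient") else character(0)
  c(s1, "stage2.intercept", "LATE", covs,
    if (spec$selection) c("sel.intercept", "sel.slope"),
    if (spec$treatment == "continuous") "stage1.variance",
    "stage2.variance",
    if (spec$robust) "df.est")
}

#' Initialize the Gibbs sampler state
#'
#' Coefficients and variances start at the frequentist two-stage estimates
#' (2SLS for continuous treatments, ML logistic first stage for binary
#' ones); the t degrees of freedom start at 30 (near-normal mid-support)
#' with unit latent weights; missing outcomes are drawn from the stage-two
#' predictive at the initial state; the selection intercept starts at the
#' probit of the observed missingness rate.  Chains beyond the first jitter
#' both coefficient blocks by `k` standard errors, with `k` drawn once per
#' chain.  A user-supplied state (via `mcmc_config(inits = )`) is passed
#' through after validity checks.
#'
#' @param data An [iv_data()] object.
#' @param spec A [model_spec()].
#' @param freq_fit A `two_stage_fit` (computed if `NULL`).
#' @param chain Chain index (1-based); chains > 1 are jittered.
#' @param user_init Optional explicit state list.
#' @return A `param_state` list.
#' @export
initialize_state <- function(data, spec, freq_fit = NULL, chain = 1L,
                             user_init = NULL) {
  n <- data$n
  nmis <- sum(data$m)
  if (!is.null(user_init)) {
    st <- user_init
    stopifnot(length(st$pi1) == 1L + ncol(data$Z),
              length(st$pi2) == 2L + ncol(data$C),
              st$s22 > 0, all(st$omega > 0),
              length(st$omega) == n)
    if (is.null(st$phi)) st$phi <- c(0, 0)
    if (is.null(st$nu)) st$nu <- 30
    if (is.null(st$s21)) st$s21 <- 1
    st$y <- data$y
    if (nmis) {
      stopifnot(length(st$y_mis) == nmis)
      st$y[data$m == 1L] <- st$y_mis
    }
    class(st) <- "param_state"
    return(st)
  }
  if (is.null(freq_fit))
    freq_fit <- if (data$x_type == "continuous") fit_2sls(data)
                else fit_logit_stage1(data)
  pi1 <- freq_fit$stage1_coefs
  pi2 <- freq_fit$stage2_coefs
  if (chain > 1L) {
    k <- stats::rnorm(1L)
    pi1 <- pi1 + k * freq_fit$stage1_ses
    pi2 <- pi2 + k * freq_fit$stage2_ses
  }
  s21 <- if (is.finite(freq_fit$stage1_sigma2)) freq_fit$stage1_sigma2 else 1
  s22 <- freq_fit$stage2_sigma2
  nu <- if (spec$df_mode == "fixed") spec$df_fixed else 30
  W1 <- .design1(data)
  xhat <- if (data$x_type == "binary") drop(stats::plogis(W1 %*% pi1))
          else drop(W1 %*% pi1)
  mu <- drop(.design2(data, xhat) %*% pi2)
  y <- data$y
  y_mis <- numeric(0)
  if (nmis) {
    y_mis <- stats::rnorm(nmis, mu[data$m == 1L], sqrt(s22))
    y[data$m == 1L] <- y_mis
  }
  rate <- mean(data$m)
  phi <- c(if (rate > 0 && rate < 1) stats::qnorm(rate) else 0, 0)
  structure(
    list(pi1 = pi1, pi2 = pi2, s21 = s21, s22 = s22, nu = nu,
         omega = rep(1, n), y = y, y_mis = y_mis, phi = phi),
    class = "param_state"
  )
}

# Proposal shape for the binary stage-1 Metropolis block: Cholesky of the
# ML covariance (inverse information), falling back to identity.
.mh_proposal_chol <- function(data, freq_fit) {
  k1 <- 1L + ncol(data$Z)
  V <- tryCatch({
    W1 <- .design1(data)
    q <- drop(stats::plogis(W1 %*% freq_fit$stage1_coefs))
    solve(crossprod(W1 * sqrt(q * (1 - q))))
  }, error = function(e) diag(k1))
  t(chol(V))
}

#' Fit one of the eight Bayesian two-stage causal models
#'
#' Runs the model-appropriate Gibbs sampler with data augmentation.  Per
#' iteration, continuous-treatment models update the stage-one coefficients
#' and variance, impute missing outcomes, update the selection layer (M5,
#' M6), the stage-two variance, the t degrees of freedom and latent weights
#' (robust models), and the stage-two coefficients, in that order.
#' Binary-treatment models replace the stage-one conjugate updates with an
#' adaptive random-walk Metropolis step on the logistic coefficients and
#' carry no stage-one error variance.  The stage-two regressor is the
#' current-draw predicted treatment (fitted value or fitted probability),
#' recomputed every iteration.
#'
#' Priors default to data-dependent priors built from the frequentist
#' two-stage fit ([make_ddp_priors()]); starting values default to the same
#' fit ([initialize_state()]).
#'
#' @param data An [iv_data()] object.
#' @param model A [model_spec()], or a model code/name passed to
#'   [model_spec()] (default `"M1"`).
#' @param prior A [prior_spec()]; `NULL` uses data-dependent priors.
#' @param config An [mcmc_config()].
#' @param engine `"cpp"` (compiled driver, default) or `"r"` (pure-R
#'   reference driver; identical draws under a common seed).
#' @param debug Logical; dump sampler state context on mid-chain failure.
#' @param grid_size Grid cells for the griddy-Gibbs df update.
#' @return An object of class `bivlate_fit` with elements `draws` (list of
#'   retained-draws matrices, one per chain), `deviance` (list of vectors),
#'   `par_names`, `model`, `prior`, `config`, `data`, `freq_fit`,
#'   `accept_rate` (binary models) and `log` (resolved-settings run log).
#' @examples
#' gen <- gen_continuous_iv(gen_spec(n = 300, seed = 7))
#' fit <- fit_model(gen$data, "M1", config = mcmc_config(n_iter = 2000))
#' summary(fit)
#' @export
fit_model <- function(data, model = "M1", prior = NULL,
                      config = mcmc_config(), engine = c("cpp", "r"),
                      debug = FALSE, grid_size = 512L) {
  stopifnot(inherits(data, "iv_data"))
  engine <- match.arg(engine)
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)

  if (spec$treatment != data$x_type)
    stop("model ", spec$code, " expects a ", spec$treatment,
         " treatment but the data's treatment is ", data$x_type,
         call. = FALSE)
  if (spec$selection && sum(data$m) == 0L)
    stop("model ", spec$code, " adds a selection layer for missing ",
         "outcomes, but the outcome is fully observed", call. = FALSE)
  if (!spec$robust) .outlier_screen(data)

  config <- .resolve_config(config, spec$selection)
  log_lines <- c(
    sprintf("model: %s (%s)", spec$code, spec$name),
    sprintf("chains: %d", config$n_chains),
    sprintf("n_iter: %d", config$n_iter),
    sprintf("n_burnin: %d", config$n_burnin),
    sprintf("thin: %d", config$thin),
    sprintf("seed: %d", config$seed))

  freq_fit <- tryCatch(
    if (data$x_type == "continuous") fit_2sls(data) else fit_logit_stage1(data),
    error = function(e) {
      warning("frequentist initializer failed (", conditionMessage(e),
              "); falling back to zero/unit starting values", call. = FALSE)
      NULL
    })
  if (is.null(freq_fit)) {
    freq_fit <- structure(list(
      stage1_coefs = rep(0, 1L + ncol(data$Z)),
      stage1_ses = rep(1, 1L + ncol(data$Z)),
      stage2_coefs = rep(0, 2L + ncol(data$C)),
      stage2_ses = rep(1, 2L + ncol(data$C)),
      stage1_sigma2 = 1, stage2_sigma2 = 1,
      method = "fallback"), class = "two_stage_fit")
  }
  log_lines <- c(log_lines,
                 sprintf("starting values: %s estimates", freq_fit$method))

  if (is.null(prior)) {
    prior <- make_ddp_priors(freq_fit)
    log_lines <- c(log_lines, sprintf("priors: %s", prior$source))
  } else {
    log_lines <- c(log_lines, sprintf("priors: %s", prior$source))
  }
  prior <- .resolve_prior(prior, 1L + ncol(data$Z), 2L + ncol(data$C))
  if (spec$df_mode == "fixed")
    log_lines <- c(log_lines, sprintf("t df fixed at %g", spec$df_fixed))

  par_names <- .par_names(data, spec)
  mod_flags <- list(binary = data$x_type == "binary",
                    robust = spec$robust,
                    selection = spec$selection,
                    df_est = spec$robust && spec$df_mode == "estimate")
  cfg <- list(n_iter = config$n_iter, n_burnin = config$n_burnin,
              thin = config$thin, debug = isTRUE(debug))
  pr <- prior
  pr$grid_size <- as.integer(grid_size)

  set.seed(config$seed)
  draws <- vector("list", config$n_chains)
  devs <- vector("list", config$n_chains)
  acc <- rep(NA_real_, config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    user_init <- if (!is.null(config$inits)) config$inits[[ch]] else NULL
    st <- initialize_state(data, spec, freq_fit, chain = ch,
                           user_init = user_init)
    init <- list(pi1 = st$pi1, pi2 = st$pi2, s21 = st$s21, s22 = st$s22,
                 nu = st$nu, omega = st$omega, y = st$y, phi = st$phi,
                 log_scale = log(2.38 / sqrt(length(st$pi1))),
                 prop_chol = if (mod_flags$binary)
                   .mh_proposal_chol(data, freq_fit)
                 else diag(length(st$pi1)))
    dat <- list(x = data$x, m = data$m, C = data$C, Z = data$Z)
    res <- if (engine == "cpp") {
      gibbs_driver_cpp(dat, pr, mod_flags, cfg, init)
    } else {
      .gibbs_driver_r(dat, pr, mod_flags, cfg, init)
    }
    colnames(res$draws) <- par_names
    draws[[ch]] <- res$draws
    devs[[ch]] <- as.numeric(res$deviance)
    acc[ch] <- res$accept_rate
  }

  structure(
    list(draws = draws, deviance = devs, par_names = par_names,
         model = spec, prior = prior, config = config, data = data,
         freq_fit = freq_fit,
         accept_rate = if (mod_flags$binary) acc else NULL,
         engine = engine, log = log_lines),
    class = "bivlate_fit"
  )
}

# Taxonomy guard: normal-family models handle missingness but not outliers;
# warn when a 6-SD screen on the observed outcomes flags candidate outliers.
# The scale estimate is the MAD (falling back to the SD) so that the
# contamination itself does not mask the screen.
.outlier_screen <- function(data) {
  y <- data$y[data$m == 0L]
  if (length(y) < 10L) return(invisible())
  s <- stats::mad(y)
  if (s == 0) s <- stats::sd(y)
  if (s > 0 && any(abs(y - stats::median(y)) > 6 * s))
    warning("observed outcomes contain values beyond 6 SDs; ",
            "normal-family models do not accommodate outliers -- ",
            "consider the robust (Student-t) variant", call. = FALSE)
  invisible()
}

# Pure-R reference driver.  Mirrors the compiled driver's update and RNG
# call order exactly; used for cross-engine validation.
.gibbs_driver_r <- function(dat, pr, mod, cfg, init) {
  x <- dat$x; m <- dat$m; C <- dat$C; Z <- dat$Z
  n <- length(x)
  mis <- which(m == 1L); nmis <- length(mis)
  W1 <- cbind(1, Z)
  pi1 <- init$pi1; pi2 <- init$pi2
  s21 <- init$s21; s22 <- init$s22; nu <- init$nu
  omega <- init$omega; y <- init$y; phi <- init$phi
  log_scale <- init$log_scale
  k1 <- length(pi1); k2 <- length(pi2)
  W2 <- cbind(1, 0, C)
  n_ret <- (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  npar <- k1 + k2 + (if (mod$selection) 2L else 0L) +
    (if (mod$binary) 1L else 2L) + (if (mod$robust) 1L else 0L)
  draws <- matrix(NA_real_, n_ret, npar)
  devs <- numeric(n_ret)
  row <- 0L; acc_post <- 0L; post_iters <- 0L

  for (j in seq_len(cfg$n_iter)) {
    if (!mod$binary) {
      pi1 <- sample_linear_coefs(W1, x, 1, s21, pr$b0, pr$B0)
      s21 <- sample_variance(x - drop(W1 %*% pi1), 1, pr$u0, pr$U0)
    } else {
      mh <- mh_logistic_stage1(pi1, W1, x, pr$b0, pr$B0,
                               init$prop_chol, log_scale,
                               adapt = j <= cfg$n_burnin, iter = j)
      pi1 <- mh$pi1; log_scale <- mh$log_scale
      if (j > cfg$n_burnin) {
        post_iters <- post_iters + 1L
        if (mh$accepted) acc_post <- acc_post + 1L
      }
    }
    eta1 <- drop(W1 %*% pi1)
    xhat <- if (mod$binary) stats::plogis(eta1) else eta1
    W2[, 2] <- xhat
    mu <- drop(W2 %*% pi2)

    if (nmis) {
      prop_sd <- if (mod$selection) stats::sd(y - mu) else NA_real_
      y[mis] <- impute_missing_y(y[mis], mu[mis], s22, omega[mis],
                                 selection = mod$selection, phi = phi,
                                 prop_sd = prop_sd)
    }
    if (mod$selection) {
      sel <- sample_selection(y, m, phi, pr$sel_loc, pr$sel_prec)
      phi <- sel$phi
    }

    r2 <- y - mu
    s22 <- sample_variance(r2, omega, pr$e0, pr$E0)
    if (mod$robust && mod$df_est)
      nu <- sample_df(omega, pr$df_lower, pr$df_upper, pr$grid_size)
    if (mod$robust)
      omega <- sample_t_weights(r2, s22, nu)
    pi2 <- sample_linear_coefs(W2, y, omega, s22, pr$g0, pr$G0)

    if (!all(is.finite(pi2)) || !is.finite(s22) || s22 <= 0) {
      if (cfg$debug)
        message("state at failure: s22=", s22,
                " pi2=", paste(signif(pi2, 6), collapse = " "))
      stop("non-finite sampler state at iteration ", j, call. = FALSE)
    }

    if (j > cfg$n_burnin && (j - cfg$n_burnin) %% cfg$thin == 0L) {
      row <- row + 1L
      mu_dev <- drop(W2 %*% pi2)
      ll <- if (!mod$binary) {
        sum(stats::dnorm(x, xhat, sqrt(s21), log = TRUE))
      } else {
        sum(x * eta1 - ifelse(eta1 > 0, eta1 + log1p(exp(-eta1)),
                              log1p(exp(eta1))))
      }
      obs <- m == 0L
      sd2 <- sqrt(s22)
      ll <- ll + if (mod$robust) {
        sum(stats::dt((y[obs] - mu_dev[obs]) / sd2, nu, log = TRUE) -
              log(sd2))
      } else {
        sum(stats::dnorm(y[obs], mu_dev[obs], sd2, log = TRUE))
      }
      devs[row] <- -2 * ll
      draws[row, ] <- c(pi1, pi2, if (mod$selection) phi,
                        if (!mod$binary) s21, s22, if (mod$robust) nu)
    }
  }
  list(draws = draws, deviance = devs,
       accept_rate = if (post_iters > 0) acc_post / post_iters else NA_real_,
       log_scale = log_scale)
}

#' @export
print.bivlate_fit <- function(x, ...) {
  cat("Bayesian two-stage IV fit: ", x$model$code, " (", x$model$name,
      ")\n", sep = "")
  cat("  ", x$config$n_chains, " chain(s), ", x$config$n_iter,
      " iterations (burn-in ", x$config$n_burnin, ", thin ",
      x$config$thin, "), ", nrow(x$draws[[1]]),
      " retained draws per chain\n", sep = "")
  cat("  parameters: ", paste(x$par_names, collapse = ", "), "\n", sep = "")
  if (!is.null(x$accept_rate))
    cat("  stage-1 Metropolis acceptance: ",
        paste(round(x$accept_rate, 3), collapse = ", "), "\n", sep = "")
  cat("Use summary() for posterior estimates.\n")
  invisible(x)
}

#' Run log of a fitted model
#'
#' Returns the resolved-settings log recorded by [fit_model()]: model code,
#' chain settings, seed, prior source and starting-value source.
#'
#' @param fit A `bivlate_fit`.
#' @return Character vector of log lines.
#' @export
run_log <- function(fit) {
  stopifnot(inherits(fit, "bivlate_fit"))
  fit$log
}
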