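#' Frequentist two-stage least squares
#'
#' Classical 2SLS used for Gibbs starting values and data-dependent priors:
#' stage one regresses the (continuous) treatment on `[1, Z]`; stage two
#' regresses the outcome on `[1, xhat, C]` where `xhat` are the stage-one
#' fitted values.  Stage two uses complete cases only (rows with missing
#' outcome dropped); the Gibbs sampler, not the initializer, handles
#' missingness.
#'
#' @param data An [iv_data()] object with a continuous treatment.
#' @return An object of class `two_stage_fit`: list with `stage1_coefs`,
#'   `stage1_ses`, `stage2_coefs`, `stage2_ses`, `stage1_sigma2`,
#'   `stage2_sigma2`, and `method = "2SLS"`.
#' @export
fit_2sls <- function(data) {
  stopifnot(inherits(data, "iv_data"))
  if (data$x_type != "continuous")
    stop("fit_2sls requires a continuous treatment; use fit_logit_stage1 ",
         "for a binary treatment", call. = FALSE)
  W1 <- .design1(data)
  s1 <- .ls_fit(W1, data$x, "stage 1")
  xhat <- drop(W1 %*% s1$coefs)
  obs <- data$m == 0L
  if (!any(obs)) stop("all outcome values are missing", call. = FALSE)
  W2 <- .design2(data, xhat)
  k2 <- ncol(W2)
  if (sum(obs) <= k2)
    stop("fewer complete cases (", sum(obs), ") than stage-2 parameters (",
         k2, ")", call. = FALSE)
  s2 <- .ls_fit(W2[obs, , drop = FALSE], data$y[obs], "stage 2")
  structure(
    list(stage1_coefs = s1$coefs, stage1_ses = s1$ses,
         stage2_coefs = s2$coefs, stage2_ses = s2$ses,
         stage1_sigma2 = s1$sigma2, stage2_sigma2 = s2$sigma2,
         method = "2SLS"),
    class = "two_stage_fit"
  )
}

# Least squares with classical SEs via the normal equations; rank-checked.
.ls_fit <- function(W, v, label) {
  qrW <- qr(W)
  if (qrW$rank < ncol(W))
    stop("weak/degenerate instrument: ", label,
         " design matrix is rank deficient", call. = FALSE)
  coefs <- qr.coef(qrW, v)
  resid <- v - drop(W %*% coefs)
  df <- length(v) - ncol(W)
  if (df <= 0) stop(label, ": no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrW))
  ses <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  list(coefs = unname(coefs), ses = unname(ses), sigma2 = sigma2)
}

#' Frequentist logistic first stage for a binary treatment
#'
#' Maximum-likelihood logistic regression of the treatment on `[1, Z]` (via
#' iteratively reweighted least squares), followed by a least-squares
#' stage-two initialization regressing the observed outcomes on
#' `[1, qhat, C]` where `qhat` are the fitted treatment probabilities.
#'
#' @param data An [iv_data()] object with a binary treatment.
#' @return A `two_stage_fit` with `method = "ML-logit"`; `stage1_sigma2` is
#'   `NA` (the Bernoulli stage has no free error variance).
#' @export
fit_logit_stage1 <- function(data) {
  stopifnot(inherits(data, "iv_data"))
  if (data$x_type != "binary")
    stop("fit_logit_stage1 requires a binary treatment", call. = FALSE)
  if (length(unique(data$x)) < 2L)
    stop("treatment has no variation", call. = FALSE)
  W1 <- .design1(data)
  fit <- suppressWarnings(
    stats::glm.fit(W1, data$x, family = stats::binomial())
  )
  coefs <- unname(fit$coefficients)
  if (anyNA(coefs))
    stop("weak/degenerate instrument: stage 1 design matrix is rank deficient",
         call. = FALSE)
  if (!fit$converged || any(abs(coefs) > 15))
    stop("complete separation detected in the logistic first stage; ",
         "consider informative stage-1 priors", call. = FALSE)
  w <- fit$weights
  info <- crossprod(W1 * sqrt(w))
  ses <- sqrt(diag(solve(info)))
  qhat <- drop(stats::plogis(W1 %*% coefs))
  obs <- data$m == 0L
  if (!any(obs)) stop("all outcome values are missing", call. = FALSE)
  W2 <- .design2(data, qhat)
  if (sum(obs) <= ncol(W2))
    stop("fewer complete cases (", sum(obs), ") than stage-2 parameters (",
         ncol(W2), ")", call. = FALSE)
  s2 <- .ls_fit(W2[obs, , drop = FALSE], data$y[obs], "stage 2")
  structure(
    list(stage1_coefs = coefs, stage1_ses = unname(ses),
         stage2_coefs = s2$coefs, stage2_ses = s2$ses,
         stage1_sigma2 = NA_real_, stage2_sigma2 = s2$sigma2,
         method = "ML-logit"),
    class = "two_stage_fit"
  )
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Frequentist two-stage fit (", x$method, ")\n", sep = "")
  cat("  stage 1:", paste(signif(x$stage1_coefs, 4), collapse = "  "), "\n")
  cat("  stage 2:", paste(signif(x$stage2_coefs, 4), collapse = "  "), "\n")
  invisible(x)
}

#' Data-dependent priors from a frequentist two-stage fit
#'
#' Builds the default priors of the Bayesian models: coefficient prior
#' locations equal the frequentist point estimates and prior precisions
#' equal `1 / (inflate * SE)^2`, so that with `inflate = 1` each prior
#' carries roughly the information of the frequentist fit.  Error-variance
#' priors stay at the weakly informative defaults.  Non-finite or zero SEs
#' trigger a fallback to the non-informative default prior with a warning.
#'
#' @param fit A [fit_2sls()] or [fit_logit_stage1()] result.
#' @param inflate Positive SD inflation factor; `inflate = 10` makes the
#'   priors 100 times less precise.
#' @return A `prior_spec` with `source = "data-dependent (<method>)"`.
#' @export
make_ddp_priors <- function(fit, inflate = 1) {
  stopifnot(inherits(fit, "two_stage_fit"), inflate > 0)
  ses <- c(fit$stage1_ses, fit$stage2_ses)
  est <- c(fit$stage1_coefs, fit$stage2_coefs)
  if (!all(is.finite(est)) || !all(is.finite(ses)) || any(ses <= 0)) {
    warning("non-finite or degenerate frequentist SEs; ",
            "falling back to non-informative priors", call. = FALSE)
    return(prior_spec())
  }
  prior <- prior_spec(
    b0 = fit$stage1_coefs, B0 = 1 / (inflate * fit$stage1_ses)^2,
    g0 = fit$stage2_coefs, G0 = 1 / (inflate * fit$stage2_ses)^2
  )
  prior$source <- paste0("data-dependent (", fit$method, ")")
  prior
}
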