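# Seeded generators with the statistical structure of the two tutorial
# settings: a continuous treatment with one instrument and five covariates
# (early-childhood reading achievement design) and a binary treatment from a
# logistic first stage with one binary instrument and two binary covariates
# (housing-voucher design).

#' Generation settings for synthetic two-stage IV data
#'
#' Defaults emulate the package's tutorial designs at unit scale: n = 600
#' rows; stage-1 coefficients `(0, 0.5)` on a single standard-normal
#' instrument (continuous) or `(-1, 2)` on a single Bernoulli(0.5)
#' instrument (binary); true LATE 0.5 (continuous) or 1.2 (binary); unit
#' error variances; endogeneity from a 0.6 correlation between the stage
#' errors.  `nu = Inf` gives normal stage-2 errors; a finite `nu` gives
#' Student-t errors of that df.
#'
#' @param n Number of rows.
#' @param treatment `"continuous"` or `"binary"`.
#' @param true_pi1 Stage-1 coefficients (intercept, instrument slopes).
#' @param true_pi2 Stage-2 coefficients (intercept, LATE, covariates).
#' @param sigma2_1 Stage-1 error variance (continuous treatment).
#' @param sigma2_2 Stage-2 error variance.
#' @param nu Stage-2 t degrees of freedom; `Inf` for normal errors.
#' @param confounding Correlation in (-1, 1) between the stage errors (for
#'   binary treatments, between the treatment shock and the outcome error),
#'   inducing the endogeneity that instruments correct.
#' @param n_covariates Number of covariates (continuous: standard normal;
#'   binary design: Bernoulli(0.5)).
#' @param outlier_frac,outlier_scale Fraction of observed outcomes shifted
#'   by `outlier_scale` outcome SDs (see [inject_outliers()]).
#' @param missing Missingness mechanism: `"none"`, `"MCAR"`, `"MAR"` or
#'   `"MNAR"` (see [impose_missingness()]).
#' @param missing_rate Target marginal missingness rate.
#' @param missing_slope Dependence strength of MAR/MNAR missingness (probit
#'   slope on the standardized driver variable).
#' @param seed Integer seed; every generator is a pure function of the spec.
#' @return An object of class `gen_spec`.
#' @export
gen_spec <- function(n = 600, treatment = c("continuous", "binary"),
                     true_pi1 = NULL, true_pi2 = NULL,
                     sigma2_1 = 1, sigma2_2 = 1, nu = Inf,
                     confounding = 0.6, n_covariates = NULL,
                     outlier_frac = 0, outlier_scale = 6,
                     missing = c("none", "MCAR", "MAR", "MNAR"),
                     missing_rate = 0.2, missing_slope = 0.8,
                     seed = 1L) {
  treatment <- match.arg(treatment)
  missing <- match.arg(missing)
  if (is.null(n_covariates))
    n_covariates <- if (treatment == "continuous") 5L else 2L
  if (is.null(true_pi1))
    true_pi1 <- if (treatment == "continuous") c(0, 0.5) else c(-1, 2)
  if (is.null(true_pi2)) {
    late <- if (treatment == "continuous") 0.5 else 1.2
    true_pi2 <- c(0, late, rep(0.3, n_covariates))
  }
  if (length(true_pi2) != 2L + n_covariates)
    stop("true_pi2 must have length 2 + n_covariates", call. = FALSE)
  if (length(true_pi1) < 2L)
    stop("true_pi1 needs an intercept and at least one instrument slope",
         call. = FALSE)
  stopifnot(abs(confounding) < 1, sigma2_1 > 0, sigma2_2 > 0, nu > 0,
            outlier_frac >= 0, outlier_frac < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(n = as.integer(n), treatment = treatment,
         true_pi1 = true_pi1, true_pi2 = true_pi2,
         sigma2_1 = sigma2_1, sigma2_2 = sigma2_2, nu = nu,
         confounding = confounding, n_covariates = as.integer(n_covariates),
         outlier_frac = outlier_frac, outlier_scale = outlier_scale,
         missing = missing, missing_rate = missing_rate,
         missing_slope = missing_slope, seed = as.integer(seed)),
    class = "gen_spec"
  )
}

# stage-2 error draws: normal or t via scale mixture, sharing a latent
# normal with the stage-1 shock so that corr(e1, e2 | scale) = confounding.
.correlated_errors <- function(n, rho, s1, s2, nu) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  e1 <- sqrt(s1) * z1
  e2 <- if (is.finite(nu)) {
    w <- stats::rgamma(n, nu / 2, rate = nu / 2)
    sqrt(s2) * z2 / sqrt(w)
  } else {
    sqrt(s2) * z2
  }
  list(e1 = e1, e2 = e2)
}

.gen_names <- function(p, J) {
  list(y = "y", x = "x",
       C = if (p) paste0("c", seq_len(p)) else character(0),
       Z = if (J == 1L) "z" else paste0("z", seq_len(J)))
}

.assemble_gen <- function(y, x, C, Z, spec, truth) {
  p <- ncol(C); J <- ncol(Z)
  nm <- .gen_names(p, J)
  tab <- data.frame(y = y, x = x)
  if (p) tab[nm$C] <- as.data.frame(C)
  tab[nm$Z] <- as.data.frame(Z)
  f <- paste0("y ~ x",
              if (p) paste0(" + ", paste(nm$C, collapse = " + ")) else "",
              " | ", paste(nm$Z, collapse = " + "))
  data <- iv_data(tab, f,
                  treatment_type = if (spec$treatment == "binary") "binary"
                                   else "continuous")
  if (spec$outlier_frac > 0)
    data <- inject_outliers(data, spec$outlier_frac, spec$outlier_scale)
  if (spec$missing != "none")
    data <- impose_missingness(data, spec$missing,
                               rate = spec$missing_rate,
                               slope = spec$missing_slope)
  list(data = data, truth = truth, table = tab)
}

#' Generate continuous-treatment IV data
#'
#' Structural generation following the two-stage model: instruments are
#' standard normal; the treatment is `x = pi10 + pi11' Z + e1`; the outcome
#' follows the structural equation `y = pi20 + LATE * x + C gamma + e2`
#' with `corr(e1, e2) = confounding`, so that naive OLS of y on x is biased
#' (the treatment is endogenous) while the instrument is clean.  Covariates
#' are independent standard normal.  Outliers and missingness, if
#' requested, are applied last.
#'
#' @param spec A [gen_spec()] with `treatment = "continuous"`.
#' @return List with `data` (an [iv_data()]), `truth` (generating
#'   parameters, including `late`), and `table` (the pre-missingness data
#'   frame).
#' @export
gen_continuous_iv <- function(spec) {
  stopifnot(inherits(spec, "gen_spec"), spec$treatment == "continuous")
  set.seed(spec$seed)
  n <- spec$n; p <- spec$n_covariates
  J <- length(spec$true_pi1) - 1L
  Z <- matrix(stats::rnorm(n * J), n, J)
  C <- matrix(stats::rnorm(n * p), n, p)
  err <- .correlated_errors(n, spec$confounding, spec$sigma2_1,
                            spec$sigma2_2, spec$nu)
  xs <- spec$true_pi1[1] + drop(Z %*% spec$true_pi1[-1])
  x <- xs + err$e1
  gamma <- spec$true_pi2[-(1:2)]
  y <- spec$true_pi2[1] + spec$true_pi2[2] * x +
    (if (p) drop(C %*% gamma) else 0) + err$e2
  truth <- list(pi1 = spec$true_pi1, pi2 = spec$true_pi2,
                late = spec$true_pi2[2], sigma2_1 = spec$sigma2_1,
                sigma2_2 = spec$sigma2_2, nu = spec$nu,
                confounding = spec$confounding, seed = spec$seed)
  .assemble_gen(y, x, C, Z, spec, truth)
}

#' Generate binary-treatment IV data
#'
#' Mirrors the generalized (logistic first stage) model: a single binary
#' instrument (Bernoulli(0.5)) by default, binary covariates, treatment
#' probability `q = plogis(pi10 + pi11' Z)`, treatment `x ~ Bernoulli(q)`,
#' and outcome `y = pi20 + LATE * q + C gamma + e` with normal or Student-t
#' error.  `confounding` adds `conf * sd(e) * (x - q)` to the outcome
#' error: a treatment shock correlated with the outcome (selection bias)
#' that is mean-zero given the instrument, so the IV structure still
#' identifies the LATE.
#'
#' @param spec A [gen_spec()] with `treatment = "binary"`.
#' @return List with `data`, `truth` and `table` as in
#'   [gen_continuous_iv()].
#' @export
gen_binary_iv <- function(spec) {
  stopifnot(inherits(spec, "gen_spec"), spec$treatment == "binary")
  set.seed(spec$seed)
  n <- spec$n; p <- spec$n_covariates
  J <- length(spec$true_pi1) - 1L
  Z <- matrix(stats::rbinom(n * J, 1L, 0.5), n, J)
  C <- matrix(stats::rbinom(n * p, 1L, 0.5), n, p)
  q <- stats::plogis(spec$true_pi1[1] + drop(Z %*% spec$true_pi1[-1]))
  x <- stats::rbinom(n, 1L, q)
  e <- if (is.finite(spec$nu)) {
    w <- stats::rgamma(n, spec$nu / 2, rate = spec$nu / 2)
    sqrt(spec$sigma2_2) * stats::rnorm(n) / sqrt(w)
  } else {
    sqrt(spec$sigma2_2) * stats::rnorm(n)
  }
  e <- e + spec$confounding * sqrt(spec$sigma2_2) * (x - q)
  gamma <- spec$true_pi2[-(1:2)]
  y <- spec$true_pi2[1] + spec$true_pi2[2] * q +
    (if (p) drop(C %*% gamma) else 0) + e
  truth <- list(pi1 = spec$true_pi1, pi2 = spec$true_pi2,
                late = spec$true_pi2[2], sigma2_2 = spec$sigma2_2,
                nu = spec$nu, confounding = spec$confounding,
                seed = spec$seed)
  .assemble_gen(y, x, C, Z, spec, truth)
}

#' Inject outliers into the observed outcomes
#'
#' Shifts a seeded random subset of `floor(frac * n)` observed (non-missing)
#' outcomes by `scale` times the observed-outcome SD, with random sign.
#' The affected row indices are recorded in the `outlier_rows` attribute
#' for test assertions.
#'
#' @param data An [iv_data()] object.
#' @param frac Fraction of rows to contaminate.
#' @param scale Shift size in observed-outcome SDs.
#' @return The modified `iv_data` with attribute `outlier_rows`.
#' @export
inject_outliers <- function(data, frac, scale = 6) {
  stopifnot(inherits(data, "iv_data"), frac >= 0, frac < 1, scale > 0)
  k <- floor(frac * data$n)
  if (k == 0L) {
    attr(data, "outlier_rows") <- integer(0)
    return(data)
  }
  obs <- which(data$m == 0L)
  if (k > length(obs)) stop("not enough observed outcomes to contaminate",
                            call. = FALSE)
  rows <- sort(sample(obs, k))
  s <- stats::sd(data$y[obs])
  signs <- ifelse(stats::runif(k) < 0.5, -1, 1)
  data$y[rows] <- data$y[rows] + signs * scale * s
  attr(data, "outlier_rows") <- rows
  data
}

#' Impose outcome missingness
#'
#' Replaces outcome values by `NA` under one of three mechanisms.  MCAR:
#' each outcome missing independently with probability `rate`.  MAR:
#' missingness probit on the (standardized) treatment with slope `slope`.
#' MNAR: missingness probit on the (standardized) outcome itself — the
#' mechanism the selection-layer models are built for.  For MAR/MNAR the
#' probit intercept is set to `sqrt(1 + slope^2) * qnorm(rate)` so the
#' marginal missingness rate is approximately `rate`.
#'
#' @param data An [iv_data()] object with a fully observed outcome.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param rate Target marginal missingness rate.
#' @param slope Probit slope on the standardized driver (MAR/MNAR).
#' @return The modified `iv_data`, with attribute `missing_truth` recording
#'   the mechanism and probit coefficients used.
#' @export
impose_missingness <- function(data, mechanism = c("MCAR", "MAR", "MNAR"),
                               rate = 0.2, slope = 0.8) {
  stopifnot(inherits(data, "iv_data"), rate >= 0, rate < 1)
  mechanism <- match.arg(mechanism)
  if (any(data$m == 1L))
    stop("outcome already contains missing values", call. = FALSE)
  if (rate == 0) {
    attr(data, "missing_truth") <- list(mechanism = mechanism, rate = 0)
    return(data)
  }
  n <- data$n
  if (mechanism == "MCAR") {
    miss <- stats::runif(n) < rate
    coefs <- c(stats::qnorm(rate), 0)
  } else {
    driver <- if (mechanism == "MNAR") data$y else data$x
    zd <- (driver - mean(driver)) / stats::sd(driver)
    a <- sqrt(1 + slope^2) * stats::qnorm(rate)
    pmiss <- stats::pnorm(a + slope * zd)
    miss <- stats::runif(n) < pmiss
    coefs <- c(a, slope)
  }
  data$y[miss] <- NA_real_
  data$m <- as.integer(miss)
  attr(data, "missing_truth") <- list(mechanism = mechanism, rate = rate,
                                      probit_coefs = coefs)
  data
}
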