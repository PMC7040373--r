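# Posterior summarization, convergence diagnostics, DIC and trace export.

#' Summarize a fitted model
#'
#' Posterior mean (`Est.`), posterior SD (reported as `S.E.`, the Bayesian
#' reporting convention), and equal-tailed 95% credible interval (`CI.L`,
#' `CI.U`) per parameter, computed on the post-burn-in draws pooled across
#' chains, in the standard row order (stage-1 coefficients, stage-2
#' intercept, LATE, covariate coefficients, selection coefficients,
#' variances, t degrees of freedom).  DIC, the effective number of
#' parameters pD, per-parameter Geweke z-scores and (with two or more
#' chains) potential scale reduction factors are attached.
#'
#' @param object A `bivlate_fit`.
#' @param ... Unused.
#' @return An object of class `summary.bivlate_fit`: a data frame with
#'   columns `Est.`, `S.E.`, `CI.L`, `CI.U` and attributes `DIC`, `pD`,
#'   `geweke_z`, `rhat`, `model`.
#' @export
summary.bivlate_fit <- function(object, ...) {
  pooled <- do.call(rbind, object$draws)
  if (nrow(pooled) == 0L) stop("no retained draws", call. = FALSE)
  est <- colMeans(pooled)
  sds <- apply(pooled, 2, stats::sd)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  if (any(sds == 0))
    warning("degenerate chain: some parameters have zero posterior SD",
            call. = FALSE)
  tab <- data.frame(`Est.` = est, `S.E.` = sds,
                    CI.L = qs[1, ], CI.U = qs[2, ],
                    row.names = object$par_names, check.names = FALSE)
  dic_res <- tryCatch(dic(object), error = function(e) list(DIC = NA_real_,
                                                            pD = NA_real_))
  gz <- vapply(seq_along(object$par_names), function(i) {
    tryCatch(geweke(object$draws[[1]][, i]), error = function(e) NA_real_)
  }, numeric(1))
  names(gz) <- object$par_names
  rh <- if (object$config$n_chains >= 2L) {
    vapply(object$par_names, function(pn) rhat(object, pn), numeric(1))
  } else NULL
  structure(tab, DIC = dic_res$DIC, pD = dic_res$pD, geweke_z = gz,
            rhat = rh, model = object$model$code,
            class = c("summary.bivlate_fit", "data.frame"))
}

#' @export
print.summary.bivlate_fit <- function(x, digits = 4, ...) {
  cat("Posterior summary (model ", attr(x, "model"), ")\n", sep = "")
  print.data.frame(round(as.data.frame(x), digits))
  cat(sprintf("\nDIC: %.2f   pD: %.2f\n", attr(x, "DIC"), attr(x, "pD")))
  rh <- attr(x, "rhat")
  if (!is.null(rh))
    cat("max Rhat:", round(max(rh), 4), "\n")
  invisible(x)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain against the mean of
#' the last `frac2`, standardized by spectral-density-at-zero variance
#' estimates of each segment computed by non-overlapping batch means.
#' Values within roughly two in absolute value are consistent with
#' stationarity.
#'
#' @param chain Numeric vector of draws for one parameter.
#' @param frac1 Leading fraction (default 0.1).
#' @param frac2 Trailing fraction (default 0.5).
#' @param n_batches Batches per segment for the variance estimate.
#' @return The z-score (scalar).
#' @export
geweke <- function(chain, frac1 = 0.1, frac2 = 0.5, n_batches = 20L) {
  n <- length(chain)
  if (n < 200L) stop("chain too short for the Geweke diagnostic (need >= 200)",
                     call. = FALSE)
  stopifnot(frac1 > 0, frac2 > 0, frac1 + frac2 <= 1)
  a <- chain[seq_len(floor(frac1 * n))]
  b <- chain[seq.int(n - floor(frac2 * n) + 1L, n)]
  va <- .batch_means_var(a, n_batches)
  vb <- .batch_means_var(b, n_batches)
  denom <- sqrt(va / length(a) + vb / length(b))
  if (!is.finite(denom) || denom == 0)
    stop("zero-variance chain segment: Geweke z undefined", call. = FALSE)
  (mean(a) - mean(b)) / denom
}

# Long-run variance via non-overlapping batch means (spectral density at
# frequency zero times 2*pi, per-draw scale).
.batch_means_var <- function(x, n_batches) {
  b <- floor(length(x) / n_batches)
  if (b < 1L) stop("segment too short for batch means", call. = FALSE)
  x <- x[seq_len(b * n_batches)]
  bm <- colMeans(matrix(x, nrow = b))
  stats::var(bm) * b
}

#' Potential scale reduction factor (Rhat)
#'
#' Classical between/within-chain variance ratio on post-burn-in draws:
#' `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the chain means times
#' `n`.  Requires at least two chains.
#'
#' @param fit A `bivlate_fit` run with `n_chains >= 2`.
#' @param parameter Parameter name (one of `fit$par_names`).
#' @return Scalar Rhat (>= sqrt((n-1)/n)).
#' @export
rhat <- function(fit, parameter) {
  stopifnot(inherits(fit, "bivlate_fit"))
  if (length(fit$draws) < 2L)
    stop("Rhat requires at least two chains; rerun with ",
         "mcmc_config(n_chains = 2) or more", call. = FALSE)
  i <- match(parameter, fit$par_names)
  if (is.na(i)) stop("unknown parameter: ", parameter, call. = FALSE)
  chains <- lapply(fit$draws, function(d) d[, i])
  n <- length(chains[[1]])
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the mean of the per-iteration deviances
#' recorded during sampling and `pD = Dbar - Dhat`, where `Dhat` is the
#' deviance at the posterior mean of the parameters.  The deviance is minus
#' twice the joint observed-data log-likelihood of the treatment (stage
#' one) and the observed outcomes (stage two), with the latent weights and
#' imputations marginalized via the t/normal observed-data density, so that
#' DIC is comparable across all eight models.
#'
#' @param fit A `bivlate_fit`.
#' @return List with elements `DIC`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bivlate_fit"))
  devs <- unlist(fit$deviance)
  if (!length(devs)) stop("no recorded deviance draws", call. = FALSE)
  if (is.null(fit$data)) stop("fit carries no dataset", call. = FALSE)
  Dbar <- mean(devs)
  pooled <- do.call(rbind, fit$draws)
  est <- colMeans(pooled)
  Dhat <- .deviance_at(fit, est)
  if (!is.finite(Dhat)) stop("deviance at the posterior mean is not finite",
                             call. = FALSE)
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

# Observed-data deviance at a named parameter vector (posterior mean).
.deviance_at <- function(fit, est) {
  data <- fit$data; spec <- fit$model
  k1 <- 1L + ncol(data$Z)
  k2 <- 2L + ncol(data$C)
  pi1 <- est[seq_len(k1)]
  pi2 <- est[k1 + seq_len(k2)]
  s22 <- est[["stage2.variance"]]
  W1 <- .design1(data)
  eta1 <- drop(W1 %*% pi1)
  if (spec$treatment == "binary") {
    ll <- sum(data$x * eta1 - ifelse(eta1 > 0, eta1 + log1p(exp(-eta1)),
                                     log1p(exp(eta1))))
    xhat <- stats::plogis(eta1)
  } else {
    s21 <- est[["stage1.variance"]]
    ll <- sum(stats::dnorm(data$x, eta1, sqrt(s21), log = TRUE))
    xhat <- eta1
  }
  mu <- drop(.design2(data, xhat) %*% pi2)
  obs <- data$m == 0L
  sd2 <- sqrt(s22)
  ll <- ll + if (spec$robust) {
    nu <- est[["df.est"]]
    sum(stats::dt((data$y[obs] - mu[obs]) / sd2, nu, log = TRUE) - log(sd2))
  } else {
    sum(stats::dnorm(data$y[obs], mu[obs], sd2, log = TRUE))
  }
  -2 * ll
}

#' Export chain traces and a run manifest
#'
#' Writes one delimited file per chain (`trace_chain<k>.csv`, with an
#' `iteration` column, one column per parameter, and the recorded
#' deviance) plus a JSON manifest (`manifest.json`) recording the model
#' code, seed, chain settings and parameter names.  The files round-trip
#' losslessly through [read_traces()].
#'
#' @param fit A `bivlate_fit`.
#' @param path Directory to write into (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_traces <- function(fit, path) {
  stopifnot(inherits(fit, "bivlate_fit"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create trace directory: ", path,
                              call. = FALSE)
  files <- character(0)
  for (ch in seq_along(fit$draws)) {
    d <- fit$draws[[ch]]
    tab <- data.frame(iteration = seq_len(nrow(d)), d,
                      deviance = fit$deviance[[ch]], check.names = FALSE)
    f <- file.path(path, sprintf("trace_chain%d.csv", ch))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(model = fit$model$code, model_name = fit$model$name,
                   seed = fit$config$seed,
                   n_chains = fit$config$n_chains,
                   n_iter = fit$config$n_iter,
                   n_burnin = fit$config$n_burnin,
                   thin = fit$config$thin,
                   parameters = fit$par_names)
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read exported traces back
#'
#' @param path Directory written by [export_traces()].
#' @return List with `draws` (list of matrices), `deviance` (list of
#'   vectors) and `manifest`.
#' @export
read_traces <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  draws <- list(); devs <- list()
  for (ch in seq_len(manifest$n_chains)) {
    tab <- utils::read.csv(file.path(path, sprintf("trace_chain%d.csv", ch)),
                           check.names = FALSE)
    devs[[ch]] <- tab$deviance
    draws[[ch]] <- as.matrix(tab[, manifest$parameters, drop = FALSE])
  }
  list(draws = draws, deviance = devs, manifest = manifest)
}
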