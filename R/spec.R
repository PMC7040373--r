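.MODEL_TABLE <- data.frame(
  code      = paste0("M", 1:8),
  name      = c("cont-normal", "cont-robust", "cat-normal", "cat-robust",
                "cont-normal-selection", "cont-robust-selection",
                "cat-normal-selection", "cat-robust-selection"),
  treatment = rep(c("continuous", "continuous", "binary", "binary"), 2),
  family    = rep(c("normal", "student_t"), 4),
  selection = rep(c(FALSE, TRUE), each = 4),
  stringsAsFactors = FALSE
)

#' Model taxonomy
#'
#' Returns the taxonomy mapping model codes M1-M8 onto the crossing of
#' treatment type (continuous/binary), stage-two error family
#' (normal/Student-t) and presence of the probit selection layer for
#' non-ignorably missing outcomes.
#'
#' @return A data frame with columns `code`, `name`, `treatment`, `family`,
#'   `selection`.
#' @export
model_taxonomy <- function() .MODEL_TABLE

#' Specify one of the eight two-stage causal models
#'
#' A model is identified either by code (`"M1"`..`"M8"`), by name
#' (`"cont-robust"`, `"cat-normal-selection"`, ...), or by its three axes.
#'
#' @param model Model code or name; overrides the axis arguments if given.
#' @param treatment `"continuous"` or `"binary"`.
#' @param family Stage-two error family, `"normal"` or `"student_t"`.
#' @param selection Logical; add the probit selection layer (MNAR outcomes)?
#' @param df Either `"estimate"` (uniform prior on the t degrees of freedom,
#'   sampled by griddy Gibbs) or a fixed numeric value > 2.  Ignored for
#'   normal-family models.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = NULL,
                       treatment = c("continuous", "binary"),
                       family = c("normal", "student_t"),
                       selection = FALSE,
                       df = "estimate") {
  tab <- .MODEL_TABLE
  if (!is.null(model)) {
    i <- match(model, tab$code)
    if (is.na(i)) i <- match(model, tab$name)
    if (is.na(i))
      stop("unknown model `", model, "`; use one of ",
           paste(tab$code, collapse = ", "), " or ",
           paste(tab$name, collapse = ", "), call. = FALSE)
    treatment <- tab$treatment[i]; family <- tab$family[i]
    selection <- tab$selection[i]
  } else {
    treatment <- match.arg(treatment)
    family <- match.arg(family)
  }
  df_fixed <- NA_real_
  if (!identical(df, "estimate")) {
    df_fixed <- as.double(df)
    if (!is.finite(df_fixed) || df_fixed <= 2)
      stop("fixed df must be a finite value > 2", call. = FALSE)
  }
  code <- tab$code[tab$treatment == treatment & tab$family == family &
                   tab$selection == selection]
  structure(
    list(code = code,
         name = tab$name[tab$code == code],
         treatment = treatment, family = family, selection = selection,
         robust = family == "student_t",
         df_mode = if (is.na(df_fixed)) "estimate" else "fixed",
         df_fixed = df_fixed),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model ", x$code, " (", x$name, "): ", x$treatment, " treatment, ",
      x$family, " stage-2 errors",
      if (x$selection) ", probit selection layer" else "", "\n", sep = "")
  if (x$robust && x$df_mode == "fixed")
    cat("  t degrees of freedom fixed at ", x$df_fixed, "\n", sep = "")
  invisible(x)
}

#' Prior specification for the two-stage model
#'
#' Normal priors on the regression coefficients of both stages
#' (location/precision pairs `b0`/`B0` for stage one, `g0`/`G0` for stage
#' two), inverse-gamma priors on the stage error variances (shape/scale
#' `u0`/`U0` and `e0`/`E0`), a uniform prior on the Student-t degrees of
#' freedom, and normal priors on the selection-layer coefficients.
#' Coefficient hyperparameters may be scalars (broadcast to all
#' coefficients of that stage) or vectors matching the coefficient count:
#' `1 + J` for stage one and `2 + p` for stage two (intercept, treatment
#' effect, covariates).
#'
#' @param b0,B0 Stage-one coefficient prior location and precision.
#' @param g0,G0 Stage-two coefficient prior location and precision.
#' @param u0,U0 Stage-one error-variance inverse-gamma shape and scale.
#' @param e0,E0 Stage-two error-variance inverse-gamma shape and scale.
#' @param df_lower,df_upper Support of the uniform prior on the t degrees of
#'   freedom.  The default lower bound 2.01 keeps the t variance finite; it
#'   may be lowered towards 0.
#' @param sel_loc,sel_prec Location and precision for the two selection
#'   coefficients (intercept, outcome slope).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(b0 = 0, B0 = 1e-6, g0 = 0, G0 = 1e-6,
                       u0 = 0.001, U0 = 0.001, e0 = 0.001, E0 = 0.001,
                       df_lower = 2.01, df_upper = 100,
                       sel_loc = 0, sel_prec = 0.01) {
  stopifnot(all(B0 > 0), all(G0 > 0), u0 > 0, U0 > 0, e0 > 0, E0 > 0,
            all(sel_prec > 0))
  if (!(df_lower >= 0 && df_lower < df_upper))
    stop("df prior requires 0 <= df_lower < df_upper", call. = FALSE)
  structure(
    list(b0 = b0, B0 = B0, g0 = g0, G0 = G0,
         u0 = u0, U0 = U0, e0 = e0, E0 = E0,
         df_lower = df_lower, df_upper = df_upper,
         sel_loc = sel_loc, sel_prec = sel_prec,
         source = "user"),
    class = "prior_spec"
  )
}

# Broadcast scalar coefficient hyperparameters to the stage dimensions and
# check vector lengths (k1 = 1 + J, k2 = 2 + p).
.resolve_prior <- function(prior, k1, k2) {
  bc <- function(v, k, what) {
    if (length(v) == 1L) rep(as.double(v), k)
    else if (length(v) == k) as.double(v)
    else stop("prior `", what, "` has length ", length(v),
              " but ", k, " coefficients are expected", call. = FALSE)
  }
  prior$b0 <- bc(prior$b0, k1, "b0"); prior$B0 <- bc(prior$B0, k1, "B0")
  prior$g0 <- bc(prior$g0, k2, "g0"); prior$G0 <- bc(prior$G0, k2, "G0")
  prior$sel_loc <- bc(prior$sel_loc, 2L, "sel_loc")
  prior$sel_prec <- bc(prior$sel_prec, 2L, "sel_prec")
  prior
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Two-stage model priors (", x$source, ")\n", sep = "")
  cat("  stage 1 coefs:  N(b0, 1/B0), b0 = ",
      paste(signif(x$b0, 4), collapse = ", "),
      "; B0 = ", paste(signif(x$B0, 4), collapse = ", "), "\n", sep = "")
  cat("  stage 2 coefs:  N(g0, 1/G0), g0 = ",
      paste(signif(x$g0, 4), collapse = ", "),
      "; G0 = ", paste(signif(x$G0, 4), collapse = ", "), "\n", sep = "")
  cat("  variances:      IG(", x$u0, ", ", x$U0, ") / IG(",
      x$e0, ", ", x$E0, ")\n", sep = "")
  cat("  t df:           Uniform(", x$df_lower, ", ", x$df_upper, "]\n",
      sep = "")
  invisible(x)
}

#' MCMC configuration
#'
#' Chain settings for [fit_model()].  Defaults follow the package
#' conventions: a single chain, thinning rate 1, burn-in equal to half the
#' iterations, and 10,000 total iterations for non-selection models or
#' 50,000 for selection models (resolved at fit time when `n_iter` is
#' `NULL`).
#'
#' @param n_chains Number of Markov chains (default 1).
#' @param n_iter Total iterations per chain; `NULL` resolves to the
#'   model-dependent default.
#' @param n_burnin Iterations discarded from the front of each chain;
#'   `NULL` resolves to `n_iter / 2`.
#' @param thin Keep-every-`thin` thinning rate (default 1).
#' @param seed Integer RNG seed.
#' @param inits Optional list of initial parameter states, one per chain.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 1L, n_iter = NULL, n_burnin = NULL,
                        thin = 1L, seed = 1L, inits = NULL) {
  stopifnot(n_chains >= 1L, thin >= 1L)
  structure(
    list(n_chains = as.integer(n_chains),
         n_iter = if (is.null(n_iter)) NULL else as.integer(n_iter),
         n_burnin = if (is.null(n_burnin)) NULL else as.integer(n_burnin),
         thin = as.integer(thin), seed = as.integer(seed), inits = inits),
    class = "mcmc_config"
  )
}

# Fill model-dependent defaults and validate retained-draw count.
.resolve_config <- function(config, selection) {
  if (is.null(config$n_iter))
    config$n_iter <- if (selection) 50000L else 10000L
  if (is.null(config$n_burnin))
    config$n_burnin <- config$n_iter %/% 2L
  if (config$n_burnin >= config$n_iter)
    stop("n_burnin must be smaller than n_iter", call. = FALSE)
  config$n_retained <- (config$n_iter - config$n_burnin) %/% config$thin
  if (config$n_retained < 100L)
    stop("fewer than 100 retained draws per chain; increase n_iter or ",
         "reduce thinning", call. = FALSE)
  config
}
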