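test_that("compiled and pure-R drivers produce identical chains", {
  cfg <- mcmc_config(n_iter = 300, n_burnin = 100, seed = 99)
  cases <- list(
    list(gen = cont_data(100, seed = 1), models = c("M1", "M2")),
    list(gen = cont_data(100, seed = 2, missing = "MNAR"),
         models = c("M5", "M6")),
    list(gen = bin_data(120, seed = 3), models = c("M3", "M4")),
    list(gen = bin_data(120, seed = 4, missing = "MNAR"),
         models = c("M7", "M8")))
  for (case in cases) {
    for (mdl in case$models) {
      fc <- fit_model(case$gen$data, mdl, config = cfg, engine = "cpp")
      fr <- fit_model(case$gen$data, mdl, config = cfg, engine = "r")
      expect_equal(fc$draws[[1]], fr$draws[[1]], tolerance = 1e-8,
                   info = mdl)
      expect_equal(fc$deviance[[1]], fr$deviance[[1]], tolerance = 1e-8,
                   info = mdl)
    }
  }
})

test_that("identical seeds reproduce chains exactly; seeds matter", {
  gen <- cont_data(100, seed = 5)
  cfg <- mcmc_config(n_iter = 400, n_burnin = 200, seed = 7)
  f1 <- fit_model(gen$data, "M2", config = cfg)
  f2 <- fit_model(gen$data, "M2", config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_model(gen$data, "M2", config = mcmc_config(n_iter = 400,
                                                       n_burnin = 200,
                                                       seed = 8))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("model taxonomy maps codes bijectively and guards data suitability", {
  tab <- model_taxonomy()
  expect_equal(nrow(tab), 8)
  expect_equal(anyDuplicated(tab[, c("treatment", "family", "selection")]), 0)
  expect_equal(model_spec("cont-robust")$code, "M2")
  expect_equal(model_spec(treatment = "binary", family = "student_t",
                          selection = TRUE)$code, "M8")
  expect_error(model_spec("M9"), "unknown model")

  gen <- cont_data(100, seed = 6)          # complete outcome
  expect_error(fit_model(gen$data, "M5"), "fully observed")
  expect_error(fit_model(gen$data, "M3"), "binary")
  genb <- bin_data(120, seed = 6)
  expect_error(fit_model(genb$data, "M1"), "continuous")
})

test_that("robust models expose df.est; normal models warn on extreme outliers", {
  cfg <- mcmc_config(n_iter = 300, n_burnin = 100, seed = 1)
  gen <- cont_data(100, seed = 7)
  f1 <- fit_model(gen$data, "M1", config = cfg)
  f2 <- fit_model(gen$data, "M2", config = cfg)
  expect_false("df.est" %in% f1$par_names)
  expect_true("df.est" %in% f2$par_names)
  expect_true(all(f2$draws[[1]][, "df.est"] > 2.01 &
                  f2$draws[[1]][, "df.est"] <= 100))
  expect_true(all(f2$draws[[1]][, "stage2.variance"] > 0))

  genx <- cont_data(300, seed = 8, outlier_frac = 0.03, outlier_scale = 8)
  expect_warning(fit_model(genx$data, "M1", config = cfg), "6 SDs")
})

test_that("initialization uses frequentist estimates, probit missing rate, jitter", {
  gen <- cont_data(600, seed = 9, missing = "MCAR", missing_rate = 0.2)
  freq <- fit_2sls(gen$data)
  set.seed(1)
  st <- initialize_state(gen$data, model_spec("M5"), freq)
  expect_equal(st$pi1, freq$stage1_coefs)
  expect_equal(st$pi2, freq$stage2_coefs)
  expect_equal(st$nu, 30)
  expect_equal(st$omega, rep(1, gen$data$n))
  rate <- mean(gen$data$m)
  expect_equal(st$phi, c(stats::qnorm(rate), 0))
  expect_equal(length(st$y_mis), sum(gen$data$m))

  set.seed(1)
  st1 <- initialize_state(gen$data, model_spec("M5"), freq)
  expect_identical(st, st1)

  set.seed(2)
  st2 <- initialize_state(gen$data, model_spec("M5"), freq, chain = 2L)
  expect_false(identical(st2$pi2, freq$stage2_coefs))

  init <- list(pi1 = c(0, 0.5), pi2 = rep(0.1, 7), s21 = 1, s22 = 1,
               nu = 10, omega = rep(1, gen$data$n),
               y_mis = rep(0, sum(gen$data$m)), phi = c(0, 0))
  stu <- initialize_state(gen$data, model_spec("M5"), freq,
                          user_init = init)
  expect_equal(stu$pi2, rep(0.1, 7))
})

test_that("a rounded missing rate of 20% starts the selection intercept at its probit", {
  expect_equal(stats::qnorm(0.20), -0.8416, tolerance = 1e-4)
})

test_that("M2 posterior means are invariant to permuting the Gibbs scan order", {
  # systematic-scan validity: an alternative update order (stage-2 coefs
  # first, then weights, df, variances, stage 1) must give the same
  # stationary distribution on a small fixture
  gen <- cont_data(30, seed = 10, nu = 5, n_covariates = 0,
                   true_pi2 = c(0, 0.5))
  d <- gen$data
  prior <- make_ddp_priors(fit_2sls(d))
  pr <- bivlate:::.resolve_prior(prior, 2, 2)
  f_ref <- fit_model(d, "M2", config = mcmc_config(n_iter = 30000,
                                                   n_burnin = 5000,
                                                   seed = 11))
  ref <- f_ref$draws[[1]][, "LATE"]

  set.seed(12)
  W1 <- cbind(1, d$Z)
  freq <- fit_2sls(d)
  pi1 <- freq$stage1_coefs; pi2 <- freq$stage2_coefs
  s21 <- freq$stage1_sigma2; s22 <- freq$stage2_sigma2
  nu <- 30; omega <- rep(1, d$n)
  keep <- numeric(25000)
  for (j in 1:30000) {
    W2 <- cbind(1, drop(W1 %*% pi1))
    pi2 <- sample_linear_coefs(W2, d$y, omega, s22, pr$g0, pr$G0)
    r2 <- d$y - drop(W2 %*% pi2)
    omega <- sample_t_weights(r2, s22, nu)
    nu <- sample_df(omega, pr$df_lower, pr$df_upper)
    s22 <- sample_variance(r2, omega, pr$e0, pr$E0)
    s21 <- sample_variance(d$x - drop(W1 %*% pi1), 1, pr$u0, pr$U0)
    pi1 <- sample_linear_coefs(W1, d$x, 1, s21, pr$b0, pr$B0)
    if (j > 5000) keep[j - 5000] <- pi2[2]
  }
  tol <- 4 * sqrt(mcse(ref)^2 + mcse(keep)^2) + 0.01
  expect_lt(abs(mean(ref) - mean(keep)), tol)
  expect_lt(abs(stats::sd(ref) - stats::sd(keep)),
            0.1 * stats::sd(ref) + 0.01)
})

test_that("stage-1 Metropolis acceptance settles in a healthy band", {
  genb <- bin_data(500, seed = 13)
  f <- fit_model(genb$data, "M3", config = mcmc_config(n_iter = 4000,
                                                       n_burnin = 2000,
                                                       seed = 13))
  expect_gt(f$accept_rate, 0.1)
  expect_lt(f$accept_rate, 0.5)
})

test_that("M2 on normal data agrees with M1 and pushes the df high", {
  gen <- cont_data(500, seed = 14)         # normal errors (nu = Inf)
  cfg <- mcmc_config(n_iter = 6000, n_burnin = 3000, seed = 14)
  f1 <- fit_model(gen$data, "M1", config = cfg)
  f2 <- fit_model(gen$data, "M2", config = cfg)
  l1 <- f1$draws[[1]][, "LATE"]; l2 <- f2$draws[[1]][, "LATE"]
  expect_lt(abs(mean(l1) - mean(l2)),
            3 * sqrt(mcse(l1)^2 + mcse(l2)^2) + 0.005)
  expect_gt(stats::median(f2$draws[[1]][, "df.est"]), 10)
})

test_that("fixed-df robust models hold the df constant", {
  gen <- cont_data(100, seed = 15, nu = 5)
  f <- fit_model(gen$data, model_spec("M2", df = 5),
                 config = mcmc_config(n_iter = 300, n_burnin = 100,
                                      seed = 1))
  expect_true(all(f$draws[[1]][, "df.est"] == 5))
})

test_that("summary rows follow the standard report order", {
  gen <- gen_continuous_iv(gen_spec(n = 200, seed = 16, n_covariates = 2,
                                    true_pi2 = c(0, 0.5, 0.3, 0.3)))
  f <- fit_model(gen$data, "M1", config = mcmc_config(n_iter = 300,
                                                      n_burnin = 100,
                                                      seed = 1))
  expect_equal(f$par_names,
               c("stage1.intercept", "stage1.slope", "stage2.intercept",
                 "LATE", "c1.coefficient", "c2.coefficient",
                 "stage1.variance", "stage2.variance"))
})
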