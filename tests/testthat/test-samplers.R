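# Each conditional sampler is checked against an independent oracle of its
# stated density: grid quadrature for the 1-2 dimensional cases, closed
# forms where the conditional is a named distribution.

test_that("coefficient draws collapse to the prior when the prior dominates", {
  set.seed(1)
  X <- cbind(1, rnorm(20))
  y <- rnorm(20)
  d <- replicate(20, sample_linear_coefs(X, y, 1, 1, c(1, 2), c(1e12, 1e12)))
  expect_true(all(abs(d[1, ] - 1) < 1e-4))
  expect_true(all(abs(d[2, ] - 2) < 1e-4))
})

test_that("flat-prior coefficient draws center on the least-squares solution", {
  set.seed(2)
  X <- cbind(1, rnorm(30))
  y <- 1 + 2 * X[, 2] + rnorm(30)
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  d <- replicate(1e5, sample_linear_coefs(X, y, 1, 1, c(0, 0), c(1e-12, 1e-12)))
  for (k in 1:2) {
    mc_se <- sd(d[k, ]) / sqrt(ncol(d))
    expect_lt(abs(mean(d[k, ]) - ols[k]), 3 * mc_se)
  }
})

test_that("one-dimensional coefficient posterior matches a quadrature oracle", {
  w <- 2; yv <- 3; s2 <- 1.5; loc <- 0.5; prec <- 0.8
  grid <- seq(-4, 6, length.out = 2e5)
  lk <- stats::dnorm(yv, w * grid, sqrt(s2), log = TRUE) +
    stats::dnorm(grid, loc, 1 / sqrt(prec), log = TRUE)
  pk <- exp(lk - max(lk)); pk <- pk / sum(pk)
  q_mean <- sum(grid * pk)
  q_var <- sum((grid - q_mean)^2 * pk)

  set.seed(3)
  d <- replicate(2e5, sample_linear_coefs(matrix(w), yv, 1, s2, loc, prec))
  expect_lt(abs(mean(d) - q_mean), 0.01 * abs(q_mean))
  expect_lt(abs(stats::var(d) - q_var), 0.05 * q_var)
})

test_that("variance draws follow the inverse-gamma conditional", {
  set.seed(4)
  # zero residuals, n = 4: posterior IG(3 + 2, 2), mean 2/(5-1) = 0.5
  d <- replicate(2e5, sample_variance(rep(0, 4), 1, 3, 2))
  expect_lt(abs(mean(d) - 0.5), 0.01 * 0.5)
  ig_var <- 2^2 / ((5 - 1)^2 * (5 - 2))
  expect_lt(abs(stats::var(d) - ig_var), 0.05 * ig_var)

  # n = 0 draws from the prior IG(shape0, scale0)
  d0 <- replicate(2e4, sample_variance(numeric(0), numeric(0), 4, 3))
  expect_lt(abs(mean(d0) - 1), 0.05)       # prior mean 3/(4-1) = 1

  # doubling weights == quartering residuals^2 (identical posteriors)
  r <- c(0.5, -1.2, 0.8)
  set.seed(9); a <- sample_variance(r, 2, 3, 2)
  set.seed(9); b <- sample_variance(r * sqrt(2), 1, 3, 2)
  expect_equal(a, b)

  expect_error(sample_variance(r, c(1, -1, 1), 3, 2), "positive")
})

test_that("t-weight draws follow the scale-mixture gamma conditional", {
  set.seed(5)
  # zero residual, nu = 5: Gamma(3, rate 2.5), mean (nu+1)/nu = 1.2
  d <- sample_t_weights(rep(0, 1e5), sigma2 = 1, nu = 5)
  expect_lt(abs(mean(d) - 1.2), 0.01 * 1.2)
  g_var <- 3 / 2.5^2
  expect_lt(abs(stats::var(d) - g_var), 0.05 * g_var)

  # normal limit: enormous df pins the weights at 1
  d2 <- sample_t_weights(rep(0.5, 1e4), sigma2 = 1, nu = 1e6)
  expect_lt(abs(mean(d2) - 1), 0.01)

  # larger residuals are stochastically downweighted
  meds <- vapply(c(0, 1, 2, 4, 8), function(r)
    stats::median(sample_t_weights(rep(r, 2e4), 1, 5)), numeric(1))
  expect_true(all(diff(meds) < 0))

  expect_error(sample_t_weights(1, 1, nu = -1), "positive")
})

test_that("griddy df draws match a fine quadrature of the kernel", {
  set.seed(6)
  omega <- rgamma(50, 2, rate = 2)         # weights generated at nu = 4
  lo <- 2.01; hi <- 100
  grid <- seq(lo, hi, length.out = 1e5)
  lk <- bivlate:::.df_log_kernel(grid, length(omega), sum(log(omega)),
                                 sum(omega))
  pk <- exp(lk - max(lk)); pk <- pk / sum(pk)
  cdf_fun <- stats::approxfun(grid, cumsum(pk), yleft = 0, yright = 1)

  draws <- replicate(1e4, sample_df(omega, lo, hi))
  expect_lt(ks_dist(draws, cdf_fun), 0.02)
  expect_true(all(draws > lo & draws <= hi))
})

test_that("with no weights the df draw is uniform over the prior support", {
  set.seed(7)
  draws <- replicate(1e4, sample_df(numeric(0), 2, 10))
  expect_lt(ks_dist(draws, function(q) stats::punif(q, 2, 10)), 0.02)
})

test_that("non-selection imputation draws from the stage-2 normal", {
  expect_identical(impute_missing_y(numeric(0), numeric(0), 1, numeric(0)),
                   numeric(0))
  set.seed(8)
  d <- impute_missing_y(rep(0, 1e5), mu_mis = rep(3, 1e5), sigma2 = 4,
                        omega_mis = rep(1, 1e5))
  expect_lt(abs(mean(d) - 3), 0.01 * 3)
  expect_lt(abs(stats::sd(d) - 2), 0.01 * 2)
})

test_that("selection imputation targets the Phi-tilted normal", {
  # Metropolis chain on 1e4 parallel cells; target N(3, 4) * Phi(0.5 + 0.8 y)
  set.seed(9)
  nchain <- 1e4
  target_mu <- rep(3, nchain)
  y <- rep(0, nchain)
  for (s in 1:300)
    y <- impute_missing_y(y, target_mu, 4, rep(1, nchain), selection = TRUE,
                          phi = c(0.5, 0.8), prop_sd = 2)
  grid <- seq(-7, 13, length.out = 2e5)
  pk <- stats::dnorm(grid, 3, 2) * stats::pnorm(0.5 + 0.8 * grid)
  pk <- pk / sum(pk)
  q_mean <- sum(grid * pk)
  q_var <- sum((grid - q_mean)^2 * pk)
  expect_lt(abs(mean(y) - q_mean), 0.02 * abs(q_mean))
  expect_lt(abs(stats::var(y) - q_var), 0.05 * q_var)

  # a zero selection slope decouples the link: draws match the plain normal
  set.seed(10)
  y0 <- rep(0, nchain)
  for (s in 1:300)
    y0 <- impute_missing_y(y0, target_mu, 4, rep(1, nchain), selection = TRUE,
                           phi = c(0.4, 0), prop_sd = 2)
  ref <- rnorm(nchain, 3, 2)
  expect_lt(suppressWarnings(stats::ks.test(y0, ref)$statistic), 0.025)
})

test_that("probit selection layer: truncation sides and parameter recovery", {
  set.seed(11)
  y <- rnorm(200)
  out <- sample_selection(y, m = rep(0L, 200), phi = c(-0.5, 0.3),
                          prior_loc = c(0, 0), prior_prec = c(0.01, 0.01))
  expect_true(all(out$latents <= 0))

  # recovery: data generated at phi = (-0.5, 0.8), n = 5000
  set.seed(12)
  n <- 5000
  yy <- rnorm(n)
  mm <- as.integer(runif(n) < pnorm(-0.5 + 0.8 * yy))
  phi <- c(0, 0)
  keep <- matrix(NA_real_, 18000, 2)
  for (s in 1:20000) {
    st <- sample_selection(yy, mm, phi, c(0, 0), c(0.01, 0.01))
    phi <- st$phi
    if (s > 2000) keep[s - 2000, ] <- phi
  }
  pm <- colMeans(keep); ps <- apply(keep, 2, sd)
  expect_lt(abs(pm[1] - (-0.5)), 3 * ps[1])
  expect_lt(abs(pm[2] - 0.8), 3 * ps[2])
})

test_that("pinned-slope selection posterior matches a 1-D probit quadrature", {
  set.seed(13)
  y <- rnorm(60)
  m <- as.integer(seq_len(60) <= 18)       # 30% missing
  grid <- seq(-3, 2, length.out = 2e5)
  lk <- sum(m) * stats::pnorm(grid, log.p = TRUE) +
    sum(1 - m) * stats::pnorm(-grid, log.p = TRUE) +
    stats::dnorm(grid, 0, 10, log = TRUE)
  pk <- exp(lk - max(lk)); pk <- pk / sum(pk)
  q_mean <- sum(grid * pk)

  phi <- c(0, 0)
  keep <- numeric(28000)
  for (s in 1:30000) {
    st <- sample_selection(y, m, phi, c(0, 0), c(0.01, 1e12))
    phi <- st$phi
    if (s > 2000) keep[s - 2000] <- phi[1]
  }
  expect_lt(abs(mean(keep) - q_mean), 0.02 * abs(q_mean))
  expect_lt(abs(phi[2]), 1e-4)             # slope pinned at 0
})

test_that("logistic stage-1 Metropolis recovers generating coefficients", {
  gen <- gen_binary_iv(gen_spec(n = 5000, treatment = "binary",
                                true_pi1 = c(1.8, 2), n_covariates = 0,
                                true_pi2 = c(0, 1.2), seed = 14))
  d <- gen$data
  W1 <- cbind(1, d$Z)
  fit <- stats::glm(d$x ~ d$Z[, 1], family = binomial())
  L <- t(chol(vcov(fit)))
  set.seed(15)
  pi1 <- c(0, 0); ls <- log(2.38 / sqrt(2))
  keep <- matrix(NA_real_, 3000, 2); acc <- 0
  for (s in 1:6000) {
    st <- mh_logistic_stage1(pi1, W1, d$x, c(0, 0), c(1e-6, 1e-6),
                             L, ls, adapt = s <= 3000, iter = s)
    pi1 <- st$pi1; ls <- st$log_scale
    if (s > 3000) {
      keep[s - 3000, ] <- pi1
      acc <- acc + st$accepted
    }
  }
  pm <- colMeans(keep); ps <- apply(keep, 2, sd)
  expect_lt(abs(pm[1] - 1.8), 3 * ps[1])
  expect_lt(abs(pm[2] - 2.0), 3 * ps[2])
  rate <- acc / 3000
  expect_gt(rate, 0.1); expect_lt(rate, 0.5)
})

test_that("Metropolis logistic chain is pinned by an overwhelming prior", {
  set.seed(16)
  W1 <- cbind(1, rbinom(100, 1, 0.5))
  x <- rbinom(100, 1, 0.4)
  pi1 <- c(0.3, -0.2); ls <- 0
  for (s in 1:50) {
    st <- mh_logistic_stage1(pi1, W1, x, c(0.3, -0.2), c(1e12, 1e12),
                             diag(2), ls, adapt = FALSE)
    pi1 <- st$pi1
  }
  expect_lt(max(abs(pi1 - c(0.3, -0.2))), 1e-4)
})

test_that("intercept-only logistic posterior matches a quadrature oracle", {
  set.seed(17)
  n <- 100
  x <- rbinom(n, 1, 0.35)
  W1 <- matrix(1, n, 1)
  grid <- seq(-3, 2, length.out = 2e5)
  lk <- sum(x) * grid - n * log1p(exp(grid)) +
    stats::dnorm(grid, 0, 10, log = TRUE)
  pk <- exp(lk - max(lk)); pk <- pk / sum(pk)
  q_mean <- sum(grid * pk)

  b <- 0; ls <- 0
  keep <- numeric(36000)
  for (s in 1:40000) {
    st <- mh_logistic_stage1(b, W1, x, 0, 0.01, matrix(1), ls,
                             adapt = s <= 4000, iter = s)
    b <- st$pi1; ls <- st$log_scale
    if (s > 4000) keep[s - 4000] <- b
  }
  expect_lt(abs(mean(keep) - q_mean), 0.02 * abs(q_mean))
})
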