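# Shared fixtures and small utilities, all built in code at test time.

# Tiny continuous-treatment table with printed values (no covariates).
tiny_cont_table <- function() {
  data.frame(
    y = c(2.10, 3.95, 1.20, 5.60, 4.05, 2.80, 6.10, 3.30),
    x = c(0.50, 1.40, 0.10, 2.20, 1.60, 0.90, 2.50, 1.10),
    z = c(0.20, 1.00, -0.30, 1.80, 1.20, 0.60, 2.10, 0.70)
  )
}

# Moderate dataset generator shortcuts.
cont_data <- function(n = 120, seed = 1, ...) {
  gen_continuous_iv(gen_spec(n = n, seed = seed, ...))
}
bin_data <- function(n = 150, seed = 1, ...) {
  gen_binary_iv(gen_spec(n = n, treatment = "binary", seed = seed, ...))
}

# Minimal fit-shaped object for diagnostics that only need draws.
fake_fit <- function(draws_list, par_names, deviance = NULL,
                     model = model_spec("M1"), data = NULL) {
  structure(
    list(draws = lapply(draws_list, function(d) {
           d <- as.matrix(d); colnames(d) <- par_names; d
         }),
         deviance = if (is.null(deviance))
           lapply(draws_list, function(d) rep(0, nrow(as.matrix(d))))
         else deviance,
         par_names = par_names, model = model,
         config = list(n_chains = length(draws_list), seed = 1L,
                       n_iter = NA_integer_, n_burnin = NA_integer_,
                       thin = 1L),
         data = data),
    class = "bivlate_fit")
}

# Kolmogorov-Smirnov distance between draws and a reference CDF given as a
# function, or between two samples.
ks_dist <- function(draws, cdf) {
  if (is.function(cdf)) {
    s <- sort(draws)
    n <- length(s)
    max(abs(cdf(s) - seq_len(n) / n), abs(cdf(s) - (seq_len(n) - 1) / n))
  } else {
    stats::ks.test(draws, cdf)$statistic
  }
}

# Monte-Carlo standard error of a chain mean via non-overlapping batch means.
mcse <- function(chain, n_batches = 25L) {
  b <- floor(length(chain) / n_batches)
  bm <- colMeans(matrix(chain[seq_len(b * n_batches)], nrow = b))
  stats::sd(bm) / sqrt(n_batches)
}
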