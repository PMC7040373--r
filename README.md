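# bivlate

Bayesian robust two-stage instrumental-variable (IV) estimation of local
average treatment effects (LATE), for observational and quasi-experimental
studies where three practical problems collide:

* **selection bias** — omitted confounders correlate the treatment with the
  outcome error, so plain regression is biased;
* **outliers** — heavy-tailed outcomes break normal-error models;
* **missing outcomes** — including outcomes missing *not* at random (MNAR),
  where the probability of being missing depends on the unobserved value.

The package is aimed at applied researchers in the social, behavioral and
health sciences who would otherwise reach for two-stage least squares
(2SLS), and at Bayesian methodologists who want the conditional samplers as
building blocks.

## The model family

For individual *i* with treatment *X*, outcome *Y*, instruments **Z** and
covariates **C**:

```
stage 1:  X_i = π10 + π11' Z_i + e1_i                (continuous treatment)
          X_i ~ Bernoulli(q_i), logit(q_i) = π10 + π11' Z_i     (binary)
stage 2:  Y_i = π20 + π21 X̂_i + γ' C_i + e2_i
```

`X̂_i` is the instrument-predicted treatment (fitted value, or fitted
probability for binary treatments) and **π21 is the LATE**.  Stage-two
errors are normal or Student-t(ν) (robust to outliers, via the
scale-mixture-of-normals augmentation); an optional probit selection layer
`P(missing) = Φ(φ0 + φ1 Y_i)` models MNAR outcomes.  The eight crossings
are models M1–M8 (`model_taxonomy()`), e.g. M2 = cont-robust,
M6 = cont-robust-selection.

Estimation is a native Gibbs sampler with data augmentation (compiled
loops, exact conjugate conditionals, griddy-Gibbs for ν, adaptive
Metropolis for the logistic first stage), initialized from 2SLS with
data-dependent priors by default.  Summaries report posterior means, SDs,
equal-tailed 95% credible intervals, DIC, and Geweke / potential-scale-
reduction convergence diagnostics.

## Worked example

```r
library(bivlate)

# a tutorial-style dataset: continuous treatment, one instrument, five
# covariates, 20% of outcomes missing not at random, true LATE = 0.5
gen <- gen_continuous_iv(gen_spec(n = 600, seed = 1, missing = "MNAR"))
fit <- fit_model(gen$data, "M6",                    # cont-robust-selection
                 config = mcmc_config(n_iter = 20000, seed = 1))
summary(fit)
```

```
Posterior summary (model M6)
                    Est.    S.E.    CI.L    CI.U
stage1.intercept -0.0625  0.0292 -0.1202 -0.0056
stage1.slope      0.5289  0.0287  0.4727  0.5850
stage2.intercept -0.1869  0.0489 -0.2839 -0.0897
LATE              0.5612  0.0801  0.4060  0.7211
c1.coefficient    0.2915  0.0396  0.2152  0.3691
c2.coefficient    0.2208  0.0410  0.1406  0.3013
c3.coefficient    0.2679  0.0400  0.1900  0.3459
c4.coefficient    0.3129  0.0398  0.2340  0.3915
c5.coefficient    0.3115  0.0393  0.2349  0.3907
sel.intercept    -0.9301  0.1109 -1.1864 -0.7443
sel.slope         0.4323  0.1076  0.2399  0.6649
stage1.variance   1.0021  0.0583  0.8958  1.1239
stage2.variance   1.6639  0.1407  1.4057  1.9612
df.est           58.6614 26.6526 11.8044 98.0472

DIC: 3282.04   pD: 7.28
```

Reading the output: the LATE row says a one-unit increase in the
instrument-driven part of the treatment raises the outcome by about 0.56
(true value 0.5), with a 95% credible interval [0.41, 0.72].  `sel.slope`
is clearly positive — larger outcomes are more likely to be missing, i.e.
the missingness is non-ignorable, which is exactly what the selection layer
corrects; fitting the non-selection M2 to the same data gives a visibly
attenuated LATE.  `S.E.` is the posterior SD; `df.est` near the top of its
support says the (normal-generated) residuals show no heavy tails.
`run_log(fit)` records every resolved default (chains, iterations, burn-in,
prior source, starting values); `geweke(fit$draws[[1]][, "LATE"])` and,
with two or more chains, `rhat(fit, "LATE")` assess convergence;
`export_traces(fit, "traces/")` writes per-chain trace files.

A command-line front end with `fit`, `generate` and `diagnose` subcommands
is installed at `inst/cli/bivlate.R`:

```sh
Rscript inst/cli/bivlate.R generate --n 600 --missing MNAR --out data/
Rscript inst/cli/bivlate.R fit --model cont-robust-selection \
    --formula "y ~ x + c1 + c2 + c3 + c4 + c5 | z" \
    --data data/data.csv --out results/
```

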