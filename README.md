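# ldcm: the low-dimensional confidence model

`ldcm` implements a tractable model of decision confidence for
two-alternative forced-choice tasks. In the drift-diffusion account,
confidence is the Bayesian posterior probability that a choice was correct
given the accumulated evidence *e*, the accumulation time *t* and the
choice *x*:

    p(correct | e, t) = Phi( e / (sigma * sqrt(t)) )

Learning that mapping point-by-point over the whole (evidence, time) plane
is intractable for an observer. The low-dimensional confidence (LDC) model
approximates it with a two-parameter logistic family

    conf(e, t, x) = 1 / (1 + exp( -(x * alpha * e + beta) / t^gamma ))

where `alpha` is the observer's evidence-reliability weight, `beta` a
stimulus-independent confidence bias, and `gamma` (default 0.5) a time
exponent. With `alpha = lambda/sigma` (`lambda ~ 1.7`, the best logistic
approximation of the probit) and `beta = 0` the model reproduces the
Bayesian readout; deviations of `alpha` and `beta` capture distinct,
experimentally dissociable confidence biases.

The package is written for computational cognitive scientists who want to

* simulate choice/RT/confidence data from the generative model
  (`simulate_trials()`, discrete random walks with post-decisional
  accumulation, Rcpp core);
* fit the model to per-participant trial tables by quantile/bin
  sum-of-squared-errors with a differential-evolution optimizer
  (`ldc_fit()`, returning a classed object with `print`, `summary`,
  `coef`, `predict`, `simulate`, `residuals` and `plot` methods);
* compare confidence models (`two_stage_fit()`, `bic_sse()`,
  `delta_bic_table()`, `rfx_bms()` for random-effects group-level
  selection, `bootstrap_contrasts()` for simulation-based contrasts);
* compute the statistical signatures of Bayesian confidence
  (`signature_curves()`: confidence~accuracy, the folded X-pattern,
  conditional accuracy by confidence half, confidence~RT);
* generate model-based trial-by-trial feedback (`generate_feedback()`,
  `feedback_presets()`) as used to manipulate confidence during training;
* validate the machinery by simulation-and-refit parameter recovery
  (`recovery_study()`).

## Worked example

```r
library(ldcm)

# a synthetic participant: three difficulty levels, calibrated confidence
dd <- ddm_params(v = c(0.08, 0.15, 0.3), a = 0.11, ter = 0.35)
set.seed(10)
tab <- simulate_trials(dd, ldc_params(alpha = 20, beta = 0.5),
                       trial_design(n_per_cell = 216))

fit <- ldc_fit(tab, seed = 7)  # ~1 minute on one core
fit
#> LDC model fit (variant 'full'), 1 conditions
#>   SSE = 0.00070 (RT 0.00065 + confidence 0.00005), k = 7, n = 48, BIC = -507.27
#>   ter = 0.356 s, a = 0.1128, v = 0.078, 0.163, 0.306
#>   [baseline] alpha = 22.80, beta = 0.565
```

The fitted non-decision time (0.356 s vs 0.35), bound (0.113 vs 0.11) and
drift rates (0.078/0.163/0.306 vs 0.08/0.15/0.3) recover the generating
decision process from 648 trials; `alpha` (22.8 vs 20) and `beta` (0.57 vs
0.5) recover the confidence mapping up to the sampling noise of binned
ratings. `SSE` is
the quantile/bin objective (squared differences of joint RT-group and
confidence-level proportions), `k` the free-parameter count and `BIC` its
Gaussian-residual information criterion. `plot(fit)` overlays observed and
predicted proportions; `signature_curves(tab)` computes the four
confidence signatures.

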