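---
title: "The low-dimensional confidence model: methods and design choices"
author: "ldcm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The low-dimensional confidence model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldcm)
```

## The problem

In two-alternative forced-choice decisions, confidence is well described as
the Bayesian posterior probability that the choice was correct given the
data available to the observer: the accumulated stimulus evidence, the time
spent accumulating it, and the choice itself. Under drift-diffusion
assumptions, with a flat prior over the sign of the drift, that posterior is

$$p(\mathrm{correct} \mid e, t) = \Phi\!\left(\frac{e}{\sigma\sqrt{t}}\right),$$

where $e$ is the signed accumulated evidence at the report, $t$ the
accumulation time, $\sigma$ the within-trial noise and $\Phi$ the standard
normal CDF. Learning this mapping point-by-point over the whole
$(e, t)$ plane is intractable for a cognitive agent. The low-dimensional
confidence (LDC) model replaces it with a two-parameter logistic family

$$\mathrm{conf}(e, t, x) =
  \frac{1}{1 + \exp\!\left(-\,\dfrac{x\,\alpha\,e + \beta}{t^{\gamma}}\right)},
  \qquad x \in \{-1, 1\},$$

where $\alpha \ge 0$ weighs the evidence (the observer's estimate of
evidence reliability, in inverse evidence units), $\beta$ is a
stimulus-independent confidence bias on the logit scale, and $x$ is the
choice. Because $\Phi(z) \approx 1/(1 + e^{-\lambda z})$ with
$\lambda \approx 1.7$ (the constant minimizing the maximum absolute
deviation; `fit_lambda()` reproduces $\lambda^* = 1.7017$ with maximum
deviation $0.0095$), the Bayesian readout is the special case
$\alpha = \lambda / \sigma$, $\beta = 0$. With the package convention
$\sigma = 0.1$ this gives $\alpha \approx 17$. Deviations of $\alpha$ from
$\lambda/\sigma$ express miscalibrated evidence reliability; nonzero
$\beta$ expresses global over- or underconfidence.

### The time exponent

The printed form of the mapping divides by $t$; the flat-prior Wiener
posterior divides by $\sqrt{t}$. We expose the exponent as a parameter
$\gamma$ (dividing by $t^\gamma$) and default to $\gamma = 0.5$: that is
the value under which the logistic family can reproduce the Bayesian
readout exactly through the probit approximation, and it makes the
$\alpha = \lambda/\sigma \approx 17$ equivalence come out adjacent to the
baseline feedback setting $\alpha = 18$ used by the feedback engine.
Observers who over- or under-weigh elapsed time are modeled by
$\gamma \gtrless 0.5$.

## The simulator

Decisions are simulated as discrete random walks: evidence starts at
$z \cdot a$ (default $z = 0$) and changes by
$\Delta = v\tau + \sigma\sqrt{\tau}\,\mathcal N(0,1)$ per step
($\tau = 1$ ms, $\sigma = 0.1$) until reaching $\pm a$; decision RT is the
first-passage time plus the non-decision time $t_{er}$. Evidence at the
decision is recorded as exactly $\pm a$: clipping the overshoot matches the
construction used by the online feedback algorithm and removes a step-size
artifact from downstream confidence computations. After the decision,
accumulation continues unbounded for a duration equal to the confidence RT,
with drift following the true stimulus direction, so errors tend to
accumulate disconfirming evidence. Ratings arise by evaluating the LDC
mapping on the total evidence and elapsed time and cutting $[0,1]$ into six
equal right-closed bins.

Numerical notes:

* A walk that has not terminated after 20 s of simulated time raises an
  error; this bounds runtime under degenerate parameter proposals (the
  fitting objective converts the condition into a large penalty instead).
* The discrete walk slightly overestimates the continuous-diffusion
  absorption probability $1/(1+e^{-2va/\sigma^2})$: barrier overshoot acts
  like widening both bounds by about $0.58\,\sigma\sqrt{\tau}$
  ($\approx 0.0018$ evidence units at the defaults), worth up to ~0.004 in
  choice probability at intermediate accuracies. Tests compare simulated
  accuracies against the closed form with tolerances that account for this.
* By default the elapsed time entering the confidence mapping is
  *accumulation* time, $(RT - t_{er}) + RT_{conf}$: the posterior above is
  defined on the accumulation process, and generator and fitter must agree
  on the convention for recovery to be meaningful. A `time = "response"`
  option uses $RT + RT_{conf}$ instead; the feedback engine always uses
  decision RT + confidence RT, mirroring the experimental procedure it
  implements.

The synthetic generator emulates the statistical structure the model
assumes: stationary drift within difficulty level, no across-trial drift or
starting-point variability, no lapses, no collapsing bounds, and log-normal
confidence RTs (median 0.55 s, sdlog 0.4) standing in for empirical
confidence-RT distributions. Passing tests on such data validate the
machinery — the estimator recovers the parameters of its own generative
model — not the adequacy of that generative model for any particular
empirical dataset.

## Fitting

`ldc_fit()` fits five decision parameters ($t_{er}$, $a$, one drift per
difficulty level) plus confidence parameters per condition by minimizing a
quantile/bin sum of squared errors between observed and model-predicted
joint proportions:

* **RT term.** Trials are grouped by the .1/.3/.5/.7/.9 RT quantiles of the
  observed data. Proportions are *joint* — normalized by the condition's
  total trial count — so accuracy itself penalizes the fit (per-class
  normalization would leave accuracy unconstrained). Cutoffs and groups are
  computed within each (difficulty x accuracy) class: with pooled
  summaries and equal trial counts per difficulty, the objective is
  invariant under permutation of the drift rates and per-difficulty drifts
  are unidentifiable.
* **Confidence term.** Joint proportions of the six rating levels by
  accuracy. Inside the joint fit these are also difficulty-resolved: the
  folded-X structure across difficulty levels is what separates evidence
  weighting ($\alpha$) from additive bias ($\beta$); pooled proportions
  leave a flat trade-off ridge between the two for high-accuracy
  parameter regimes.

Predictions are simulated: `oversample` times the observed trial count
(default 20), matching the observed difficulty mix, with post-decisional
durations drawn from the observed confidence RTs such that each empirical
value is used exactly `oversample` times. Model confidence is binned into
six equal-width bins and compared against the observed cutoffs. Smaller
oversampling factors save time but leave more simulation noise in the
predicted proportions, which visibly degrades the precision of the bound
and drift estimates.

Two implementation choices make the optimization tractable and exactly
reproducible:

* **Common random numbers.** Each fit pre-draws a noise pool from the seed;
  every simulated trial reads the pool from a fixed per-trial offset. The
  objective is then a deterministic function of the parameters, which
  differential evolution requires for its stagnation-based stopping rule to
  be meaningful, and identical (data, parameters, seed) give bit-identical
  SSE values.
* **Profiling the confidence parameters.** $(\alpha, \beta)$ do not affect
  the simulated walks, so for every decision-parameter proposal they are
  profiled out (two-level grid plus Nelder-Mead on the confidence term).
  The minimized objective is identical to the joint SSE over all
  parameters, while the evolutionary search runs in 5 dimensions with
  population $10 \times 5 = 50$ (ten times the searched dimension). A
  denser profile is used once at the final solution. Variants whose
  sharing structure prevents per-condition profiling (`alpha_free`,
  `beta_free`) carry their confidence parameters in the search vector.
  The profile adds a tiny quadratic tie-break on $\beta$
  ($10^{-6}\beta^2$, never included in reported SSEs): when confidence
  saturates — nearly all ratings at the scale's end — the confidence term
  is flat over a ridge in $(\alpha, \beta)$ and the tie-break pins the
  solution at the unbiased-confidence end of the ridge instead of letting
  it drift to a bound. After the evolutionary search a short Nelder-Mead
  polish refines the decision parameters on the same deterministic
  surface.

The population is seeded with one member at closed-form EZ-style moment
estimates (drift and bound from edge-corrected accuracy and RT variance per
difficulty, non-decision time from the mean RT); differential evolution
($F = 0.8$, $CR = 0.9$) then refines. The default mutation strategy is
local-to-best/1/bin — the canonical default of the reference DE
implementation in this literature — which converged markedly faster than
rand/1/bin on these surfaces at equal budgets; `strategy = "rand"` selects
plain rand/1/bin. At desk scale the search is capped at 20-30 generations
(the warm start plus the final polish carry the last distance); at full
scale it runs under the 100-stagnant-generations rule with a hard cap of
1000. Default bounds:
$v \in [0, 1]$ per difficulty, $a \in [0.01, 0.3]$,
$t_{er} \in [0.05,\ 0.9 \cdot \min RT]$, $\alpha \in [0, 100]$,
$\beta \in [-5, 5]$ — spanning all parameter settings the feedback presets
imply, with headroom.

## Model comparison

`two_stage_fit()` implements the comparison scheme: stage 1 fits the five
decision parameters to the RT term only; stage 2 freezes them — identical
across candidates — and fits each candidate's confidence parameters to the
pooled confidence term (6 levels x 2 accuracies per condition, so
$n = 36$ data points for three conditions). Candidates:

| candidate     | confidence mapping                    | free parameters $k$ |
|---------------|---------------------------------------|---------------------|
| `null`        | one $(\alpha, \beta)$ for all conditions | 2 |
| `alpha_free`  | $\alpha$ per condition, shared $\beta$ | $C + 1$ |
| `beta_free`   | $\beta$ per condition, shared $\alpha$ | $C + 1$ |
| `full`        | $(\alpha, \beta)$ per condition        | $2C$ |
| `bayes_fixed` | exact readout, stage-1 drifts          | 0 |
| `bayes_free`  | exact readout, drifts re-fit per condition | $3C$ |

The Bayesian-readout candidates compute the exact posterior under the
discrete mixture of the estimated drift magnitudes (equiprobable signs,
mixture weights from the difficulty mix); the flat-prior
$\Phi(e/(\sigma\sqrt t))$ form is available separately as
`bayes_p_correct()`. Goodness of fit converts to
$BIC = k \ln n + n \ln(SSE/n)$, valid under Gaussian zero-mean residuals;
a saturated fit ($SSE = 0$) has no BIC and raises an error. Group-level
selection uses `rfx_bms()`: per-participant model evidence $-BIC/2$
(the BIC-weight convention), a variational fixed-point update of Dirichlet
frequency parameters (tolerance $10^{-6}$), exceedance probabilities from
$10^5$ Dirichlet draws, and the Bayesian omnibus risk from the free-energy
comparison against the equal-frequency null. Ties in the mean-BIC table
are all reported as $\Delta BIC = 0$.

## Signatures and contrasts

`signature_curves()` computes the four signatures of Bayesian confidence:
confidence by accuracy; the folded X-pattern over evidence strength
(difficulty level — the observable proxy for drift magnitude); conditional
accuracy by confidence half (median split per participant; trials at the
median rating go to the lower half for reproducibility, unless that leaves
the upper half empty — a median at the top rating — in which case they go
to the upper half); and mean
confidence over successive decision-RT quantile bins (6 within-participant
bins by default). Cells without trials are flagged `NA` rather than
raising.

`confidence_contrast()` pools the baseline and plus conditions and
subtracts the minus condition, separately for corrects and errors;
`bootstrap_contrasts()` simulates datasets of the observed design from a
fitted model (500 by default) and reports the .025/.975 type-1 quantiles,
so at small replicate counts the interval endpoints are order statistics.

## Model-generated feedback

`generate_feedback()` reproduces the online algorithm used to manipulate
confidence during training: evidence at the decision is assumed equal to
the pilot-session average bound (in the chosen option's frame), a
post-decisional walk runs for the observed confidence RT with the
pilot-average drift magnitude signed by the observed accuracy, and the
feedback value is the LDC confidence of the result at total time decision
RT + confidence RT. The five presets are baseline
($\alpha = 18, \beta = 0$), $\alpha$-minus/plus ($\alpha = 9 / 36$) and
$\beta$-minus/plus ($\beta = \mp 1$). This module follows the experimental
procedure verbatim, including the response-time convention, even though
the fitting default uses accumulation time. Because the pilot averages
behind the published experiments are not public, the preset defaults
(bound 0.1, drift 0.15) are synthetic stand-ins on the same scale as the
fitting bounds; pass your own pilot values for empirical use. Manipulating
$\alpha$ moves feedback on correct trials while leaving errors nearly
unchanged (evidence on errors is weak or disconfirming); manipulating
$\beta$ moves both — the dissociation the training manipulation relies on.

## Study sizes and reproducibility

All stochastic components thread through R's RNG via explicit seeds; fits
additionally freeze their noise pool so that identical seeds give
bit-identical results. The package's default study sizes are chosen for a
single desktop core:

* parameter recovery: 20 participants x 648 trials (216 per difficulty),
  oversample 20, DE population 50, a 20-generation cap — roughly a minute
  per participant; `recovery_study(full = TRUE)` switches to 200
  participants and the stagnation-ruled optimizer;
* posterior-approximation check: 20 parameter sets x ~5000 trials
  ($10^5$ total);
* property checks: $5 \times 10^4$ walks per (drift, bound) point.

At the reduced recovery scale the drift rates recover with correlations
above .9 and the remaining parameters in the .75-.9 range (the acceptance
suite recomputes these). The weakest recoveries, and the residual negative
$\hat\alpha$-$\hat\beta$ coupling, trace to genuine weak identifiability
for near-ceiling-accuracy participants: the sampled ranges allow
drift/bound combinations with accuracy above 99% and ratings saturated at
the top of the scale, where almost nothing in the data informs the
confidence mapping.

## Known limitations

* No across-trial variability parameters, collapsing bounds or biased
  starting points: the generative model is the plain symmetric
  random-walk approximation.
* The quantile-proportion objective is not a likelihood; BIC values are
  the Gaussian-residual surrogate standard in this literature.
* The discrete-time walk carries the small absorption-probability bias
  noted above; continuous-time exact samplers are out of scope.
* Confidence scales other than the 6-point rating (e.g. continuous
  reports) are only supported through the continuous `conf` column of
  simulated tables.
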