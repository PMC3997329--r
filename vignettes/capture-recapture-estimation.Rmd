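---
title: "Capture probabilities and abundance in closed populations: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture probabilities and abundance in closed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capgee)
```

## The model

A closed population of unknown size $N$ is sampled on $m$ trapping
occasions.  $Y_{ij} \in \{0,1\}$ records whether animal $i$ is caught on
occasion $j$; $T_i = \sum_j Y_{ij}$ is its capture count and $t_i$ its
first-capture occasion.  Heterogeneity in catchability is carried by
individual covariates $\mathbf{x}_i$ through a logistic model,
$$\operatorname{logit} p_i = \mathbf{x}_i'\boldsymbol\beta
  \qquad(\text{GLMM: } + \sigma_b z_i,\; z_i \sim N(0,1)),$$
with $p_i$ constant over occasions.  The probability of entering the
sample at all is $\pi_i = 1-(1-p_i)^m$, and abundance is estimated over
the $n$ captured animals by Horvitz–Thompson,
$\hat N = \sum_{i=1}^n 1/\hat\pi_i$.

Assumptions: demographic closure over the study; covariates recorded
without error for every captured animal; capture probability constant
across occasions (no trap response, no time effects); and within-animal
dependence across occasions induced only through shared $p_i$ (covariates
plus, in the GLMM, a latent effect).

## Estimators

**Quasi-likelihood GEE** (`method = "ql-gee"`).  Because covariates are
unobservable for animals never caught, estimation conditions on the $n$
captured animals.  Two mean forms are available for the occasion
indicator:

* *conditional* (default): $\mathrm E[Y_{ij} \mid T_i \ge 1] = p_i/\pi_i$,
  which is the correct mean among captured animals; the estimating
  equations reduce to moment equations in $T_i$, e.g. intercept-only:
  $m\,p/\pi(p) = \bar T$, solved by bracketed root-finding (the left side
  is strictly increasing, so the root is unique);
* *marginal*: $\mathrm E[Y_{ij}] = p_i$, giving the closed form
  $\hat p_0 = \sum T_i/(nm)$ for the intercept-only model.  Applied to
  captured-only data the marginal form understates abundance slightly —
  both forms are kept because each matches one of the two published
  intercept conventions for the chipmunk example, and the package pins
  each worked-example row to the form that reproduces it.

Fisher scoring starts at $\boldsymbol\beta = 0$ with step-halving on the
estimating-function norm; convergence when the step or the score norm
falls below $10^{-8}$, at most 100 iterations.  With an exchangeable
working correlation $R(\alpha)$ and occasion-constant means, every
animal's score is rescaled by the same factor $1/(1+(m-1)\alpha)$, so the
root is identical to the independence fit and only the model-based
covariance changes; $\alpha$ is estimated by the moment average of
within-animal cross-products of Pearson residuals.  A sandwich covariance
is computed alongside the model-based one.

**Partial-likelihood GLM** (`method = "pl-glm"`).  Given $t_i$, the
recaptures satisfy $(T_i - 1)\mid t_i \sim \mathrm{Bin}(m-t_i,\,p_i)$,
free of $N$.  This is a weighted binomial-logit regression on
$(T_i-1,\; m-t_i)$ records, fitted by iteratively reweighted least
squares; animals first caught on the last occasion contribute zero trials
and are inert in the fit but keep fitted $\hat\pi_i$ for the abundance
sum.

**Partial-likelihood GLMM** (`method = "pl-glmm"`).  Adds the random
intercept $\sigma_b z_i$ for heterogeneity not explained by covariates.
Fitting is penalized quasi-likelihood: each outer iteration linearizes
the binomial likelihood into a working response with weights
$w_i = (m-t_i)\,p_i(1-p_i)$, solves the diagonal working linear mixed
model in closed form, and updates $\sigma_b^2$ by maximizing the working
restricted likelihood on $[0, 25]$ (so $\hat\sigma_b = 0$ is found
exactly at the boundary, collapsing the fit to the GLM).  Convergence at
$10^{-6}$ on both $\boldsymbol\beta$ and $\sigma_b$, at most 200 outer
iterations.  The equivalent ridge penalty is $\lambda = 1/\sigma_b^2$; a
generalized cross-validation selector over 25 log-spaced candidates in
$[10^{-4}, 10^4]$ is provided (`select_lambda_gcv()`), minimizing
$n\,D(\lambda)/(n-\mathrm{edf}(\lambda))^2$ with ties broken toward the
smallest penalty.  The coefficient covariance for a penalized fit uses
the ridge-penalized working information as a sandwich with the
per-animal weights $\eta_i = \pi_i^{-2}\, m\, p_i (1-\pi_i)$.

**Abundance.**  $\hat N = \sum w_i/\hat\pi_i$ (weights are group counts
for grouped data), with variance
$\sum w_i (1-\hat\pi_i)/\hat\pi_i^2 +
 \mathbf d' \widehat{\mathrm{Var}}(\hat{\boldsymbol\beta})\, \mathbf d$,
$\mathbf d = \partial \hat N/\partial \boldsymbol\beta$.  The published
analyses never state their interval form, so the default is a 95% Wald
interval $\hat N \pm 1.96\,\mathrm{SE}$, with a log-normal interval on
$\hat N - n$ as an option (it respects the $\hat N \ge n$ constraint);
coverage figures from the harness are therefore interpretable relative
to that stated choice.  $\pi$ is evaluated as
$-\mathrm{expm1}(m \log\mathrm{1p}(-p))$ so small $p$ does not lose
precision to cancellation.  For GLMM fits the abundance sum evaluates
$\pi_i$ at the predicted random effect (animals with $t_i = m$ carry no
recapture information and get $z_i = 0$); this conditional convention is
a deliberate choice — the published account does not say which was used,
so the corresponding GLMM abundance row is treated as a diagnostic, not
a benchmark.

## Grouped (summary-only) data

Some classic datasets survive only as printed sufficient statistics.
`grouped_summary()` carries per-group animal counts and capture totals;
GEE fits then use the per-group closed forms above (a saturated
categorical design), and the individual-level solver reproduces them to
$10^{-8}$ on matched data — one of the package's cross-checks.  The
bundled chipmunk summary fixes the male/female capture totals at 41/47,
the unique integers consistent with the printed group means (1.86, 2.04)
and the printed total of 88; this is documented as a reconstruction, not
raw data.  Partial-likelihood estimators need $t_i$, which grouped data
do not carry, and refuse such input explicitly.  The companion
`synthetic_chipmunk_history()` builds a deterministic individual-level
matrix matching every printed margin (capture frequencies, per-occasion
counts, group totals) for code paths that need full histories; its
first-capture times are invented, so only moment-based fits on it are
meaningful.

## The simulator

`scenario()`/`simulate_capture()` generate the study design used
throughout: sex $\sim$ Bernoulli(0.5), weight $\sim N(15, 4)$ (variance
4, i.e. SD 2 — grams around a 15 g animal), capture model
$\operatorname{logit} p_i = \beta_0 + 0.1\,\mathrm{sex} +
0.2\,\mathrm{weight} + 0.1\,z_i$ with presets $\beta_0 = -3.5$ ("high",
$\bar p \approx 0.4$ at weight 15), $-4.0$ ("medium"), $-4.5$ ("low",
$\bar p \approx 0.2$).  The latent $z_i$ is drawn once per animal and
held constant across occasions, so occasion dependence enters only
through shared $p_i$.  One master seed spawns per-replicate seeds, so any
replicate is reproducible in isolation.

What the simulator does *not* emulate: time-varying effort, behavioral
(trap-happy/shy) response, misidentification, or covariate measurement
error.  Passing tests therefore demonstrate correctness of the
estimators under covariate-driven heterogeneity with a small shared
latent effect — not robustness to those field realities.

A note on fidelity: with weight variance 4 the expected number of
distinct animals captured under the "low" scenario ($N = 100$, $m = 6$)
is about 71, while the published study table prints 69 alongside $m=10$
at-least-once probabilities that are likewise consistent with a wider
weight spread (SD 4) — an internal inconsistency of the source tables.
The generator keeps the stated variance; the harness reports the mean
captured as computed.

## The Monte-Carlo harness

`run_study()` simulates, fits every requested estimator on the *same*
replicate data, estimates abundance, and aggregates: AVE (mean $\hat N$),
SE (sample SD across replicates, denominator $r-1$), PRB
($100(\mathrm{AVE}-N)/N$), CV ($100\,\mathrm{SE}/\mathrm{AVE}$), RMSE
($\sqrt{\mathrm{mean}(\hat N - N)^2}$, so
$\mathrm{RMSE}^2 = \mathrm{SE}^2 (r-1)/r + \mathrm{bias}^2$ holds exactly
— an asserted invariant) and COV (percent of intervals covering $N$).
Replicates where a fit fails, does not converge, or hits a boundary (any
fitted logit beyond $\pm 10$, the package's non-estimability flag) are
excluded from that estimator's metrics and tallied.  With one replicate
the SD is undefined and reported as missing, never zero.

Problem sizes used by the shipped tests: 1000 replicates for the
published-table comparisons (matching the source study), 100–400
replicates for recovery and qualitative checks, populations up to
$N = 2000$ for coefficient-recovery properties — sizes chosen to make
Monte-Carlo bands a small fraction of the effects being checked.
Published Monte-Carlo averages are compared as what they are, a pair of
independent 1000-replicate means, i.e. with tolerance
$3\,\mathrm{sd}\sqrt{2/1000}$.

## Known limitations

* **PQL attenuation.**  With recapture trials of at most $m-1$ per
  animal, penalized quasi-likelihood systematically underestimates
  $\sigma_b$ when heterogeneity is substantial — the package's recovery
  tests show estimates around three quarters of a generating
  $\sigma_b = 1$.  This is the classic behaviour of PQL on few-trial
  binomial data.
* **Capture-selection bias in the random-effects partial likelihood.**
  The GLMM treats $z_i \sim N(0,1)$ among *captured* animals, but
  conditioning on capture size-biases the latent effect (poorly
  catchable animals are under-represented and caught late, so their
  trial counts are informative about $z_i$).  Even an exact
  marginal-likelihood fit of this model therefore does not recover the
  generating $(\boldsymbol\beta, \sigma_b)$; intercept and variance
  estimates trade off against each other.  This is a property of the
  model formulation, not of the optimizer, and it plausibly contributes
  to the GLMM's overestimation of $N$ at low capture probabilities,
  which the harness reproduces qualitatively.
* **Conditional-GEE tail behaviour at low capture probability.**  When
  few animals are recaptured, the conditional moment equations can place
  $\hat p$ close to zero, inflating $1/\hat\pi$; the abundance
  distribution is right-skewed and replicate SDs are tail-dominated.
  Model-based SEs dominated by the binomial variance term can understate
  this Monte-Carlo spread considerably — worth remembering when
  comparing estimators by reported SE rather than by replicate SD.
* Estimators assume closure and no behavioral response; neither is
  testable from within this model family.
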