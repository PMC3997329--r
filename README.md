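# capgee

Estimation of animal abundance from closed-population capture–recapture
data with individual covariates.

## The problem

A closed population of unknown size *N* is trapped on *m* occasions.  For
each of the *n* distinct animals caught at least once we observe a binary
capture history and individual covariates (sex, body weight, ...).  Capture
probabilities are heterogeneous — a covariate-driven version of the classic
M<sub>h</sub> model — and repeated captures of the same animal are
correlated across occasions.  `capgee` estimates the per-occasion capture
probability

&nbsp;&nbsp;&nbsp;&nbsp;logit(*p*<sub>*i*</sub>) = **x**<sub>*i*</sub>′**β**&nbsp;&nbsp;(optionally + *σ*<sub>b</sub>*z*<sub>*i*</sub>, *z*<sub>*i*</sub> ~ N(0,1)),

the probability of being caught at least once,
*π*<sub>*i*</sub> = 1 − (1 − *p*<sub>*i*</sub>)<sup>*m*</sup>, and the
population size by the Horvitz–Thompson estimator over captured animals,

&nbsp;&nbsp;&nbsp;&nbsp;*N̂* = Σ<sub>*i*=1..*n*</sub> 1 / *π̂*<sub>*i*</sub>,

with a variance combining the binomial term
Σ(1 − *π̂*)/*π̂*² and a delta-method term through the coefficient
covariance.

Three estimators of **β** are provided behind one fitting front-end:

* **`ql-gee`** — quasi-likelihood generalized estimating equations across
  occasions, with independence or exchangeable working correlation and a
  conditional (`E[Y_ij | captured] = p_i/π_i`, default) or marginal
  (`E[Y_ij] = p_i`) mean form;
* **`pl-glm`** — partial likelihood of recaptures after first capture:
  (*T*<sub>*i*</sub> − 1) | *t*<sub>*i*</sub> ~ Binomial(*m* − *t*<sub>*i*</sub>, *p*<sub>*i*</sub>),
  an ordinary binomial-logit GLM;
* **`pl-glmm`** — the same partial likelihood with a Gaussian random
  intercept, fitted by penalized quasi-likelihood (PQL).

The package also ships the simulator and Monte-Carlo harness used to
characterize the estimators (bias, RMSE, coefficient of variation,
confidence-interval coverage).

## Worked example

A classic least chipmunk live-trapping study survives as printed summary
statistics: 45 animals captured over 6 occasions, 88 captures in total,
22 males (41 captures) and 23 females (47 captures).
`chipmunk_summary()` packages these; `crfit()` fits the sex model by
quasi-likelihood GEE:

```r
library(capgee)
fit <- crfit(~ sex, chipmunk_summary(), method = "ql-gee")
summary(fit)
#> Quasi-likelihood GEE capture-probability fit
#> (Intercept) = -0.84 (0.26), sex = -0.21 (0.39)
#>
#> Coefficients:
#>             Estimate Std. Error     z
#> (Intercept)   -0.844      0.257 -3.28
#> sex           -0.206      0.395 -0.52
#>
#> Horvitz-Thompson abundance: N_hat = 52.39 (SE 4.14)
#> 95% wald CI: [44.29, 60.50]   (n = 45 captured)
```

The intercept is the logit capture probability of a female
(p ≈ 0.30 per occasion), the `sex` coefficient the male–female contrast
(males slightly less catchable), and N̂ = 52.4 the estimated population
size — about 7 animals beyond the 45 actually seen.  The intercept-only
fit with the marginal mean form (`crfit(~ 1, ..., mean_form = "marginal")`)
gives p̂ = 88/270 and N̂ = 49.66.

Simulation and estimator evaluation:

```r
res <- run_study(scenario("low", N = 100, m = 6),
                 c("ql-gee", "pl-glm"), reps = 100, seed = 42)
res
#>  scenario   N m estimator n_bar reps    AVE    SE  PRB    CV  RMSE COV
#>       low 100 6    ql-gee 71.21  100 102.86 13.62 2.86 13.24 13.85  97
#>       low 100 6    pl-glm 71.21  100 102.62 12.22 2.62 11.91 12.44  95
```

Each row: mean number captured (`n_bar`), mean and SD of N̂ across
replicates, percentage relative bias, coefficient of variation, RMSE and
95%-interval coverage for one estimator under a low-capture-probability
scenario (per-occasion p ≈ 0.2).

A thin command-line wrapper (`inst/scripts/capgee`) exposes `fit`,
`simulate` and `study` subcommands over the same functions.

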