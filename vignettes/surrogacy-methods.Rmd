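---
title: "Trial-level surrogacy methods in surrometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level surrogacy methods in surrometa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrometa)
```

## The problem

Overall survival (OS) is the definitive efficacy endpoint in oncology
trials, but it takes years to mature and is diluted by treatments given
after progression. Radiographic progression-free survival (rPFS) is read
much earlier. Whether a treatment effect on rPFS can stand in for a
treatment effect on OS is a *trial-level surrogacy* question: across
randomized trials, how strongly does the treatment effect on the surrogate
predict the treatment effect on the true endpoint? Note the contrast with
individual-level surrogacy — a high patient-level correlation between the
two endpoints neither implies nor is implied by a high correlation between
*treatment effects* across trials.

`surrometa` works entirely from published per-trial summaries: one hazard
ratio (HR) with its confidence interval per endpoint per trial. The bundled
table `mcrpc_trials()` contains eleven phase 3 trials of first-line
treatments for asymptomatic or mildly symptomatic, ARPi-naive metastatic
castration-resistant prostate cancer. One trial (PEACEIII) violates the
proportional-hazards assumption for OS and is excluded from the primary
analysis set; two further trials (NCT02294461, ERA 223) are conventionally
excluded by the second sensitivity analysis as outliers.

## From published intervals to analysis-scale effects

All modelling happens on the log-HR scale, where treatment effects are
approximately normal and the linearity assumption is natural. For each
endpoint, `to_effects()` computes

$$y = \log(\mathrm{HR}), \qquad
  se = \frac{\log(\mathrm{UCL}) - \log(\mathrm{LCL})}{2\,z_{(1+L)/2}},$$

with $z_{0.975} = 1.959964$ at the default 95% level. The exact normal
quantile is used rather than 1.96; the difference is negligible but using
the exact value makes the CI-to-SE conversion exactly invertible, which the
test suite checks as a round trip. Hazard ratios are taken at their printed
precision and never re-rounded.

## The bivariate random-effects model

`fit_brma()` implements the standard two-level bivariate model. Writing
$y_i = (y_{1i}, y_{2i})'$ for trial $i$'s estimated log HRs on the
surrogate and true endpoint:

$$y_i \mid \theta_i \sim N_2(\theta_i, S_i), \qquad
  \theta_i \sim N_2(\mu, \Sigma),$$

where $S_i$ carries the known squared standard errors on its diagonal and a
within-trial correlation $c$ on the off-diagonal, and

$$\Sigma = \begin{pmatrix} \tau_1^2 & \rho\tau_1\tau_2 \\
  \rho\tau_1\tau_2 & \tau_2^2 \end{pmatrix}.$$

The between-trial correlation $\rho$ is the surrogacy parameter; its square
is the trial-level $R^2$. The within-trial correlation $c$ cannot be
estimated from published summaries (it would require patient-level data or
bootstrap estimates per trial); the default is $c = 0$, with a knob
(`within_corr`) for sensitivity sweeps — in our experiments moving $c$
across $\{0, 0.3, 0.5, 0.7\}$ moves the fitted between-trial quantities
only in the third decimal for the bundled data.

Estimation maximizes the marginal likelihood (REML by default, which is
preferred at the 8–11 trials typical of this literature; ML is available)
over $(\log\tau_1, \log\tau_2, \operatorname{atanh}\rho)$, with $\mu$
profiled out by generalized least squares. The parameterization makes every
iterate admissible. Numerical choices: bounded L-BFGS-B from five starting
points (one is a moment estimate derived from the weighted regression),
objective tolerance `factr = 1e4` (about $10^{-12}$ relative), $\tau$
floored at $10^{-6}$, ties broken by the higher objective and then the
smaller parameter norm. The optimizer is validated in the test suite
against a brute-force five-dimensional grid search of an independently
coded joint likelihood, and against `metafor::rma.mv(struct = "UN")`.

### The boundary problem, and the estimator actually reported

For meta-analyses of strongly correlated endpoints with moderate
within-trial error — including the bundled mCRPC data — the marginal
likelihood of this model is maximized *on the boundary* $\rho = 1$: the
observed correlation of the effect estimates is larger than any interior
$\rho$ can produce once the within-trial noise is accounted for. This is a
well-known degeneracy of bivariate meta-analysis with few trials, not a
software artifact: the profile likelihood increases monotonically in $\rho$
all the way to 1 for these data, under both ML and REML and for any fixed
within-trial correlation. A boundary estimate $\hat R^2 = 1$ is reported
honestly by `fit_brma()`, but it is not a useful summary of surrogacy
strength, and its Fisher-type confidence interval degenerates.

`fit_shrinkage()` therefore provides the estimator that `run_analysis()`
reports as the headline trial-level $R^2$:

1. fit a univariate random-effects meta-analysis per endpoint
   (DerSimonian–Laird heterogeneity by default, the field's standard);
2. form each trial's empirical-Bayes (BLUP) prediction of its true effect,
   which shrinks the observed effect toward the pooled mean in proportion
   to its within-trial variance;
3. report the Pearson correlation of the shrunken pairs, and the least-
   squares line through them as the correlation equation.

Shrinkage removes (approximately) the within-trial noise from each
coordinate before correlating, so the estimate is deattenuated relative to
the raw Pearson correlation of the observed effects, yet — unlike the
moment-deattenuated correlation, which exceeds 1 for these data — it can
never leave $[-1, 1]$. On the bundled primary set the raw Pearson $R^2$ of
the observed log effects is 0.66, the shrinkage estimate is 0.80, and the
likelihood estimate is 1.00 (boundary). The shrinkage estimate's interval
uses the Fisher transformation with nominal standard error
$1/\sqrt{n - 3}$; with $n \approx 10$ trials this interval is wide, and we
regard the interval (not the point) as the primary inferential output, as
does the IQWiG framework below.

The conditional-mean ("correlation") line of either fit is
$\log \mathrm{HR}_{OS} = a + b \log \mathrm{HR}_{rPFS}$ with
$b = \rho\,\tau_2/\tau_1$ and $a = \mu_2 - b\mu_1$ (`implied_line()`).

### Predicting a new trial

`predict_new()` gives the conditional distribution of a new trial's
observed true-endpoint effect given its observed surrogate effect:

$$m = \mu_2 + \frac{\rho\tau_1\tau_2 + c\,se_1 se_2}{\tau_1^2 + se_1^2}
      (y_1 - \mu_1), \qquad
  v = (\tau_2^2 + se_2^2) -
      \frac{(\rho\tau_1\tau_2 + c\,se_1 se_2)^2}{\tau_1^2 + se_1^2}.$$

Setting `se2_new = 0` predicts the latent true effect instead of the
observed one. A `param_uncertainty` flag adds delta-method propagation of
the estimation uncertainty in $(\mu, \tau_1, \tau_2, \rho)$ (GLS covariance
for the means, inverse observed information for the variance parameters).
The default is the plain conditional variance: the package's leave-one-out
calibration experiments show the plain intervals already attain nominal
coverage under the generating model, and the inflation variant is kept as a
documented sensitivity option. Negative computed variances (possible only
through rounding at degenerate fits) are clipped at zero with a warning.

## Weighted linear regression

`fit_wlr()` is the classical summary-data alternative: weighted least
squares of $\log \mathrm{HR}_{OS}$ on $\log \mathrm{HR}_{rPFS}$. "Inverse
variance" is interpreted as the inverse variance of the *regressand*,
$w_i = 1/se_{2i}^2$ (the default); the summed-variance and sample-size
schemes are selectable. The reported $R^2$ is the squared weighted Pearson
correlation, which for a one-covariate weighted regression equals the
weighted coefficient of determination (the code computes both and asserts
agreement to $10^{-10}$). Unlike the bivariate model, the regression treats
the surrogate effects as fixed and does not separate within- from
between-trial variation; its $R^2$ is accordingly attenuation-biased
downward, which is visible in the bundled results (0.63 weighted vs 0.80
shrinkage on the primary set).

Regression bands (`prediction_interval()`) use the textbook form with the
weighted residual scale $s^2$ ($n-2$ denominator) and a $t_{n-2}$ quantile
by default:

$$\hat y(x_0) \pm q\,\sqrt{s^2\Big(\tfrac{1}{w_{new}} + \tfrac{1}{\sum w} +
  \tfrac{(x_0 - \bar x_w)^2}{S_{xx,w}}\Big)},$$

where the $1/w_{new}$ term is present only in the prediction band; the new
trial's weight defaults to the mean observed weight (a "typical trial"),
with a unit-weight alternative.

## Surrogate threshold effect

The STE is the largest surrogate HR at which a new trial can still be
predicted to achieve a statistically significant true-endpoint benefit: the
root of the band's upper limit, found by bracketed root-finding over
HR $\in [10^{-3}, 1]$ to a $10^{-12}$ tolerance (`compute_ste()`), and
checked in the tests for consistency with `prediction_interval()` at
$10^{-8}$.

**Band choice.** The package's default inverts the **confidence band** for
the conditional mean: the threshold then answers "at what surrogate effect
does the *expected* true-endpoint effect of a new trial become
significant?". Inverting the prediction band instead answers the same
question for a *single* new trial including its own between-trial scatter,
and yields markedly more stringent thresholds (0.49 vs 0.83 on the bundled
primary set). Both are legitimate readings of the threshold concept; the
confidence-band default was chosen because it is the reading consistent
with the rest of the package's reporting (thresholds near 0.83 on the
primary set alongside a medium correlation), and because the prediction
band's strong dependence on the arbitrary new-trial weight makes it a
fragile default. The band, quantile rule and new-trial weight are all
exposed as options. In degenerate no-scatter limits the threshold can
exceed 1; it is then reported with an `exceeds_null` flag rather than as an
error, since it is analytically well-defined but clinically vacuous. With
enough residual scatter the band never excludes the null and the STE is
reported as unsolvable.

## Leave-one-out cross-validation

`run_loocv()` removes one trial at a time, refits the bivariate model on
the rest (the likelihood engine by default; the shrinkage engine is
selectable), and predicts the held-out trial's observed OS effect from its
rPFS effect with a 95% interval from `predict_new()`. The headline accuracy
is the proportion of observed effects inside their intervals. The
procedure is deterministic given options; failed refits are flagged,
excluded from the denominator, and counted. Calibration is verified in the
test suite: on a 500-trial synthetic meta-analysis drawn from the fitted
model class, the leave-one-out intervals cover at the nominal rate within
binomial error.

## IQWiG classification and orchestration

`classify_iqwig()` implements the German HTA thresholds, which act on the
correlation scale R: *high* requires the lower 95% limit of R to reach
0.85 (R² 0.7225); *low* means the upper limit is at most 0.7 (R² 0.49);
everything else is *medium*. Validity of the surrogate requires *high*; a
*medium* result permits conclusions only through the threshold-effect
route, so `run_analysis()` always computes the STE and labels it
"required" under a medium classification and "informational" under high;
under low it notes that no surrogacy statement is possible. The overall
label is the weaker of the two methods' labels.

`flag_outliers()` operationalizes "outside the 95% CI in the scatterplot"
as the weighted regression's prediction band (default): the confidence band
at 8–11 trials is so narrow that it flags a third of the trials and is
useless as an outlier screen, though it remains selectable. Note that
visual outlier calls in the literature do not always coincide with any
fixed band rule; the conventional exclusions for the bundled data are
therefore configured explicitly in `build_analysis_set()` rather than
recomputed.

`run_analysis()` wires everything together per analysis set and serializes
to JSON with sorted keys and fixed precision, so a rerun with identical
inputs and options is byte-identical.

## The synthetic-data generator

`simulate_trials()` inverts the analysis model: true surrogate effects
$\theta_1 \sim N(\beta_1, \tau_1^2)$; true clinical effects
$\theta_2 = a + b\,\theta_1 + \epsilon$ with residual SD $\sigma_r$;
within-trial SEs drawn uniformly from stated ranges; observed effects drawn
around the true ones; everything serialized back to HR + 95% CI rows
through the exact inverse of the CI-to-SE conversion. The implied
trial-level $R^2 = b^2\tau_1^2 / (b^2\tau_1^2 + \sigma_r^2)$ is exposed
read-only, and the line and correlation parameterizations are
interconvertible (`line_to_corr()`, `corr_to_line()`).

Defaults emulate the bundled primary analysis: 10 trials, $\beta_1 = -0.42$
and $\tau_1 = 0.42$ (the scale of the observed rPFS effects), conditional
line $-0.03 + 0.33x$ with $\sigma_r = 0.07$ (implied $R^2 \approx 0.80$),
and within-trial SE ranges $[0.05, 0.20]$ and $[0.06, 0.37]$ matching the
span observed in the fixture. Sample sizes are back-computed from the
surrogate SE by the rough balanced-arms rule $se \approx 2/\sqrt{n}$.

What the generator does **not** emulate: non-proportional hazards (PH
status is a flag, never a generated phenomenon), patient-level censoring
and follow-up, correlated within-trial errors beyond a single correlation
parameter, and publication selection. Passing recovery and calibration
tests on synthetic data therefore demonstrates the estimators' internal
correctness under the model, not robustness to those real-data features.

`recovery_experiment()` replicates simulate-and-analyze loops with derived
per-replicate seeds (`seed + replicate`, a counter scheme that keeps
replicates independent and reproducible) and summarizes bias, RMSE and
interval coverage. The package's own calibration experiments use 500
replicates at 50 trials with small within-trial error for bias checks —
small-sample bias of any correlation-type estimator (of order
$(1-R^2)(1-3R^2)/n$) dominates at 10 trials and is a property of the
estimand, not the code — and a single 500-trial meta-analysis for
leave-one-out calibration.

## Worked example

```{r example}
tab <- mcrpc_trials()
report <- suppressWarnings(run_analysis(tab, "primary"))
report
```

## Known limitations

* With ~10 trials the likelihood surface for $(\tau_2, \rho)$ is very
  flat and boundary solutions are the norm, not the exception; the
  shrinkage estimator is a pragmatic, not a fully efficient, answer, and
  its Fisher-type interval ignores the estimation uncertainty in the
  shrinkage weights.
* Between-trial heterogeneity in populations, comparators and assessment
  schedules enters $\tau$ undifferentiated; no meta-regression on trial
  characteristics is offered.
* The within-trial correlation of the two log-HR estimates is assumed, not
  estimated; results should be read alongside the `within_corr`
  sensitivity knob.
* The STE depends visibly on band, quantile and weighting conventions; any
  reported threshold should state all three (the `ste_result` object
  carries them).
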