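# surrometa

Trial-level surrogate-endpoint validation from published summary data, with
radiographic progression-free survival (rPFS) versus overall survival (OS)
in first-line metastatic castration-resistant prostate cancer (mCRPC) as
the bundled worked example.

## What it does

Health-technology assessment bodies ask whether a treatment effect on an
early endpoint predicts the treatment effect on the clinical endpoint
*across trials*. Given a table of per-trial hazard ratios with 95%
confidence intervals for both endpoints, `surrometa`:

* converts each HR + CI to a log-scale effect with standard error,
  `se = (log UCL − log LCL) / (2 · 1.959964)`;
* fits the bivariate random-effects model
  `(y1, y2) ~ N2(θ, S_i)`, `θ ~ N2(μ, Σ)` by REML/ML (`fit_brma()`), where
  the between-trial correlation ρ of Σ squared is the trial-level R²; and,
  because the likelihood estimate of ρ degenerates to the boundary |ρ| = 1
  for typical data of this shape, also computes a shrinkage
  (empirical-Bayes) correlation of the per-endpoint BLUP effects
  (`fit_shrinkage()`), which is the headline R² it reports;
* fits the inverse-variance weighted linear regression
  `log HR_OS = a + b · log HR_rPFS` with weights `1/se_OS²` (`fit_wlr()`);
* computes the surrogate threshold effect (STE): the largest rPFS hazard
  ratio at which the upper 95% limit of the regression band still touches
  `log HR_OS = 0` (`compute_ste()`);
* validates predictions by leave-one-out cross-validation: refit without
  one trial, predict its OS effect from its rPFS effect, count how many
  observed effects fall inside their 95% prediction intervals
  (`run_loocv()`);
* classifies correlation strength per IQWiG (high: lower 95% limit of
  R ≥ 0.85; low: upper limit ≤ 0.7; medium otherwise, `classify_iqwig()`);
* generates synthetic meta-analyses with known surrogacy structure for
  calibration and recovery experiments (`simulate_trials()`,
  `recovery_experiment()`).

The bundled `mcrpc_trials()` table holds eleven phase 3 first-line mCRPC
trials reporting both endpoints; `build_analysis_set()` derives the
conventional analysis sets (primary = PH-assumption met, 10 trials;
sensitivity 1 = all 11; sensitivity 2 = 8 after also dropping two outlier
trials).

## Worked example

```r
library(surrometa)
tab <- mcrpc_trials()
report <- run_analysis(tab, "primary")
report
```

```
Trial-level surrogacy report — primary set (10 trials, 9481 patients)
  BRMA (shrinkage) R2: 0.80 (0.37, 0.95); line: y2 = -0.067 +0.191 y1 [medium]
  BRMA (likelihood) R2: 1.00 (0.00, 1.00) [boundary]
  WLR R2: 0.63 (0.11, 0.90); line: y2 = -0.024 +0.304 y1 [medium]
  IQWiG overall: medium
  STE: HR = 0.83 — required (medium correlation)
  LOOCV: 8/10 inside 95% prediction interval (80%)
  flagged outliers: NCT02294461
```

Reading the output: the shrinkage estimate of the trial-level R² is 0.80
with a wide interval, so per IQWiG the correlation is *medium* and
surrogacy conclusions go through the threshold effect: a new trial whose
rPFS hazard ratio is convincingly below 0.83 would be predicted to show a
statistically significant OS benefit. The likelihood fit is shown alongside
and is flagged as a boundary solution (R² = 1.00), the reason the shrinkage
estimator is the reported one — see the methods vignette
(`vignettes/surrogacy-methods.Rmd`). In leave-one-out validation, 8 of the
10 observed OS effects fall inside their 95% prediction intervals.

`plot_correlation(fit_wlr(to_effects(tab)))` draws the scatter with
confidence and prediction bands; `plot_loocv(run_loocv(to_effects(tab)))`
draws the observed-versus-predicted interval plot.

A thin CLI over the same functions is installed at
`inst/scripts/surrogate-eval` (subcommands `run`, `dump-fixture`,
`simulate`).

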