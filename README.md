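# velogaze

Cyclist attention from wearable eye-tracking: composite scoring and
hierarchical ordered logistic modelling.

## What it does

Campus roads carry dense, tidal flows of bicycles and pedestrians, and how
much attention a cyclist devotes to the riding task is a safety-relevant,
indirectly observable quantity. `velogaze` implements the full analysis
chain for studying it from eye-tracking data:

* **Gaze metrics** — per-trial indicators from a labelled 50 Hz sample
  stream: fixation/saccade time shares, blink rate, mean event durations,
  pupil statistics, the *lane fixation share* (fixation time on the
  driving-lane area over total fixation time) and the *pupil diameter
  coefficient of variation* P = σ/d̄.
* **Composite attention score** — correlation-matrix PCA over the
  indicators, eigenvalue > 1 retention, eigenvalue-proportional weights,
  oriented so higher = more focused; equal-frequency cuts into three
  ordered levels (1 Distracted, 2 Scattered, 3 Focused). One-way ANOVA
  screening of candidate factors.
* **Two ordinal models** of attention level F with riding style and traffic
  density as dummy-coded predictors, logit P(F ≤ k) = γ_k − θ:
  * a standard cumulative-logit model fitted by maximum likelihood
    (`fit_ordered_logit()`), with Wald statistics, 95% intervals and odds
    ratios;
  * a hierarchical ordered logistic model (`fit_hier_mcmc()`) with
    cyclist-specific thresholds γ_kj = γ_k + Σ_q α_q z_qij + B_j, where z
    are the two gaze covariates and B_j ~ N(0, 1/τ) is a cyclist random
    effect with τ ~ Gamma(0.01, 0.01) — estimated by a Metropolis-within-
    Gibbs sampler with a conjugate Gibbs update for τ.
* **Evaluation** — observed-vs-predicted cross tables, overall accuracy,
  model comparison in percentage points, and odds-ratio analysis with
  reference-level recoding.
* **Synthetic data** — a generator that emulates the study design
  (9 cyclists × 3 sections × 2 directions × 2 periods = 108 trials, ~11
  lost to attrition) under known true parameters, down to raw gaze streams,
  so the whole chain is testable offline.

The methods vignette (`vignettes/attention-modelling.Rmd`) documents the
models, priors, sampler, generator assumptions and numerical choices.

## Worked example

Simulate a study, fit both models, and compare them in-sample:

```r
library(velogaze)

design <- generate_design(design_spec(), seed = 1)   # 108 trial skeletons
trials <- simulate_trials(design, true_params(), seed = 2)
nrow(trials)
#> [1] 93        # after ~10% recording attrition

fit_std <- fit_ordered_logit(trials)
fit_std
#> Cumulative-logit attention model (3 levels, n = 93)
#>                        term estimate     se    wald         p ci_lower ci_upper
#> 1               threshold_1   0.8562 0.4017  4.5437 3.304e-02  0.06893    1.643
#> 2               threshold_2   1.8780 0.4409 18.1442 2.048e-05  1.01388    2.742
#> 3 riding_style=conservative   1.1902 0.4312  7.6204 5.771e-03  0.34514    2.035
#> 4  traffic_density=moderate   0.1374 0.5124  0.0719 7.886e-01 -0.86689    1.142
#> 5    traffic_density=sparse   1.8657 0.5127 13.2439 2.735e-04  0.86089    2.871
#> log-likelihood: -87.0924

fit_hier <- fit_hier_mcmc(trials, n_iter = 2000, n_warmup = 2000,
                          n_chains = 2, seed = 3)

acc <- function(fit, predict_fun) {
  accuracy(cross_table(trials$attention, predict_fun(fit, trials)$level))
}
acc(fit_std, predict_category)        # in-sample accuracy, standard model
#> [1] 56.99
acc(fit_hier, predict_category_hier)  # hierarchical model
#> [1] 67.74
```

The positive `riding_style=conservative` coefficient means conservative
riders have higher odds of a more focused attention level (here
exp(1.19) ≈ 3.3 times the odds of aggressive riders); `traffic_density=sparse`
likewise means sparse traffic favours attention relative to dense traffic.
The hierarchical model's in-sample gain comes from absorbing per-cyclist
heterogeneity through the random threshold shifts.

Odds ratios with reference recoding work on fits or on plain coefficient
tables:

```r
refs <- load_reference_tables()   # published campus-study results (bundled)
odds_ratios(refs$coefficients$hologit)
#>                        term estimate   odds_ratio
#> 1 riding_style=conservative    1.133 3.1049574140
#> 2    traffic_density=sparse    2.031 7.6217042535
#> 3  traffic_density=moderate    0.862 2.3678917446
#> 4              lane_fix_pct    0.105 1.1107106104
#> 5                  pupil_cv   -9.560 0.0000704928

odds_ratios(refs$coefficients$hologit,
            recode_reference = c(traffic_density = "sparse"),
            old_reference = c(traffic_density = "dense"))
# moderate vs sparse: OR 0.311
```

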