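# harmimpute

Self-harm is one of the most under-recorded outcomes in US administrative
claims: most true events never receive an intentional-self-harm diagnosis
code, which cripples observational studies of whether bipolar-disorder (BD)
treatments prevent it. `harmimpute` is an R package for
comparative-effectiveness analysis of self-harm risk under BD treatment
regimens in longitudinal claims data, built around machine-learning
imputation of the under-coded outcome. It is aimed at
pharmacoepidemiologists and biostatisticians who work with visit/fill-level
claims tables.

## What it does

* **Meta-visits** — merges a patient's consecutive
  outpatient/inpatient/ER visits (overlapping or on adjacent days) into
  single care episodes, and labels the coded self-harm phenotype from a
  configurable code set.
* **Outcome imputation** — for every meta-visit with an inpatient/ER
  component, estimates P(self-harm) by k-fold cross-validated penalized
  logistic regression on age, sex, start year and binary indicators for
  every non-self-harm billing code expanded to its vocabulary ancestors.
  The outcome at threshold *t* is *coded or imputed*:
  coded ∨ (inpatient/ER ∧ p > t).
* **Staging** — inclusion (≥2 BD diagnosis codes), exclusion (other major
  mental illness), and the prespecified sequence of events: 365-day
  lookback → BD index visit → index exposure (time 0 = last day of the
  index visit) → follow-up to the first outcome, the first
  self-harm-unrelated inpatient/ER meta-visit, a censoring condition, or
  the end of enrollment.
* **Time-varying exposure** — reconstructs per-agent drug coverage from
  fills with a 30-day grace period, resolves switch vs combination by
  residual coverage, labels regimens (monotherapies by agent, combinations
  by drug-class sets, within-class multi-MSA/multi-SGA), pools rare
  regimens (uncommon monotherapy, polypharmacy 2/3/4), and emits
  counting-process rows `(start, stop, event]` with a time-varying
  psychotherapy flag and prior-drug count.
* **Cox models** — model 1: every retained regimen vs lithium monotherapy
  (plus psychotherapy and baseline covariates); model 2: pharmacotherapy ×
  psychotherapy in four categories vs no treatment. Both use Efron ties,
  natural-spline terms (df = 4) for age and prior unique BD drugs with a
  separable linear component and a joint nonlinear test, and
  Benjamini–Yekutieli FDR correction of the treatment contrasts:
  reject the k smallest p-values where k is the largest index with
  p(k) ≤ k·q / (m·Σᵢ1/i).
* **Factorial covariate selection** — a resolution-IV two-level
  fractional factorial over pretreatment covariates (fold-over of a
  saturated resolution-III design, plus an all-exclude reference run); one
  Cox fit per run; OLS of each treatment coefficient on the design;
  significance counts at 0.05/n_treatments; discard-never-significant,
  backward elimination, and an L2-norm bias diagnostic against the
  reference run.
* **Sensitivity framework** — the imputation threshold sweep
  (0.20–0.95 and coded-only), incidence per 100,000 person-years at risk
  (PYAR), and publication-shaped tables/figures via `render_report()`,
  `autoplot()` and `tidy()`/`glance()` methods.
* **Synthetic claims generator** — because real claims are proprietary,
  `ground_truth()` + `simulate_population()` generate a full synthetic
  world (enrollment, diagnosis streams, confounded regimen episodes,
  proportional-hazards events, proxy-coded event visits with configurable
  under-recording, fills) with oracle tables for parameter-recovery
  testing.

## A worked example

```r
library(harmimpute)

# a synthetic world: 50% of true events coded, lamotrigine protective
# (log-HR -0.30), drug-free periods at log-HR -0.58, psychotherapy log(0.59)
gt    <- ground_truth(coding_fraction = 0.5, baseline_hazard = 1.5e-4, seed = 1)
vocab <- generate_vocabulary(seed = 1)
sim   <- simulate_population(gt, vocab, n_patients = 4000, seed = 1)

res <- run_pipeline(sim, threshold = 0.5, seed = 1,
                    min_intervals = 20, min_events = 3)

mv <- res$metavisits
rank_auc(mv$selfharm_prob[mv$has_inpatient_or_er],
         mv$coded_selfharm[mv$has_inpatient_or_er])
#> [1] 0.9698911

dplyr::filter(tidy(res$model), is_treatment)[, c("term", "hr", "conf.low",
                                                 "conf.high", "p.value")]
#> # A tibble: 5 × 5
#>   term                  hr conf.low conf.high p.value
#>   <chr>              <dbl>    <dbl>     <dbl>   <dbl>
#> 1 regimenLITHIUM+MSA 1.69     1.10      2.59  0.0169
#> 2 regimenhaloperidol 1.38     0.768     2.46  0.284
#> 3 regimenquetiapine  1.21     0.743     1.97  0.443
#> 4 regimenlamotrigine 0.763    0.452     1.29  0.310
#> 5 regimenno_drug     0.508    0.316     0.816 0.00508
```

The cross-validated AUC of 0.97 against the coded label shows the proxy
injury codes make the outcome imputable, and the fitted hazard ratios
recover the planted values within their intervals (lamotrigine planted at
e^-0.30 ≈ 0.74, drug-free periods at e^-0.58 ≈ 0.56, lithium+MSA at
e^0.30 ≈ 1.35, all vs the lithium reference), with 199 outcome events at
this threshold.
`autoplot(res$model)` draws the forest plot; `threshold_sweep()` repeats
staging and fitting across imputation thresholds.

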