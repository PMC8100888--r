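---
title: "Methods: imputed self-harm outcomes and time-varying treatment risk in claims data"
author: "harmimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputed self-harm outcomes and time-varying treatment risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmimpute)
```

## The problem

Self-harm is severely under-recorded in US administrative claims: most true
events never receive an intentional-self-harm diagnosis code, even though
the surrounding billing activity (injury codes, poisoning codes, emergency
care) is highly characteristic. Comparative-effectiveness studies of
bipolar-disorder (BD) pharmacotherapy that rely on coded self-harm alone are
therefore badly under-powered and potentially biased.

`harmimpute` implements an end-to-end pipeline for this setting:

1. merge raw visits into **meta-visits** (contiguous care episodes),
2. **impute** the probability of self-harm for every inpatient/ER
   meta-visit by cross-validated penalized logistic regression on
   hierarchy-expanded billing codes,
3. **stage** patients through a prespecified sequence of events (lookback
   year, BD index visit, index exposure, follow-up, outcome or censoring),
4. construct **time-varying drug-regimen exposure intervals** from
   outpatient fills and emit counting-process rows,
5. fit two **time-varying Cox models** (65-regimen comparison against
   lithium monotherapy; a 4-category pharmacotherapy-by-psychotherapy
   comparison against no treatment) with natural-spline terms and
   Benjamini–Yekutieli false-discovery control,
6. select bias-relevant pretreatment covariates with a **resolution-IV
   fractional factorial** sensitivity procedure, and
7. sweep the imputation **probability threshold** (0.20–0.95 and
   coded-only) as a sensitivity framework.

Because real claims databases are proprietary, the package ships a
synthetic claims generator with planted ground truth; every stage is
validated against that ground truth.

## The synthetic world

`ground_truth()` + `simulate_population()` define the data-generating
process. Time is day-indexed (day 0 = simulation start); visit intervals
are closed on both ends, drug coverage and exposure intervals are half-open
`[start, stop)`.

* **Enrollment and demographics.** Each patient receives an enrollment span
  (500+ days, exponential tail), a sex, and a birth year giving ages 15–80.
* **Diagnosis stream.** Almost all patients (95% by default) receive two
  or more BD diagnosis codes, one of them on a planted index visit placed
  366–426 days after enrollment start so that the 12-month lookback is
  satisfiable; 5% carry an excluding major-mental-illness code.
* **Exposure episodes.** Post-index time is partitioned into episodes
  (30 days + exponential with mean 150). Each episode draws a regimen from
  a configurable label set via a multinomial logit whose weights are tilted
  by patient-level binary confounders — this is what creates indication
  bias for the factorial procedure to detect. Episodes emit 30-day fills
  per agent, so the exposure module can reconstruct the timeline from
  fills alone.
* **Events.** True self-harm events arise from a piecewise-constant-hazard
  exponential process: hazard = baseline × exp(regimen log-HR + confounder
  effects + psychotherapy effect). This matches the proportional-hazards
  model fitted downstream, so parameter recovery is a clean test.
* **Under-recording.** Every true event produces an inpatient-or-ER visit
  that always carries a random bundle of 3–8 proxy injury codes and
  carries an explicit self-harm code only with probability
  `coding_fraction`. The proxy bundle is what makes imputation learnable —
  the high classifier AUC regime reported for real claims is only possible
  because self-harm has strong code correlates.
* **Noise.** Background outpatient visits (≈6/year) with random hierarchy
  codes, plus self-harm-unrelated inpatient/ER visits (≈0.4/year) that act
  downstream both as censoring events and as class-0 training examples.

### Default conditions

The generator defaults encode the study conditions the pipeline targets:

| Parameter | Default | Why |
|---|---|---|
| `coding_fraction` | 1/19 | the observed under-recording of self-harm in US claims |
| `baseline_hazard` | 4e-5 /day | ≈0.015 events/person-year, so coded events ≈ 80/100,000 PYAR and total events ≈ 1,400/100,000 PYAR — the BD-cohort regime |
| `psychotherapy_log_hr` | log 0.59 | the protective psychosocial-intervention association |
| `no_drug` log-HR | −0.58 | drug-free intervals at HR ≈ 0.56 vs lithium |
| `lamotrigine` log-HR | −0.30 | a protective monotherapy (HR ≈ 0.74) |
| non-event inpatient/ER rate | 0.4 /person-year | keeps uncoded event visits a small minority of inpatient/ER meta-visits, the regime in which AUC vs the coded label is high |

What the generator does **not** emulate: real vocabulary structure (a small
synthetic DAG stands in for SNOMED/ICD hierarchies), dose/route/release
information, state of residence, plan types, and the slow calendar drift of
coding practice. Passing recovery tests therefore demonstrates the
statistical machinery, not robustness to real-world coding idiosyncrasies.

## Meta-visits and the coded phenotype

`build_meta_visits()` merges a patient's visits whenever the next visit
starts no later than the running maximum end day plus `gap_days`
(default 1). "No gap" is operationalized as *adjacent-or-overlapping
calendar days*: a discharge on day d followed by an admission on day d+1 is
one care episode, which captures transfers between settings. `gap_days = 0`
(overlap/same-day only) is available since the adjacency convention is a
judgment call. Codes and settings are unions over merged visits, the
partition is order-independent, and re-merging the output is idempotent.

`label_coded_selfharm()` marks class 1 iff the meta-visit's code set
intersects the vocabulary's self-harm set.

## Imputation

Features per inpatient/ER meta-visit: age at start, sex, calendar start
year, and one binary indicator per non-self-harm code present, expanded to
all vocabulary ancestors. Self-harm codes *and ancestors reachable only
from the self-harm set* are excluded — they would leak the label. Code
indicators seen fewer than `min_support = 10` times are dropped for
tractability.

The default classifier is ridge-penalized logistic regression (glmnet) fit
along a warm-started path down to `lambda = 1e-3`; the interface is
pluggable (`fit_fun`/`predict_fun`) because the pipeline is
classifier-agnostic by design. Folds are stratified by class (prevalence is
well under 1%, so unstratified folds risk empty-positive folds); every
meta-visit is scored by the model that never saw it (out-of-fold
discipline). Meta-visit-level folds are the default to match the unit of
analysis; patient-level folds are available to preclude within-patient
leakage.

Outpatient-only meta-visits receive probability 0: coded self-harm during
purely outpatient episodes is negligible, and scoring them would
extrapolate the model outside its training support.

`apply_threshold(mv, t)` defines the outcome as *coded or imputed*:
`coded | (inpatient/ER & prob > t)`, with a strict inequality, so `t = 1`
reduces exactly to the coded phenotype. Outcome sets are nested
(monotone) in `t`.

At desk scale the imputation tests raise `coding_fraction` to 0.3–0.5 so
that five folds each contain enough coded positives to train on; this
exercises classifier learnability, while the 1-in-19 under-recording itself
is tested directly on the generator at scale.

## Staging

Eligibility: ≥2 BD diagnosis-code occurrences, and no excluding
major-mental-illness code at any time. The index visit is the first
BD-coded meta-visit with ≥365 days of enrollment before its last day
(continuous enrollment is assumed — the stricter reading — and the window
is configurable). Time zero is the last day of the index visit. Follow-up
ends at the earliest of: the first post-index outcome meta-visit; the first
post-index self-harm-unrelated inpatient/ER meta-visit (treatment cannot be
observed during facility stays, and hospitalization itself alters risk);
onset of a censoring condition (intellectual disability / autism / organic
mental illness / Parkinson-type codes, or an anti-dementia fill); or the
end of enrollment. Same-day ties resolve outcome > hospitalization >
condition. Outcomes strictly after time zero count ("newly observed");
prior coded self-harm is a covariate, not an exclusion.

Baseline covariates from the lookback year: configurable code-set
indicators (the mechanism generalizes to arbitrary condition/drug lists;
the package ships a representative subset rather than a fixed 78-covariate
catalogue), prior coded self-harm, prior hospitalization, prior unique BD
drugs, sex, age at index, and index-visit characteristics (mood polarity
with an explicit unknown level, outpatient presence).

## Exposure intervals

Per agent, coverage is the union of `[fill, fill + days_supply)` spans with
gaps ≤ `grace_days` (default 30, the conventional pharmacoepidemiology
grace period) bridged. When a new agent starts while a previous agent has
fewer than `grace_days` of residual coverage, the overlap is read as a
switch (the old agent is truncated); longer overlaps are combinations.
Uncovered spans are `no_drug`. Labels: monotherapies by agent name,
within-class multi-agent regimens as `MULTI_MSA`/`MULTI_SGA` (the only two
classes where this is common), other combinations by sorted class names.

Regimens need ≥ `min_intervals` intervals and ≥ `min_events` events to be
retained (the publication-scale requisites are 1000/5; desk-scale analyses
use smaller values such as 20/3 — the package takes them as parameters, and
lower imputation thresholds naturally retain more regimens). Failing
monotherapies pool into `UNCOMMON_MONOTHERAPY`, failing combinations into
`POLYPHARMACY_2/3/4` by class count; `no_drug` never collapses.

Counting-process rows are half-open `[start, stop)` with time zero at the
index exposure and the event on the terminal interval — the standard
survival::Surv(start, stop, event) layout. Psychotherapy is a binary
time-varying covariate (any psychotherapy procedure code during the
interval). `prior_unique_bd_drugs` counts agents first filled in the
lookback year or in any earlier interval, so it is non-decreasing within a
patient.

## Cox models, splines, multiplicity

Fitting is via `survival::coxph` with Efron ties (day-granular data tie
heavily; Efron is the accepted default), Wald CIs, convergence at relative
log-likelihood change < 1e-9. Model 1: regimen factor against lithium
monotherapy + psychotherapy + selected baseline covariates + spline terms.
Model 2: a four-category time-varying factor (no treatment / drug alone /
psychotherapy alone / both) against no treatment, same covariates.
Zero-event regimens are dropped with a message.

Spline terms for age and prior unique BD drugs use a natural cubic basis
with interior knots at quantiles (df = 4 by default), reparameterized into
the raw linear term plus df−1 nonlinear columns orthogonalized against
span{1, x}. This makes the *linear component* directly reportable as a
hazard ratio and gives a joint Wald test for the nonlinear components, and
`spline_hazard_curve()` evaluates HR(x) against a reference value (HR = 1
with a zero-width CI at the reference) with delta-method pointwise bands.
Fewer than df+2 distinct values degrade gracefully to a linear term.

Treatment-term p-values are corrected by the Benjamini–Yekutieli step-up
procedure (valid under the arbitrary dependence of 60+ contrasts sharing
one reference), implemented directly so the realized p-cutoff can be
reported, and cross-checked against `stats::p.adjust(method = "BY")` in the
tests.

## Factorial covariate selection

Instead of asking whether pretreatment covariates predict the outcome, the
procedure asks whether their inclusion *moves the treatment estimates*.
`build_design(p, n)` constructs a two-level design: a saturated
resolution-III design on n/2 runs (Yates-ordered interaction columns of a
full factorial), folded over (sign-reversed runs appended) to resolution
IV — main effects orthogonal to two-factor interactions — plus an
all-exclude reference run. The published scale is 78 covariates × 512 runs
(+ reference); the aliasing property is verified programmatically at any
scale.

`run_factorial()` fits one Cox model per run (treatment terms always in,
covariate j in iff +1) and collects the treatment-coefficient matrix Y.
`score_covariates()` regresses each treatment column of Y on the design by
OLS and counts significances at 0.05/n_treatments; never-significant
covariates are discarded. `backward_eliminate()` drops candidates in order
of increasing impact (ties broken toward larger minimum p) with a Cox refit
per step, stopping at the first candidate with minimum p below `stop_p`
(default 1e-3 — "highly significant" is not quantified in the source
procedure, so it is a configurable operationalization). `bias_norm()` takes
each run's Euclidean distance of the coefficient vector from the reference
run's vector and regresses those distances on the design to rank global
bias sources. The distance is computed on rows of the *coefficient* matrix:
distances between ±1 design rows carry no information about estimates, so
the procedure is only meaningful on Y.

Desk-scale defaults in the examples use ~8–15 candidate covariates on
16–32 base runs; the 78 × 512 configuration remains available and is
exercised structurally in the tests.

## Threshold sensitivity and incidence

`threshold_sweep()` re-runs staging, exposure construction (requisites
re-checked) and the model per threshold, reusing the probabilities computed
once — only the threshold varies, never the classifier. Outcome counts and
retained-regimen sets shrink monotonically in t (asserted). Infeasible
thresholds (zero events) are reported and skipped.

`incidence()` is exact arithmetic — events (or summed probabilities) per
person-year, scaled to 100,000 PYAR, with integer rounding for display
only; full precision is retained in files.

## Numerical and design choices

* Penalized-path fitting for the classifier: a single small ridge penalty
  can diverge in coordinate descent; a warm-started path to the target
  penalty is stable and deterministic.
* The nonlinear spline transfer map uses a minimum-norm pseudo-inverse
  (the projected natural-spline basis is rank df−1 by construction).
* Same-day tie precedence in staging (outcome > hospitalization >
  condition) is a convention; events on the index day are never outcomes.
* All randomness flows from explicit integer seeds; fixed seed ⇒
  byte-identical tables end to end.
* Problem sizes in the tests (populations of 600–5,000 patients, 16–32
  base factorial runs, 20–50 replicates) were chosen as the smallest
  scales at which the statistical properties under test are comfortably
  powered.

## Limitations

Treatment assignment is non-randomized and only the planted confounders
are adjustable; the factorial procedure ranks *impact on estimates*, not
causal confounding per se. Dose, route and release mechanism are out of
scope. The synthetic vocabulary is a minimal DAG, not a SNOMED emulator,
and the synthetic schema is a minimal claims stand-in rather than an
emulation of any vendor's internal layout. Hazard ratios from the
published real-data analysis are not reproducible from synthetic data;
what the package demonstrates is recovery of *planted* parameters under
the same modelling assumptions.

## A worked example

```{r example, eval = FALSE}
library(harmimpute)

gt <- ground_truth(coding_fraction = 0.5, baseline_hazard = 1.5e-4, seed = 1)
vocab <- generate_vocabulary(seed = 1)
sim <- simulate_population(gt, vocab, n_patients = 1600, seed = 1)

res <- run_pipeline(sim, threshold = 0.5, seed = 1,
                    min_intervals = 20, min_events = 3)
tidy(res$model)          # hazard ratios vs lithium
glance(res$model)
autoplot(res$model)      # forest plot

mv <- res$metavisits
rank_auc(mv$selfharm_prob[mv$has_inpatient_or_er],
         mv$coded_selfharm[mv$has_inpatient_or_er])
```
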