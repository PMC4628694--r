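---
title: "shockwatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shockwatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockwatch)
```

This vignette is the package's own account of its science: the models
and rules it implements, the conventions it adopts where several were
defensible, what the synthetic-data generator does and does not
emulate, and the limits of what a green test establishes.

## Data model

A patient record holds up to 15 irregularly sampled series — seven
from continuous hemodynamic monitoring (SBP, DBP, MAP in mmHg, HR in
bpm, RR in breaths/min, CVP in mmHg, CO in L/min) and eight
clinical/laboratory parameters (T in °C, arterial pH, creatinine in
mg/dL, glucose in mg/dL, lactate in mmol/L, hematocrit in %, WBC in
cells/cmm, SpO2 in %) — plus timestamped intravenous fluid volumes
(mL), the ICU stay length and an optional death time. The time axis is
hours since ICU admission, as floating point: none of the downstream
logic needs calendar dates, and this avoids timezone handling
entirely.

Cohorts are exchanged as three long-format CSV files (vitals, fluids,
outcomes). Duplicate timestamps within one variable are rejected at
read time rather than averaged: silently aggregating charting errors
would be irreversible, and rejection keeps the reader deterministic.

**Inclusion criteria.** A record enters the analysis when HR, T, SBP
and RR each carry at least 10 values, WBC at least 2, and the ICU stay
is at least 48 h (the stated exclusion is a stay *less than* 48 h, so
the boundary is included). The value counts are taken over the whole
stay; no windowing is stated for them. Patients missing an entire
non-gating variable (say, no CO series) remain included — their
derived features become missing and flow to imputation.

## Onset detection

All interval reasoning uses **sample-and-hold** semantics: a
measurement is valid from its own timestamp until the next measurement
of the same variable, and the last value is held to the end of stay.
This is the weakest assumption consistent with reasoning like "the
temperature was above 38 °C from hour 1 to 23" about discrete
samples; no interpolation is implied by such statements.

SIRS abnormality episodes are built in four steps:

1. per-criterion abnormal intervals (T > 38 or < 36 °C; HR > 90 bpm;
   RR > 20 breaths/min; WBC > 12,000 or < 4,000 cells/cmm — all
   comparisons strict as printed);
2. intervals where at least `min_criteria` criteria are abnormal
   simultaneously;
3. each interval's start backtracked to the earliest time from which
   at least one contributing criterion is continuously abnormal into
   the interval — so an episode is dated from the first measured
   parameter that met its criterion, not from the moment the criterion
   count was reached (a patient febrile from hour 1 whose first
   abnormal WBC arrives at hour 6 has an episode starting at hour 1);
4. intervals less than 6 h apart merged (strict), then merged episodes
   lasting 5 h or less discarded (strict).

The merge-before-duration order is deliberate: filtering first could
discard a genuinely prolonged abnormality fragmented by sparse
sampling. `min_criteria` defaults to 2 of 4 — the conventional SIRS
definition, and the only reading consistent with the hour-1/hour-6
example, where only temperature and WBC are ever abnormal — but 4 of 4
is selectable.

Prolonged hypotension is SBP < 90 mmHg held for at least 30 minutes.
The resuscitation window of an episode runs from 1 h before its start
to halfway through it, closed at both ends (an event exactly on a
boundary counts). An episode is sepsis-induced when it overlaps an
abnormality episode — overlap, not containment, since hypotension can
outlast the abnormality interval that contains its onset — and its
window fluid intake strictly exceeds 600 mL. The earliest
sepsis-induced episode's start is the onset. A record with exactly one
prolonged hypotensive episode is classified as *without* septic shock
(`single_hypotension_episode`); the count rule is keyed on prolonged
hypotension episodes, as stated, not on sepsis-induced ones. When
several no-onset reasons apply at once the hypotension-count rules
take precedence over `no_sirs`. Episodes end when their defining
condition ends; no separate end rule is defined.

**Numerical choice.** Duration and gap comparisons carry a 10⁻⁹ h
tolerance so that a gap of exactly 6 h, computed from sample times
that are not exactly representable in binary, behaves as exact
arithmetic would. This is ten orders of magnitude below charting
resolution and exists purely to make strict boundaries deterministic;
it is what lets the implementation agree exactly with the
integer-minute brute-force oracle used in the tests.

## Features and labels

From each series restricted to [onset, onset + 48 h] (closed
endpoints, times re-expressed as hours since onset) nine statistics
are computed: mean, sample (n−1) standard deviation, min, max, median,
kurtosis, skewness, OLS slope against time (units/h, irregular
sampling respected, unweighted), and delta = last − first observed
value (raw endpoint samples, not held values). With 15 variables this
gives the 135-feature vector, ordered variable-major.

Conventions worth naming:

* **Kurtosis is Pearson (non-excess)**, the population moment ratio
  m₄/m₂², so a Gaussian tends to 3 — consistent with published
  survivor/nonsurvivor tables in this setting reporting lactate
  kurtosis near 3. Skewness is m₃/m₂^1.5. Both use population
  (biased) moment estimators.
* **Minimum counts**: 1 sample for mean/min/max/median, 2 for
  std/slope/delta, 3 for skewness, 4 for kurtosis — the smallest n for
  which each estimator is defined; below that, the statistic is
  missing. A zero-variance series has undefined skewness/kurtosis
  (missing), slope 0, delta 0.
* The 7-day label is NS iff death occurs within 168 h of onset,
  boundary included ("within 7 days").

Mean imputation replaces each missing cell by the across-patient mean
of the observed values of that feature, once, cohort-wide, before all
analyses. This mirrors a single-imputation design and deliberately
accepts its leakage caveat: imputation values computed on the full
cohort touch patients later placed in CV test folds. Fold-wise
imputation would be cleaner for honest error estimation; the package
keeps the single-step design because the screen and the model are
specified downstream of one imputed matrix, and flags the caveat here.

## Univariate screen

Each feature is compared between survivors and nonsurvivors with the
two-sided Wilcoxon rank-sum test: exact-distribution p-values by
enumeration when both groups have ≤ 10 observations and no ties,
otherwise the normal approximation with tie-corrected variance and no
continuity correction. Multiplicity is handled by Benjamini–Hochberg
step-up q-values (the procedure is not named in the source analyses;
BH is the standard choice). Group summaries are medians and quartiles
with the linear-interpolation quantile definition (type 7).
Significance is declared at raw p < 0.05, matching the stated
significance level; q-values are reported alongside.

## Mortality model

The outcome model is a penalized **linear** regression on the 0/1
label — not logistic — because that is the stated model class;
classification thresholds the linear prediction at 0.5. The elastic
net objective is

$$\frac{1}{2n}\lVert y - X\beta\rVert^2
  + \lambda\left(\alpha\lVert\beta\rVert_1
  + \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

solved by cyclic coordinate descent with soft-thresholding on
standardized features (population SD), warm starts along a 100-point
log-spaced grid from λ_max (the smallest penalty zeroing every
coefficient) down to 10⁻⁴ λ_max, convergence when the largest
coefficient change in a sweep is below 10⁻⁷, with active-set sweeps
between full sweeps for speed. Standardization is computed on the
training portion within each CV fold (avoiding scale leakage);
reported coefficients are returned on the original feature scale.

Cross-validation is stratified, at 3, 4 and 5 folds; the selection
criterion is misclassification error at the 0.5 threshold; λ_1se is
the largest penalty within one standard error (across-fold SD/√k) of
the minimum. The "best model" across fold counts is the one whose
1se model has the lowest cross-validated error, ties to the larger
fold count — the source analysis names no criterion, and this is
recorded as a package choice. The mixing weight α is unreported in
the source; the default is 0.5, configurable.

Features active at λ_1se (falling back to λ_min if the 1se model is
empty — possible on weak-signal cohorts) are then pruned by iterative
VIF: VIF_j = 1/(1−R²_j) of feature j regressed on the others; while
max VIF > 5 the single worst feature is removed and VIFs recomputed.
Exact collinearity gives VIF = ∞ and goes first; ties remove the
later feature in canonical order. The pruned set is refit by ordinary
least squares, reported with in-sample MSE, and evaluated by 5-fold
stratified CV with per-fold rank-based (trapezoidal) AUC, reported as
mean ± SD over folds.

## The synthetic cohort generator

The generator exists so that every stage is testable without access
to protected clinical databases; it emulates the *statistical
structure the analysis assumes*, not physiology. Per patient, each
series is a piecewise-constant-plus-trend baseline with Gaussian
noise, sampled at exponential inter-arrival times — monitor variables
every 0.25–1 h on average, laboratory variables every 4–12 h. A
SIRS-type abnormality period (elevated HR/RR/T, abnormal WBC) begins a
few hours into the stay. Two prolonged hypotension dips are planted
inside it: a decoy whose resuscitation-window fluid stays at or below
600 mL, and the true onset episode with a qualifying bolus (650–1200
mL) — so the fluid rule is exercised in both directions in every
record. SBP samples are pinned at the dip boundaries, making the
ground-truth onset exactly recoverable; between the dips SBP is kept
normotensive so the two episodes cannot fuse.

Default survivor/nonsurvivor contrasts follow the direction and rough
magnitude of published group comparisons in septic shock: nonsurvivor
MAP ≈ 64 vs survivor ≈ 75 mmHg, SBP slope ≈ −0.04 vs +0.33 mmHg/h,
lactate ≈ 6.7 vs 3.2 mmol/L, CVP ≈ 17.3 vs 14.3 mmHg, SpO2 ≈ 94.4 vs
97.3 %, with smaller contrasts on HR, RR, T, pH, CO and WBC
variability. Nonsurvivors die 50–160 h after onset (within the 7-day
horizon, and late enough that the 48 h feature window is fully
observed); survivors' stays extend 24–96 h beyond the window. The
declared planted-feature list is {mean_MAP, mean_SpO2, mean_lactate,
mean_CVP, slope_SBP}; `minimal_effect_profile()` removes every other
group contrast for experiments that need the informative set to be
exactly those five variables. `generate_null_cohort()` draws all
patients from the survivor physiology and assigns labels (with
consistent death times) independently of every series, for
false-discovery calibration.

What the generator does **not** emulate: physiological coupling
between variables (each series is independent given the group),
treatment dynamics beyond fluid events, missingness that is
informative rather than sampling-driven, measurement artifacts, and
class overlap as severe as real cohorts — the planted contrasts make
mortality nearly separable, which is why the demo pipeline reaches
AUC ≈ 1. A green test therefore establishes that the machinery is
correct (rules, statistics, solver, bookkeeping), not that the model
would achieve any particular discrimination on real patients.

## Selection recovery and correlated twins

One acceptance experiment deserves an honest note. Planting an effect
on a series *level* necessarily informs the whole statistic family of
that variable — a MAP shift moves mean_MAP and median_MAP by the same
standardized amount — so "exactly 5 informative features among 135"
cannot exist at the series level; each planted feature has
near-duplicate twins. At the default mixing α = 0.5 the 1se-selected
model always located all five planted effect families, but in 4 of 10
seeds substituted a twin within one family (median_MAP for mean_MAP),
failing strict feature-level recovery. At the grouping-oriented
mixing α = 0.2 — the standard elastic-net configuration when
informative predictors come in correlated groups, which is precisely
this situation — strict recovery was 10/10. The acceptance test
asserts strict recovery at α = 0.2 and family-level recovery at the
default; the pipeline default remains α = 0.5.

## Known limitations

* Cohort-wide mean imputation leaks information into CV folds (see
  above); offered as-is by design, with the caveat recorded.
* The linear probability model can emit predictions outside [0, 1];
  thresholding at 0.5 is still well-defined, and a logistic variant
  was deliberately left out of scope to keep the model class as
  stated.
* Exact rank-sum p-values are only used for groups of ≤ 10 without
  ties; published cohort sizes (15/8, 53/20) fall in the approximate
  regime either way.
* The detector's episode *ends* follow the defining condition's end;
  no clinical end-of-shock rule is implemented.
* Reported headline numbers from credentialed clinical extracts
  (attrition fractions, table values, AUC comparisons against SOFA
  and SAPS) are out of reproduction scope; the package reproduces the
  analysis, not the data.
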