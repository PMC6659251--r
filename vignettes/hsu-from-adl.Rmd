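---
title: "Estimating health-state utility from ADL records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating health-state utility from ADL records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cost-effectiveness analyses weight life-years by health-state utility (HSU),
but HSU is rarely measured in a representative sample of patients: patient
surveys are small and tend to recruit younger patients with fewer
comorbidities. Hospital discharge registries offer another route. They cover
essentially all patients with a severe condition, and in post-acute
(rehabilitation) care six activities of daily living (ADLs) — dressing or
bathing, functional mobility, self-feeding, continence, social interaction,
communication — are scored on a common ordinal scale (0 = total dependence to
3 = independence) at admission and then weekly until discharge. `hsuADL`
turns such records into HSU estimates by health state and month of follow-up,
in four steps, and ships a synthetic registry generator with known ground
truth so every step can be validated quantitatively.

## Step I — incident cohort

Patients qualify through a diagnosis code of the condition (primary or
associated position). A patient is *incident* when the first qualifying
record falls in the incident window and no qualifying record exists in the
preceding washout window; patients carrying a personal-history code at or
before their diagnosis day are excluded to avoid misclassifying an old cancer
as a new one. The anchoring of the history exclusion at the diagnosis day is
a design choice: the data carry no other time anchor, and a history code
recorded only *after* diagnosis is most plausibly a consequence of the
incident disease, so it does not exclude. Windows are half-open day
intervals `[start, end)` on an integer day calendar; only relative windows
matter, so no real dates are used.

## Step II — five health states over two periods

The initial-treatment phase is the first 180 days after diagnosis. Stage at
initial treatment is a composite of recorded events with precedence
metastatic > locally advanced > early: any distant-metastasis record means
metastatic; otherwise any locoregional-extension diagnosis or any treatment
incompatible with an early stage (chemotherapy) means locally advanced; early
is the default. Metastatic is absorbing. From day 180, early and
locally-advanced patients are relapse-free until a relapse event — the first
record, at day ≥ 180, of a *primary-position* diagnosis at the original
cancer site (the primary-position requirement applies to local relapse only)
or of any extension event (metastasis, locoregional extension, chemotherapy,
any position). Relapse is absorbing too.

Timelines are built to the earlier of death and administrative censoring
without an artificial truncation; the 12-month analysis cap is applied per
analysis — survival and admission analyses use at most 360 days *from state
entry*, and follow-up-state months (clocked from day 180) run to month 12,
i.e. day 540 after diagnosis. "Month" is a fixed 30-day half-open window
throughout; the source registries define no month length, and fixed windows
make month membership disjoint and testable.

Survival by state uses the Kaplan–Meier estimator with Greenwood variance
(via the `survival` package). Admission into post-acute care is analysed as
a competing-risks problem — death without post-acute care competes — with
Aalen–Johansen cumulative incidence functions (multi-state `survfit`, which
conserves CIFs + survival = 1 identically) and a Fine–Gray
subdistribution-hazard regression (`cmprsk::crr`) reporting hazard ratios.
One row per patient per state entry; an admission on the entry day itself is
placed at time 0.5 day so it remains a positive-time event.

## Step III — graded response model, calibration, interpolation

All ADL assessments are pooled and modelled with a two-parameter graded
response model: the probability of scoring category $k$ or above on ADL $j$
is logistic in a latent health trait $\theta$,

$$P(X_j \ge k \mid \theta) = \frac{e^{\alpha_j(\theta - \beta_{jk})}}
 {1 + e^{\alpha_j(\theta - \beta_{jk})}},$$

with slope $\alpha_j > 0$ and ordered thresholds
$\beta_{j1} < \beta_{j2} < \beta_{j3}$; at $\theta = \beta_{jk}$ a patient
has exactly a 50% chance of scoring $k$ or above. Assumptions worth stating
plainly: one latent dimension drives all six items (screened before fitting
via the eigenvalues of the polychoric correlation matrix — second eigenvalue
below 1, first-to-second ratio above 3, first component dominant); local
independence of items given $\theta$; and independence of assessment
records, which ignores the within-patient correlation of repeated
assessments — a deliberate simplification matching the pooled-records
design, acceptable for point estimation of item parameters.

Numerical choices:

* **Identification.** $\theta \sim N(0,1)$; slopes on the logistic metric
  exactly as written (no 1.7 constant).
* **Fitting.** Marginal ML by Bock–Aitkin EM: 41 Gauss–Hermite nodes,
  responses collapsed to unique patterns, per-item M-steps by BFGS on
  $(\log\alpha_j,\ \beta_{j1},\ \log\Delta\beta)$ so threshold order is
  structural. Convergence when the largest absolute parameter change falls
  below $10^{-4}$, cap 500 iterations; the observed-data log-likelihood
  trace is retained and is non-decreasing. Items observed in a single
  category carry no threshold information and are rejected; incomplete rows
  are dropped with a warning.
* **Scoring.** Expected-a-posteriori (EAP) estimates with posterior SDs.
  The estimator is a package choice (none is mandated by the design);
  scoring integrates on a dense equispaced grid (step 0.02 over
  $[-8, 8]$) rather than the 41-node fitting grid, because posterior means
  of sharply peaked six-item posteriors need finer resolution than the
  marginal likelihood does — the dense grid agrees with reference
  integration to $10^{-4}$.
* **Calibration.** Raw EAP scores are mapped affinely onto the worst
  (−0.53) and best (1.00) anchors of the French EQ-5D-3L social value set:
  $\hat U = (\hat U_{RAW} - \min)/(\max - \min) \times 1.53 - 0.53$. The
  min/max are the observed extremes over *all assessment records*, frozen
  once and reused wherever predictions are calibrated later; the assessment
  level is the only level at which these extremes exist. The map is
  strictly increasing, so it preserves the ranking of scores. This
  calibration assumes a perfect correlation between the latent ADL scale
  and the value set — its strongest assumption, inherited by every
  downstream number.
* **Interpolation.** Utility is linearly interpolated to daily values from
  the first to the last record of each patient, across stays, with no
  extrapolation beyond either end. Duplicate same-day assessments are
  averaged on the raw scale before interpolation (one node per day);
  same-day records from different stays collapse to that one node.

## Step IV — monthly HSU with selection correction

Forty-eight subpopulations are formed: all patients alive at the start of
each month in a given state (months 1–6 for the two initial non-metastatic
stages, 1–12 for metastatic, relapse and relapse-free). "Alive at the start"
is strict — a death on the boundary day excludes, the boundary instant
belonging to the month. A patient's monthly HSU is the mean of their daily
utility estimates in the window (30 values = area under the curve; one value
= assumed uniform over the month). The admitted-in-month indicator is
defined as having at least one daily estimate in the window: a stay-overlap
definition differs only in the rare case of a stay whose records end before
the window, and an observed monthly value requires an estimate in any case.

Admission into post-acute care selects sicker patients, so observed-only
means are biased. Each subpopulation gets a Heckman two-step model:

* selection: probit $P(\text{admitted}) = \Phi(\beta X_i)$ on the large
  covariate set $X$ (age band, sex, comorbidity count, hospital type,
  depression, palliative care);
* outcome: OLS $\text{HSU}_i = \gamma Y_i + \lambda\,\text{IMR}_i$ on the
  admitted, where $Y$ drops hospital type (the exclusion restriction:
  hospital type shifts admission but not health) and
  $\text{IMR} = \phi(\beta X_i)/\Phi(\beta X_i)$ is computed on the log
  scale so it stays accurate arbitrarily far into the left tail.

Selection bias is assessed by the two-sided test of $\lambda = 0$ with
heteroskedasticity-robust (HC1) standard errors — two-step residuals are
heteroskedastic by construction, and the two-step SEs are not fully
efficient; this is a known limitation of the estimator class, accepted here.
HSU for the non-admitted is imputed as the population-level prediction
$\gamma Y_i$ — the literal reading of "use the outcome equation to impute";
the non-selected conditional expectation
$\gamma Y_i - \lambda \phi/(1-\Phi)$ is available behind a flag for
sensitivity analysis. Imputed values are clipped to $[-0.53, 1.00]$ with
clip counts logged, since a linear prediction is unbounded but the scale is
not. Combined cell means are patient-count-weighted averages of observed
and imputed components (equivalently, pooled per-patient means); SEs are
bootstrap over patients (200 resamples by default). Quasi-separated probits
fall back to a ridge-stabilized penalized fit and are flagged; cells too
small for the two-step design fall back to observed-mean imputation and are
flagged; empty cells are reported missing, never zero.

## The synthetic registry

The generator emulates exactly the structure the pipeline assumes: a
day-indexed calendar (washout days 0–729, incident window 730–1824,
administrative censoring at day 2007); a small diagnosis vocabulary (two
site codes, locoregional extension, distant metastasis, chemotherapy,
personal history, comorbidities, depression, palliative care) standing in
for the real coding dictionary; stage mix (0.30, 0.55, 0.15) reproducing
the ~70% late-stage share reported for head and neck cancer; relapse as a
constant daily hazard ($1.2\times10^{-3}$/day) after day 180;
piecewise-exponential death with per-state daily hazards ordered metastatic
> relapse > locally advanced > early > relapse-free; a latent trait
constant within 30-day months, $\theta = $ state shift + covariate shifts +
patient intercept (SD 0.5) + monthly noise (SD 0.3), with state shifts
ordered so the metastatic state is lowest; ADL scores drawn category-wise
from the ground-truth graded response model (slopes 1.1–5.5, mostly
negative thresholds, mirroring the fitted range in this setting); and
monthly post-acute admission from a probit with latent-trait coefficient
$\delta = -0.6$, so that sicker patients are admitted more — the selection
bias Step IV corrects. A quarter of patients are prevalent and 5% carry a
personal-history code, so Step I has real work to do.

What it does **not** emulate: real coding practice and its misclassification,
mortality outside hospital (synthetic deaths are complete), informative
weekly-assessment gaps, within-stay trends in $\theta$, geographic
structure, and costs. Tests passing on this generator therefore validate
the estimators and their composition under the model's own assumptions —
they do not validate those assumptions against real registry data.

## Problem sizes and test design

The package's validation suite works at sizes chosen to make Monte Carlo
tolerances meaningful while staying desk-scale: GRM parameter recovery at
5,000 assessments over three seeds (slopes within ±15%, thresholds within
±0.15); polychoric recovery at 5,000–10,000 observations; Heckman
properties over 200 replicates of n = 5,000 (γ within 3 SE, combined-mean
bias below observed-only bias in ≥ 90% of replicates) and λ-test size over
400 replicates; Fine–Gray CI coverage of a true subdistribution HR of 3.5
over 200 replicates of n = 3,000; and an end-to-end run with 2,000 patients
checking that the estimated HSU ordering reproduces the generated state
ordering and that EAP scores correlate ≥ 0.85 with the true latent trait.

## Known limitations

The calibration rests on the perfect-correlation assumption above and on
two anchors only; it cannot capture non-linear relations between the ADL
scale and a value set. Pooled-record GRM fitting ignores within-patient
correlation (point estimates are fine; item-parameter SEs would be
optimistic and are not reported). The two-step selection model identifies
the correction through the exclusion restriction and joint normality;
monthly models are fitted independently, ignoring that the same patient
appears in consecutive months. Treatment-modality effects cannot be
separated from the stage construct, which consumes treatment codes.
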