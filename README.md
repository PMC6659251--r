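# hsuADL

Health-state utility (HSU) estimation from activities-of-daily-living (ADL)
records in hospital discharge registries.

Cost-effectiveness analyses need HSU — a preference weight per health state
that turns survival time into QALYs — but patient surveys measuring it are
small and unrepresentative. Discharge registries cover everyone, and in
post-acute care six ADLs (dressing/bathing, mobility, self-feeding,
continence, social interaction, communication) are scored 0–3 at admission
and weekly thereafter. `hsuADL` turns those ordinal records into HSU
estimates by cancer health state and month of follow-up, in four steps:

1. **Incident cohort** — patients whose first qualifying diagnosis falls in
   the incident window, with a clean washout period and no prior
   personal-history code (`build_cohort()`).
2. **Health states** — five states over two periods: early / locally
   advanced / metastatic stage during the first 180 days (precedence
   metastatic > locally advanced > early), then relapse vs relapse-free;
   metastatic and relapse are absorbing. Kaplan–Meier survival and a
   Fine–Gray competing-risks analysis of post-acute admission
   (`build_timelines()`, `km_by_state()`, `fit_competing_admission()`).
3. **IRT utility** — a two-parameter graded response model pooled over all
   ADL assessments,

   $$P(X_j \ge k \mid \theta) = \frac{e^{\alpha_j(\theta-\beta_{jk})}}{1+e^{\alpha_j(\theta-\beta_{jk})}},$$

   fitted by marginal ML (EM, Gauss–Hermite quadrature, θ ~ N(0,1)) after a
   polychoric-eigenvalue unidimensionality screen; EAP scoring; affine
   calibration of the raw latent scale onto the French EQ-5D-3L anchors
   (−0.53, 1.00); daily linear interpolation between assessments
   (`grm()`, `fit_irt_stage()`).
4. **Selection-corrected HSU** — 48 (state × month) subpopulations of
   patients alive at month start; per-patient monthly HSU as the mean of
   daily estimates; a Heckman two-step model per subpopulation (probit
   admission equation, outcome OLS with the inverse Mills ratio, robust
   λ-test of selection bias) and outcome-equation imputation for patients
   unrecorded in post-acute care (`heckit2()`, `estimate_hsu()`).

A synthetic registry generator with known ground truth (`sim_config()`,
`generate_registry()`) emulates all of this — including the admission
process that selects sicker patients into post-acute care — so parameter
recovery and bias correction are tested quantitatively. `run_pipeline()`
runs everything reproducibly from one config and seed.

## Worked example

```r
library(hsuADL)
registry  <- generate_registry(sim_config(n_patients = 800, seed = 42))
cohort    <- build_cohort(registry)
timelines <- build_timelines(cohort, registry, censor_day = 2007)
irt       <- fit_irt_stage(registry, patient_ids = cohort$patient_id)
summary(irt$grm)
#> Graded response model parameter estimates
#>      slope     b1     b2    b3 threshold_range
#> adl1 4.363 -2.241 -0.298 2.224           4.464
#> adl2 2.648 -1.656 -0.158 1.990           3.646
#> adl3 0.897 -0.656  0.717 2.084           2.740
#> adl4 1.770 -1.886 -0.660 0.496           2.382
#> adl5 2.269 -1.392  0.079 1.616           3.008
#> adl6 1.280 -1.530 -0.013 0.740           2.270
#>
#> log-likelihood -50176.52 on 8131 assessments
#> unidimensionality screen: pass (lambda1 = 3.64, 60.6% variance, ratio 4.80)
```

Of 800 simulated patients, 177 are excluded as prevalent and 31 for a
personal history of cancer, leaving 592 incident patients (the flow chart is
`attr(cohort, "flow")`). The fitted slopes say dressing/bathing (`adl1`,
slope 4.4) discriminates latent health most sharply and self-feeding
(`adl3`, slope 0.9) least; the first eigenvalue of the polychoric matrix
carries 61% of the variance with a first-to-second ratio of 4.8, supporting
a single latent dimension. Calibrated utilities span exactly [−0.53, 1.00].

```r
sp  <- build_subpopulations(timelines, irt$trajectories, registry)
hsu <- estimate_hsu(sp, boot_reps = 50)
hsu
#> Health-state utility by state and month of follow-up
#>   47 subpopulation cells, 31 with a fitted selection model
#> Overall per-state combined HSU:
#>              state    n   mean    sd
#> 1            early 1027  0.402 0.196
#> 2 locally_advanced 1782  0.303 0.190
#> 3       metastatic  568 -0.082 0.192
#> 4          relapse  533  0.076 0.200
#> 5     relapse_free 3494  0.446 0.193
```

The per-state means reproduce the generated ordering — metastatic worst,
relapse next, relapse-free best — and `hsu$by_state_month` holds the
month-by-month combined means, bootstrap SEs, and the λ-tests of selection
bias per cell. Because admission selects low-utility patients
(δ < 0 in the generator), the combined means sit above the observed-only
means in `hsu_observed_only` analogues: correcting selection raises HSU.

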