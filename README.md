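# pneumodose

Radiotherapy "lung dose" is ambiguous: the dose-volume histogram (DVH) of
the normal lung can be computed from the **Total Lung** (both lungs), from
**Lung−PGTV** (lungs minus the intrapulmonary planning gross tumor volume)
or from **Lung−PTV** (lungs minus the intrapulmonary planning target
volume). Because the excluded target occupies the highest-dose region, the
three conventions systematically shift V5, V20 and mean lung dose (MLD) —
and therefore shift every dose constraint and every prediction of grade ≥ 2
radiation pneumonitis (RP2) built on them. `pneumodose` is an R package for
quantifying that effect end to end, aimed at radiation-oncology physicists
and outcome modellers.

It provides:

* **Geometry** — voxel structure masks, exact Euclidean margin expansion
  (anisotropic spacing supported), and the overlap-subtraction rule that
  builds the three normal-lung definitions (`expand_margin()`,
  `normal_lung_mask()`, `lung_definitions()`);
* **DVH metrics** — cumulative DVHs and V5 / V20 / MLD by direct voxel
  counting (`compute_dvh()`, `vx()`, `mld()`);
* **Synthetic data** — a thorax phantom with margin-derived targets and an
  exponential-falloff dose field, and a cohort simulator whose outcome is a
  Lyman dose-response on Lung−PTV MLD (`generate_phantom()`,
  `simulate_cohort()`);
* **Statistics** — 2×2 odds ratios with Wald inference, univariate logistic
  regression, Mann–Whitney U, paired mean differences, repeated-measures
  ANOVA (`odds_ratio()`, `logistic_fit_univariate()`, `mann_whitney_u()`,
  `paired_mean_difference()`, `repeated_measures_anova()`);
* **ROC comparison** — Mann–Whitney AUC and DeLong's paired test for
  correlated AUCs (`auc_mann_whitney()`, `delong_paired_test()`);
* **NTCP modelling** — the Lyman probit model with n = 1 (dose covariate =
  MLD), deterministic maximum-likelihood fitting of (TD50, m), iso-risk
  cutoff-dose inversion and between-definition curve comparison
  (`ntcp_lyman()`, `fit_lyman_mle()`, `cutoff_dose()`,
  `compare_definitions_ntcp()`);
* **Pipeline** — `run_analysis()` turns a cohort CSV into the full set of
  report tables; `run_phantom_demo()` demonstrates the definition ordering
  on the phantom. A thin CLI lives at `inst/cli/pneumodose`.

The core model: RP2 probability at mean lung dose *D* is
`NTCP(D) = Φ((D − TD50) / (m·TD50))`, with the 20% iso-risk MLD cutoff given
by the exact inverse `D = TD50·(1 + m·Φ⁻¹(0.20))`. Two fitted curves are
compared at a common dose by the relative difference
`100·(p_high − p_low)/p_low`.

## Worked example

```r
library(pneumodose)

# a published-style 2x2 row: female 6 events/15 non-events vs male 20/142
odds_ratio(6, 15, 20, 142)
#> OR 2.84 (95% CI 0.99-8.17), p = 0.053

# simulate a 183-patient cohort and run the full univariate analysis
co  <- simulate_cohort(cohort_config(seed = 1))
rep <- run_analysis(co)
rep
#> <analysis_report> n = 183, RP2 events = 26 (14.2%)
#>   NTCP fits:
#>     Lung-PTV   TD50 =  20.8 Gy, m = 0.453, MLD cutoff(20%) = 12.8 Gy
#>     Lung-PGTV  TD50 =  23.5 Gy, m = 0.443, MLD cutoff(20%) = 14.8 Gy
#>     Total Lung TD50 =  24.6 Gy, m = 0.443, MLD cutoff(20%) = 15.4 Gy

subset(rep$paired_differences, metric == "MLD")
#>   metric               comparison mean_difference    ci_low   ci_high ...
#> 7    MLD   Lung-PTV vs. Lung-PGTV       1.6961749 1.6631559 1.7291938
#> 8    MLD  Lung-PTV vs. Total Lung       2.2797814 2.2367317 2.3228311
#> 9    MLD Lung-PGTV vs. Total Lung       0.5836066 0.5518444 0.6153687
```

Reading the output: the same simulated patients yield a 20%-risk MLD
constraint of 12.8 Gy under Lung−PTV but 15.4 Gy under Total Lung — a
2.6 Gy disagreement produced purely by the lung definition — and the mean
MLD gaps between definitions (1.70 and 2.28 Gy here) recover the simulator's
calibrated offsets. The phantom shows the same ordering geometrically:

```r
run_phantom_demo()$metrics
#>   definition       v5      v20      mld
#> 1 Total Lung 58.40446 24.97247 14.11517
#> 2  Lung-PGTV 57.29932 22.97908 12.89607
#> 3   Lung-PTV 56.00612 20.64648 11.46951
```

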