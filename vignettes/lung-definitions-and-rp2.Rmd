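---
title: "Normal-lung definitions, DVH metrics, and radiation pneumonitis risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-lung definitions, DVH metrics, and radiation pneumonitis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumodose)
```

## The problem

When a thoracic radiotherapy plan is evaluated, "lung dose" is not a single
number: the dose-volume histogram (DVH) of the normal lung depends on what
counts as *normal lung*. Three conventions coexist in practice:

* **Total Lung** — both lungs, nothing subtracted;
* **Lung−PGTV** — lungs minus the intrapulmonary part of the planning gross
  tumor volume (GTV plus a setup margin);
* **Lung−PTV** — lungs minus the intrapulmonary part of the planning target
  volume (CTV plus a setup margin, hence the largest exclusion).

Because the excluded target sits in the highest-dose region, the three
definitions order every common metric the same way:
V5, V20 and mean lung dose (MLD) are smallest for Lung−PTV and largest for
Total Lung. The clinically interesting question is not the ordering but its
consequence: the *same* numeric dose constraint predicts very different
complication rates depending on which definition produced the number, and one
definition may be a genuinely better predictor of symptomatic (grade ≥ 2)
radiation pneumonitis, RP2, than another.

This package implements the full comparison pipeline: voxel-mask geometry and
margin expansion, DVH metric extraction, a synthetic thorax phantom and a
synthetic patient cohort, the univariate statistical battery, ROC/AUC
comparison with DeLong's paired test, and Lyman NTCP modelling with iso-risk
cutoff inversion.

## The dose-response model

The Lyman normal-tissue-complication-probability (NTCP) model maps an
effective dose through a probit curve,

$$\mathrm{NTCP}(D) = \Phi\!\left(\frac{D - TD_{50}}{m \cdot TD_{50}}\right),$$

where $TD_{50}$ (Gy) is the dose at 50% complication probability and $m$ the
dimensionless relative slope. The volume-effect exponent $n$ is fixed at 1
throughout this package, which reduces the generalized effective dose to the
mean lung dose — so the model is a two-parameter probit regression of RP2 on
MLD. `fit_lyman_mle()` maximizes the Bernoulli log-likelihood over
$(TD_{50}, m)$ with a deterministic optimizer: a coarse grid over
$TD_{50} \in [5, 60]$ Gy and $m \in [0.05, 2]$, refined by Nelder–Mead from
the best grid point. No stochastic restarts are used, so fits are
bit-reproducible; probabilities are clamped to $[10^{-12}, 1-10^{-12}]$
before logging so extreme proposals during the search never produce infinite
objective values. A fit that terminates on the grid boundary is flagged, not
silently returned.

The iso-risk cutoff is the exact inverse,
$D = TD_{50}\,(1 + m\,\Phi^{-1}(p))$: with $p = 0.20$ it is the MLD
constraint that limits predicted RP2 incidence to 20%. When two fitted curves
are compared at a common dose, the "probability difference" is reported
relative to the smaller probability, $100\,(p_\text{high} -
p_\text{low})/p_\text{low}$, rounded to integer percent — the convention
under which 13% vs 20% is a 54% difference and 20% vs 29% a 45% difference.

## Geometry and DVH conventions

Masks use voxel-center membership with no partial-volume weighting; the error
this introduces is bounded by the voxel size, and every DVH metric is
computed directly from the voxel set (the binned DVH, default bin width
0.1 Gy, is a reporting artifact only). `expand_margin()` performs exact
Euclidean dilation in physical units — a voxel is added when its center lies
within the margin of any input voxel's center — which handles anisotropic
spacing correctly; dilation is clipped at the grid boundary with a warning.
Target subtraction follows the overlap rule: only the intrapulmonary part of
PTV/PGTV is removed, an extrapulmonary target changes nothing. The
CTV-to-PTV expansion applies no anatomical cropping (e.g. at the chest
wall): the phantom has no anatomy to crop against, and the convention is
stated here so that real-data users know the masks they supply are used
as-is.

## What the synthetic data emulate — and what they do not

Two generators make every downstream stage testable without any patient
data.

**The thorax phantom** (`generate_phantom()`) builds two ellipsoidal lungs,
a spherical GTV inside one lung, and the margin-derived CTV/PTV/PGTV
(defaults: 8 mm GTV→CTV, as for non-squamous histology; 5 mm setup margin).
Dose is the prescription (default 60 Gy, constrained to [50, 70] Gy) inside
the PTV and decays exponentially with distance outside it,
$D = Rx\,e^{-d\,u/\lambda}$ with a default length-scale $\lambda = 20$ mm —
chosen so the phantom's per-definition MLDs (≈11.5/12.9/14.1 Gy on the
default grid) sit in the range typical of thoracic IMRT. The per-voxel
lognormal factor $u$ (sd 0.05) perturbs the *effective distance*, a choice
with two exact consequences: every PTV voxel dominates every outside voxel in
dose, so the definition ordering V5/V20/MLD(Lung−PTV) ≤ (Lung−PGTV) ≤
(Total Lung) holds by construction, and the $\lambda \to \infty$ limit is an
exactly uniform field. The phantom is geometric: it has no heterogeneity
correction, no beam model, no respiratory motion, and the great vessels and
proximal airways that a clinical lung contour excludes are simply absent.
Trachea/great-vessel exclusion is the phantom's (absent) anatomy, not a
runtime carving operation.

**The cohort simulator** (`simulate_cohort()`) draws, per patient, a
Lung−PTV MLD from a lognormal distribution (median 10.3 Gy, `sdlog` 0.22)
truncated to [6, 16] Gy — positive, right-skewed, matching the reported
median and range of such cohorts — then adds positive jittered increments of
mean 1.7 Gy (to Lung−PGTV) and 2.3 Gy (to Total Lung). V5 and V20 are
monotone noisy transforms of MLD (slopes 4.7 and 1.75 %/Gy, with shared
patient-level noise so the between-definition ordering is inherited and
V20 ≤ V5 is enforced); the joint distribution of V5/V20/MLD in real plans is
not published, so this monotone-transform model is a modelling choice, and
correlations among the three metrics in simulated data are somewhat tighter
than in real plans. Clinical covariates (age, gender, smoking, histology,
stage, chemotherapy, surgery, target volumes and prescriptions) are drawn
from realistic marginal frequencies and are outcome-independent by default —
emulating cohorts in which no clinical factor predicts RP2 — with a hook for
effect injection in power studies. The outcome is
$\mathrm{RP2} \sim \mathrm{Bernoulli}\{\mathrm{NTCP}(\text{MLD}_{\text{Lung-PTV}};
TD_{50}=17.5\ \mathrm{Gy}, m=0.34)\}$, giving ≈14% incidence at n = 183; the
driving definition is configurable to study misspecification. Because the
outcome model *is* the model later fitted, parameter recovery is well-posed:
passing tests show the estimator works, not that real lungs obey a Lyman
curve. Metrics are rounded to 0.1, which creates the ties that the midrank
conventions in the rank statistics are there to handle.

One integer seeds a single RNG stream per generator (covariates, then
metrics, then outcomes, in a fixed order), so equal seeds give bit-identical
cohorts.

## Statistical conventions

* **2×2 odds ratios** use the closed form $(a/b)/(c/d)$ with Wald 95% CIs
  and p-values — the convention that reproduces published univariate tables
  digit-for-digit (e.g. counts 6/15 vs 20/142 give OR 2.84, CI 0.99–8.17,
  p 0.053). A zero cell yields the degenerate point estimate with an
  explicit non-estimable flag.
* **Univariate logistic regression** is IRLS via `glm` (tightened to
  `epsilon = 1e-12` so that on a binary covariate the fitted OR and Wald CI
  match the 2×2 closed form to machine precision). Separation and
  constant-covariate designs are flagged, never silently estimated.
* **Mann–Whitney U** uses midranks; the p-value is exact by enumeration when
  the combined sample size is ≤ 10 with no ties, otherwise the normal
  approximation with tie and continuity corrections.
* **Paired mean differences** are t-based; the sign convention reports the
  larger-volume definition minus the smaller, so published positive
  magnitudes are matched. Zero-variance differences return a degenerate
  zero-width interval with a flag.
* **Repeated-measures ANOVA** across the three definitions uses the balanced
  within-subject closed form, $F = MS_{\text{cond}}/MS_{\text{error}}$ on
  $(2, 2(n-1))$ df; identical columns and zero error variance are flagged
  rather than propagated as NaN.
* **ROC/AUC** is the Mann–Whitney concordance estimate (midrank ties);
  paired AUCs are compared with DeLong's placement-value covariance test,
  implemented in-package and cross-checked against pROC in the test suite.
  All p-values are two-sided; no multiple-testing correction is applied
  anywhere, matching the univariate reporting style this pipeline mirrors.

Dichotomization of continuous covariates in the Table-1-style screen is
≤ median vs > median, with the lower half as reference.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data, at
sizes chosen to make each check informative while keeping a full run in
minutes: geometry oracles on grids up to 64³; type-I error simulations at
2000 replicates (Monte-Carlo error ≈ 0.5 percentage points at α = 5%);
parameter recovery and closed-loop cutoff inversion on a 5000-patient
cohort; coverage of the 1.7 Gy paired offset over 100 replicate cohorts of
183.

## Known limitations

* No DICOM-RT input; grids and masks use a flat-binary + JSON sidecar
  format, and cohorts a documented CSV schema.
* The phantom's dose model is a distance-falloff caricature of an IMRT dose
  distribution; it demonstrates orderings and conventions, not planning
  realism.
* Only univariate association is implemented, by design; multivariable or
  adjusted modelling is out of scope.
* NTCP confidence intervals are provided only through the DeLong AUC
  variance convenience; profile-likelihood intervals for $(TD_{50}, m)$ are
  not implemented.
* With dose ranges far below $TD_{50}$ (the realistic regime — cohort MLDs
  of 6–16 Gy against $TD_{50} \approx 17.5$ Gy), the likelihood surface is
  a shallow ridge: $TD_{50}$ and $m$ are individually soft while the low-dose
  curve, and hence the 20% cutoff, is well determined. Recovery tolerances
  in the tests (±2 Gy on $TD_{50}$, ±0.08 on $m$, ±1 Gy on the cutoff at
  n = 5000) reflect that geometry.
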