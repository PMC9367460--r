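---
title: "Voxel-region-aware dosimetric analysis of paired lung VMAT plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-region-aware dosimetric analysis of paired lung VMAT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmapdose)
```

## The problem

In locally advanced lung cancer treated with (chemo-)radiotherapy,
respecting the classical organ-at-risk dose constraints does not reliably
protect patients from grade >= 2 acute pulmonary toxicity (APT, radiation
pneumonitis). Voxel-based analyses have identified a sub-region of the
posterior right lung — here called the *Pmap* region — whose mean
biologically effective dose (BED) is strongly associated with APT risk. Two
decision thresholds operationalise that association: a mean Pmap BED dose of
**30.3 Gy**, and a predicted APT probability of **8%** from an 11-feature
model combining Pmap dose with standard dosimetric and clinical covariates.

`pmapdose` implements the analysis pipeline built around those thresholds:
it takes paired *initial* and *optimized* treatment plans (dose grids plus
structure masks on one lattice), computes the DVH metric panel and plan
indices for both, adjudicates whether the optimization successfully spared
the Pmap region without compromising target coverage, classifies and
re-classifies APT risk, and quantifies how well the PTV–Pmap overlap
predicts optimization failure. Because the underlying clinical data are not
public, the package also ships a synthetic thoracic phantom and plan-pair
generator so the entire pipeline runs, and is tested, end to end with no
external data.

## Data model

Everything lives on a single voxel lattice (`grid_geometry`): arrays are
ordered (z, y, x), indices are 1-based, world coordinates are voxel-centred
millimetres. Dose grids carry a `dose_kind` (physical or BED) and structure
sets hold named binary masks: `PTV`, `LungH` (homolateral lung), `LungC`
(contralateral), `Heart`, `SpinalCord`, `Pmap`, with `2Lungs` derived as
the lung union when absent. A voxel is in or out of a mask — there is no
partial-volume weighting — so DVH values can differ slightly from a
treatment planning system that uses fractional voxel contributions.

## Dose metrics

BED conversion uses the standard linear-quadratic form with the voxel's
per-fraction dose $d(v) = D(v)/n$:

$$\mathrm{BED}(v) = D(v)\left(1 + \frac{D(v)/n}{\alpha/\beta}\right),$$

with $\alpha/\beta = 3$ Gy for normal tissue and $10$ Gy for tumour. The
metric panel (`compute_plan_metrics()`) reports V5/V10/V13/V20/V30, Dmean
and Dmax per lung; V13/V20/V30 and Dmean for both lungs; V30/V40 and Dmean
for the heart; cord Dmax; PTV95; the conformity index IC = PIV/PTV and the
heterogeneity index HIV = D95%/D5%. The Pmap mean dose — the quantity the
30.3 Gy threshold applies to — is always computed on the BED grid with
$\alpha/\beta = 3$; all other metrics default to physical dose (the only
threshold explicitly defined on BED is the Pmap one), with `bed_all = TRUE`
converting the whole panel.

Numerical conventions, chosen for determinism and testability:

* $V_x$ thresholds are **inclusive** (dose >= x), so ties count as covered
  and every value equals an integer voxel count.
* $D_{q\%}$ is the largest DVH edge still covering $q\%$ of the VOI — a
  bin-resolution quantile that is exact for uniform dose (D95 = D5 on a
  flat VOI) and provably within one bin width (default 0.1 Gy) of the
  order-statistic quantile.
* The prescription isodose volume in IC is counted over the whole grid;
  the data model carries no body contour.
* Dice of two empty masks returns 0 with a warning rather than NaN, so
  downstream ROC analysis never receives missing scores.

## Sub-region transfer

The Pmap region is defined once on a reference thoracic phantom and carried
into each patient's lattice with `map_pmap_to_patient()`: inverse-lookup
nearest-neighbour resampling through an identity, affine, or
displacement-field transform (the displacement field is given on the
patient lattice, i.e. the registration exported in reverse, which is the
direction resampling needs). The elastic registration itself is out of
scope — the package consumes its output. Registration quality is summarised
as the Dice overlap of the hybrid lungs-plus-heart VOI
(`registration_qa()`); affine round trips on the synthetic phantom recover
masks with Dice > 0.95, the residual being nearest-neighbour
discretisation.

## Risk model and decision rules

The 11 features, in the canonical order of `risk_feature_names()`, are:
Pmap mean BED dose, both-lungs Dmean and V30, smoking status, MEVS (mean
expiratory volume per second, % of theoretical), COPD, homolateral-lung
V10, AJCC stage (encoded ordinally), homolateral V5 and Dmean, and heart
V40. The originally trained model's coefficients are unpublished, so
`risk_model()` is a pluggable interface: a pure threshold rule, a logistic
surrogate (used throughout the synthetic studies), or an external
serialized logistic model. The package makes no claim to reproduce the
original model's probabilities; what it reproduces is the *decision
machinery* around any such model. Both decision thresholds are inclusive:
risk is high when probability >= 8% or when mean Pmap BED dose >= 30.3 Gy.

Cohort assignment and success adjudication follow the study rules. Patients
with predicted probability below 8% are excluded. Included patients with
initial Pmap dose >= 30.3 Gy are Cohort 1 (optimization succeeded) or
Cohort 2 (failed); those below 30.3 Gy are Cohort 3. Success for Cohorts
1/2 means: optimized Pmap dose < 30.3 Gy, PTV coverage maintained, and all
organ-at-risk constraints met; for Cohort 3 it means a >= 20% relative Pmap
dose reduction with maintained coverage. "Coverage maintained" is
operationalised as optimized PTV95 >= min(95%, initial PTV95 − 1 point):
a strict 95% floor would contradict the fact that successfully optimized
plans can start below 95% coverage, so plans are judged against their own
baseline once below the floor, with both knobs configurable in
`constraint_set()`. The default OAR bounds (both lungs V20 <= 35%, cord
Dmax <= 45 Gy, heart V40 <= 30%) are conventional lung-RT planning values,
**not** the study's appendix constraints (which are unavailable), and are
fully overridable.

Two statistical conventions deserve a note. Plan-set comparison
(`compare_plan_sets()`) is *unpaired* — a two-sample t-test when both arms
pass Shapiro–Wilk at $\alpha = 0.05$, Mann–Whitney otherwise — matching the
convention of published initial-vs-optimized plan tables, even though the
plans are paired. The reclassification summary uses properly *paired*
tests: an exact McNemar test (binomial test on discordant transitions) and
a Wilcoxon signed-rank test on the probability pairs. Mean CIs are
t-based; median CIs are seeded percentile bootstraps (2000 resamples).

The ROC analysis (`roc_dice_vs_success()`) treats the PTV–Pmap Dice score
as a predictor of optimization *failure* — geometric overlap is what makes
sparing the sub-region impossible — so reported AUCs are in the orientation
where higher Dice predicts failure. The AUC equals the all-pairs
Mann–Whitney statistic with half credit for ties, and the operating cutoff
maximises the Youden index.

## The synthetic generator

`generate_phantom()` builds a 64×64×64 voxel, 4 mm isotropic thorax — two
lung ellipsoids with a heart carved out between them, a spinal-cord
cylinder, a spherical PTV inside the right lung, and the Pmap box in the
posterior right lung. The 4 mm/64³ lattice is a deliberate compromise: the
source study does not state its planning-grid resolution, and this size
keeps a full phantom-plus-plan-pair under a third of a second while leaving
>1000 voxels in each structure of interest.

`paint_plan_pair()` emulates the paired plans by direct dose sculpting
rather than inverse optimization (the commercial optimizer is out of
scope). The initial plan combines, by voxelwise maximum, (i) a target field
with an error-function penumbra in the distance from the PTV surface —
slightly hot inside (2.5%), rolling off so PTV-edge voxels sit near 94.5%
of prescription, which lands PTV95 near 97%, HIV near 0.93 and IC below 1;
(ii) a posterior dose bath at the Pmap box whose amplitude
(`posterior_spill`) is the knob controlling the Pmap mean dose; and (iii) a
broad low-dose body bath. The max-composition plus a 98%-of-prescription
cap outside the PTV mimics what an optimizer enforces; summing the fields
instead inflates the conformity index beyond 1.8 and destroys coverage
realism. Additive Gaussian voxel noise (0.5 Gy) is drawn from the painter
seed. The optimized plan multiplies the initial dose by a smooth
attenuation field shaped like the bath, forced to 1 inside the PTV (the
PTV dose distribution is untouched voxel for voxel, so PTV95 changes by
exactly 0) and scaled so the Pmap mean dose drops by the requested
fraction; when PTV–Pmap overlap caps the attainable reduction the scale
saturates and the pair is flagged unachievable — which is precisely the
mechanism that makes high Dice predict failure downstream.

`simulate_cohort()` draws, per patient: an anatomy jitter (whole-thorax
shift ±2 voxels, an independent posterior-biased PTV shift and a ±1 voxel
radius draw — the source of PTV–Pmap Dice variation), a prescription of
60 Gy/30 fx or 66 Gy/33 fx, a posterior spill uniform on 0.05–0.45, and a
reduction target uniform on 0.10–0.45. The spill range was calibrated once
so that initial Pmap BED doses span roughly 12–58 Gy, straddling the
30.3 Gy threshold with both a high-dose stratum (around 40 Gy, matching the
reported high-dose cohort mean of 40.4 ± 4.4 Gy) and a low-dose stratum
(around 15 Gy, matching the reported 14.6 Gy). APT outcomes and predicted
probabilities come from `default_outcome_model()`, a logistic surrogate
whose intercept (−6.0) gives clinical covariates enough weight that
low-dose patients can still exceed the 8% threshold — without that, the
low-dose cohort would be empty, contrary to the study's structure. All
randomness flows from one master seed through per-patient sub-seeds, so
cohorts are bit-reproducible. `simulate_feature_cohort()` is the fast
feature-level counterpart (no imaging) used for parameter-recovery studies
of `fit_surrogate()`; the recovery tests use generative weights with
standardized magnitudes around 2.2–2.7, sized so that a ±15% relative
recovery band spans at least five coefficient standard errors at n = 2000.

What the generator does *not* emulate: CT intensities, beam/arc geometry,
scatter tails and build-up, realistic cord/heart dose levels (the body bath
under-doses them relative to clinical plans), inter-observer contouring
variation, and any real registration error beyond rigid jitter. Passing
tests therefore demonstrate the correctness of the *analysis machinery*
under controlled inputs, not the clinical performance of the thresholds on
real plans.

## Problem sizes used in the shipped checks

Unit and property tests run on 8³–64³ lattices with brute-force voxel-loop
oracles; the DVH equivalence sweep uses 100 random dose/mask pairs; ROC
checks use 50 random score sets plus a null simulation at n = 200;
parameter recovery uses n = 2000 feature-level patients; the end-to-end
cohort checks use 60–100 imaging patients. `scripts/acceptance.R` simulates
60 patients and reports the pipeline's headline quantities.

## Known limitations

* The surrogate risk model shares only the feature list with the original
  model; absolute probabilities are not comparable.
* Published cohort counts, Table-level means and the reported AUC of 0.83
  derive from private clinical data and are not reproducible here; the
  synthetic pipeline reproduces their *structure* (success rates near 50%,
  one-third to one-half of patients reclassified low, Dice AUC in the
  0.7–0.9 range, Youden cutoffs near 0.15).
* DVH metrics are voxel-exact, not partial-volume weighted.
* The conformity index counts the prescription isodose over the whole
  grid; against a body-restricted PIV it is an upper bound.
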