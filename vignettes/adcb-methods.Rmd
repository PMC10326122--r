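---
title: "ADC-B: deriving and applying breast ADC categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADC-B: deriving and applying breast ADC categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcb)
```

## The problem

Diffusion-weighted MRI quantifies water mobility in tissue through the
apparent diffusion coefficient (ADC, reported here in units of
10^-3^ mm^2^/s). Cellular breast tumors restrict diffusion, so malignant
lesions tend to have lower ADC than benign ones — but the overlap between
entities is substantial and a single "malignant vs benign" cut-off is too
crude for reporting. The ADC-B system mirrors the logic of BI-RADS: instead
of a binary call, a lesion's ADC is mapped to an ordered category whose
empirical malignancy rate is known, so the category itself communicates
risk and a management expectation.

The six categories are:

| category | meaning | default range |
|---|---|---|
| B0 | ADC not measurable (artifacts) | — |
| B1 | no enhancing lesion | — |
| B2 | very high ADC, rule-out level risk | ADC ≥ 1.9 |
| B3 | high ADC, probably benign | 1.5 ≤ ADC < 1.9 |
| B4 | intermediate/low ADC, biopsy-level risk | 1.0 ≤ ADC < 1.5 |
| B5 | very low ADC, mostly invasive carcinoma | ADC < 1.0 |

B0 and B1 are input states, not ADC ranges; intervals are closed below and
open above, so an ADC of exactly 1.0 is B4 (B5 is "< 1.0") and 1.9 is B2.

## The cumulative malignancy-rate curve

All threshold derivation rests on one construction (`build_curve()`):
lesions with measurable ADC are ordered by descending ADC and, at every
distinct observed value `t`, we record the *cumulative malignancy rate*

    rate(t) = #{malignant lesions with ADC >= t} / N,

where `N` is the **total** number of measurable lesions. The total-cohort
denominator is a deliberate design decision: it is the only definition
under which the published per-category rate arithmetic is internally
consistent (at the default boundaries 1.9/1.5/1.0 the published cumulative
rates equal 2/1736, 30/1736 and 425/1736 — a tail-conditional denominator
would instead reproduce the *within-category* rates of 2.9%, 15.0%,
57.8%). Tied ADC values collapse into one curve point counting all tied
lesions, and a lesion exactly at a threshold counts in the "≥ t" tail,
consistent with the closed-lower-bound category convention.

## Threshold derivation

`derive_scheme()` runs the five-step procedure:

1. build the curve;
2. fix target cumulative malignancy rates in analogy to BI-RADS — by
   default < 0.1% for the rule-out category B2 and 2% for the
   probably-benign category B3;
3. read the ADC at each target off the curve: the *crossing* is the
   smallest observed ADC whose cumulative rate is at or below the target
   (`threshold_at_rate()`);
4. set the B4/B5 boundary from the invasive-vs-DCIS ROC: the largest
   one-decimal cut-off whose PPV for invasive carcinoma reaches 95%
   (`select_ppv_cutoff()`);
5. round the curve-derived cut-offs to one decimal (more precision is not
   reproducible between readers in practice) and recompute the category
   rates at the rounded values.

Two numerical choices deserve emphasis. First, rounding happens **after**
the crossing is located, not by scanning a rounded grid against the raw
targets: rounding a crossing of, say, 1.486 up to 1.5 is intended behavior
and shifts the recomputed rate slightly off the target (1.7% instead of
≤ 2% on the benchmark cohort). The recomputed rates are part of the
derivation report, and the crossing itself always honors its target
whenever the `attained` flag is true. Second, an unattainable target (for
example a malignant lesion at the very top of the ADC range with a 0.1%
target) yields a flagged result, never a silent reordering or an
exception; the same holds for a PPV target no grid cut-off reaches, and
for a derived triple that violates `t_b45 < t_b3 < t_b2`.

## ROC and PPV conventions

Low ADC is test-positive throughout (`roc_curve()` documents this in its
output), so sensitivity at cut-off `c` is the fraction of positives with
ADC **strictly below** `c`, matching "B5: < 1.0". The positive class is
invasive carcinoma *excluding* mucinous carcinomas, whose low cellularity
and mucin content give them atypically high ADC; the comparator is DCIS
only. A switch (`include_mucinous`) folds mucinous tumors back in. The AUC
is the trapezoidal area over the full empirical curve, which equals the
Mann-Whitney pair-counting statistic exactly, ties counted one half (a
property the test suite verifies on a thousand random instances). The
reported standard error is the Hanley–McNeil approximation; it is provided
for comparison, not asserted anywhere, since binormal and bootstrap
alternatives give slightly different values.

## Group statistics

The validation statistics mirror a radiology-journal analysis plan:
classic one-way ANOVA across histology groups, Games-Howell post hoc
pairs, Welch t tests for size strata, and a multivariable linear model of
ADC on diagnosis, center, field strength, vendor and lesion size. The t
tests, ANOVA and least-squares fits call the standard `stats` routines;
Games-Howell is implemented here: per pair, Welch standard error and
degrees of freedom, statistic `q = |m_i - m_j| / sqrt(se^2/2)`, and the
p-value from the upper tail of the studentized-range distribution with `k`
means, evaluated by base R's `ptukey` quadrature. With two groups this
reduces exactly to the Welch t test, which the suite asserts, and a
three-group case is checked against an independently computed reference to
three decimals. `ptukey` is undefined below 2 degrees of freedom, which a
pair involving a 2-observation group can produce; such pairs are returned
flagged (`insufficient_df`) rather than as NaN. No Bonferroni-style
correction is layered on top — the studentized range already accounts for
the k-group family.

Categorical covariates are dummy-coded with the *largest* level as
reference (the coding is otherwise arbitrary and affects only coefficient
labels, not fit statistics). Because vendor is a property of the center in
any realistic multicenter calibration, the full design is exactly
rank-deficient; `adc_regression()` treats that as an error naming the
aliased columns by default, and drops aliased covariates with a message
when `on_alias = "drop"` (what `run_pipeline()` uses). Adjusted R² is the
usual `1 - (1 - R²)(n - 1)/(n - p - 1)`.

## The synthetic generator: what it emulates, and what not

`default_generator_config()` encodes the cohort structure reported for the
1736-lesion multicenter derivation database: subtype counts 466 benign /
115 high-risk / 1020 invasive / 98 DCIS / 26 mucinous / 11 other
malignancies; per-group ADC as truncated normals with the published
mean/SD as pre-truncation parameters and the published observed range as
truncation bounds; lesion sizes normal(23.1, 13) mm (malignant) and
normal(15.9, 17) mm (benign) truncated to [3, 130] mm; seven centers
sampled with the published lesion weights, carrying vendor and
field-strength labels (centers 1 and 5 ran both field strengths with an
unreported split, modelled 50/50); and roughly 6.8% of patients
contributing two lesions. Subtype counts use exact largest-remainder
allocation by default so composition percentages are reproducible;
`allocation = "multinomial"` samples them instead. Truncated-normal draws
use inverse-CDF sampling (`qnorm` of uniforms on `[F(a), F(b)]`), which is
exact and loop-free; using the printed means as pre-truncation parameters
biases the realized means slightly toward the interval center, an accepted
and tested-for effect (the parameter-recovery check compares against the
closed-form truncated moments, not the raw inputs).

Deliberate simplifications, which bound what passing tests can claim about
real data:

* ADC and size are independent within outcome class; the small reported
  size effect in benign lesions is not modelled.
* Hardware has zero effect on ADC by default, consistent with the
  published regression; `center_effect_sd` adds an additive per-center
  shift for robustness experiments only.
* Real per-group ADC distributions are not truncated normals. One visible
  consequence: under the idealized model the expected PPV for invasive
  carcinoma at a 1.1 cut-off is ≈ 95.5%, marginally above the 95% bar, so
  the PPV-anchored boundary derived on simulated cohorts is most often 1.1
  rather than the published 1.0 (which remains within one grid step, and
  the mean PPV at 1.0 itself, ≈ 96%, matches the published 95.8% well).
  The real cohort evidently carried more DCIS mass just above 1.0 than a
  normal tail implies.
* The generator contains no B0/B1 material by default
  (`adc_missing_rate = 0`), as in the derivation database.

Separately, `reference_cohort()` is a *deterministic* synthetic cohort
that realizes the published per-category benign/malignant counts exactly
(69/187/683/797 lesions in B2–B5), with evenly spaced ADC inside each
category bin, every lesion within its subtype's published ADC range, and
DCIS placed toward the top of B5 and bottom of B4 (the clinically expected
pattern). On it, the whole derivation returns the published
(1.9, 1.5, 1.0) triple and all published rate arithmetic is exact; it is
the fixed test surface for everything downstream of the generator.

## Problem sizes used in the checks

The test suite and the acceptance script run at the study's own scale
where that is cheap (cohorts of 1736; 200 simulation replicates of the
1020-vs-98 ROC comparison; 20 replicate cohorts for parameter recovery)
and at reduced scale for brute-force oracles (curves recounted
quadratically at n ≤ 40; AUC pair-counting at class sizes ≤ 12 over 1000
random instances). All randomized checks run under fixed seeds.

## Limitations

The package operates strictly on measured per-lesion ADC values: ROI
placement, ADC-map computation and image I/O are out of scope, as is any
combination of ADC-B with contrast-enhancement descriptors into a joint
score. Patient-level clustering (some patients contribute two lesions) is
ignored in all inference, matching the per-lesion convention of the
analysis plan the package reproduces; standard errors for regression
coefficients are therefore mildly optimistic. Thresholds derived on
synthetic cohorts inherit every simplification listed above and should be
read as consistency checks of the *procedure*, not as clinical
re-derivations.
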