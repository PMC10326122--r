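# adcb — breast ADC categorization (ADC-B)

`adcb` implements the ADC-B category system for contrast-enhancing breast
lesions on MRI. The apparent diffusion coefficient (ADC, in units of
10⁻³ mm²/s) measured on diffusion-weighted imaging is a quantitative
malignancy marker — cellular tumors restrict water diffusion and show low
ADC — but its overlap across lesion entities makes a single cut-off too
crude for clinical reporting. ADC-B instead maps a lesion's ADC to one of
six ordered categories, in analogy to BI-RADS: **B0** (ADC not
measurable), **B1** (no enhancing lesion), and **B2–B5** with decreasing
ADC and increasing malignancy rate (defaults: B2 ≥ 1.9, B3 1.5–<1.9,
B4 1.0–<1.5, B5 < 1.0).

The package is aimed at breast-imaging researchers who want to apply the
published scheme to their own lesion tables, re-derive thresholds on new
cohorts, or study the derivation procedure itself. It provides:

* the **cumulative malignancy-rate curve**: at each threshold `t`,
  `rate(t) = #{malignant with ADC ≥ t} / N_total` — the anchor of the
  B2/B3 bounds (targets < 0.1% and 2%, cut-offs rounded to one decimal);
* **ROC/PPV selection** of the B4/B5 boundary: the largest one-decimal
  cut-off giving ≥ 95% PPV for invasive carcinoma versus DCIS, with low
  ADC as test-positive and trapezoidal AUC equal to the Mann-Whitney
  statistic;
* a **classifier and per-category audit table** (counts, within-category
  and cumulative malignancy rates);
* the accompanying **validation statistics**: Welch/Student t tests,
  one-way ANOVA, Games-Howell post hoc comparisons (studentized range via
  `ptukey`), and multivariable linear regression with adjusted R²;
* a **calibrated synthetic cohort generator** (truncated-normal ADC per
  histology group, published subtype mix, sizes, centers) and a
  deterministic **benchmark cohort** realizing the published per-category
  counts, so the whole pipeline is testable without the non-public
  multicenter database.

## Worked example

```r
library(adcb)

co <- generate_cohort(default_generator_config(), seed = 1)
co
#> ADC-B lesion cohort: 1736 lesions, 1625 patients (synthetic (seed 1))
#>   malignant 1155 (66.5%), benign 581; ADC missing: 0

derive_scheme(co)
#> ADC-B threshold scheme (derived from cohort), ADC in 1e-3 mm^2/s
#>   B2: ADC >= 1.9   B3: 1.5 to < 1.9   B4: 1.2 to < 1.5   B5: < 1.2
#>   B2 target 0.1%: raw 1.875 -> 1.9 (rate there 0.058%)
#>   B3 target 2%: raw 1.47 -> 1.5 (rate there 1.7%)
#>   B4/B5 PPV target 95%: cutoff 1.2, PPV 95.2% (909/955)
#>   ROC AUC 0.759 (SE 0.021)
```

Reading the report: the 0.1% cumulative-malignancy crossing sits at ADC
1.875 and rounds to the B2 bound 1.9, where the recomputed rate is 0.058%;
the 2% crossing (1.47) rounds to 1.5, where the rate is 1.7%. The B4/B5
boundary is the largest one-decimal cut-off keeping the PPV for invasive
carcinoma (vs DCIS) above 95% — on this simulated cohort 1.2 (PPV 95.2%),
one grid step above the published 1.0, because idealized truncated-normal
tails put slightly less DCIS just above 1.0 than the real cohort had.

Classifying against the published scheme and auditing per category:

```r
summarize_categories(co, threshold_scheme())
#>  category   n n_benign n_malignant within_rate cumulative_rate
#>        B0   0        0           0
#>        B1   0        0           0
#>        B2  71       70           1        1.4%            0.1%
#>        B3 199      171          28       14.1%            1.7%
#>        B4 722      277         445       61.6%           27.3%
#>        B5 744       63         681       91.5%           66.5%
```

`within_rate` is the malignancy prevalence inside each category;
`cumulative_rate` is the curve rate at the category's lower ADC bound
(total-cohort denominator). On the deterministic benchmark cohort,
`summarize_categories(reference_cohort())` reproduces the published audit
table exactly (within-category rates 2.9 / 15.0 / 57.8 / 91.6%, cumulative
rates 0.1 / 1.7 / 24.5%), and `derive_scheme(reference_cohort())` returns
the published (1.9, 1.5, 1.0) triple.

`run_pipeline(run_config(...))` chains generation/loading, validation,
derivation, classification and statistics, writing delimited tables plus a
JSON manifest; `inst/scripts/adcb_run.R` is a command-line wrapper around
it.

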