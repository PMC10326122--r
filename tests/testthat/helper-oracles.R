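# Independent brute-force oracles and small cohort builders used across the
# suite. The oracles deliberately avoid the implementation's code paths.

# minimal cohort from ADC + outcome vectors (generic subtype labels)
make_cohort <- function(adc, outcome, subtype = NULL, size_mm = 10) {
  n <- length(adc)
  if (is.null(subtype)) {
    subtype <- ifelse(outcome == "malignant", "invasive", "benign")
  }
  as_cohort(data.frame(
    lesion_id = sprintf("T%04d", seq_len(n)),
    patient_id = sprintf("Q%04d", seq_len(n)),
    center_id = "C1",
    field_strength = 1.5,
    vendor = "Siemens",
    adc = adc,
    size_mm = size_mm,
    mass = TRUE,
    subtype = subtype,
    outcome = outcome,
    high_risk = subtype == "high_risk",
    stringsAsFactors = FALSE
  ), source_label = "test")
}

# random small cohort with ties (ADC rounded to limited precision)
random_cohort <- function(n, seed) {
  set.seed(seed)
  adc <- round(runif(n, 0.3, 2.5), sample(1:2, 1))
  outcome <- sample(c("benign", "malignant"), n, replace = TRUE)
  make_cohort(adc, outcome)
}

# O(n^2) recount of the cumulative malignancy curve: for every distinct ADC
# t (descending), count malignant and total lesions with ADC >= t
oracle_curve <- function(adc, malignant) {
  keep <- !is.na(adc)
  adc <- adc[keep]; malignant <- malignant[keep]
  ts <- sort(unique(adc), decreasing = TRUE)
  data.frame(
    adc = ts,
    cum_malignant = vapply(ts, function(t) sum(malignant & adc >= t), 0),
    cum_total = vapply(ts, function(t) sum(adc >= t), 0),
    cum_rate = vapply(ts, function(t) sum(malignant & adc >= t), 0) /
      length(adc)
  )
}

# Mann-Whitney AUC by exhaustive pair counting (low ADC = test-positive):
# fraction of (pos, neg) pairs with pos < neg, ties counted one half
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}
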