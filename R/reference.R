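# Deterministic benchmark cohort.
#
# The original multicenter lesion database is not public; what is published
# is its per-category audit table (benign/malignant counts per ADC-B
# category), the subtype totals and the per-subtype ADC ranges. This module
# reconstructs a SYNTHETIC cohort that realizes those published marginals
# exactly, with evenly spaced ADC values inside each category bin. All the
# printed rate arithmetic (within-category rates 2.9/15.0/57.8/91.6%,
# cumulative rates 0.1/1.7/24.5% at 1.9/1.5/1.0) is reproduced by
# construction, and the full five-step derivation returns the published
# (1.9, 1.5, 1.0) scheme on it. Subtypes are placed where the published
# group ADC ranges put them (DCIS toward the top of B5 and bottom of B4,
# mucinous carcinoma in the mid-ADC bins), so the PPV-anchored boundary
# lands at 1.0 as well.

#' Benchmark cohort realizing the published category counts
#'
#' A deterministic, synthetic 1736-lesion cohort whose ADC-B category table
#' under the default scheme is exactly the published one: 67/2
#' (benign/malignant) in B2, 159/28 in B3, 288/395 in B4, 67/730 in B5,
#' with 466 plain-benign, 115 high-risk, 1020 invasive, 98 DCIS, 26
#' mucinous and 11 other-malignant lesions overall. ADC values are evenly
#' spaced within each category bin and every lesion respects its subtype's
#' published ADC range. Used as the fixed arithmetic test surface for the
#' curve, classifier and derivation modules.
#'
#' @return An [as_cohort()] object with 1736 lesions from 1625 patients.
#' @export
#' @examples
#' summarize_categories(reference_cohort())
reference_cohort <- function() {
  seg <- function(adc, outcome, subtype) {
    data.frame(adc = adc, outcome = outcome, subtype = subtype,
               stringsAsFactors = FALSE)
  }

  # B2 (ADC >= 1.9): 67 benign, 2 malignant (DCIS, placed just above the
  # boundary so the 0.1% rate crossing rounds to 1.9)
  b2_ben <- seq(1.95, 2.69, length.out = 67)
  b2 <- rbind(seg(c(1.90, 1.93), "malignant", "dcis"),
              seg(b2_ben, "benign",
                  ifelse(seq_along(b2_ben) <= 10, "high_risk", "benign")))

  # B3 [1.5, 1.9): 159 benign, 28 malignant (8 mucinous low, 6 invasive
  # mid, 14 DCIS high — all within the published subtype ranges)
  b3_mal_adc <- seq(1.50, 1.88, length.out = 28)
  b3_mal_sub <- c(rep("mucinous", 8), rep("invasive", 6), rep("dcis", 14))
  b3_ben <- seq(1.501, 1.895, length.out = 159)
  b3 <- rbind(seg(b3_mal_adc, "malignant", b3_mal_sub),
              seg(b3_ben, "benign",
                  ifelse(seq_along(b3_ben) <= 35, "high_risk", "benign")))

  # B4 [1.0, 1.5): 288 benign, 395 malignant; descending malignant ADC is
  # 320 invasive, then 18 mucinous + 2 other, then 55 DCIS at the bottom
  b4_mal_adc <- seq(1.49, 1.001, length.out = 395)          # descending
  b4_mal_sub <- c(rep("invasive", 320), rep("mucinous", 18),
                  rep("other_malignant", 2), rep("dcis", 55))
  b4_ben <- seq(1.4995, 1.0005, length.out = 288)
  b4 <- rbind(seg(b4_mal_adc, "malignant", b4_mal_sub),
              seg(b4_ben, "benign",
                  ifelse(seq_along(b4_ben) <= 60, "high_risk", "benign")))

  # B5 (< 1.0): 67 benign, 730 malignant; 27 DCIS at the top, 9 other
  # malignancies near 0.45, invasive elsewhere down to 0.27
  b5_mal_adc <- seq(0.999, 0.27, length.out = 730)          # descending
  b5_mal_sub <- rep("invasive", 730)
  b5_mal_sub[1:27] <- "dcis"
  oth <- order(abs(b5_mal_adc - 0.45))[1:9]
  b5_mal_sub[oth] <- "other_malignant"
  b5_ben <- seq(0.995, 0.40, length.out = 67)               # descending
  b5 <- rbind(seg(b5_mal_adc, "malignant", b5_mal_sub),
              seg(b5_ben, "benign",
                  ifelse(seq_along(b5_ben) <= 10, "high_risk", "benign")))

  tab <- rbind(b2, b3, b4, b5)
  n <- nrow(tab)
  mal <- tab$outcome == "malignant"

  # deterministic covariates: sizes spread around the published outcome
  # means, centers cycled with their vendor labels
  size <- numeric(n)
  size[mal] <- seq(8, 38.2, length.out = sum(mal))
  size[!mal] <- seq(5, 26.8, length.out = sum(!mal))
  centers <- paste0("C", 1:7)
  vendors <- c(C1 = "Siemens", C2 = "Siemens", C3 = "Siemens",
               C4 = "Siemens", C5 = "Philips", C6 = "Philips",
               C7 = "Philips")
  center_id <- rep_len(centers, n)
  # 1625 patients for 1736 lesions: the first 111 patients have two lesions
  patient_id <- c(paste0("P", rep(1:111, each = 2)),
                  paste0("P", 112:(n - 111)))

  lesions <- data.frame(
    lesion_id = sprintf("L%04d", seq_len(n)),
    patient_id = patient_id,
    center_id = center_id,
    field_strength = ifelse(center_id %in% c("C1", "C5"), 3.0, 1.5),
    vendor = vendors[center_id],
    adc = tab$adc,
    size_mm = size,
    mass = TRUE,
    subtype = tab$subtype,
    outcome = tab$outcome,
    high_risk = tab$subtype == "high_risk",
    stringsAsFactors = FALSE
  )
  as_cohort(lesions, source_label = "synthetic benchmark (published marginals)")
}
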