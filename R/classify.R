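# ADC-B category scheme: encoding, classification, audit summaries, and the
# five-step threshold derivation.
#
# Category semantics (defaults in 1e-3 mm^2/s):
#   B0  ADC not measurable (artifacts etc.)      — input state, no range
#   B1  no enhancing lesion                      — input state, no range
#   B2  ADC >= 1.9        "very high", rule-out-level malignancy rate
#   B3  1.5 <= ADC < 1.9  "high", probably benign
#   B4  1.0 <= ADC < 1.5  "intermediate/low", biopsy-level rate
#   B5  ADC < 1.0         "very low", mostly invasive carcinoma
# Intervals are closed below and open above ("1.5 to < 1.9").

.adcb_levels <- c("B0", "B1", "B2", "B3", "B4", "B5")

#' ADC-B threshold scheme
#'
#' The three ADC cut-offs defining categories B2-B5. B0/B1 are input-state
#' codes and carry no thresholds.
#'
#' @param t_b2 Lower bound of B2 (default 1.9).
#' @param t_b3 Lower bound of B3 (default 1.5).
#' @param t_b45 Boundary between B4 and B5 (default 1.0).
#' @param provenance Free text describing where the cut-offs came from.
#' @return A `threshold_scheme` list.
#' @export
#' @examples
#' threshold_scheme()            # the published defaults
threshold_scheme <- function(t_b2 = 1.9, t_b3 = 1.5, t_b45 = 1.0,
                             provenance = "fixed defaults") {
  if (!(0 < t_b45 && t_b45 < t_b3 && t_b3 < t_b2)) {
    stop("thresholds must satisfy 0 < t_b45 < t_b3 < t_b2", call. = FALSE)
  }
  structure(list(t_b2 = t_b2, t_b3 = t_b3, t_b45 = t_b45,
                 provenance = provenance),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf(paste0(
    "ADC-B threshold scheme (%s), ADC in 1e-3 mm^2/s\n",
    "  B2: ADC >= %.4g   B3: %.4g to < %.4g   B4: %.4g to < %.4g   B5: < %.4g\n"),
    x$provenance, x$t_b2, x$t_b3, x$t_b2, x$t_b45, x$t_b3, x$t_b45))
  invisible(x)
}

#' Classify lesions into ADC-B categories
#'
#' Total, vectorized classification: a non-enhancing case is B1 regardless
#' of ADC; an enhancing case without measurable ADC is B0; otherwise the
#' ADC falls into exactly one of B2-B5 under the half-open interval
#' convention (lower bounds closed). An ADC exactly at a boundary belongs
#' to the higher-ADC category of the two it separates (1.0 is B4, since B5
#' is "< 1.0").
#'
#' @param adc Numeric ADC values (1e-3 mm^2/s); NA = not measurable.
#' @param enhancing Logical, recycled; FALSE yields B1.
#' @param scheme A [threshold_scheme()].
#' @return Factor with levels B0, B1, B2, B3, B4, B5.
#' @export
#' @examples
#' classify_adcb(c(2.0, 1.9, 1.7, 1.0, 0.6, NA))
classify_adcb <- function(adc, enhancing = TRUE, scheme = threshold_scheme()) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (any(!is.na(adc) & adc < 0)) {
    stop("ADC values must be non-negative", call. = FALSE)
  }
  enhancing <- rep_len(enhancing, length(adc))
  cat <- ifelse(!enhancing, "B1",
         ifelse(is.na(adc), "B0",
         ifelse(adc >= scheme$t_b2, "B2",
         ifelse(adc >= scheme$t_b3, "B3",
         ifelse(adc >= scheme$t_b45, "B4", "B5")))))
  factor(cat, levels = .adcb_levels)
}

#' Per-category audit summary
#'
#' Tabulates benign/malignant counts per ADC-B category, the
#' within-category malignancy rate, and the cumulative malignancy rate at
#' each category's lower ADC bound (computed on the malignancy curve with
#' the total-cohort denominator). Counts always conserve the cohort size.
#' All cohort records are treated as enhancing (a recorded lesion exists),
#' so B1 is only populated via `enhancing` metadata in future extensions;
#' B0 collects the missing-ADC lesions.
#'
#' @param cohort An `adcb_cohort`.
#' @param scheme A [threshold_scheme()].
#' @return A `category_summary` data.frame with columns `category`, `n`,
#'   `n_benign`, `n_malignant`, `within_rate`, `cumulative_rate`.
#' @export
summarize_categories <- function(cohort, scheme = threshold_scheme()) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  cat <- classify_adcb(cohort$adc, enhancing = TRUE, scheme = scheme)
  mal <- cohort$outcome == "malignant"
  n <- as.integer(table(cat))
  n_mal <- as.integer(table(cat[mal]))
  out <- data.frame(category = .adcb_levels,
                    n = n,
                    n_benign = n - n_mal,
                    n_malignant = n_mal,
                    stringsAsFactors = FALSE)
  out$within_rate <- ifelse(out$n > 0 & !(out$category %in% c("B0", "B1")),
                            out$n_malignant / out$n, NA_real_)
  out$cumulative_rate <- NA_real_
  if (any(!is.na(cohort$adc))) {
    curve <- build_curve(cohort)
    bounds <- c(B2 = scheme$t_b2, B3 = scheme$t_b3, B4 = scheme$t_b45, B5 = 0)
    out$cumulative_rate[match(names(bounds), out$category)] <-
      rate_at_threshold(curve, bounds)
  }
  structure(out, class = c("category_summary", "data.frame"))
}

#' @export
print.category_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$within_rate <- ifelse(is.na(y$within_rate), "",
                          sprintf("%.1f%%", 100 * y$within_rate))
  y$cumulative_rate <- ifelse(is.na(y$cumulative_rate), "",
                              sprintf("%.1f%%", 100 * y$cumulative_rate))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Derive an ADC-B threshold scheme from a cohort
#'
#' Runs the five-step derivation:
#' 1. build the cumulative malignancy-rate curve (descending ADC);
#' 2./3. read the ADC values at the B2 and B3 target cumulative malignancy
#'    rates off the curve;
#' 4. set the B4/B5 boundary as the largest grid cut-off giving at least
#'    `ppv_target` PPV for invasive carcinoma vs DCIS (low ADC positive);
#' 5. round the curve-derived cut-offs to `decimals` decimals and recompute
#'    the (slightly shifted) category rates at the rounded values.
#'
#' The returned report carries the raw and rounded thresholds, attainment
#' flags, recomputed rates and the PPV diagnostics. If the three rounded
#' thresholds violate the ordering `t_b45 < t_b3 < t_b2` the scheme is
#' still returned unreordered with `ordering_ok = FALSE`.
#'
#' @param cohort An `adcb_cohort` containing benign lesions, invasive
#'   carcinomas and DCIS.
#' @param b2_rate,b3_rate Target cumulative malignancy rates for the B2 and
#'   B3 lower bounds (defaults 0.001 and 0.02, i.e. the "< 0.1%" rule-out
#'   and 2% probably-benign anchors).
#' @param ppv_target Required PPV for invasive vs DCIS at the B4/B5
#'   boundary (default 0.95).
#' @param decimals Rounding precision of all cut-offs (default 1).
#' @param include_mucinous Passed to [roc_classes()].
#' @return An `adcb_derivation` list: `scheme` (a [threshold_scheme()]),
#'   `b2`, `b3` (results of [threshold_at_rate()]), `ppv` (result of
#'   [select_ppv_cutoff()]), `roc` (an [roc_curve()] object),
#'   `ordering_ok`, `summary` (a [summarize_categories()] table when the
#'   ordering holds).
#' @export
derive_scheme <- function(cohort, b2_rate = 0.001, b3_rate = 0.02,
                          ppv_target = 0.95, decimals = 1,
                          include_mucinous = FALSE) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  curve <- build_curve(cohort)
  b2 <- threshold_at_rate(curve, b2_rate, decimals)
  b3 <- threshold_at_rate(curve, b3_rate, decimals)
  cls <- roc_classes(cohort, include_mucinous = include_mucinous)
  if (length(cls$positives) == 0L || length(cls$negatives) == 0L) {
    stop("cohort must contain invasive carcinomas and DCIS for the B4/B5 ",
         "boundary", call. = FALSE)
  }
  roc <- roc_curve(cls$positives, cls$negatives)
  ppv <- select_ppv_cutoff(cls$positives, cls$negatives, ppv_target, decimals)
  ordering_ok <- 0 < ppv$cutoff && ppv$cutoff < b3$threshold &&
    b3$threshold < b2$threshold
  scheme <- if (ordering_ok) {
    threshold_scheme(b2$threshold, b3$threshold, ppv$cutoff,
                     provenance = "derived from cohort")
  } else {
    structure(list(t_b2 = b2$threshold, t_b3 = b3$threshold,
                   t_b45 = ppv$cutoff,
                   provenance = "derived from cohort (ordering violated)"),
              class = "threshold_scheme")
  }
  res <- list(scheme = scheme, b2 = b2, b3 = b3, ppv = ppv, roc = roc,
              ordering_ok = ordering_ok,
              targets = list(b2_rate = b2_rate, b3_rate = b3_rate,
                             ppv_target = ppv_target, decimals = decimals),
              summary = if (ordering_ok) summarize_categories(cohort, scheme)
                        else NULL)
  class(res) <- "adcb_derivation"
  res
}

#' @export
print.adcb_derivation <- function(x, ...) {
  print(x$scheme)
  cat(sprintf(
    "  B2 target %.2g%%: raw %.4g -> %.4g (rate there %.2g%%)%s\n",
    100 * x$targets$b2_rate, x$b2$raw_threshold, x$b2$threshold,
    100 * x$b2$rate_at_threshold,
    if (x$b2$attained) "" else "  [UNATTAINED]"))
  cat(sprintf(
    "  B3 target %.2g%%: raw %.4g -> %.4g (rate there %.2g%%)%s\n",
    100 * x$targets$b3_rate, x$b3$raw_threshold, x$b3$threshold,
    100 * x$b3$rate_at_threshold,
    if (x$b3$attained) "" else "  [UNATTAINED]"))
  cat(sprintf(
    "  B4/B5 PPV target %.0f%%: cutoff %.4g, PPV %.1f%% (%d/%d)%s\n",
    100 * x$targets$ppv_target, x$ppv$cutoff, 100 * x$ppv$ppv,
    x$ppv$n_true_positive, x$ppv$n_test_positive,
    if (x$ppv$attained) "" else "  [UNATTAINED]"))
  cat(sprintf("  ROC AUC %.3f (SE %.3f)\n", x$roc$auc, x$roc$std_error))
  if (!x$ordering_ok) cat("  WARNING: threshold ordering violated\n")
  invisible(x)
}
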