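# ROC / PPV machinery for the ADC-B4 vs ADC-B5 boundary.
#
# Orientation: LOW ADC is test-positive throughout (restricted diffusion
# suggests invasive carcinoma), i.e. a lesion is called positive when its
# ADC falls BELOW the cut-off. This is stated explicitly because silently
# inverted orientation produces 1 - AUC and is a classic failure mode.

#' Empirical ROC curve for ADC (low ADC = test-positive)
#'
#' One operating point per distinct observed ADC value plus the two
#' degenerate endpoints (call nothing / call everything). At cut-off `c`,
#' sensitivity is the fraction of positives with ADC < `c` and
#' 1 - specificity the fraction of negatives with ADC < `c` (strict
#' inequality, matching the category definition "ADC-B5: < 1.0"). The AUC
#' is the trapezoidal area under the full empirical curve, which equals the
#' Mann-Whitney statistic (ties counted 1/2). The standard error is the
#' Hanley-McNeil approximation.
#'
#' @param positives ADC values of the test-positive class (invasive
#'   carcinomas in the ADC-B derivation).
#' @param negatives ADC values of the comparator class (DCIS).
#' @return An `adc_roc` list: `thresholds` (descending), `sensitivity`,
#'   `one_minus_specificity`, `auc`, `std_error`, `n_pos`, `n_neg`,
#'   `positive_definition`.
#' @export
#' @examples
#' r <- roc_curve(c(0.7, 0.8, 0.9), c(1.1, 1.2, 1.3))
#' r$auc
roc_curve <- function(positives, negatives) {
  positives <- as.numeric(positives)
  negatives <- as.numeric(negatives)
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (anyNA(positives) || anyNA(negatives)) {
    stop("ADC values must not be missing", call. = FALSE)
  }
  # cut-offs: every distinct observed value, plus one above the maximum so
  # that "call everything" is on the curve; -Inf end is the all-negative
  # point (sens = fpr = 0) reached at the minimum cut-off
  vals <- sort(unique(c(positives, negatives)))
  cuts <- c(vals, max(vals) + 1)
  # findInterval with left.open counts values strictly below each cut-off
  sp <- sort(positives)
  sn <- sort(negatives)
  sens <- findInterval(cuts, sp, left.open = TRUE) / length(positives)
  fpr <- findInterval(cuts, sn, left.open = TRUE) / length(negatives)
  sens <- c(0, sens)
  fpr <- c(0, fpr)
  # trapezoid over the (fpr, sens) polyline; fpr is non-decreasing
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  n_pos <- length(positives)
  n_neg <- length(negatives)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  structure(list(thresholds = rev(cuts),
                 sensitivity = rev(sens[-1]),
                 one_minus_specificity = rev(fpr[-1]),
                 auc = auc,
                 std_error = se,
                 n_pos = n_pos,
                 n_neg = n_neg,
                 positive_definition = "invasive; low ADC is test-positive"),
            class = "adc_roc")
}

#' @export
print.adc_roc <- function(x, ...) {
  cat(sprintf("ADC ROC (%s)\n  AUC %.3f (SE %.3f), %d positives vs %d negatives\n",
              x$positive_definition, x$auc, x$std_error, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.adc_roc <- function(x, ...) {
  plot(c(0, rev(x$one_minus_specificity)), c(0, rev(x$sensitivity)),
       type = "l", xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Positive predictive value at an ADC cut-off
#'
#' PPV for the low-ADC test: among all observations (both classes) with
#' ADC strictly below `cutoff`, the fraction that are true positives. With
#' an empty test-positive set the PPV is undefined and the result is
#' flagged rather than raised.
#'
#' @inheritParams roc_curve
#' @param cutoff ADC cut-off (test-positive: ADC < `cutoff`).
#' @return List with `ppv` (NA when undefined), `defined`,
#'   `n_test_positive`, `n_true_positive`.
#' @export
ppv_at <- function(positives, negatives, cutoff) {
  tp <- sum(positives < cutoff)
  fp <- sum(negatives < cutoff)
  n <- tp + fp
  list(ppv = if (n > 0) tp / n else NA_real_,
       defined = n > 0,
       n_test_positive = as.integer(n),
       n_true_positive = as.integer(tp))
}

#' PPV-anchored cut-off selection
#'
#' Scans the `decimals`-rounded candidate grid spanning the observed ADC
#' range and returns the LARGEST cut-off whose PPV meets `target_ppv` —
#' i.e. the most sensitive operating point that still satisfies the PPV
#' constraint. Candidates with an empty test-positive set are skipped.
#' When no candidate qualifies the result is flagged `attained = FALSE`
#' and carries the best (highest-PPV) candidate for diagnostics.
#'
#' @inheritParams roc_curve
#' @param target_ppv Required PPV in (0, 1).
#' @param decimals Grid precision (default 1 decimal of ADC).
#' @return List with `cutoff`, `attained`, `ppv`, `n_test_positive`,
#'   `n_true_positive` at the selected cut-off, and the scanned `grid`
#'   (data.frame of candidate, ppv, n_test_positive).
#' @export
select_ppv_cutoff <- function(positives, negatives, target_ppv,
                              decimals = 1) {
  stopifnot(target_ppv > 0, target_ppv <= 1)
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  vals <- c(positives, negatives)
  step <- 10^(-decimals)
  lo <- floor(min(vals) * 10^decimals) / 10^decimals + step
  hi <- ceiling(max(vals) * 10^decimals) / 10^decimals
  candidates <- round(seq(lo, hi, by = step), decimals)
  grid <- do.call(rbind, lapply(candidates, function(ct) {
    p <- ppv_at(positives, negatives, ct)
    data.frame(cutoff = ct, ppv = p$ppv,
               n_test_positive = p$n_test_positive,
               n_true_positive = p$n_true_positive)
  }))
  ok <- which(!is.na(grid$ppv) & grid$ppv >= target_ppv)
  if (length(ok) > 0L) {
    sel <- max(ok)
    attained <- TRUE
  } else {
    sel <- if (any(!is.na(grid$ppv))) which.max(grid$ppv) else 1L
    attained <- FALSE
  }
  list(cutoff = grid$cutoff[sel],
       attained = attained,
       ppv = grid$ppv[sel],
       n_test_positive = grid$n_test_positive[sel],
       n_true_positive = grid$n_true_positive[sel],
       grid = grid)
}

#' Extract ROC classes from a cohort
#'
#' Splits a cohort into the ADC vectors of the invasive-carcinoma positives
#' and DCIS negatives used for the ADC-B4/B5 boundary. By default the
#' positives are the invasive group EXCLUDING mucinous carcinomas (whose
#' high ADC makes them an outlier among invasive tumors) and excluding
#' non-breast malignancies; `include_mucinous = TRUE` folds mucinous
#' carcinomas back in.
#'
#' @param cohort An `adcb_cohort`.
#' @param include_mucinous Include mucinous carcinomas among positives.
#' @return List with numeric vectors `positives`, `negatives` (missing ADC
#'   dropped).
#' @export
roc_classes <- function(cohort, include_mucinous = FALSE) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  grp <- subtype_group(cohort$subtype)
  pos_groups <- if (include_mucinous) c("invasive", "mucinous") else "invasive"
  pos <- cohort$adc[grp %in% pos_groups & !is.na(cohort$adc)]
  neg <- cohort$adc[grp == "dcis" & !is.na(cohort$adc)]
  list(positives = pos, negatives = neg)
}
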