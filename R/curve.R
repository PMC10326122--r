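# Cumulative malignancy-rate curve.
#
# The backbone of the ADC-B derivation: lesions are ordered by descending
# ADC and, at each distinct ADC value t, the cumulative malignancy rate is
# the number of malignant lesions with ADC >= t divided by the TOTAL number
# of lesions with measurable ADC. The total-cohort denominator is what the
# published per-category arithmetic implies (2/1736 = 0.1%, 30/1736 = 1.7%,
# 425/1736 = 24.5% at the 1.9/1.5/1.0 boundaries); a tail-conditional
# denominator would instead give the within-category rates (2.9/15.0/57.8%).

#' Build the cumulative malignancy-rate curve
#'
#' Orders lesions by strictly descending ADC (ties collapse into one point
#' counting all tied lesions) and accumulates malignant and total counts
#' from the top. Lesions with missing ADC are excluded — they belong in
#' category ADC-B0, not on the curve.
#'
#' @param cohort An `adcb_cohort` with at least one measurable ADC.
#' @return A `malignancy_curve`: a data.frame with one row per distinct ADC
#'   (descending) and columns `adc`, `cum_malignant`, `cum_total`,
#'   `cum_rate`, plus attributes `n_total` and `n_malignant` (measurable
#'   lesions only).
#' @export
#' @examples
#' co <- generate_cohort(default_generator_config(n_lesions = 100), seed = 1)
#' head(build_curve(co))
build_curve <- function(cohort) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  usable <- !is.na(cohort$adc)
  if (!any(usable)) {
    stop("no lesions with measurable ADC: cannot build a malignancy curve",
         call. = FALSE)
  }
  adc <- cohort$adc[usable]
  malignant <- cohort$outcome[usable] == "malignant"
  ord <- order(adc, decreasing = TRUE)
  adc <- adc[ord]
  malignant <- malignant[ord]
  # collapse ties: one point per distinct ADC, counting all tied lesions
  grp <- cumsum(!duplicated(adc))
  pts <- data.frame(
    adc = adc[!duplicated(adc)],
    cum_malignant = cumsum(tapply(malignant, grp, sum)[unique(grp)]),
    cum_total = cumsum(tabulate(grp))
  )
  n_total <- length(adc)
  pts$cum_rate <- pts$cum_malignant / n_total
  rownames(pts) <- NULL
  structure(pts, class = c("malignancy_curve", "data.frame"),
            n_total = n_total, n_malignant = sum(malignant))
}

#' @export
print.malignancy_curve <- function(x, ...) {
  cat(sprintf(
    "Cumulative malignancy-rate curve: %d points, %d/%d malignant (%.1f%%)\n",
    nrow(x), attr(x, "n_malignant"), attr(x, "n_total"),
    100 * attr(x, "n_malignant") / attr(x, "n_total")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Cumulative malignancy rate at a threshold
#'
#' The fraction of all measurable lesions that are malignant AND have
#' ADC >= `adc` (lower bound closed, matching the category convention
#' "1.5 to < 1.9"). Above the maximum observed ADC the tail is empty and the
#' rate is 0; at or below the minimum it is the overall malignancy rate.
#'
#' @param curve A [build_curve()] result.
#' @param adc Query threshold(s), 1e-3 mm^2/s; vectorized.
#' @return Numeric rate(s) in \[0, 1\].
#' @export
rate_at_threshold <- function(curve, adc) {
  stopifnot(inherits(curve, "malignancy_curve"), nrow(curve) > 0)
  # curve$adc is strictly descending; tail counts all points with adc >= t
  n_total <- attr(curve, "n_total")
  vapply(adc, function(t) {
    idx <- which(curve$adc >= t)
    if (length(idx) == 0L) 0 else curve$cum_malignant[max(idx)] / n_total
  }, numeric(1))
}

#' ADC threshold for a target cumulative malignancy rate
#'
#' Finds the ADC at which the cumulative malignancy-rate curve crosses a
#' target rate and rounds it to the clinically workable precision. The raw
#' crossing is the smallest observed ADC value whose cumulative rate is at
#' or below `target_rate`; it is then rounded to `decimals` decimals.
#' Because of the rounding, the rate recomputed at the returned threshold
#' can differ slightly from the target (the recomputed rate is part of the
#' result). When even the highest observed ADC exceeds the target rate the
#' result is flagged `attained = FALSE` and carries the rounded maximum ADC.
#'
#' @param curve A [build_curve()] result.
#' @param target_rate Target cumulative malignancy rate in (0, 1).
#' @param decimals Rounding precision of the reported threshold (default 1,
#'   i.e. one decimal of ADC in 1e-3 mm^2/s).
#' @return List with `threshold` (rounded), `raw_threshold` (observed ADC at
#'   the crossing), `attained` (logical), `rate_at_raw` and
#'   `rate_at_threshold` (cumulative rates at the raw and rounded values).
#' @export
threshold_at_rate <- function(curve, target_rate, decimals = 1) {
  stopifnot(inherits(curve, "malignancy_curve"), nrow(curve) > 0,
            target_rate > 0, target_rate < 1)
  ok <- which(curve$cum_rate <= target_rate)
  if (length(ok) == 0L) {
    raw <- curve$adc[1L]   # even the top of the curve exceeds the target
    attained <- FALSE
  } else {
    raw <- curve$adc[max(ok)]  # lowest ADC still meeting the target
    attained <- TRUE
  }
  thr <- round(raw, decimals)
  list(threshold = thr,
       raw_threshold = raw,
       attained = attained,
       rate_at_raw = rate_at_threshold(curve, raw),
       rate_at_threshold = rate_at_threshold(curve, thr))
}

#' Export a malignancy curve as delimited text
#'
#' @param curve A [build_curve()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, sep = ",") {
  stopifnot(inherits(curve, "malignancy_curve"))
  utils::write.table(as.data.frame(curve), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.malignancy_curve <- function(x, scheme = NULL, ...) {
  plot(x$adc, x$cum_rate, type = "s", xlim = rev(range(x$adc)),
       xlab = "ADC (1e-3 mm²/s)", ylab = "cumulative malignancy rate",
       ...)
  if (!is.null(scheme)) {
    graphics::abline(v = c(scheme$t_b2, scheme$t_b3, scheme$t_b45),
                     lty = c(2, 3, 1), col = "grey40")
  }
  invisible(x)
}
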