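# Validation statistics for group ADC comparisons.
#
# Thin, typed wrappers around the standard tests (t test, classic one-way
# ANOVA, least-squares regression) plus a Games-Howell post hoc
# implementation. Games-Howell is the unequal-variance, unequal-n pairwise
# procedure: Welch standard errors and degrees of freedom per pair, with
# p-values from the studentized-range distribution over all k group means
# (evaluated with base R's ptukey). No multiplicity correction beyond the
# studentized range itself is applied.

#' Independent two-sample t test
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param welch Use the Welch (Satterthwaite) variant; `FALSE` pools the
#'   variances.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff` (a minus b).
#' @export
adc_t_test <- function(a, b, welch = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(fit$statistic),
       df = unname(fit$parameter),
       p_value = fit$p.value,
       mean_diff = mean(a) - mean(b))
}

#' Classic one-way ANOVA
#'
#' Equal-variance (pooled) one-way ANOVA of values over group labels.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
adc_anova <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df1 = unname(fit$parameter[1L]),
       df2 = unname(fit$parameter[2L]),
       p_value = fit$p.value)
}

#' Games-Howell post hoc comparisons
#'
#' All pairwise group comparisons without assuming equal variances or equal
#' group sizes. For groups i, j with means m, variances s2 and sizes n:
#' standard error `se = sqrt(s2_i/n_i + s2_j/n_j)`, studentized statistic
#' `q = |m_i - m_j| / sqrt(se^2 / 2)`, Welch degrees of freedom
#' `df = se^4 / ((s2_i/n_i)^2/(n_i-1) + (s2_j/n_j)^2/(n_j-1))`, and the
#' p-value is the upper tail of the studentized-range distribution with
#' `k` means at `df` degrees of freedom (`ptukey`, which base R evaluates
#' by numerical quadrature). With k = 2 this reduces exactly to the Welch
#' t test. A pair in which both groups have zero variance has no defined
#' statistic and is flagged instead, as is a pair whose Welch df falls
#' below 2 (outside the domain of the studentized-range quadrature).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; every group n >= 2.
#' @return Data.frame with one row per unordered pair: `group1`, `group2`,
#'   `mean_diff`, `se`, `q`, `df`, `p_value`, `flag` (empty or
#'   `"zero_variance"`).
#' @export
#' @examples
#' co <- generate_cohort(default_generator_config(n_lesions = 400), seed = 2)
#' games_howell(co$adc, subtype_group(co$subtype))
games_howell <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  k <- nlevels(groups)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  labs <- levels(groups)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    vi <- v[i] / n[i]; vj <- v[j] / n[j]
    se2 <- vi + vj
    if (se2 == 0) {
      return(data.frame(group1 = labs[i], group2 = labs[j],
                        mean_diff = unname(m[i] - m[j]), se = 0,
                        q = NA_real_, df = NA_real_,
                        p_value = if (m[i] == m[j]) 1 else 0,
                        flag = "zero_variance", stringsAsFactors = FALSE))
    }
    df <- se2^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    # ptukey's quadrature is undefined below 2 df (possible when a group
    # has only 2-3 observations); such pairs are flagged, not NaN'd
    if (df < 2) {
      p <- NA_real_
      flag <- "insufficient_df"
    } else {
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      flag <- ""
    }
    data.frame(group1 = labs[i], group2 = labs[j],
               mean_diff = unname(m[i] - m[j]), se = unname(sqrt(se2)),
               q = unname(q), df = unname(df), p_value = unname(p),
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Multivariable linear ADC model
#'
#' Least-squares regression of ADC on final diagnosis, acquisition labels
#' and lesion size — the robustness check that the category thresholds rest
#' on diagnosis rather than hardware. Categorical covariates are
#' dummy-coded with the LARGEST level as reference. Covariates that are
#' constant in the cohort are dropped with a message; a rank-deficient
#' design (after encoding) is an error naming the aliased columns.
#'
#' Acquisition covariates are often nested (a center runs one vendor's
#' scanners), which makes the full design aliased; `on_alias = "drop"`
#' removes the aliased covariates with a message instead of erroring, which
#' is what the pipeline uses.
#'
#' @param cohort An `adcb_cohort` (rows with missing ADC are dropped).
#' @param include_diagnosis Include the benign/malignant outcome covariate;
#'   `FALSE` fits the hardware/size-only model used for comparison.
#' @param on_alias `"error"` (default): a rank-deficient design is an error
#'   naming the aliased columns; `"drop"`: aliased covariates are removed.
#' @return List with `coefficients` (data.frame: term, estimate, std_error,
#'   p_value), `term_p` (per-covariate F-test p-values), `r_squared`,
#'   `adjusted_r_squared`, `n`, `dropped` (constant or aliased covariates
#'   removed).
#' @export
adc_regression <- function(cohort, include_diagnosis = TRUE,
                           on_alias = c("error", "drop")) {
  on_alias <- match.arg(on_alias)
  stopifnot(inherits(cohort, "adcb_cohort"))
  dat <- data.frame(
    adc = cohort$adc,
    diagnosis = cohort$outcome,
    center = cohort$center_id,
    field_strength = as.character(cohort$field_strength),
    vendor = cohort$vendor,
    size_mm = cohort$size_mm,
    stringsAsFactors = FALSE
  )
  dat <- dat[!is.na(dat$adc) & !is.na(dat$size_mm), , drop = FALSE]
  covars <- c(if (include_diagnosis) "diagnosis", "center",
              "field_strength", "vendor", "size_mm")
  # largest level as reference for factors; drop constant covariates
  dropped <- character(0)
  for (cv in covars) {
    if (cv == "size_mm") next
    f <- factor(dat[[cv]])
    if (nlevels(f) < 2L) {
      dropped <- c(dropped, cv)
      next
    }
    ref <- names(which.max(table(f)))
    dat[[cv]] <- stats::relevel(f, ref = ref)
  }
  covars <- setdiff(covars, dropped)
  if (length(dropped) > 0L) {
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  if (length(covars) == 0L) stop("no usable covariates", call. = FALSE)
  repeat {
    form <- stats::reformulate(covars, response = "adc")
    fit <- stats::lm(form, data = dat)
    aliased <- is.na(stats::coef(fit))
    if (!any(aliased)) break
    if (on_alias == "error") {
      stop("rank-deficient design; aliased column(s): ",
           paste(names(stats::coef(fit))[aliased], collapse = ", "),
           call. = FALSE)
    }
    # drop the covariate owning the first aliased coefficient and refit
    owner <- covars[fit$assign[which(aliased)[1L]]]
    message("dropping aliased covariate: ", owner)
    dropped <- c(dropped, owner)
    covars <- setdiff(covars, owner)
    if (length(covars) == 0L) stop("no usable covariates", call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1L],
                      std_error = sm$coefficients[, 2L],
                      p_value = sm$coefficients[, 4L],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  dr <- stats::drop1(fit, test = "F")
  term_p <- stats::setNames(dr[["Pr(>F)"]][-1L], rownames(dr)[-1L])
  list(coefficients = coefs,
       term_p = term_p,
       r_squared = sm$r.squared,
       adjusted_r_squared = sm$adj.r.squared,
       n = nrow(dat),
       dropped = dropped,
       fit = fit)
}

#' Size-stratified benign/malignant comparison
#'
#' The published robustness check that splits lesions at 10 mm and compares
#' ADC between and within the size strata: within each outcome class, small
#' (<= 10 mm) vs large (> 10 mm) lesions; and within each size stratum,
#' benign vs malignant.
#'
#' @param cohort An `adcb_cohort`.
#' @param cut_mm Size cut in millimetres (default 10).
#' @param welch Passed to [adc_t_test()].
#' @return Data.frame with columns `comparison`, `n1`, `n2`, `mean1`,
#'   `mean2`, `statistic`, `df`, `p_value`.
#' @export
size_stratified_tests <- function(cohort, cut_mm = 10, welch = TRUE) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  ok <- !is.na(cohort$adc) & !is.na(cohort$size_mm)
  adc <- cohort$adc[ok]
  small <- cohort$size_mm[ok] <= cut_mm
  mal <- cohort$outcome[ok] == "malignant"
  one <- function(label, x, y) {
    t <- adc_t_test(x, y, welch = welch)
    data.frame(comparison = label, n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               statistic = t$statistic, df = t$df, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }
  rbind(
    one("benign: small vs large", adc[!mal & small], adc[!mal & !small]),
    one("malignant: small vs large", adc[mal & small], adc[mal & !small]),
    one("small: benign vs malignant", adc[!mal & small], adc[mal & small]),
    one("large: benign vs malignant", adc[!mal & !small], adc[mal & !small])
  )
}
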