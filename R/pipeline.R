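# End-to-end pipeline: cohort in (file or generator), thresholds derived or
# fixed, category audit and validation statistics out as delimited tables
# plus a JSON run manifest. All numeric output is written deterministically
# so identical (config, seed) runs produce byte-identical files.

#' Pipeline run configuration
#'
#' Exactly one of `input` (a lesion-table path) or `generator` (a
#' [default_generator_config()]) must be active; `generator` is ignored
#' when `input` is given.
#'
#' @param input Optional path to a delimited lesion table.
#' @param generator Generator configuration used when `input` is NULL.
#' @param seed Integer seed for the generator.
#' @param scheme `"derive"` to run the five-step derivation, or a fixed
#'   [threshold_scheme()].
#' @param b2_rate,b3_rate,ppv_target,decimals Derivation targets, passed to
#'   [derive_scheme()].
#' @param include_mucinous Passed to [derive_scheme()].
#' @param out_dir Output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL,
                       generator = default_generator_config(),
                       seed = 1,
                       scheme = "derive",
                       b2_rate = 0.001, b3_rate = 0.02,
                       ppv_target = 0.95, decimals = 1,
                       include_mucinous = FALSE,
                       out_dir = tempfile("adcb_run_")) {
  if (!is.null(input) && !is.character(input)) {
    stop("input must be a file path or NULL", call. = FALSE)
  }
  if (is.null(input)) validate_generator_config(generator)
  if (!identical(scheme, "derive") && !inherits(scheme, "threshold_scheme")) {
    stop("scheme must be \"derive\" or a threshold_scheme", call. = FALSE)
  }
  structure(list(input = input, generator = generator, seed = seed,
                 scheme = scheme, b2_rate = b2_rate, b3_rate = b3_rate,
                 ppv_target = ppv_target, decimals = decimals,
                 include_mucinous = include_mucinous, out_dir = out_dir),
            class = "run_config")
}

write_table_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "",
                                                sprintf("%.17g", x)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full ADC-B pipeline
#'
#' Stages: load or generate the cohort; validate it; build the cumulative
#' malignancy-rate curve; derive (or adopt) the threshold scheme with its
#' ROC/PPV diagnostics; classify and audit per category; run the validation
#' statistics (group ANOVA + Games-Howell, size-stratified t tests,
#' multivariable regression with and without diagnosis). Each stage logs
#' its in/out counts via `message()`. Outputs written to `config$out_dir`:
#' `cohort.csv` (generated cohorts only), `curve.csv`, `roc.csv`,
#' `scheme.csv`, `category_summary.csv`, `group_comparisons.csv`,
#' `size_tests.csv`, `regression.csv`, `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, curve, derivation (or fixed
#'   scheme), summary, stats tables and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input)
    message(sprintf("stage load: %d lesions read from %s",
                    nrow(cohort), config$input))
  } else {
    cohort <- generate_cohort(config$generator, seed = config$seed)
    message(sprintf("stage generate: %d lesions (seed %d)",
                    nrow(cohort), config$seed))
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
  }

  violations <- validate_cohort(cohort)
  if (nrow(violations) > 0L) {
    stop("stage validate: cohort has ", nrow(violations),
         " invariant violation(s); first: ", violations$message[1L],
         call. = FALSE)
  }
  message("stage validate: no violations")

  n_missing <- sum(is.na(cohort$adc))
  curve <- build_curve(cohort)
  message(sprintf("stage curve: %d lesions on curve, %d excluded (no ADC)",
                  attr(curve, "n_total"), n_missing))
  write_curve(curve, file.path(config$out_dir, "curve.csv"))

  if (identical(config$scheme, "derive")) {
    derivation <- derive_scheme(cohort, b2_rate = config$b2_rate,
                                b3_rate = config$b3_rate,
                                ppv_target = config$ppv_target,
                                decimals = config$decimals,
                                include_mucinous = config$include_mucinous)
    scheme <- derivation$scheme
    message(sprintf("stage derive: scheme (%.4g, %.4g, %.4g), AUC %.3f",
                    scheme$t_b2, scheme$t_b3, scheme$t_b45,
                    derivation$roc$auc))
    write_table_det(data.frame(one_minus_specificity =
                                 derivation$roc$one_minus_specificity,
                               sensitivity = derivation$roc$sensitivity,
                               threshold = derivation$roc$thresholds),
                    file.path(config$out_dir, "roc.csv"))
  } else {
    derivation <- NULL
    scheme <- config$scheme
    message(sprintf("stage derive: fixed scheme (%.4g, %.4g, %.4g)",
                    scheme$t_b2, scheme$t_b3, scheme$t_b45))
  }
  write_table_det(data.frame(threshold = c("t_b2", "t_b3", "t_b45"),
                             adc = c(scheme$t_b2, scheme$t_b3, scheme$t_b45),
                             provenance = scheme$provenance),
                  file.path(config$out_dir, "scheme.csv"))

  summary <- summarize_categories(cohort, scheme)
  message(sprintf("stage summarize: %d lesions over %d categories",
                  sum(summary$n), sum(summary$n > 0)))
  write_table_det(as.data.frame(summary),
                  file.path(config$out_dir, "category_summary.csv"))

  ok <- !is.na(cohort$adc)
  gh <- games_howell(cohort$adc[ok], subtype_group(cohort$subtype)[ok])
  write_table_det(gh, file.path(config$out_dir, "group_comparisons.csv"))
  st <- size_stratified_tests(cohort)
  write_table_det(st, file.path(config$out_dir, "size_tests.csv"))
  reg_full <- adc_regression(cohort, include_diagnosis = TRUE,
                             on_alias = "drop")
  reg_null <- adc_regression(cohort, include_diagnosis = FALSE,
                             on_alias = "drop")
  write_table_det(data.frame(
    model = c("with_diagnosis", "without_diagnosis"),
    r_squared = c(reg_full$r_squared, reg_null$r_squared),
    adjusted_r_squared = c(reg_full$adjusted_r_squared,
                           reg_null$adjusted_r_squared),
    n = c(reg_full$n, reg_null$n)),
    file.path(config$out_dir, "regression.csv"))
  message("stage stats: group comparisons, size strata and regression written")

  manifest <- list(
    package_version = as.character(utils::packageVersion("adcb")),
    seed = config$seed,
    input = if (is.null(config$input)) "generator" else config$input,
    n_lesions = nrow(cohort),
    n_patients = attr(cohort, "n_patients"),
    scheme = list(t_b2 = scheme$t_b2, t_b3 = scheme$t_b3,
                  t_b45 = scheme$t_b45, provenance = scheme$provenance),
    targets = list(b2_rate = config$b2_rate, b3_rate = config$b3_rate,
                   ppv_target = config$ppv_target,
                   decimals = config$decimals)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, curve = curve, derivation = derivation,
                 scheme = scheme, summary = summary,
                 group_comparisons = gh, size_tests = st,
                 regression = list(with_diagnosis = reg_full,
                                   without_diagnosis = reg_null),
                 manifest = manifest, out_dir = config$out_dir))
}
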