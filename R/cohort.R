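# Lesion cohort data model and delimited-text I/O.
#
# One row = one lesion ("per-lesion basis"); patients may contribute several
# lesions, so patient counts are summaries, never an aggregation level.
# ADC is stored throughout in units of 1e-3 mm^2/s (i.e. 1.45, not 0.00145),
# matching how breast ADC values are reported clinically. A missing ADC is a
# first-class state: such lesions belong in category ADC-B0 and are encoded
# as empty fields on disk, never as zero.

.cohort_columns <- c("lesion_id", "patient_id", "center_id", "field_strength",
                     "vendor", "adc", "size_mm", "mass", "subtype", "outcome",
                     "high_risk")

#' Assemble a lesion cohort
#'
#' Builds an `adcb_cohort` from per-lesion vectors, deriving the
#' `invasiveness` column from the subtype vocabulary and attaching lesion and
#' patient counts. This is the constructor used by [read_cohort()],
#' [generate_cohort()] and [reference_cohort()]; most users will not call it
#' directly.
#'
#' @param lesions A data.frame with columns `lesion_id`, `patient_id`,
#'   `center_id`, `field_strength`, `vendor`, `adc`, `size_mm`, `mass`,
#'   `subtype`, `outcome`, `high_risk`.
#' @param source_label Free-text provenance tag stored as an attribute.
#' @return An `adcb_cohort` (a data.frame subclass) with an additional
#'   derived `invasiveness` column and attributes `source_label`,
#'   `n_lesions`, `n_patients`.
#' @export
as_cohort <- function(lesions, source_label = "unspecified") {
  stopifnot(is.data.frame(lesions))
  missing_cols <- setdiff(.cohort_columns, names(lesions))
  if (length(missing_cols) > 0L) {
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lesions <- as.data.frame(lesions)[, .cohort_columns]
  unknown <- setdiff(unique(lesions$subtype), .subtype_table$label)
  if (length(unknown) > 0L) {
    stop("unknown subtype label(s): ", paste(unknown, collapse = ", "),
         "; allowed labels: ", paste(.subtype_table$label, collapse = ", "),
         call. = FALSE)
  }
  if (!all(lesions$outcome %in% c("benign", "malignant"))) {
    stop("outcome must be 'benign' or 'malignant'", call. = FALSE)
  }
  lesions$lesion_id <- as.character(lesions$lesion_id)
  lesions$patient_id <- as.character(lesions$patient_id)
  lesions$center_id <- as.character(lesions$center_id)
  lesions$vendor <- as.character(lesions$vendor)
  lesions$field_strength <- as.numeric(lesions$field_strength)
  lesions$adc <- as.numeric(lesions$adc)
  lesions$size_mm <- as.numeric(lesions$size_mm)
  lesions$mass <- as.logical(lesions$mass)
  lesions$high_risk <- as.logical(lesions$high_risk)
  lesions$invasiveness <- subtype_invasiveness(lesions$subtype)
  rownames(lesions) <- NULL
  structure(lesions,
            class = c("adcb_cohort", "data.frame"),
            source_label = source_label,
            n_lesions = nrow(lesions),
            n_patients = length(unique(lesions$patient_id)))
}

#' @export
print.adcb_cohort <- function(x, ...) {
  cat(sprintf("ADC-B lesion cohort: %d lesions, %d patients (%s)\n",
              attr(x, "n_lesions"), attr(x, "n_patients"),
              attr(x, "source_label")))
  n_mal <- sum(x$outcome == "malignant")
  n_na <- sum(is.na(x$adc))
  cat(sprintf("  malignant %d (%.1f%%), benign %d; ADC missing: %d\n",
              n_mal, 100 * n_mal / max(nrow(x), 1L),
              nrow(x) - n_mal, n_na))
  invisible(x)
}

#' Read a lesion table
#'
#' Reads a delimited lesion table (comma by default, tab accepted) with a
#' mandatory header into an `adcb_cohort`. Required columns: `lesion_id`,
#' `patient_id`, `center_id`, `field_strength`, `vendor`, `adc`, `size_mm`,
#' `mass`, `subtype`, `outcome`, `high_risk`. Empty `adc` fields are read as
#' missing (category ADC-B0 material), never coerced to zero. Subtype labels
#' outside [adcb_subtypes()] raise an error listing the allowed vocabulary.
#'
#' @param path Path to the delimited file (UTF-8).
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return An [as_cohort()] object.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, name) {
    out <- suppressWarnings(as.numeric(ifelse(col == "", NA, col)))
    bad <- which(!is.na(col) & col != "" & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable %s value '%s' at data row %d",
                   name, col[bad[1L]], bad[1L]), call. = FALSE)
    }
    out
  }
  raw$adc <- parse_num(raw$adc, "adc")
  raw$size_mm <- parse_num(raw$size_mm, "size_mm")
  raw$field_strength <- parse_num(raw$field_strength, "field_strength")
  raw$mass <- ifelse(raw$mass == "", NA, raw$mass) == "TRUE"
  raw$high_risk <- raw$high_risk == "TRUE"
  as_cohort(raw, source_label = path)
}

#' Write a lesion table
#'
#' Writes an `adcb_cohort` back to delimited text. Numeric fields are
#' serialized with full double precision (`%.17g`) so that a
#' read-write-read round trip reproduces the cohort exactly; missing values
#' become empty fields.
#'
#' @param cohort An `adcb_cohort`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "adcb_cohort"))
  out <- as.data.frame(cohort)[, .cohort_columns]
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out$adc <- fmt(out$adc)
  out$size_mm <- fmt(out$size_mm)
  out$field_strength <- fmt(out$field_strength)
  out$mass <- ifelse(is.na(out$mass), "", ifelse(out$mass, "TRUE", "FALSE"))
  out$high_risk <- ifelse(out$high_risk, "TRUE", "FALSE")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a lesion cohort
#'
#' Scans a cohort for violations of the record-level invariants and returns
#' them as a report rather than raising errors. Checked rules:
#' * `adc_range` — ADC, when present, must lie in \[0, 5\] (1e-3 mm^2/s);
#' * `size_positive` — lesion size must be a positive number of millimetres;
#' * `high_risk_benign` — a high-risk lesion is by definition benign at
#'   final histology, so `high_risk = TRUE` with a malignant outcome is a
#'   contradiction;
#' * `duplicate_lesion_id` — lesion ids must be unique within a cohort;
#' * `outcome_subtype` — the recorded outcome must match the outcome implied
#'   by the subtype vocabulary.
#'
#' @param cohort An `adcb_cohort`.
#' @return A data.frame with columns `lesion_id`, `row`, `rule`, `message`;
#'   zero rows if and only if the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "adcb_cohort"))
  viol <- function(idx, rule, message) {
    if (length(idx) == 0L) return(NULL)
    data.frame(lesion_id = cohort$lesion_id[idx], row = idx, rule = rule,
               message = message, stringsAsFactors = FALSE)
  }
  vocab <- .subtype_table
  implied <- vocab$outcome[match(cohort$subtype, vocab$label)]
  reports <- list(
    viol(which(!is.na(cohort$adc) & (cohort$adc < 0 | cohort$adc > 5)),
         "adc_range", "ADC outside [0, 5] x 1e-3 mm^2/s"),
    viol(which(!is.na(cohort$size_mm) & cohort$size_mm <= 0),
         "size_positive", "lesion size must be > 0 mm"),
    viol(which(cohort$high_risk & cohort$outcome == "malignant"),
         "high_risk_benign", "high-risk lesions are benign by definition"),
    viol(which(duplicated(cohort$lesion_id) |
                 duplicated(cohort$lesion_id, fromLast = TRUE)),
         "duplicate_lesion_id", "lesion_id not unique within cohort"),
    viol(which(!is.na(implied) & implied != cohort$outcome),
         "outcome_subtype", "outcome contradicts subtype vocabulary")
  )
  out <- do.call(rbind, reports)
  if (is.null(out)) {
    out <- data.frame(lesion_id = character(), row = integer(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$row, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}
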