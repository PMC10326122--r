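# Controlled histology vocabulary.
#
# Each lesion carries a histologic subtype label from a closed set. Labels
# map to one of six analysis groups (benign, high_risk, invasive, dcis,
# mucinous, other_malignant) which drive outcome, invasiveness and the
# high-risk flag. Generic group-level labels are part of the vocabulary so
# that simulated cohorts, which are parameterized at group level, are valid
# input for every reader and validator.

.subtype_table <- local({
  df <- function(label, group) data.frame(label = label, group = group,
                                          stringsAsFactors = FALSE)
  tab <- rbind(
    # malignant, invasive carcinomas (mucinous kept as its own group: it is
    # invasive but behaves differently on ADC and is excluded from the
    # invasive-vs-DCIS ROC by default)
    df("invasive_nst",                "invasive"),
    df("invasive_lobular",            "invasive"),
    df("invasive_mixed_ductal_lobular", "invasive"),
    df("papillary_carcinoma",         "invasive"),
    df("medullary_carcinoma",         "invasive"),
    df("cribriform_carcinoma",        "invasive"),
    df("mucinous_carcinoma",          "mucinous"),
    df("dcis",                        "dcis"),
    df("other_malignancy",            "other_malignant"),
    # benign lesions of uncertain malignant potential ("high risk"); by
    # definition not malignant at final histology
    df("atypical_ductal_hyperplasia", "high_risk"),
    df("lobular_carcinoma_in_situ",   "high_risk"),
    df("columnar_cell_hyperplasia",   "high_risk"),
    df("radial_scar",                 "high_risk"),
    df("flat_epithelial_atypia",      "high_risk"),
    df("papilloma",                   "high_risk"),
    df("phyllodes_tumor",             "high_risk"),
    # benign
    df("fibrocystic_changes",         "benign"),
    df("adenosis",                    "benign"),
    df("epithelial_proliferation",    "benign"),
    df("fibroadenomatoid_hyperplasia","benign"),
    df("fibroadenoma",                "benign"),
    df("fat_necrosis",                "benign"),
    df("apocrine_metaplasia",         "benign"),
    df("inflammation",                "benign"),
    df("pash",                        "benign"),
    df("other_benign",                "benign"),
    # generic group-level labels (used by the synthetic generator)
    df("benign",                      "benign"),
    df("high_risk",                   "high_risk"),
    df("invasive",                    "invasive"),
    df("mucinous",                    "mucinous"),
    df("other_malignant",             "other_malignant")
  )
  tab$outcome <- ifelse(tab$group %in% c("benign", "high_risk"),
                        "benign", "malignant")
  tab$high_risk <- tab$group == "high_risk"
  tab$invasiveness <- c(benign = "not_applicable",
                        high_risk = "not_applicable",
                        invasive = "invasive",
                        mucinous = "invasive",
                        dcis = "in_situ",
                        other_malignant = "not_applicable")[tab$group]
  rownames(tab) <- NULL
  tab
})

#' Histologic subtype vocabulary
#'
#' The closed set of subtype labels accepted in lesion tables, with the
#' analysis group, expected outcome, high-risk flag and invasiveness each
#' label implies. Unknown labels are rejected by [read_cohort()] rather than
#' silently mapped.
#'
#' Invasiveness is `"in_situ"` only for ductal carcinoma in situ (DCIS),
#' `"invasive"` for invasive carcinoma labels (including mucinous carcinoma,
#' which nonetheless forms its own analysis group because of its atypically
#' high ADC), and `"not_applicable"` otherwise (benign lesions and
#' malignancies of non-breast origin).
#'
#' @return A data.frame with columns `label`, `group`, `outcome`,
#'   `high_risk`, `invasiveness`.
#' @export
#' @examples
#' head(adcb_subtypes())
adcb_subtypes <- function() .subtype_table

#' Analysis group of subtype labels
#'
#' Maps subtype labels to their six analysis groups (`benign`, `high_risk`,
#' `invasive`, `dcis`, `mucinous`, `other_malignant`); NA for labels outside
#' the vocabulary.
#'
#' @param subtype Character vector of subtype labels.
#' @return Character vector of group names.
#' @export
subtype_group <- function(subtype) {
  .subtype_table$group[match(subtype, .subtype_table$label)]
}

subtype_invasiveness <- function(subtype) {
  .subtype_table$invasiveness[match(subtype, .subtype_table$label)]
}
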