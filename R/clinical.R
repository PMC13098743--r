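# The bundled clinical table of the pilot transfusion cohort and the
# descriptive statistics computed from it.

#' Clinical table of the pilot transfusion cohort
#'
#' Demographics, pre/post blood-gas values (arterial hemoglobin and
#' hematocrit) and red-cell unit storage age for the 15 recruited subjects
#' of the ICU transfusion pilot cohort. One subject was discarded for poor
#' optical signal quality (`included = FALSE`) and one included subject has
#' no blood-gas data.
#'
#' @param included_only drop the discarded subject (default TRUE).
#' @return a data.frame with one row per subject.
#' @export
clinical_cohort <- function(included_only = TRUE) {
  path <- system.file("extdata", "transfusion_cohort_clinical.csv",
                      package = "rbctdo", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  if (included_only) tab <- tab[tab$included, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Descriptive and pre/post statistics of the clinical cohort
#'
#' Reproduces the cohort's report values: mean (SD) of age and red-cell
#' storage age over the included subjects, mean (SD) of hemoglobin and
#' hematocrit before and after transfusion over the subjects with blood-gas
#' data, the paired Wilcoxon signed-rank tests of the pre/post change, and
#' the median-based effect sizes (difference of the post- and pre-
#' transfusion medians, the convention used for reporting changes).
#'
#' @param cohort the [clinical_cohort()] table.
#' @return a list with `age`, `storage`, `hgb`, `hct` components.
#' @export
clinical_cohort_stats <- function(cohort = clinical_cohort()) {
  blood <- cohort[is.finite(cohort$hgb_pre), ]
  one <- function(pre, post, variable) {
    list(pre = cohort_summary(pre), post = cohort_summary(post),
         test = paired_prepost_test(pre, post, variable = variable),
         test_one_sided = paired_prepost_test(pre, post,
                                              alternative = "greater",
                                              variable = variable),
         median_change = stats::median(post) - stats::median(pre))
  }
  list(age = cohort_summary(cohort$age),
       storage = cohort_summary(cohort$rbc_storage_days),
       n_included = nrow(cohort), n_blood = nrow(blood),
       hgb = one(blood$hgb_pre, blood$hgb_post, "hgb"),
       hct = one(blood$hct_pre, blood$hct_post, "hct"))
}
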