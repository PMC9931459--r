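#' Read a cohort CSV
#'
#' Reads a patient-level cohort table. Expected columns: `patient_id`,
#' `diagnosis` (IPF / CVD_IP / iNSIP / CHP / UC_ILD), `sex`
#' (female / male), `age`, `fvc_pct`, `dlco_pct` (empty cell = cannot
#' perform, stored as NA), `followup_days`, `ae_day`, `death_day`,
#' `death_cause`, and either a precomputed `ccis` column or the 19
#' comorbidity flag columns of [charlsonWeights()] (values 0/1). When both
#' flags and `ccis` are present the flags win and any mismatch triggers a
#' warning.
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame with a `ccis` column.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("dlco_pct", "ae_day", "death_day")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is.character(v)) {
        v[v %in% c("", "NA", "cannot_perform", "none")] <- NA
        v <- as.numeric(v)
      }
      df[[col]] <- as.numeric(v)
    }
  }
  flag_cols <- names(charlsonWeights())
  has_flags <- all(flag_cols %in% names(df))
  if (has_flags) {
    flag_ccis <- charlsonScore(df[, flag_cols, drop = FALSE])
    if ("ccis" %in% names(df) && any(df$ccis != flag_ccis)) {
      warning("`ccis` column disagrees with the comorbidity flags for ",
              sum(df$ccis != flag_ccis),
              " patient(s); using the flag-derived score")
    }
    df$ccis <- flag_ccis
  } else if (!"ccis" %in% names(df)) {
    stop_validation("cohort must carry a `ccis` column or all 19 ",
                    "comorbidity flag columns")
  }
  validate_cohort_fields(df)
  df
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
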