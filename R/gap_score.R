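#' @name ildSubtypes
#' @title ILD diagnosis categories
#' @description The five ILD subtypes handled by the scoring models:
#'   idiopathic pulmonary fibrosis (`IPF`), unclassifiable ILD (`UC_ILD`),
#'   collagen-vascular-disease-related interstitial pneumonia (`CVD_IP`),
#'   idiopathic nonspecific interstitial pneumonia (`iNSIP`) and chronic
#'   hypersensitivity pneumonitis (`CHP`). IPF and UC-ILD score 0 diagnosis
#'   points; the other three score -2.
#' @return Character vector of the five subtype codes.
#' @export
ildSubtypes <- function() {
  c("IPF", "CVD_IP", "iNSIP", "CHP", "UC_ILD")
}

validate_cohort_fields <- function(cohort,
                                   fields = c("diagnosis", "sex", "age",
                                              "fvc_pct", "dlco_pct", "ccis")) {
  if (!is.data.frame(cohort)) {
    stop_validation("cohort must be a data.frame")
  }
  missing_cols <- setdiff(fields, names(cohort))
  if (length(missing_cols)) {
    stop_validation("cohort is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  if ("diagnosis" %in% fields) {
    dx <- as.character(cohort$diagnosis)
    bad <- setdiff(unique(dx), ildSubtypes())
    if (length(bad)) {
      stop_validation("unknown diagnosis value(s): ",
                      paste(bad, collapse = ", "),
                      " (expected ", paste(ildSubtypes(), collapse = "/"), ")")
    }
  }
  if ("sex" %in% fields) {
    sx <- as.character(cohort$sex)
    bad <- setdiff(unique(sx), c("female", "male"))
    if (length(bad)) {
      stop_validation("`sex` must be 'female' or 'male'; got: ",
                      paste(bad, collapse = ", "))
    }
  }
  if ("age" %in% fields && (anyNA(cohort$age) || any(cohort$age < 0))) {
    stop_validation("`age` must be non-negative and non-missing")
  }
  if ("fvc_pct" %in% fields && (anyNA(cohort$fvc_pct) || any(cohort$fvc_pct <= 0))) {
    stop_validation("`fvc_pct` must be positive and non-missing")
  }
  if ("dlco_pct" %in% fields && any(!is.na(cohort$dlco_pct) & cohort$dlco_pct <= 0)) {
    stop_validation("`dlco_pct` must be positive (NA = cannot perform)")
  }
  if ("ccis" %in% fields && (anyNA(cohort$ccis) || any(cohort$ccis < 0))) {
    stop_validation("`ccis` must be non-negative and non-missing")
  }
  invisible(cohort)
}

#' Per-component ILD-GAP / ILD-GAPC points
#'
#' Assigns the point-table values for each model component and the two
#' totals. Diagnosis: IPF / UC-ILD 0, CVD-IP / iNSIP / CHP -2. Sex: female 0,
#' male 1. Age (years): <=60 0, (60, 65] 1, >65 2. Percent-predicted FVC:
#' >75 0, [50, 75] 1, <50 2. Percent-predicted DLco: >55 0, (35, 55] 1,
#' <=35 2, cannot perform (NA) 3. The CCIS term ([ccisPoints()]) is added
#' only to the ILD-GAPC total. Bands are read on the real line with closed
#' ends as printed (e.g. exactly 75.0 %FVC scores 1, exactly 35.0 %DLco
#' scores 2).
#'
#' @param cohort data.frame with columns `diagnosis`, `sex`, `age`,
#'   `fvc_pct`, `dlco_pct` (NA = cannot perform) and `ccis`.
#' @return data.frame with one row per patient: `diagnosis_pts`, `sex_pts`,
#'   `age_pts`, `fvc_pts`, `dlco_pts`, `ccis_pts`, `ild_gap_total`
#'   (range -2..8) and `ild_gapc_total` (range -2..10).
#' @examples
#' componentPoints(data.frame(diagnosis = "IPF", sex = "male", age = 70,
#'                            fvc_pct = 60, dlco_pct = 40, ccis = 4))
#' @export
componentPoints <- function(cohort) {
  validate_cohort_fields(cohort)
  dx <- as.character(cohort$diagnosis)
  diagnosis_pts <- ifelse(dx %in% c("IPF", "UC_ILD"), 0L, -2L)
  sex_pts <- ifelse(as.character(cohort$sex) == "male", 1L, 0L)
  age_pts <- ifelse(cohort$age <= 60, 0L, ifelse(cohort$age <= 65, 1L, 2L))
  fvc_pts <- ifelse(cohort$fvc_pct > 75, 0L,
                    ifelse(cohort$fvc_pct >= 50, 1L, 2L))
  dlco_pts <- ifelse(is.na(cohort$dlco_pct), 3L,
                     ifelse(cohort$dlco_pct > 55, 0L,
                            ifelse(cohort$dlco_pct > 35, 1L, 2L)))
  ccis_pts <- ccisPoints(cohort$ccis)
  gap <- diagnosis_pts + sex_pts + age_pts + fvc_pts + dlco_pts
  data.frame(
    diagnosis_pts = as.integer(diagnosis_pts),
    sex_pts = as.integer(sex_pts),
    age_pts = as.integer(age_pts),
    fvc_pts = as.integer(fvc_pts),
    dlco_pts = as.integer(dlco_pts),
    ccis_pts = as.integer(ccis_pts),
    ild_gap_total = as.integer(gap),
    ild_gapc_total = as.integer(gap + ccis_pts)
  )
}

#' ILD-GAP stage
#'
#' Four-stage classification of the ILD-GAP total: stage I (<=1 point),
#' II (2-3), III (4-5) and IV (>5).
#'
#' @param total Integer ILD-GAP totals in \[-2, 8\].
#' @return Ordered factor with levels `I < II < III < IV`.
#' @examples
#' gapStage(c(-2, 1, 2, 5, 8))
#' @export
gapStage <- function(total) {
  if (!is.numeric(total) || anyNA(total)) {
    stop_validation("`total` must be numeric and non-missing")
  }
  if (any(total < -2 | total > 8)) {
    stop_validation("ILD-GAP total out of range [-2, 8]")
  }
  lab <- ifelse(total <= 1, "I",
                ifelse(total <= 3, "II", ifelse(total <= 5, "III", "IV")))
  factor(lab, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}

#' Low / moderate / high risk group
#'
#' Three-group classification used for both models: low (<=1 point),
#' moderate (2-3 points), high (>=4 points). The same cutpoints apply to
#' ILD-GAP and ILD-GAPC totals.
#'
#' @param total Integer score totals in \[-2, 10\].
#' @return Ordered factor with levels `low < moderate < high`.
#' @examples
#' riskGroup(c(-2, 2, 4, 10))
#' @export
riskGroup <- function(total) {
  if (!is.numeric(total) || anyNA(total)) {
    stop_validation("`total` must be numeric and non-missing")
  }
  if (any(total < -2 | total > 10)) {
    stop_validation("score total out of range [-2, 10]")
  }
  lab <- ifelse(total <= 1, "low", ifelse(total <= 3, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Score a cohort
#'
#' Appends the point breakdown, both totals, the 4-level ILD-GAP stage and
#' the 3-level risk group under each model to a cohort table.
#'
#' @param cohort data.frame with the columns required by
#'   [componentPoints()].
#' @return The cohort with appended columns `diagnosis_pts` .. `ccis_pts`,
#'   `ild_gap`, `ild_gapc`, `gap_stage`, `gap_group`, `gapc_group`.
#' @export
scoreCohort <- function(cohort) {
  pts <- componentPoints(cohort)
  out <- cbind(cohort, pts)
  out$ild_gap <- pts$ild_gap_total
  out$ild_gapc <- pts$ild_gapc_total
  out$gap_stage <- gapStage(pts$ild_gap_total)
  out$gap_group <- riskGroup(pts$ild_gap_total)
  out$gapc_group <- riskGroup(pts$ild_gapc_total)
  out
}
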