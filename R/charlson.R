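#' Charlson comorbidity conditions and weights
#'
#' The 19 comorbid conditions of the Charlson Comorbidity Index with their
#' original severity weights: ten conditions weighted 1, six weighted 2, one
#' weighted 3 and two weighted 6. Three pairs are mutually exclusive because
#' the severer form supersedes the milder one: uncomplicated diabetes vs.
#' diabetes with end-organ damage, mild vs. moderate/severe liver disease,
#' and any (non-metastatic) tumour vs. metastatic solid tumour.
#'
#' @return Named integer vector of length 19 mapping condition name to weight.
#' @examples
#' charlsonWeights()
#' @export
charlsonWeights <- function() {
  c(
    myocardial_infarction         = 1L,
    congestive_heart_failure      = 1L,
    peripheral_vascular_disease   = 1L,
    cerebrovascular_disease       = 1L,
    dementia                      = 1L,
    chronic_pulmonary_disease     = 1L,
    connective_tissue_disease     = 1L,
    peptic_ulcer                  = 1L,
    mild_liver_disease            = 1L,
    diabetes_uncomplicated        = 1L,
    hemiplegia                    = 2L,
    moderate_severe_renal_disease = 2L,
    diabetes_end_organ_damage     = 2L,
    any_tumor                     = 2L,
    leukemia                      = 2L,
    lymphoma                      = 2L,
    moderate_severe_liver_disease = 3L,
    metastatic_solid_tumor        = 6L,
    aids                          = 6L
  )
}

# severer form supersedes the milder: flagging both is a coding error
charlson_exclusive_pairs <- function() {
  list(
    c("diabetes_uncomplicated", "diabetes_end_organ_damage"),
    c("mild_liver_disease", "moderate_severe_liver_disease"),
    c("any_tumor", "metastatic_solid_tumor")
  )
}

# Coerce a profile (named logical/0-1 vector, list, or data.frame of the 19
# condition columns) to an n x 19 logical matrix in canonical column order.
as_charlson_matrix <- function(profile) {
  nms <- names(charlsonWeights())
  if (is.data.frame(profile)) {
    missing_cols <- setdiff(nms, names(profile))
    if (length(missing_cols)) {
      stop_validation("comorbidity profile is missing condition(s): ",
                      paste(missing_cols, collapse = ", "))
    }
    m <- sapply(nms, function(nm) as.logical(profile[[nm]]))
    m <- matrix(as.logical(m), nrow = nrow(profile),
                dimnames = list(NULL, nms))
  } else {
    profile <- unlist(profile)
    missing_cols <- setdiff(nms, names(profile))
    if (length(missing_cols)) {
      stop_validation("comorbidity profile is missing condition(s): ",
                      paste(missing_cols, collapse = ", "))
    }
    m <- matrix(as.logical(profile[nms]), nrow = 1,
                dimnames = list(NULL, nms))
  }
  if (anyNA(m)) {
    stop_validation("comorbidity flags must be TRUE/FALSE (or 0/1), without NA")
  }
  m
}

#' Charlson Comorbidity Index score (CCIS)
#'
#' Sums the severity weights of the flagged conditions. With the three
#' mutual-exclusion rules the attainable range is 0 to 33. Optionally adds
#' the age adjustment of the extended index (one point per decade from age
#' 50, capped at 4); the unadjusted 19-condition index is the default.
#'
#' @param profile A named logical (or 0/1) vector with the 19 condition
#'   names of [charlsonWeights()], or a data.frame with those columns (one
#'   row per patient).
#' @param age Numeric age(s) in years; required only when
#'   `age_adjust = TRUE`.
#' @param age_adjust Add the age decade points (default `FALSE`).
#' @param exclude_index_disease If `TRUE`, `chronic_pulmonary_disease` is not
#'   counted. In an ILD cohort the index disease is itself a chronic
#'   pulmonary disease, so counting a flagged chronic_pulmonary_disease
#'   double-counts the index condition; whether to flag it is the caller's
#'   decision and it is counted by default.
#' @return Integer vector of scores (one per patient/row).
#' @examples
#' p <- setNames(rep(FALSE, 19), names(charlsonWeights()))
#' p["myocardial_infarction"] <- TRUE
#' p["diabetes_uncomplicated"] <- TRUE
#' charlsonScore(p)  # 2
#' @export
charlsonScore <- function(profile, age = NULL, age_adjust = FALSE,
                          exclude_index_disease = FALSE) {
  m <- as_charlson_matrix(profile)
  for (pair in charlson_exclusive_pairs()) {
    bad <- m[, pair[1]] & m[, pair[2]]
    if (any(bad)) {
      stop_validation(
        "mutually exclusive conditions both flagged: ",
        pair[1], " and ", pair[2],
        " (row ", paste(which(bad), collapse = ", "), ")")
    }
  }
  w <- charlsonWeights()
  if (exclude_index_disease) w["chronic_pulmonary_disease"] <- 0L
  score <- as.integer(m %*% w)
  if (age_adjust) {
    if (is.null(age)) {
      stop_validation("age_adjust = TRUE requires `age`")
    }
    if (length(age) != nrow(m)) {
      stop_validation("`age` must have one value per profile row")
    }
    score <- score + pmin(pmax(floor(age / 10) - 4L, 0L), 4L)
  }
  as.integer(score)
}

#' CCIS point category
#'
#' Collapses the Charlson score into the 3-level point term used by the
#' ILD-GAPC model: CCIS 0-1 contributes 0 points, 2-3 contributes 1 point,
#' and 4 or more contributes 2 points.
#'
#' @param ccis Non-negative integer vector of Charlson scores.
#' @return Integer vector with values in {0, 1, 2}.
#' @examples
#' ccisPoints(c(0, 1, 2, 3, 4, 9))
#' @export
ccisPoints <- function(ccis) {
  if (!is.numeric(ccis) || anyNA(ccis)) {
    stop_validation("`ccis` must be numeric and non-missing")
  }
  if (any(ccis < 0)) {
    stop_validation("`ccis` must be non-negative")
  }
  ifelse(ccis <= 1, 0L, ifelse(ccis <= 3, 1L, 2L))
}
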