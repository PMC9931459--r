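#' Three-year endpoint construction
#'
#' Builds the two right-censored endpoints from raw follow-up fields, at a
#' fixed horizon (default 1095 days = 3 years).
#'
#' ILD-related events: the composite of first acute exacerbation (AE) or
#' respiratory (ILD-related) death within the horizon. Patients who died of
#' a non-respiratory cause within the horizon without a prior AE are not
#' interpretable for this endpoint; by default they are excluded from it
#' (`analysis_eligible = FALSE`), or censored at the death day when
#' `nonresp_death_handling = "censor"`. A non-respiratory death after the
#' horizon is an ordinary administrative censoring at the horizon.
#'
#' All-cause mortality: death from any cause within the horizon; every
#' patient is eligible.
#'
#' @param cohort data.frame with columns `followup_days`, `ae_day`
#'   (NA = none), `death_day` (NA = none) and `death_cause`
#'   (`"respiratory"`, `"non_respiratory"` or `"none"`).
#' @param horizon_days Positive horizon in days (default 1095).
#' @param nonresp_death_handling `"exclude"` (default) or `"censor"`.
#' @return data.frame with columns `ild_time`, `ild_event`, `ild_eligible`,
#'   `ac_time`, `ac_event` (times in days, events 0/1, eligibility logical).
#' @examples
#' outcome3yr(data.frame(followup_days = 400, ae_day = NA, death_day = NA,
#'                       death_cause = "none"))
#' @export
outcome3yr <- function(cohort, horizon_days = 1095,
                       nonresp_death_handling = c("exclude", "censor")) {
  nonresp_death_handling <- match.arg(nonresp_death_handling)
  validate_cohort_fields(cohort, fields = character(0))
  need <- c("followup_days", "ae_day", "death_day", "death_cause")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop_validation("cohort is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  if (!is_scalar_number(horizon_days) || horizon_days <= 0) {
    stop_validation("`horizon_days` must be a positive number")
  }
  fu <- cohort$followup_days
  ae <- cohort$ae_day
  dd <- cohort$death_day
  cause <- as.character(cohort$death_cause)
  if (anyNA(fu) || any(fu < 0)) {
    stop_validation("`followup_days` must be non-negative and non-missing")
  }
  bad_cause <- setdiff(unique(cause), c("respiratory", "non_respiratory", "none"))
  if (length(bad_cause)) {
    stop_validation("unknown death_cause value(s): ",
                    paste(bad_cause, collapse = ", "))
  }
  if (any((is.na(dd)) != (cause == "none"))) {
    stop_validation("`death_cause` must be 'none' exactly when `death_day` is NA")
  }
  if (any(!is.na(ae) & ae > fu) || any(!is.na(dd) & dd > fu)) {
    stop_validation("event days must not exceed `followup_days`")
  }

  resp_dd <- ifelse(cause == "respiratory", dd, NA_real_)
  # first ILD-related event: earlier of first AE and respiratory death
  cand <- pmin(ae, resp_dd, na.rm = TRUE)
  ild_event <- !is.na(cand) & cand <= horizon_days
  ild_time <- ifelse(ild_event, cand, pmin(fu, horizon_days))

  nonresp_no_ae <- cause == "non_respiratory" & is.na(ae) &
    !is.na(dd) & dd <= horizon_days
  ild_eligible <- if (nonresp_death_handling == "exclude") {
    !nonresp_no_ae
  } else {
    rep(TRUE, length(fu))
  }

  ac_event <- !is.na(dd) & dd <= horizon_days
  ac_time <- ifelse(ac_event, dd, pmin(fu, horizon_days))

  data.frame(
    ild_time = as.numeric(ild_time),
    ild_event = as.integer(ild_event),
    ild_eligible = ild_eligible,
    ac_time = as.numeric(ac_time),
    ac_event = as.integer(ac_event)
  )
}
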