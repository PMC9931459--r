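#' Time-dependent ROC AUC at a horizon (cumulative/dynamic, IPCW)
#'
#' AUC for discriminating subjects who experience the event by the horizon
#' (cumulative cases: `time <= horizon` with an event) from subjects still
#' at risk beyond it (dynamic controls: `time > horizon`, or censored
#' exactly at the horizon, as happens when follow-up is administratively
#' truncated there), weighted by the inverse probability of censoring.
#' Censoring survival `G` is estimated by the reverse Kaplan-Meier
#' (censorings as events); a case observed at time `T_i` receives weight
#' `1 / G(T_i-)` and each control `1 / G(horizon-)` (left limits, so that
#' administrative censoring at the horizon itself does not enter the
#' weights).
#' When no censoring occurs before the horizon all weights are 1 and the
#' estimate reduces exactly to the Mann-Whitney AUC of the score against
#' event-by-horizon status. Score ties count 1/2.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score Numeric risk score (higher = higher risk).
#' @param horizon Positive horizon on the time scale of `time`.
#' @param ipcw Use censoring weights (default `TRUE`); `FALSE` gives the
#'   unweighted (naive binary) AUC over the same case/control sets.
#' @return AUC in \[0, 1\].
#' @examples
#' aucTimeDependent(c(1, 2, 10, 12), c(1, 1, 0, 0), c(9, 8, 1, 2), 5)  # 1
#' @export
aucTimeDependent <- function(time, event, score, horizon, ipcw = TRUE) {
  check_survival_sample(time, event)
  if (length(score) != length(time) || anyNA(score)) {
    stop_validation("`score` must be non-missing, one value per subject")
  }
  if (!is_scalar_number(horizon) || horizon <= 0) {
    stop_validation("`horizon` must be a positive number")
  }
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon | (time == horizon & event == 0))
  if (length(cases) == 0L) {
    stop_validation("no events before the horizon: AUC is undefined")
  }
  if (length(controls) == 0L) {
    stop_validation("no subjects at risk past the horizon: AUC is undefined")
  }
  if (ipcw) {
    gkm <- kmEstimate(time, 1 - event)
    w_case <- 1 / kmSurvAt(gkm, time[cases], left = TRUE)
    w_ctrl <- rep(1 / kmSurvAt(gkm, horizon, left = TRUE), length(controls))
  } else {
    w_case <- rep(1, length(cases))
    w_ctrl <- rep(1, length(controls))
  }
  s_case <- score[cases]
  s_ctrl <- score[controls]
  num <- 0
  for (i in seq_along(cases)) {
    gt <- s_case[i] > s_ctrl
    eq <- s_case[i] == s_ctrl
    num <- num + w_case[i] * (sum(w_ctrl[gt]) + 0.5 * sum(w_ctrl[eq]))
  }
  num / (sum(w_case) * sum(w_ctrl))
}
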