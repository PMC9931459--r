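#' Harrell's concordance index
#'
#' Fraction of usable pairs ordered concordantly by the risk score. A pair
#' (i, j) is usable when the shorter follow-up time ends in an event
#' (`time_i < time_j` and `event_i = 1`); it is concordant when the subject
#' failing first has the higher score, and score ties count 1/2. Pairs with
#' exactly tied follow-up times are not used. Orientation is that of a risk
#' score: higher score predicts earlier failure.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score Numeric risk score.
#' @return Concordance index in \[0, 1\].
#' @examples
#' harrellC(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 2, 1))  # 1
#' @export
harrellC <- function(time, event, score) {
  check_survival_sample(time, event)
  if (length(score) != length(time) || anyNA(score)) {
    stop_validation("`score` must be non-missing, one value per subject")
  }
  idx <- which(event == 1)
  num <- 0
  den <- 0
  for (i in idx) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0L) next
    den <- den + m
    num <- num + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  if (den == 0) {
    stop_validation("no usable pairs: concordance is undefined")
  }
  num / den
}
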