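check_survival_sample <- function(time, event) {
  if (length(time) < 1L) stop_validation("survival sample is empty")
  if (length(event) != length(time)) {
    stop_validation("`time` and `event` must have the same length")
  }
  if (anyNA(time) || any(time <= 0)) {
    stop_validation("`time` must be positive and non-missing")
  }
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    stop_validation("`event` must be 0/1 and non-missing")
  }
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with the
#' Greenwood variance `S(t)^2 * sum d_i / (n_i (n_i - d_i))`. Subjects
#' censored at an event time are still counted at risk at that time (the
#' usual "events before censorings" tie convention).
#'
#' @param time Positive follow-up times (days).
#' @param event 0/1 event indicators.
#' @return Object of class `km_curve`: a list with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `surv`, `var` (Greenwood
#'   variance of S, set to 0 where S = 0 since the estimate is degenerate
#'   there), and `n` (sample size).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(time, event) {
  check_survival_sample(time, event)
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), var = numeric(0), n = n)
    class(out) <- "km_curve"
    return(out)
  }
  st <- sort(time)
  # at risk just before t: subjects with time >= t
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  d <- tabulate(match(time[event == 1], ut), nbins = length(ut))
  surv <- cumprod(1 - d / n_risk)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0)
  v <- surv^2 * cumsum(gw_terms)
  v[surv == 0] <- 0
  out <- list(time = ut, n_risk = as.integer(n_risk), n_event = as.integer(d),
              surv = surv, var = v, n = n)
  class(out) <- "km_curve"
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation of `S(t)`; `S = 1` before the first
#' event time. With `left = TRUE` returns the left limit `S(t-)` (the value
#' just before `t`), used for inverse-probability-of-censoring weights.
#'
#' @param curve A `km_curve` from [kmEstimate()].
#' @param t Times at which to evaluate.
#' @param left Return the left limit instead of `S(t)`.
#' @return Numeric survival probabilities.
#' @export
kmSurvAt <- function(curve, t, left = FALSE) {
  if (!inherits(curve, "km_curve")) stop_validation("`curve` must be a km_curve")
  idx <- findInterval(t, curve$time, left.open = left)
  c(1, curve$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s)\n",
              x$n, length(x$time)))
  if (length(x$time)) {
    df <- data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     surv = round(x$surv, 4),
                     std_err = round(sqrt(x$var), 4))
    print(utils::head(df, 10), row.names = FALSE)
    if (length(x$time) > 10) cat("  ...\n")
  }
  invisible(x)
}

# step-function table used when serialising curves
km_step_table <- function(curve) {
  data.frame(time = c(0, curve$time),
             surv = c(1, curve$surv),
             n_risk = c(curve$n, curve$n_risk),
             n_event = c(0L, curve$n_event))
}
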