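#' k-sample log-rank test
#'
#' Standard log-rank test across k groups: at every distinct event time the
#' observed events per group are compared with the expectation under the
#' null of a common hazard, with the multivariate hypergeometric
#' variance-covariance. The statistic is the quadratic form of the
#' observed-minus-expected vector (first k-1 groups) in the inverse of its
#' covariance; the p-value is from a chi-square with k-1 degrees of freedom.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Group labels (factor, character or integer); every group
#'   must contain at least one subject, and k >= 2.
#' @return Object of class `logrank_test`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, `n` (per-group sizes).
#' @examples
#' logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 0), c("a", "a", "b", "b"))
#' @export
logrankTest <- function(time, event, group) {
  check_survival_sample(time, event)
  group <- as.factor(group)
  if (length(group) != length(time)) {
    stop_validation("`group` must have the same length as `time`")
  }
  counts <- table(group)
  if (any(counts == 0)) {
    stop_validation("group(s) with zero subjects: ",
                    paste(names(counts)[counts == 0], collapse = ", "))
  }
  k <- nlevels(group)
  if (k < 2) stop_validation("log-rank test needs at least 2 groups")

  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) stop_validation("no events in the sample")
  J <- length(ut)
  st <- sort(time)
  n_all <- length(time) - findInterval(ut, st, left.open = TRUE)
  d_all <- tabulate(match(time[event == 1], ut), nbins = J)

  n_g <- matrix(0, J, k)
  d_g <- matrix(0, J, k)
  for (i in seq_len(k)) {
    sel <- group == levels(group)[i]
    tg <- sort(time[sel])
    n_g[, i] <- length(tg) - findInterval(ut, tg, left.open = TRUE)
    ev <- time[sel & event == 1]
    d_g[, i] <- tabulate(match(ev, ut), nbins = J)
  }

  E <- n_g * (d_all / n_all)
  O <- colSums(d_g)
  Evec <- colSums(E)
  OME <- O - Evec

  # hypergeometric variance multiplier per event time
  mult <- ifelse(n_all > 1,
                 d_all * (n_all - d_all) / ((n_all - 1) * n_all^2), 0)
  V <- matrix(0, k, k)
  for (i in seq_len(k)) {
    V[i, i] <- sum(mult * n_g[, i] * (n_all - n_g[, i]))
    if (i < k) {
      for (l in seq(i + 1L, k)) {
        V[i, l] <- V[l, i] <- -sum(mult * n_g[, i] * n_g[, l])
      }
    }
  }

  x <- OME[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(
    drop(t(x) %*% solve(Vsub, x)),
    error = function(e) drop(t(x) %*% pinv(Vsub) %*% x)
  )
  stat <- max(stat, 0)
  df <- k - 1L
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              observed = stats::setNames(O, levels(group)),
              expected = stats::setNames(Evec, levels(group)),
              n = stats::setNames(as.integer(counts), levels(group)))
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)))
  invisible(x)
}
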