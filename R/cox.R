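# Partial-likelihood cumulants for one beta: log partial likelihood,
# score vector U and information matrix I, with Efron or Breslow handling
# of tied event times. Rows must be pre-sorted by decreasing time so that
# risk-set sums are cumulative sums.
cox_cumulants <- function(t_d, e_d, X, beta, ties) {
  n <- length(t_d)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)  # guard overflow; lpl shift cancels in U, I
  w <- exp(eta)
  S0 <- cumsum(w)
  wX <- X * w
  S1 <- apply(wX, 2, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)

  # S2 cumulants stored for the upper triangle
  ut_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  S2 <- matrix(0, n, nrow(ut_idx))
  for (m in seq_len(nrow(ut_idx))) {
    S2[, m] <- cumsum(w * X[, ut_idx[m, 1]] * X[, ut_idx[m, 2]])
  }
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(ut_idx[, 1], ut_idx[, 2])] <- v
    M[cbind(ut_idx[, 2], ut_idx[, 1])] <- v
    M
  }

  # blocks of tied times (descending order): last row of each block carries
  # the full risk-set cumulant for that time
  r <- rle(t_d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  lpl <- 0
  U <- numeric(p)
  Info <- matrix(0, p, p)
  # shift of eta adds n_event * max back; constant w.r.t. beta per iteration
  for (b in seq_along(ends)) {
    rows <- starts[b]:ends[b]
    ev <- rows[e_d[rows] == 1]
    d <- length(ev)
    if (d == 0L) next
    i2 <- ends[b]
    S0R <- S0[i2]
    S1R <- S1[i2, ]
    S2R <- unpack(S2[i2, ])
    lpl <- lpl + sum(eta[ev])
    U <- U + colSums(X[ev, , drop = FALSE])
    if (ties == "efron" && d > 1L) {
      S0D <- sum(w[ev])
      S1D <- colSums(wX[ev, , drop = FALSE])
      S2D <- matrix(0, p, p)
      for (m in seq_len(nrow(ut_idx))) {
        val <- sum(w[ev] * X[ev, ut_idx[m, 1]] * X[ev, ut_idx[m, 2]])
        S2D[ut_idx[m, 1], ut_idx[m, 2]] <- val
        S2D[ut_idx[m, 2], ut_idx[m, 1]] <- val
      }
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0 <- S0R - f * S0D
        s1 <- S1R - f * S1D
        s2 <- S2R - f * S2D
        lpl <- lpl - log(s0)
        U <- U - s1 / s0
        Info <- Info + s2 / s0 - tcrossprod(s1 / s0)
      }
    } else {
      lpl <- lpl - d * log(S0R)
      U <- U - d * S1R / S0R
      Info <- Info + d * (S2R / S0R - tcrossprod(S1R / S0R))
    }
  }
  list(lpl = lpl, U = U, I = Info)
}

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximises the Cox partial likelihood for an arbitrary design matrix with
#' Efron (default) or Breslow handling of tied event times, with
#' step-halving. Used by [coxUnivariate()] and [coxAIC()].
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param x Covariate vector or matrix (one column per coefficient).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return List of class `cox_fit` with `coef`, `se`, `var`, `loglik`
#'   (length 2: at beta = 0 and at the maximum), `score_test` (score
#'   chi-square at beta = 0 with df and p), `iter`, `n`, `n_event`, `ties`.
#' @export
coxFit <- function(time, event, x, ties = c("efron", "breslow"),
                   max_iter = 30L, tol = 1e-9) {
  ties <- match.arg(ties)
  check_survival_sample(time, event)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (nrow(X) != length(time)) {
    stop_validation("covariates must have one row per subject")
  }
  if (sum(event) < 1) stop_validation("no events in the sample")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_validation("covariate is constant; the Cox model is not identified")
  }
  # centre/scale for numerical stability; transform back at the end
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")

  ord <- order(time, decreasing = TRUE)
  t_d <- time[ord]
  e_d <- event[ord]
  Xd <- Xs[ord, , drop = FALSE]
  p <- ncol(Xd)

  beta <- numeric(p)
  cum <- cox_cumulants(t_d, e_d, Xd, beta, ties)
  loglik0 <- cum$lpl
  score_stat <- tryCatch(
    drop(t(cum$U) %*% solve(cum$I, cum$U)),
    error = function(e) NA_real_
  )
  monotone <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(cum$I, cum$U), error = function(e) NULL)
    if (is.null(step)) {
      monotone <- TRUE
      break
    }
    new_beta <- beta + step
    new_cum <- cox_cumulants(t_d, e_d, Xd, new_beta, ties)
    halved <- 0L
    while (new_cum$lpl < cum$lpl && halved < 12L) {
      halved <- halved + 1L
      new_beta <- beta + step / 2^halved
      new_cum <- cox_cumulants(t_d, e_d, Xd, new_beta, ties)
    }
    done <- max(abs(new_beta - beta)) < tol ||
      abs(new_cum$lpl - cum$lpl) < tol
    beta <- new_beta
    cum <- new_cum
    if (any(abs(beta) > 18)) {  # on the scaled covariates: |HR| beyond e^18/sd
      monotone <- TRUE
      break
    }
    if (done || iter >= max_iter) break
  }
  if (monotone) {
    warning("possible monotone partial likelihood (perfect separation); ",
            "estimate bounded at the last stable iterate")
  }
  vcv_s <- tryCatch(solve(cum$I), error = function(e) pinv(cum$I))
  # back-transform to the original covariate scale
  coef <- beta / sds
  vcv <- vcv_s / tcrossprod(sds)
  out <- list(
    coef = stats::setNames(coef, colnames(X)),
    se = sqrt(pmax(diag(vcv), 0)),
    var = vcv,
    loglik = c(loglik0, cum$lpl),
    score_test = list(statistic = score_stat, df = p,
                      p_value = stats::pchisq(score_stat, p,
                                              lower.tail = FALSE)),
    iter = iter, n = length(time), n_event = sum(event),
    ties = ties, monotone = monotone
  )
  class(out) <- "cox_fit"
  out
}

#' Univariate Cox regression on a risk score
#'
#' Fits the single-covariate Cox model and reports the hazard ratio per
#' score point with its Wald 95% confidence interval and p-value.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score Numeric risk score (must vary).
#' @param ties Tie handling, see [coxFit()].
#' @return List of class `cox_univariate`: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `log_partial_likelihood` (at the maximum),
#'   `loglik0`, `score_test`, `n`, `n_event`.
#' @examples
#' fit <- coxUnivariate(c(2, 4, 6, 8, 10), c(1, 1, 1, 0, 0),
#'                      c(5, 4, 3, 2, 1))
#' fit$hr
#' @export
coxUnivariate <- function(time, event, score, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (anyNA(score)) stop_validation("`score` must be non-missing")
  fit <- coxFit(time, event, matrix(as.numeric(score), ncol = 1), ties = ties)
  beta <- unname(fit$coef[1])
  se <- fit$se[1]
  z <- beta / se
  out <- list(
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    z = z, p_value = 2 * stats::pnorm(-abs(z)),
    log_partial_likelihood = fit$loglik[2],
    loglik0 = fit$loglik[1],
    score_test = fit$score_test,
    n = fit$n, n_event = fit$n_event, ties = fit$ties,
    monotone = fit$monotone
  )
  class(out) <- "cox_univariate"
  out
}

#' @export
print.cox_univariate <- function(x, ...) {
  cat(sprintf(
    "Univariate Cox fit (%s ties): n = %d, events = %d\n  HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
    x$ties, x$n, x$n_event, x$hr, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' AIC of a Cox risk-score model
#'
#' `AIC = -2 * maximised log partial likelihood + 2 * k`, with k = 1 for the
#' linear-score model or k = (number of score levels - 1) when the score is
#' entered as a categorical covariate.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score Numeric risk score.
#' @param score_as `"linear"` (default) or `"categorical"`.
#' @param ties Tie handling, see [coxFit()].
#' @return AIC (numeric scalar).
#' @export
coxAIC <- function(time, event, score, score_as = c("linear", "categorical"),
                   ties = c("efron", "breslow")) {
  score_as <- match.arg(score_as)
  ties <- match.arg(ties)
  if (score_as == "linear") {
    fit <- coxFit(time, event, matrix(as.numeric(score), ncol = 1), ties = ties)
  } else {
    f <- factor(score)
    if (nlevels(f) < 2) stop_validation("categorical score needs >= 2 levels")
    X <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    fit <- coxFit(time, event, X, ties = ties)
  }
  -2 * fit$loglik[2] + 2 * length(fit$coef)
}
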