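test_that("KM matches hand-computed product-limit values on small fixtures", {
  # all events at distinct times
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  # all censored
  km <- kmEstimate(c(5, 7, 9), c(0, 0, 0))
  expect_identical(length(km$time), 0L)
  expect_equal(kmSurvAt(km, c(1, 100)), c(1, 1))
  # censoring shrinks the risk set: S(2) = 0 with risk set of 1
  km <- kmEstimate(c(1, 2), c(0, 1))
  expect_equal(km$surv, 0)
  expect_equal(km$n_risk, 1L)
  # mixed fixture, hand product: events at 2 (n=5), 4 (n=3), censor at 3, 6
  km <- kmEstimate(c(2, 3, 4, 5, 6), c(1, 0, 1, 1, 0))
  expect_equal(km$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
  # Greenwood variance, hand sum at first event time
  expect_equal(km$var[1], (4 / 5)^2 * (1 / (5 * 4)))
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(11)
  t <- rexp(40)
  km <- kmEstimate(t, rep(1, 40))
  ecdf_surv <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, ecdf_surv)
})

test_that("KM survival is a non-increasing step function in [0, 1]", {
  set.seed(12)
  for (i in 1:10) {
    t <- round(rexp(30, 0.1) + 0.5)  # force ties
    e <- rbinom(30, 1, 0.6)
    km <- kmEstimate(t, e)
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(c(1, km$surv)) <= 1e-12))
    expect_true(all(km$var >= 0))
  }
})

test_that("log-rank is zero on identical groups and matches survdiff", {
  t <- c(1, 2, 3, 4, 5)
  e <- c(1, 0, 1, 1, 0)
  lr <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  skip_if_not_installed("survival")
  set.seed(21)
  for (k in 2:4) {
    n <- 40 * k
    time <- round(rexp(n, 0.1) + 0.5)
    event <- rbinom(n, 1, 0.7)
    group <- sample(letters[1:k], n, replace = TRUE)
    lr <- logrankTest(time, event, group)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
    expect_identical(lr$df, k - 1L)
  }
})

test_that("log-rank is invariant to group relabeling and monotone time transforms", {
  set.seed(22)
  time <- rexp(60)
  event <- rbinom(60, 1, 0.7)
  group <- sample(c("x", "y", "z"), 60, replace = TRUE)
  s1 <- logrankTest(time, event, group)$statistic
  relab <- c(x = "B", y = "C", z = "A")
  s2 <- logrankTest(time, event, relab[group])$statistic
  s3 <- logrankTest(exp(time), event, group)$statistic
  expect_equal(s2, s1)
  expect_equal(s3, s1)
  expect_error(logrankTest(time, event, factor(group, levels = c("x", "y", "z", "w"))),
               "zero subjects")
})

test_that("Cox fit matches closed-form for 2 subjects and coxph generally", {
  # two subjects, earlier one an event: lpl(beta) = eta1 - log(e^eta1 + e^eta2)
  fit <- coxUnivariate(c(1, 2), c(1, 0), c(1, 0))
  # maximum is at beta -> Inf (separation); expect bounded warning path not hit
  # at tol because likelihood is monotone -- use a non-separating fixture
  fit <- coxUnivariate(c(1, 2, 3, 4), c(1, 1, 1, 0), c(0, 1, 0, 1))
  expect_true(is.finite(fit$beta))

  skip_if_not_installed("survival")
  set.seed(31)
  n <- 150
  x <- rnorm(n)
  time <- rexp(n, exp(0.5 * x) / 10)
  event <- rbinom(n, 1, 0.8)
  for (ties in c("efron", "breslow")) {
    fit <- coxUnivariate(time, event, x, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])),
                 tolerance = 1e-6)
    expect_equal(fit$log_partial_likelihood, ref$loglik[2], tolerance = 1e-7)
    expect_equal(fit$loglik0, ref$loglik[1], tolerance = 1e-9)
  }
  # tied event times exercise the Efron correction
  time_t <- round(time * 2) / 2 + 0.5
  fit <- coxUnivariate(time_t, event, x)
  ref <- survival::coxph(survival::Surv(time_t, event) ~ x, ties = "efron")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$log_partial_likelihood, ref$loglik[2], tolerance = 1e-7)
})

test_that("Cox reparameterization: doubling the score halves beta, same lpl", {
  set.seed(32)
  x <- rnorm(80)
  time <- rexp(80, exp(0.4 * x) / 5)
  event <- rbinom(80, 1, 0.7)
  f1 <- coxUnivariate(time, event, x)
  f2 <- coxUnivariate(time, event, 2 * x)
  expect_equal(f2$beta, f1$beta / 2, tolerance = 1e-7)
  expect_equal(f2$log_partial_likelihood, f1$log_partial_likelihood,
               tolerance = 1e-9)
})

test_that("Cox null behaviour: independent score gives |beta| near 0", {
  cfg <- simConfig(n_patients = 5000, seed = 33, beta_score = 0,
                   beta_extra_ccis = 0, baseline_hazard = 5e-4)
  co <- scoreCohort(simulateCohort(cfg))
  ep <- sim_endpoint(co)
  fit <- coxUnivariate(ep$time, ep$event, co$ild_gapc[ep$sel])
  expect_lt(abs(fit$beta), 0.05)
})

test_that("Cox errors are explicit for degenerate inputs", {
  expect_error(coxUnivariate(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3)), "events")
  expect_error(coxUnivariate(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)), "constant")
  expect_warning(coxUnivariate(1:20, rep(1, 20), 20:1), "monotone")
})

test_that("Cox score test at beta = 0 equals the 2-group log-rank statistic", {
  set.seed(34)
  time <- sample(1:1000, 60)  # distinct times: no tie-correction slack needed
  event <- rbinom(60, 1, 0.7)
  x <- rbinom(60, 1, 0.5)
  fit <- coxFit(time, event, matrix(x, ncol = 1))
  lr <- logrankTest(time, event, x)
  expect_equal(fit$score_test$statistic, lr$statistic, tolerance = 1e-6)
})

test_that("coxAIC satisfies its identities", {
  set.seed(35)
  x <- rnorm(100)
  time <- rexp(100, exp(0.4 * x) / 5)
  event <- rbinom(100, 1, 0.8)
  fit <- coxUnivariate(time, event, x)
  aic <- coxAIC(time, event, x)
  expect_equal(aic - (-2 * fit$log_partial_likelihood), 2)
  # affine rescaling leaves AIC unchanged
  expect_equal(coxAIC(time, event, 3 * x - 7), aic, tolerance = 1e-7)
  # on informative data the score model beats the null (-2 * loglik0 + 0)
  expect_lt(aic, -2 * fit$loglik0)
  # categorical coding counts one parameter per extra level
  s <- sample(0:3, 100, replace = TRUE)
  time2 <- rexp(100, exp(0.5 * s) / 5)
  expect_type(coxAIC(time2, event, s, score_as = "categorical"), "double")
})

test_that("Harrell's C matches exhaustive pair enumeration on a 6-subject fixture", {
  time <- c(2, 4, 5, 7, 8, 10)
  event <- c(1, 0, 1, 1, 0, 1)
  score <- c(5, 3, 3, 4, 1, 2)
  expect_identical(harrellC(time, event, score),
                   harrell_c_oracle(time, event, score))
  # randomized property check against the same oracle
  set.seed(41)
  for (i in 1:20) {
    t <- sample(1:15, 8)
    e <- rbinom(8, 1, 0.7)
    s <- sample(1:5, 8, replace = TRUE)
    if (sum(e[t < max(t)]) == 0) next
    expect_equal(harrellC(t, e, s), harrell_c_oracle(t, e, s))
  }
})

test_that("Harrell's C has the expected limits and antisymmetry", {
  set.seed(42)
  t <- sort(rexp(30))
  e <- rep(1, 30)
  expect_equal(harrellC(t, e, rep(1, 30)), 0.5)       # constant score
  expect_equal(harrellC(t, e, rev(seq_len(30))), 1)   # perfect anti-ranking
  s <- rnorm(30)  # continuous: no ties
  expect_equal(harrellC(t, e, -s), 1 - harrellC(t, e, s))
  expect_error(harrellC(c(1, 2, 3), c(0, 0, 1), c(1, 2, 3)), "usable")
})

test_that("IPCW AUC reduces to the Mann-Whitney AUC without early censoring", {
  set.seed(51)
  n <- 120
  score <- rnorm(n)
  time <- rexp(n, exp(score) / 8)
  event <- rep(1, n)
  # censor only beyond the horizon so all weights are 1
  horizon <- stats::quantile(time, 0.45)
  cens <- time > horizon & rbinom(n, 1, 0.5) == 1
  event[cens] <- 0
  auc <- aucTimeDependent(time, event, score, horizon)
  cases <- time <= horizon & event == 1
  controls <- time > horizon
  expect_equal(auc, mann_whitney_auc(score[cases], score[controls]))
  # perfectly separating score, no censoring at all
  expect_equal(aucTimeDependent(c(1, 2, 9, 10), c(1, 1, 1, 1),
                                c(10, 9, 1, 2), 5), 1)
})

test_that("IPCW AUC is invariant under strictly monotone score transforms", {
  set.seed(52)
  n <- 200
  score <- rnorm(n)
  time <- rexp(n, exp(score) / 8)
  event <- rbinom(n, 1, 0.8)
  horizon <- stats::median(time)
  a1 <- aucTimeDependent(time, event, score, horizon)
  a2 <- aucTimeDependent(time, event, exp(2 * score) + 5, horizon)
  expect_equal(a1, a2)
  expect_error(aucTimeDependent(c(5, 6), c(0, 1), c(1, 2), 2), "no events")
})

test_that("compareGroups matches hand-computed Pearson chi-square and handles nulls", {
  r <- compareGroups(rep(c("m", "f", "m", "f"), c(10, 10, 10, 10)),
                     rep(c("g1", "g2"), each = 20), "categorical")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # 2x2 cells 49/8 vs 66/51: closed-form Pearson X2 = n(ad-bc)^2/(r1 r2 c1 c2)
  male <- rep(c(1, 0, 1, 0), c(49, 8, 66, 51))
  grp <- rep(c("IPF", "other"), c(57, 117))
  r <- compareGroups(male, grp, "categorical")
  n <- 174
  x2_hand <- n * (49 * 51 - 8 * 66)^2 / (57 * 117 * 115 * 59)
  expect_equal(r$statistic, x2_hand)
  expect_equal(r$p_value, pchisq(x2_hand, 1, lower.tail = FALSE))
  # identical continuous samples: two-sided Wilcoxon p = 1
  x <- c(1, 2, 3, 4, 5)
  r <- compareGroups(c(x, x), rep(c("a", "b"), each = 5), "continuous")
  expect_equal(r$p_value, 1)
  # k > 2 falls through to Kruskal-Wallis
  set.seed(61)
  v <- rnorm(60)
  g3 <- rep(c("a", "b", "c"), 20)
  r <- compareGroups(v, g3, "continuous")
  expect_equal(r$p_value, kruskal.test(v, factor(g3))$p.value)
  expect_error(compareGroups(v, factor(g3, levels = c("a", "b", "c", "d")),
                             "continuous"), "zero subjects")
})
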