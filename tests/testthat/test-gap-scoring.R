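test_that("componentPoints reproduces hand-summed point-table examples", {
  b1 <- componentPoints(patient_row("CVD_IP", "female", 58, 80, 60, 1))
  expect_identical(unlist(b1[1, 1:6], use.names = FALSE),
                   c(-2L, 0L, 0L, 0L, 0L, 0L))
  expect_identical(b1$ild_gap_total, -2L)
  expect_identical(b1$ild_gapc_total, -2L)

  b2 <- componentPoints(patient_row("IPF", "male", 70, 60, 40, 4))
  expect_identical(unlist(b2[1, 1:6], use.names = FALSE),
                   c(0L, 1L, 2L, 1L, 1L, 2L))
  expect_identical(b2$ild_gap_total, 5L)
  expect_identical(b2$ild_gapc_total, 7L)

  b3 <- componentPoints(patient_row("IPF", "male", 70, 45, NA, 5))
  expect_identical(b3$ild_gap_total, 8L)
  expect_identical(b3$ild_gapc_total, 10L)
})

test_that("band boundaries follow the closed-interval reading", {
  pts <- function(...) componentPoints(patient_row(...))
  expect_identical(pts(age = 60)$age_pts, 0L)
  expect_identical(pts(age = 65)$age_pts, 1L)
  expect_identical(pts(age = 65.01)$age_pts, 2L)
  expect_identical(pts(fvc_pct = 75)$fvc_pts, 1L)
  expect_identical(pts(fvc_pct = 75.01)$fvc_pts, 0L)
  expect_identical(pts(fvc_pct = 50)$fvc_pts, 1L)
  expect_identical(pts(fvc_pct = 49.99)$fvc_pts, 2L)
  expect_identical(pts(dlco_pct = 55)$dlco_pts, 1L)
  expect_identical(pts(dlco_pct = 55.01)$dlco_pts, 0L)
  expect_identical(pts(dlco_pct = 35)$dlco_pts, 2L)
  expect_identical(pts(dlco_pct = 35.01)$dlco_pts, 1L)
})

test_that("unknown enum values are rejected", {
  expect_error(componentPoints(patient_row(diagnosis = "sarcoidosis")),
               "diagnosis")
  expect_error(componentPoints(patient_row(sex = "m")), "sex")
})

test_that("all 432 table cells satisfy the score identities and ranges", {
  g <- score_grid()
  expect_identical(nrow(g), 432L)
  pts <- componentPoints(g)
  expect_true(all(pts$ild_gapc_total - pts$ild_gap_total == pts$ccis_pts))
  expect_true(all(pts$ccis_pts %in% 0:2))
  expect_true(all(pts$ild_gap_total >= -2 & pts$ild_gap_total <= 8))
  expect_true(all(pts$ild_gapc_total >= -2 & pts$ild_gapc_total <= 10))
  # staging and risk grouping are defined (partition) on every attainable total
  expect_false(anyNA(gapStage(pts$ild_gap_total)))
  expect_false(anyNA(riskGroup(pts$ild_gap_total)))
  expect_false(anyNA(riskGroup(pts$ild_gapc_total)))
})

test_that("moving any one component to a worse band never lowers totals, stage or group", {
  worse <- list(
    diagnosis = c("CVD_IP", "IPF"),
    sex = c("female", "male"),
    age = c(55, 63, 70),
    fvc_pct = c(90, 60, 40),
    dlco_pct = c(70, 45, 30, NA),
    ccis = c(0, 2, 5)
  )
  g <- score_grid()
  base_pts <- componentPoints(g)
  for (comp in names(worse)) {
    ladder <- worse[[comp]]
    for (step in seq_len(length(ladder) - 1)) {
      from <- ladder[step]
      to <- ladder[step + 1]
      sel <- if (is.na(from)) is.na(g[[comp]]) else
        !is.na(g[[comp]]) & g[[comp]] == from
      if (!any(sel)) next
      g2 <- g[sel, , drop = FALSE]
      g2[[comp]] <- to
      p1 <- base_pts[sel, ]
      p2 <- componentPoints(g2)
      expect_true(all(p2$ild_gap_total >= p1$ild_gap_total), label = comp)
      expect_true(all(p2$ild_gapc_total >= p1$ild_gapc_total), label = comp)
      expect_true(all(gapStage(p2$ild_gap_total) >= gapStage(p1$ild_gap_total)),
                  label = comp)
      expect_true(all(riskGroup(p2$ild_gapc_total) >=
                        riskGroup(p1$ild_gapc_total)), label = comp)
    }
  }
})

test_that("stage and risk-group cutpoints match their band definitions", {
  expect_identical(as.character(gapStage(c(-2, 1, 2, 3, 4, 5, 6, 8))),
                   c("I", "I", "II", "II", "III", "III", "IV", "IV"))
  expect_identical(as.character(riskGroup(c(-2, 1, 2, 3, 4, 10))),
                   c("low", "low", "moderate", "moderate", "high", "high"))
  # the low boundary agrees between the two classifications
  for (tot in -2:8) {
    expect_identical(gapStage(tot) == "I", riskGroup(tot) == "low")
  }
  expect_error(gapStage(9), "range")
  expect_error(riskGroup(11), "range")
})

test_that("outcome3yr implements the endpoint definitions", {
  # censored: no AE, no death
  co <- data.frame(followup_days = 400, ae_day = NA_real_,
                   death_day = NA_real_, death_cause = "none")
  o <- outcome3yr(co)
  expect_equal(o$ild_time, 400)
  expect_identical(o$ild_event, 0L)
  expect_true(o$ild_eligible)
  expect_equal(o$ac_time, 400)
  expect_identical(o$ac_event, 0L)

  # AE at 100, respiratory death at 300: composite takes the AE
  co <- data.frame(followup_days = 300, ae_day = 100,
                   death_day = 300, death_cause = "respiratory")
  o <- outcome3yr(co)
  expect_equal(o$ild_time, 100)
  expect_identical(o$ild_event, 1L)
  expect_true(o$ild_eligible)
  expect_equal(o$ac_time, 300)
  expect_identical(o$ac_event, 1L)

  # non-respiratory death without AE: excluded from the ILD endpoint only
  co <- data.frame(followup_days = 200, ae_day = NA_real_,
                   death_day = 200, death_cause = "non_respiratory")
  o <- outcome3yr(co)
  expect_false(o$ild_eligible)
  expect_identical(o$ac_event, 1L)
  expect_equal(o$ac_time, 200)
  o2 <- outcome3yr(co, nonresp_death_handling = "censor")
  expect_true(o2$ild_eligible)
  expect_identical(o2$ild_event, 0L)
  expect_equal(o2$ild_time, 200)

  # events beyond the horizon are censored at the horizon
  co <- data.frame(followup_days = 1500, ae_day = 1200,
                   death_day = NA_real_, death_cause = "none")
  o <- outcome3yr(co)
  expect_identical(o$ild_event, 0L)
  expect_equal(o$ild_time, 1095)

  # a non-respiratory death after the horizon stays eligible
  co <- data.frame(followup_days = 1300, ae_day = NA_real_,
                   death_day = 1300, death_cause = "non_respiratory")
  o <- outcome3yr(co)
  expect_true(o$ild_eligible)
  expect_equal(o$ild_time, 1095)
  expect_identical(o$ac_event, 0L)
})

test_that("outcome3yr validates its inputs", {
  base <- data.frame(followup_days = 100, ae_day = NA_real_,
                     death_day = NA_real_, death_cause = "none")
  bad <- base
  bad$ae_day <- 150
  expect_error(outcome3yr(bad), "exceed")
  bad <- base
  bad$death_cause <- "respiratory"
  expect_error(outcome3yr(bad), "death_cause")
  expect_error(outcome3yr(base, horizon_days = -1), "positive")
})

test_that("scoreCohort appends breakdown, totals and classifications", {
  co <- patient_row("IPF", "male", 70, 60, 40, 4)
  sc <- scoreCohort(co)
  expect_identical(sc$ild_gap, 5L)
  expect_identical(sc$ild_gapc, 7L)
  expect_identical(as.character(sc$gap_stage), "III")
  expect_identical(as.character(sc$gap_group), "high")
  expect_identical(as.character(sc$gapc_group), "high")
})
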