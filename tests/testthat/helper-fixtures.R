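# Shared fixtures and independent oracles used across test files.

# a blank 19-condition profile
blank_profile <- function() {
  stats::setNames(rep(FALSE, length(charlsonWeights())),
                  names(charlsonWeights()))
}

profile_with <- function(...) {
  p <- blank_profile()
  p[c(...)] <- TRUE
  p
}

# one-row patient constructor with sensible defaults
patient_row <- function(diagnosis = "IPF", sex = "male", age = 70,
                        fvc_pct = 80, dlco_pct = 60, ccis = 0) {
  data.frame(diagnosis = diagnosis, sex = sex, age = age,
             fvc_pct = fvc_pct, dlco_pct = dlco_pct, ccis = ccis,
             stringsAsFactors = FALSE)
}

# all 432 point-table cells: representative covariate values per band
score_grid <- function() {
  expand.grid(
    diagnosis = c("IPF", "CVD_IP"),
    sex = c("female", "male"),
    age = c(55, 63, 70),            # <=60 / (60,65] / >65
    fvc_pct = c(90, 60, 40),        # >75 / [50,75] / <50
    dlco_pct = c(70, 45, 30, NA),   # >55 / (35,55] / <=35 / cannot perform
    ccis = c(0, 2, 5),              # 0-1 / 2-3 / >=4
    stringsAsFactors = FALSE
  )
}

# brute-force concordance oracle: enumerate every ordered pair
harrell_c_oracle <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Mann-Whitney AUC oracle (rank-sum formulation)
mann_whitney_auc <- function(case_scores, control_scores) {
  r <- rank(c(case_scores, control_scores))
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# build ILD-related / all-cause endpoint vectors straight from a simulated
# cohort (used where the test wants the latent structure)
sim_endpoint <- function(cohort, endpoint = "ild_events",
                         horizon = 1095) {
  out <- outcome3yr(cohort, horizon_days = horizon)
  if (endpoint == "ild_events") {
    sel <- out$ild_eligible
    list(time = out$ild_time[sel], event = out$ild_event[sel], sel = sel)
  } else {
    list(time = out$ac_time, event = out$ac_event,
         sel = rep(TRUE, nrow(out)))
  }
}
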