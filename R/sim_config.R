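#' Simulator configuration
#'
#' Configuration object for the synthetic ILD cohort generator. Defaults
#' emulate the reference cohort the package is calibrated to: 185-patient
#' subtype mix (IPF 57/185, CVD-IP 31/185, iNSIP 86/185, CHP 6/185, UC-ILD
#' 5/185), per-subtype male fraction, age 71.9 +/- 9.1 years, %FVC 94.2 +/-
#' 18.8, per-subtype %DLco means, negative-binomial CCIS with mean 2.5 and
#' SD 2.1, exponential administrative censoring with mean 792 days, and a
#' proportional-hazards event process whose baseline hazard is calibrated so
#' that the marginal 3-year event probability is 0.114.
#'
#' The event hazard for patient i is
#' `baseline_hazard * exp(beta_score * ILD-GAPC_i + beta_extra_ccis * CCIS_i)`
#' (a Weibull time-scale power `weibull_shape` is exposed for robustness
#' checks; 1 = exponential). `beta_extra_ccis > 0` makes comorbidity carry
#' hazard beyond its contribution to the score, the mechanism under which
#' the comorbidity-extended model should out-predict the base model.
#'
#' @param n_patients Number of patients (non-negative integer; default 185).
#' @param seed Integer RNG seed.
#' @param diagnosis_mix Named probabilities over [ildSubtypes()], summing
#'   to 1.
#' @param male_prob Named per-subtype probability of male sex.
#' @param age_mean,age_sd Age distribution (years), truncated below at
#'   `trunc_lower`.
#' @param fvc_mean,fvc_sd Percent-predicted FVC distribution, truncated
#'   below at `trunc_lower`.
#' @param dlco_mean,dlco_sd Named per-subtype %DLco distributions,
#'   truncated below at `trunc_lower`.
#' @param dlco_missing_prob Probability a patient cannot perform the DLco
#'   manoeuvre (recorded as NA; default 0 — the emulated cohort required a
#'   measurable DLco for enrolment).
#' @param fvc_dlco_rho Gaussian-copula correlation between %FVC and %DLco
#'   (default 0.5; the joint distribution is not identified by published
#'   marginals).
#' @param ccis_mean,ccis_dispersion Negative-binomial mean and size for the
#'   CCIS (mean 2.5, size 3.27 gives SD ~2.1); capped at `ccis_cap`.
#' @param ccis_cap Upper cap for simulated CCIS (default 15).
#' @param baseline_hazard Baseline event hazard (events/day). The default is
#'   the output of [calibrateBaselineHazard()] at the other defaults for a
#'   marginal 3-year event probability of 0.114.
#' @param beta_score Log-hazard per ILD-GAPC point (default 0.4, i.e. hazard
#'   ratio ~1.49 per point).
#' @param beta_extra_ccis Additional log-hazard per raw CCIS point beyond
#'   the score term (default 0.25).
#' @param weibull_shape Weibull shape of the event-time law (default 1 =
#'   constant hazard).
#' @param censor_mean_days Mean of the exponential administrative censoring
#'   time (default 792; `Inf` disables censoring).
#' @param nonresp_rate Hazard (per day) of the independent non-respiratory
#'   death process (default 4.6e-5, which makes ~3% of patients die of a
#'   non-respiratory cause first).
#' @param p_ae Probability that an ILD-related event is a first acute
#'   exacerbation rather than a respiratory death (default 0.5).
#' @param trunc_lower Lower truncation for age/%FVC/%DLco (default 20).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simConfig(n_patients = 50, seed = 1)
#' @export
simConfig <- function(n_patients = 185,
                      seed = 1,
                      diagnosis_mix = c(IPF = 57, CVD_IP = 31, iNSIP = 86,
                                        CHP = 6, UC_ILD = 5) / 185,
                      male_prob = c(IPF = 0.86, CVD_IP = 0.564, iNSIP = 0.564,
                                    CHP = 0.667, UC_ILD = 1.0),
                      age_mean = 71.9, age_sd = 9.1,
                      fvc_mean = 94.2, fvc_sd = 18.8,
                      dlco_mean = c(IPF = 81.9, CVD_IP = 97.6, iNSIP = 97.6,
                                    CHP = 83.1, UC_ILD = 118.9),
                      dlco_sd = c(IPF = 26.2, CVD_IP = 30.2, iNSIP = 30.2,
                                  CHP = 17.6, UC_ILD = 25.0),
                      dlco_missing_prob = 0,
                      fvc_dlco_rho = 0.5,
                      ccis_mean = 2.5, ccis_dispersion = 3.27,
                      ccis_cap = 15,
                      baseline_hazard = 1.60788e-05,
                      beta_score = 0.4,
                      beta_extra_ccis = 0.25,
                      weibull_shape = 1,
                      censor_mean_days = 792,
                      nonresp_rate = 4.6e-05,
                      p_ae = 0.5,
                      trunc_lower = 20) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    diagnosis_mix = diagnosis_mix, male_prob = male_prob,
    age_mean = age_mean, age_sd = age_sd,
    fvc_mean = fvc_mean, fvc_sd = fvc_sd,
    dlco_mean = dlco_mean, dlco_sd = dlco_sd,
    dlco_missing_prob = dlco_missing_prob,
    fvc_dlco_rho = fvc_dlco_rho,
    ccis_mean = ccis_mean, ccis_dispersion = ccis_dispersion,
    ccis_cap = ccis_cap,
    baseline_hazard = baseline_hazard,
    beta_score = beta_score, beta_extra_ccis = beta_extra_ccis,
    weibull_shape = weibull_shape,
    censor_mean_days = censor_mean_days,
    nonresp_rate = nonresp_rate, p_ae = p_ae,
    trunc_lower = trunc_lower
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  subtypes <- ildSubtypes()
  if (!is_scalar_number(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients)) {
    stop_validation("`n_patients` must be a non-negative integer")
  }
  if (!is_scalar_number(cfg$seed)) {
    stop_validation("`seed` must be a number")
  }
  mix <- cfg$diagnosis_mix
  if (!all(subtypes %in% names(mix))) {
    stop_validation("`diagnosis_mix` must name all of: ",
                    paste(subtypes, collapse = ", "))
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop_validation("`diagnosis_mix` must be non-negative and sum to 1")
  }
  if (!all(subtypes %in% names(cfg$male_prob)) ||
      any(cfg$male_prob < 0 | cfg$male_prob > 1)) {
    stop_validation("`male_prob` must give a probability in [0,1] per subtype")
  }
  for (nm in c("age_sd", "fvc_sd")) {
    if (cfg[[nm]] <= 0) stop_validation("`", nm, "` must be > 0")
  }
  if (!all(subtypes %in% names(cfg$dlco_mean)) ||
      !all(subtypes %in% names(cfg$dlco_sd)) || any(cfg$dlco_sd <= 0)) {
    stop_validation("`dlco_mean`/`dlco_sd` must cover all subtypes with sd > 0")
  }
  for (nm in c("dlco_missing_prob", "p_ae")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_validation("`", nm, "` must be in [0,1]")
    }
  }
  if (abs(cfg$fvc_dlco_rho) >= 1) {
    stop_validation("`fvc_dlco_rho` must be in (-1, 1)")
  }
  if (cfg$ccis_mean <= 0 || cfg$ccis_dispersion <= 0) {
    stop_validation("`ccis_mean` and `ccis_dispersion` must be > 0")
  }
  if (cfg$baseline_hazard < 0 || cfg$nonresp_rate < 0) {
    stop_validation("hazard rates must be non-negative")
  }
  if (cfg$weibull_shape <= 0) {
    stop_validation("`weibull_shape` must be > 0")
  }
  if (cfg$censor_mean_days <= 0) {
    stop_validation("`censor_mean_days` must be > 0 (Inf disables censoring)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ILD cohort configuration\n")
  cat(sprintf("  n_patients: %d   seed: %s\n", x$n_patients,
              format(x$seed)))
  cat("  diagnosis mix: ",
      paste(sprintf("%s %.3f", names(x$diagnosis_mix), x$diagnosis_mix),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  age %.1f +/- %.1f, %%FVC %.1f +/- %.1f, CCIS mean %.1f\n",
              x$age_mean, x$age_sd, x$fvc_mean, x$fvc_sd, x$ccis_mean))
  cat(sprintf(
    "  hazard: h0 = %.3g/day, beta_score = %.3g, beta_extra_ccis = %.3g\n",
    x$baseline_hazard, x$beta_score, x$beta_extra_ccis))
  cat(sprintf("  censoring mean %.0f d, nonresp rate %.3g/day, p_ae %.2f\n",
              x$censor_mean_days, x$nonresp_rate, x$p_ae))
  invisible(x)
}
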