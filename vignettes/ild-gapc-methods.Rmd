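---
title: "Methods: comorbidity-extended ILD-GAP staging and its evaluation"
author: "ildgapc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity-extended ILD-GAP staging and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildgapc)
```

## The problem and the models

The clinical course of interstitial lung disease (ILD) is highly variable,
and point-based indices are the standard bedside tool for prognostic
staging. The ILD-GAP index assigns points for ILD subtype (IPF or
unclassifiable ILD 0; collagen-vascular-disease-related IP, idiopathic
NSIP or chronic hypersensitivity pneumonitis −2), sex (female 0, male 1),
age (≤60: 0; 61–65: 1; >65: 2), percent-predicted FVC (>75: 0; 50–75: 1;
<50: 2) and percent-predicted DLco (>55: 0; 36–55: 1; ≤35: 2; cannot
perform: 3), for a total in [−2, 8]. It omits comorbidity, although
cardiovascular disease, malignancy and other chronic conditions are known
to shape ILD outcomes. The extension implemented here, ILD-GAPC, adds a
categorised Charlson Comorbidity Index score (CCIS): 0–1 comorbidity
points add 0, 2–3 add 1, and ≥4 add 2, for a total in [−2, 10].

Two classifications are used downstream: the four ILD-GAP stages
(I: ≤1, II: 2–3, III: 4–5, IV: >5) and the three risk groups
(low ≤1, moderate 2–3, high ≥4), the latter applied with identical
cutpoints to both models so that their stratifications are comparable.

Band boundaries are read on the real line with closed ends as printed:
exactly 75.0 %FVC scores 1 point, exactly 55.0 %DLco scores 1, exactly
35.0 %DLco scores 2, and the age bands are ≤60 / (60, 65] / >65 (the
printed "61–65" presumes integer ages). Two typographical inconsistencies
in the published point table are resolved in favour of the convention that
makes the bands a partition: %DLco "≥35: 2" is read as ≤35 → 2 (the
original ILD-GAP convention), and CCIS "≤4: 2" is read as ≥4 → 2 (the
verbal definition, and the only reading that does not overlap the other
bands).

The Charlson score itself is the unadjusted 19-condition index with the
original weights (ten conditions at 1, six at 2, one at 3, two at 6).
Three pairs are mutually exclusive — uncomplicated diabetes vs end-organ
damage, mild vs moderate/severe liver disease, any tumour vs metastatic
solid tumour — giving an attainable range of 0–33. The age-adjusted
variant (one point per decade from 50, capped at 4) is available behind
`age_adjust`, off by default, since the categorisation above was defined
on the unadjusted score. In an ILD cohort the index disease is itself a
chronic pulmonary disease; whether to flag `chronic_pulmonary_disease` is
the data owner's decision, and `exclude_index_disease = TRUE` removes
that point if double counting is a concern.

## Endpoints

Two endpoints are constructed at a 3-year horizon (1095 days, follow-up
being recorded in days):

* **3-year ILD-related events** — the composite of first acute
  exacerbation (AE) or respiratory death within the horizon. Patients who
  died of a non-respiratory cause within the horizon without a prior AE
  are uninterpretable for this endpoint and are excluded from it by
  default (`nonresp_death_handling = "censor"` keeps them, censored at
  the death day). A non-respiratory death *after* the horizon is ordinary
  administrative censoring at the horizon.
* **3-year all-cause mortality** — death from any cause within the
  horizon; everyone is eligible.

## The synthetic cohort generator

Patient-level data of the kind this analysis needs are rarely deposited,
so the package ships a generator whose defaults emulate the reference
cohort the scoring models were evaluated on: 185 patients with subtype
mix IPF 57/185, CVD-IP 31/185, iNSIP 86/185 (the two are
indistinguishable to the score and are split according to the published
enumeration of CVD-IP diagnoses), CHP 6/185 and UC-ILD 5/185; per-subtype
male fractions (0.86 for IPF, 0.564 for CVD-IP/iNSIP, 0.667 for CHP, 1.0
for UC-ILD); age 71.9 ± 9.1 years; %FVC 94.2 ± 18.8; per-subtype %DLco
(81.9 ± 26.2 for IPF up to 118.9 ± 25.0 for UC-ILD); and a
negative-binomial CCIS with mean 2.5 and dispersion 3.27 (SD ≈ 2.1),
capped at 15. Age and the physiology variables are normal truncated below
at 20 to stay positive and plausible; %FVC and %DLco share a Gaussian
copula with rank correlation 0.5, a deliberate free choice because the
joint distribution is not identified by published marginals. CCIS is
sampled marginally, not conditional on subtype, because the reference
cohort shows no meaningful subtype difference in CCIS. "Cannot perform
DLco" has probability 0 by default (the emulated cohort required a
measurable DLco for enrolment) and is exposed as a stress knob.

Events follow a proportional-hazards process: patient $i$ has event
hazard

$$\lambda_i = h_0 \exp(\beta_s \cdot \mathrm{ILDGAPC}_i + \beta_c \cdot \mathrm{CCIS}_i),$$

with exponential event times by default (a Weibull shape is exposed for
robustness checks), exponential administrative censoring with mean 792
days (the cohort's mean follow-up), and an independent non-respiratory
death process with rate 4.6e-5/day, chosen analytically so that ≈3% of
patients die of a non-respiratory cause first (6/185 in the reference
cohort). An ILD-related event is labelled a first AE with probability
`p_ae = 0.5`, otherwise a respiratory death; the published event table
does not break down the AE/death composition, so an even split is the
neutral choice.

The defaults for the hazard coefficients are $\beta_s = 0.4$ per ILD-GAPC
point — matching the published univariate hazard ratio of ≈1.49 per score
point — and $\beta_c = 0.25$ per raw CCIS point. A positive $\beta_c$
means comorbidity carries hazard *beyond* what its score category
contributes; this is exactly the mechanism under which the extended model
should out-predict the base model, and setting $\beta_c = 0$ recovers the
null in which the CCIS term only adds noise. The baseline hazard default
($1.60788 \times 10^{-5}$/day) is the output of
`calibrateBaselineHazard()` at these defaults for a marginal (latent,
pre-censoring) 3-year event probability of 0.114, the reference cohort's
21/185 event fraction. Calibration integrates the event probability over
20,000 covariate draws at a fixed internal seed and root-finds on the log
hazard, so it is deterministic and accurate to about 1e-3.

What the generator does *not* emulate: correlated comorbidity profiles
(CCIS is drawn as a count, not from the 19 flags), subtype-specific age
structure, non-proportional hazards, informative censoring, and any
longitudinal physiology. Tests that pass on these cohorts therefore
validate the statistical machinery and the qualitative model-comparison
logic, not clinical performance on real patients.

## Survival statistics

All estimators of the evaluation toolkit are implemented from their
defining formulas, and each is checked in the test suite against an
independent oracle (hand-computed fixtures, exhaustive enumeration,
permutation distributions, reductions to rank statistics) as well as
cross-checked against the reference implementations in the `survival`
package.

* **Kaplan–Meier**: product-limit estimate with Greenwood variance;
  subjects censored at an event time remain at risk at that time. Where
  the curve reaches 0 the Greenwood variance is reported as 0 (the
  estimate is degenerate there).
* **Log-rank**: k-sample observed-minus-expected statistic with the
  multivariate hypergeometric covariance; the quadratic form uses a
  pseudo-inverse if the covariance submatrix is numerically singular;
  p from $\chi^2_{k-1}$.
* **Cox partial likelihood**: Newton–Raphson with step-halving on
  centred/scaled covariates, Efron tie correction by default (Breslow
  available for cross-checks). Monotone likelihoods (perfect separation)
  are detected and reported with a warning and a bounded estimate. The
  score test at $\beta = 0$ is exposed; for a binary covariate without
  ties it equals the 2-group log-rank statistic.
* **Harrell's C**: pairs are usable when the shorter follow-up ends in an
  event; score ties count 1/2; exactly tied times are not used. The
  original Harrell estimator is used, not the IPCW variant, because the
  evaluation design names the concordance index generically.
* **Time-dependent AUC**: cumulative-case / dynamic-control AUC at the
  horizon with inverse-probability-of-censoring weights from the reverse
  Kaplan–Meier. Cases are weighted by $1/\hat G(T_i^-)$ and controls by
  $1/\hat G(t^-)$ — left limits, so that administrative truncation of
  follow-up exactly at the horizon does not deflate the weights. Controls
  are the subjects at risk past the horizon, operationally
  `time > horizon` or censored exactly at it. When no censoring precedes
  the horizon every weight is 1 and the estimator reduces exactly to the
  Mann–Whitney AUC, which the tests assert. The incident/dynamic variant
  is out of scope; the unweighted binary-status AUC is available via
  `ipcw = FALSE`.
* **AIC**: $-2\hat\ell + 2k$ from the Cox partial likelihood with the
  integer score as one linear covariate ($k = 1$); `score_as =
  "categorical"` enters the score as factor levels instead, since the
  evaluation design does not pin the coding down.
* **Group comparisons**: Pearson chi-square without continuity correction
  for categorical variables; two-sided Wilcoxon rank-sum (normal
  approximation with continuity correction — ties make the exact
  distribution unavailable) for two groups, Kruskal–Wallis for more.

Two-sided tests and a 0.05 significance convention are used throughout.

## The analysis pipeline

`runAnalysis()` reproduces the full comparison on any cohort: a
per-subtype characteristics table with comparison p-values; the
seven-variable univariate Cox screen of 3-year ILD-related events (age,
male sex, CCIS, IPF vs non-IPF, ILD-GAP score, %FVC, %DLco — the %DLco
row drops cannot-perform patients); time-dependent AUC, Harrell's C and
Cox AIC for each model and endpoint; and Kaplan–Meier curve sets with
log-rank tests for the 4-stage classification and the low/moderate/high
grouping under both models and both endpoints. Empty strata are reported
as empty rather than dropped, group sizes always partition the
analysis-eligible cohort, endpoints with zero events are marked
unavailable without aborting the run, and every filtering step logs its
counts. `renderReport()` serialises the report to step-function tables
(TSV) or a single JSON document, byte-identically for identical inputs;
figures are deliberately emitted as plot-ready tables, keeping the core
headless.

## Numerical and design choices

* Newton–Raphson tolerance 1e-9 on the coefficient step with at most 30
  iterations and 12 step-halvings; covariates are centred and scaled
  internally and estimates transformed back.
* The log-rank and KM risk sets are computed by sorted
  `findInterval()` counts, so cohort-scale resampling studies run in
  milliseconds.
* Simulated cohorts are deterministic given the configuration seed;
  covariates and outcomes use derived sub-streams so that the two draws
  are independently reproducible, and the caller's RNG state is always
  restored.
* Validation is strict and early: mutually exclusive comorbidity pairs
  are rejected by name, out-of-range totals error, and `n_patients = 0`
  returns an empty cohort (only negative counts are errors).

## Problem sizes used in the checks

The package's statistical checks run at sizes chosen to put each
asymptotic quantity in its validity regime while remaining quick on one
CPU: coefficient recovery uses cohorts of n = 2000 (≈130 events), with
the mean over 20 replicates and Wald-coverage over 100 replicates
(coverage over only 20 replicates has granularity 0.05 and cannot
discriminate 0.95 from 1.0); null calibration of the log-rank p uses 2000
cohorts of n = 500 (≈30 events each, enough for the $\chi^2_2$ reference
to hold); the null AUC is the mean over 20 cohorts of n = 5000 (a single
cohort's AUC has Monte Carlo SE ≈ 0.019, wider than the question being
asked); and the qualitative model comparison uses n = 2000 with the
comorbidity effect on and n = 5000 with it off.

## Known limitations

The generator's event process is exponential and proportional by
construction, so it cannot probe misspecification of the scoring models
themselves. CCIS enters the hazard linearly; threshold effects of
comorbidity are not represented. The ILD-related endpoint treats the
AE/death composite as a single event type and does not model competing
risks formally (the non-respiratory death process is an exclusion
mechanism, matching the evaluation design, not a Fine–Gray model).
Multivariable Cox models, bootstrap confidence intervals for AUC
differences, and ICD-code-to-comorbidity mapping are out of scope.
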