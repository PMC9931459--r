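# ildgapc

Prognostic staging of interstitial lung disease (ILD) with the **ILD-GAP**
index and its comorbidity-extended variant **ILD-GAPC**, plus the survival
machinery needed to compare the two models on a cohort.

## Who this is for

Pulmonology and biostatistics groups who stage ILD patients with point
indices and want a tested, reproducible implementation of: Charlson
comorbidity scoring, ILD-GAP/ILD-GAPC point assignment and
stage/risk-group classification, 3-year endpoint construction under right
censoring, and the model-comparison toolkit (Kaplan–Meier, log-rank,
univariate Cox, time-dependent ROC AUC, Harrell's C-index, AIC). Because
patient-level ILD cohorts are rarely shareable, the package also ships a
calibrated synthetic cohort generator so every stage of the analysis is
runnable and testable end to end.

## The models

ILD-GAP assigns points for ILD subtype (IPF/UC-ILD 0; CVD-IP/iNSIP/CHP
−2), sex (F 0 / M 1), age (≤60: 0, 61–65: 1, >65: 2), %FVC (>75: 0,
50–75: 1, <50: 2) and %DLco (>55: 0, 36–55: 1, ≤35: 2, cannot perform: 3);
total in [−2, 8]. ILD-GAPC adds a categorised Charlson Comorbidity Index
score (CCIS 0–1 → 0, 2–3 → 1, ≥4 → 2); total in [−2, 10]. Totals map to
stages I (≤1), II (2–3), III (4–5), IV (>5) and risk groups low (≤1),
moderate (2–3), high (≥4).

Model discrimination for 3-year ILD-related events (first acute
exacerbation or respiratory death) is compared via the IPCW
cumulative/dynamic AUC at 1095 days, Harrell's C, and the Cox
partial-likelihood AIC of the score.

## Worked example

```r
library(ildgapc)

co <- simulateCohort(simConfig(n_patients = 185, seed = 20))
sc <- scoreCohort(co)
table(sc$gap_stage)
#>   I  II III  IV
#> 111  60  12   2

rep <- runAnalysis(co, seed = 20)
#> cohort: 185 patients
#> ILD-related endpoint: 11 excluded (non-respiratory death, no prior AE)
#> events within 1095 days: 13 ILD-related, 16 deaths
rep
#> ILD-GAP / ILD-GAPC analysis report (n = 185)
#>
#> Model comparison metrics:
#>     model   endpoint   auc c_index   aic   n n_event available
#>   ild_gap ild_events 0.818   0.742 115.2 174      13      TRUE
#>  ild_gapc ild_events 0.870   0.821 107.1 174      13      TRUE
#>   ild_gap  all_cause 0.644   0.595 142.6 185      16      TRUE
#>  ild_gapc  all_cause 0.701   0.653 140.3 185      16      TRUE
#>
#> Log-rank stratifications:
#>   ild_gap by stage (ild_events): p = 0.003077
#>   ild_gap by stage (all_cause): p = 0.01629
#>   ild_gap by risk (ild_events): p = 0.0009996
#>   ild_gap by risk (all_cause): p = 0.01771
#>   ild_gapc by risk (ild_events): p = 0.0003735
#>   ild_gapc by risk (all_cause): p = 0.003201
```

Reading this: most patients sit in stage I/II (mild physiology), the
simulated comorbidity effect carries hazard beyond the base score, so the
comorbidity-extended model separates the risk groups more sharply —
higher AUC and C-index, lower AIC, smaller log-rank p — which is the
qualitative pattern the package is designed to reproduce and test.
`renderReport(rep, "out/")` writes the tables and step-function KM curves
to disk; a thin CLI over the same functions lives at
`inst/scripts/ildgapc-cli.R` (`simulate | score | evaluate | report`).

Real cohorts are read with `readCohort("cohort.csv")` (columns:
`patient_id, diagnosis, sex, age, fvc_pct, dlco_pct` — empty cell =
cannot perform — `followup_days, ae_day, death_day, death_cause`, and
either `ccis` or the 19 Charlson flag columns of `charlsonWeights()`).

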