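# n2bpk

Formulation optimization and nose-to-brain pharmacokinetics in R.

Nasal delivery of poorly soluble CNS drugs is often engineered in two
stages: a designed-experiment optimization of the formulation (here,
drug nanocrystals stabilized with HPMC, sized by response-surface
methodology), followed by rat pharmacokinetic studies comparing brain and
plasma exposure to quantify how much drug reaches the brain directly
through the nasal cavity rather than through the systemic circulation.
n2bpk implements the complete statistical chain of such a study for
formulation scientists and pharmacokineticists:

* **Designs** — 12-run Plackett–Burman screening designs and inscribed
  central composite designs (factorial ±1, axial ±α = 2^(k/4), natural
  bounds mapped to ±α), with coded↔natural transforms that snap rounded
  published levels back to canonical codes.
* **Response-surface models** — OLS fits of
  y = β₀ + Σβᵢxᵢ + Σβᵢⱼxᵢxⱼ + Σβᵢᵢxᵢ² on coded factors, ANOVA with partial
  (Type III) term SS and the lack-of-fit / pure-error partition, R²/adjusted
  R²/PRESS/predicted R², hierarchy-preserving backward elimination, and
  Derringer–Suich desirability optimization over the coded cube.
* **Non-compartmental analysis** — Cmax, Tmax, AUC₀→tlast, AUMC, MRT by
  linear trapezoid with explicit BLQ rules; pooling of destructive (sparse)
  brain sampling into a mean profile; arm summaries as mean ± SD.
* **Targeting indices** — %DTE = ((AUC_brain/AUC_plasma)i.n. /
  (AUC_brain/AUC_plasma)i.v.) × 100 and
  %DTP = (B_i.n. − Bₓ)/B_i.n. × 100 with Bₓ = (B_i.v./P_i.v.)·P_i.n.,
  including calibration of the i.v. ratio from a known %DTE.
* **Quality metrics and group statistics** — % yield, dosing-precision
  %RSD, stability %-bias assessment; one-way ANOVA with Tukey HSD, exact
  (tie-capable) Wilcoxon rank-sum.
* **Synthetic data** — seeded generators for response surfaces and
  one-compartment extravascular PK studies with dense plasma / destructive
  brain schedules, plus estimator-recovery experiments.

A worked case study — the optimization and nasal PK of rufinamide
nanocrystals — is bundled as plain data.frame constructors
(`rufi_ccd_table()`, `rufi_formulation_auc()`, `rufi_stability_table()`).

## Worked example

```r
library(n2bpk)

# refit the case-study particle-size model on canonical coded levels
design <- rufi_ccd_design()
fit <- rsm_fit(design, rufi_ccd_table()$particle_size, rufi_reduced_terms())
round(coef(fit), 2)
#>  (Intercept)         hpmc   sonication sonication^2
#>       486.73       171.08       -23.57       -30.86

subset(fit$anova, source %in% c("model", "lack_of_fit", "pure_error"),
       c(source, sum_of_squares, df, F))
#>        source sum_of_squares df         F
#> 1       model     421274.803  3 62.041684
#> 6 lack_of_fit      32171.450 11  3.617058
#> 7  pure_error       4042.895  5        NA

rsm_optimize(fit, "minimize")
#> Desirability optimum (minimize)
#>              coded natural
#> hpmc            -1  0.4851
#> sonication       1 12.9730
#> temperature      0 10.0000
#> predicted response 261.2 | desirability 1

# nose-to-brain indices: calibrate the i.v. ratio on one formulation,
# apply it to another
auc <- rufi_formulation_auc()
iv <- calibrate_iv_ratio(formulation_pk("Rufi-NC-Susp", 340.7, 258.2), 373.16)
dtp(formulation_pk("Rufi-NC-RXG", 471.3, 192.3), iv)
#> Rufi-NC-RXG: %DTE 693.1 | %DTP 85.6 | Bx 68 min*ug/g
```

The fitted equation says particle size rises steeply with HPMC
concentration (+171 nm per coded unit) and falls with ultrasonication time,
with curvature in the latter; the minimum over the factorial region is the
low-HPMC/high-sonication corner, predicting 261.2 nm. The %DTE of 693
means the gel delivers roughly 7× the brain:plasma exposure ratio of an
intravenous dose, and the %DTP of 85.6 attributes ~86% of its brain
exposure to direct nose-to-brain transport.

A fully synthetic miniature study (design CSV, responses, plasma and
destructive brain concentrations) can be written with
`write_fixture_study(dir, seed)` and read back with the `read_*_csv`
functions.

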