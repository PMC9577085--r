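Package: n2bpk
Title: Formulation Optimization and Nose-to-Brain Pharmacokinetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the computational chain of a nanocrystal formulation
    optimization and nose-to-brain pharmacokinetic study: Plackett-Burman and
    inscribed central composite designs with coded/natural level transforms,
    quadratic response-surface fitting with lack-of-fit ANOVA, PRESS and
    predicted R-squared diagnostics, hierarchy-preserving backward elimination
    and desirability-based optimization; non-compartmental analysis of
    concentration-time profiles including pooling of sparse destructive brain
    sampling; direct nose-to-brain transport indices (%DTE and %DTP) with
    calibration of the intravenous reference ratio; formulation quality
    arithmetic (% yield, dosing %RSD, stability %-bias); group-comparison
    statistics (one-way ANOVA with Tukey HSD, exact Wilcoxon rank-sum); and a
    synthetic-data generator emulating the study designs so every pipeline
    stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
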