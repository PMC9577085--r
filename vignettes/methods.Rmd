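---
title: "Methods: response-surface optimization and nose-to-brain PK indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface optimization and nose-to-brain PK indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2bpk)
```

n2bpk implements the statistical chain of a nanocrystal
formulation-optimization and nasal pharmacokinetic study: designed
experiments and quadratic response-surface models for the formulation step,
non-compartmental analysis (NCA) for the in-vivo step, and the %DTE/%DTP
indices that quantify direct nose-to-brain drug transport. This vignette
explains the models, the conventions the numbers depend on, and the design
choices that were genuinely open.

## Designed experiments and coding

Screening uses the 12-run Plackett–Burman design built by cyclic rotation
of the standard 11-element generator row plus the closing all-minus row;
columns beyond the real factors are kept as dummy columns for error
estimation. The generator row for N = 12 is not unique in the literature;
the standard one is used here, and any two of the eleven columns are
orthogonal over the twelve runs, which is the property the screening
analysis relies on.

Optimization uses a central composite design (CCD). Each factor is coded as
`x = (natural − center)/step`; factorial corners sit at ±1, axial points at
±α, centers at 0. For k factors the rotatable axial distance is
α = 2^(k/4) (1.6818 for k = 3). The *inscribed* convention maps the user's
natural bounds to ±α, so `step = range/(2α)` and the factorial corners are
interior points — for HPMC bounds of 0.1–2.0 % w/v the corners fall at
0.485 and 1.615 % w/v. Standard order is Yates order for the factorial
block, then axial pairs in factor order (low before high), then the center
replicates.

Published design tables print natural levels to 2–3 significant figures
(12.973 min appears as "12.9"). Re-coding such a table with the raw
transform would give levels like 0.9754 instead of +1 and would not
reproduce the regression computed on the exact design. `to_coded()`
therefore snaps a raw code to a canonical level in {0, ±1, ±α} when it lies
within a relative `snap_tolerance` of it, defaulting to 3%. That tolerance
was chosen from the arithmetic of printing: truncating 12.973 to 12.9
perturbs the code by 2.46%, while the smallest gap between canonical levels
(1 to 1.6818) is about 40%, so 3% is both necessary and safely
unambiguous. Snapping can be disabled with `snap_tolerance = 0`.

## The response-surface model

The fitted model is the quadratic polynomial in coded factors

y = β₀ + Σᵢ βᵢxᵢ + Σᵢ<ⱼ βᵢⱼxᵢxⱼ + Σᵢ βᵢᵢxᵢ², fit by ordinary least squares.
The ANOVA table reports:

* **Per-term partial (Type III) sums of squares**, `SSⱼ = βⱼ²/[(XᵀX)⁻¹]ⱼⱼ`,
  each tested against the residual mean square. On a CCD the linear columns
  are orthogonal, so their partial SS coincide with sequential SS; the
  intercept/quadratic block is not orthogonal, and the partial convention
  is the one under which the case study's printed quadratic-term SS
  (13973.18) reproduces.
* **Lack of fit vs pure error**: pure error is the within-group SS over
  replicate groups (runs with identical coded rows), lack of fit the
  remaining residual. With no replicated runs these rows are reported as
  `NA` — undefined, not zero.
* **R² diagnostics**: adjusted R² penalizes by degrees of freedom; PRESS is
  the leave-one-out prediction error sum computed through the hat-matrix
  identity `e₍ᵢ₎ = eᵢ/(1 − hᵢ)`, and predicted R² = 1 − PRESS/SS_total. The
  identity is verified in the test suite against n explicit refits.

Model reduction is backward elimination: repeatedly drop the non-intercept
term with the largest p above `alpha_keep` (default 0.05), refitting after
each drop, under the hierarchy rule that a linear term is never dropped
while its quadratic or an interaction containing it remains. Ties in p are
broken deterministically by term order (linear < interaction < quadratic,
then factor index). On the bundled case-study table this path ends at
{intercept, linear HPMC, linear sonication, sonication²}, retaining linear
sonication (p = 0.086) because its quadratic is significant.

p-values below 10⁻⁴ print as "<0.0001", the convention of the DoE software
this package's reports are meant to be compared against.

## Desirability optimization

Optimization maximizes a Derringer–Suich desirability: a one-sided ramp for
minimize/maximize goals, two-sided for a target goal, with shape exponents
defaulting to 1 (no evidence in the case study supports anything sharper).
The ramp anchors default to the predicted range over the search region, so
for one-sided goals the desirability optimum coincides with the constrained
extremum of the prediction. The search is a dense grid (41 points per
active dimension) refined by L-BFGS-B polish; a one-dimensional quadratic
with an interior vertex recovers the analytic vertex −β₁/(2β₁₁) to 10⁻⁶.

The default region is the coded factorial cube [−1, 1]^k rather than the
axial sphere. This is a substantive choice: on the case-study fit the
cube's corner gives the reported optimum (0.485 % w/v HPMC, 12.97 min),
whereas searching out to ±α would push HPMC to its axial extreme. Factors
that appear in no model term are unconstrained and reported at the region
center — processing temperature in the case study, reported at 10 °C. If
the desirability is flat over the region the center is returned with a
`degenerate` flag rather than an arbitrary grid point.

## Non-compartmental analysis

NCA uses the linear trapezoid rule on C(t) and t·C(t) from the first
sampled time to the last quantifiable point, with Cmax, Tmax (earliest time
attaining the maximum), AUC₀→tlast, AUMC₀→tlast and MRT = AUMC/AUC. Three
conventions are fixed deliberately:

* **Linear, not lin-up/log-down, trapezoids.** The lin/log rule needs a
  declared switch point and makes results depend on it; the linear rule is
  the reproducible default and is what the AUC identities in the test
  suite (segment-insertion invariance, pooling linearity) hold for exactly.
* **No extrapolation to infinity and no terminal-slope fit** — all
  quantities are to-tlast, matching how sparse brain data can honestly be
  summarized.
* **BLQ handling**: below-quantification points before the first
  quantifiable point count as zero, embedded ones count as zero, trailing
  ones are excluded; an all-BLQ profile is an error, not a zero AUC.

Destructive brain sampling (each animal contributes one time point) is
pooled by `pool_destructive()` into a single mean profile with per-time n
and SD kept as metadata; brain NCA is computed on that pooled profile and
reported as a point estimate without a standard deviation, because with one
observation per animal no subject-level AUC distribution exists.
Bailer-type variance approximations for sparse AUCs are out of scope.
Since brain sampling starts at 30 min rather than 0, the pooled brain AUC
covers 30–480 min; the %DTE computed downstream inherits that window.

## Targeting indices

For a nasally dosed formulation with brain AUC B and plasma AUC P, and an
intravenous reference with brain:plasma ratio R:

* %DTE = (B/P)/R × 100 — total brain exposure relative to what the same
  systemic exposure would give intravenously;
* Bₓ = R·P — the brain exposure explained by systemic distribution;
* %DTP = (B − Bₓ)/B × 100 — the share of brain exposure attributed to
  direct nose-to-brain transport.

Only the ratio R is identifiable in these formulas, so the reference is
stored as a ratio, with a constructor from the i.v. AUC pair. When the
i.v. AUCs live in an earlier publication but one formulation's %DTE is
known, `calibrate_iv_ratio()` inverts the %DTE formula; the bundled
case-study table calibrates to R = 0.3536 from its first column, and that
single ratio reproduces the other three formulations' printed %DTE and
%DTP within ±0.15. The algebraic identity %DTP = 100 − 10⁴/%DTE holds for
every computed pair and is asserted property-style in the tests. Brain AUC
is per gram of tissue and plasma AUC per mL; their quotient is used as
printed, with no density correction, matching the source arithmetic.

## Group comparisons

One-way ANOVA is delegated to `stats::aov`, with the degenerate
all-identical case reported as F = 0, p = 1. Tukey HSD uses the
studentized-range distribution with the Tukey–Kramer standard error for
unequal group sizes. The Wilcoxon rank-sum test enumerates the permutation
null of the mid-rank statistic exactly for combined n ≤ 20 — exact p-values
remain available with ties, which `stats::wilcox.test` does not provide —
and falls back to the tie-corrected normal approximation with continuity
correction otherwise. All tests are two-sided at α = 0.05 by default.

## The synthetic-data generator

The generator exists so the full pipeline is exercisable without any raw
in-vivo data, which the source study does not publish. `simulate_rsm()`
adds Gaussian replicate noise to a known polynomial on a design.
`simulate_pk_study()` draws one-compartment extravascular subjects,

C(t) = c₀ · ka/(ka − ke) · (e^(−ke·t) − e^(−ka·t)),

with lognormal between-subject variability on ka, ke, c₀ and proportional
residual error, on the study schedules: plasma at predose and 5–600 min,
destructive brain sampling at 30/60/120/240/480 min with 4 animals per
point. Default typical values (ka = 0.05/min, ke = 0.006/min,
c₀ = 1.2 µg/mL, brain:plasma partition 1.45, BSV CV 25%, residual CV 10%)
put plasma Tmax near 45 min, plasma Cmax near 0.9 µg/mL and brain Cmax
near 1.3 µg/g — the concentration and time scales of the rat study this
package's defaults emulate. These were fixed once from the study's summary
statistics and are not tuning knobs.

What the generator deliberately does not emulate: direct nose-to-brain
transport kinetics (brain is a fixed partition of plasma, so simulated
%DTE reflects the partition and sampling windows, not olfactory-pathway
physiology), absorption transit chains, multiple-peak profiles, and
assay-specific BLQ patterns. Passing recovery tests therefore demonstrates
that the estimators are unbiased for data with the assumed structure; they
say nothing about model misspecification in real profiles.

`recovery_experiment()` wraps the simulate–analyze loop and reports bias,
RMSE and Monte-Carlo standard errors; the test suite runs it at 200
replicates for coefficient recovery (noise SD 20 nm, the replicate
pure-error scale of the case-study table) and 100 replicates for AUC
recovery, sizes chosen to keep the default suite under a minute for these
blocks while leaving Monte-Carlo error well below the asserted bounds.

## Numerical notes and known limitations

* Case-study natural levels are snapped to canonical codes before fitting;
  with snapping disabled the coefficients differ in the first decimal,
  which is exactly the discrepancy the snap exists to remove.
* The published ANOVA's HPMC partial SS (3.9977×10⁵) disagrees in its 5th
  significant figure with the value implied by its own printed coefficient
  (171.08² × 13.657 = 3.9972×10⁵); the package reproduces the latter, and
  the test tolerance for that single cell is 2×10⁻⁴ relative.
* The published stability narrative claims all %-bias values stay below 5%,
  but the tabulated gel %-yield series reaches −5.13% at day 45; the
  bundled table reproduces the numbers, and `stability_assess()` reports
  what they imply.
* Percent yield is computed as pellet/total × 100 (recovery); the
  complementary loss-fraction form is available via `as_printed = TRUE`.
* Exact Wilcoxon enumeration is limited to combined n ≤ 25
  (`choose(25, 12)` ≈ 5×10⁶ assignments); beyond that the approximation is
  used automatically.
* The optimization region, like the model itself, is in coded units; users
  supplying natural-unit constraints must code them first.
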