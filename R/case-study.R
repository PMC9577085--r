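# Bundled worked case study: optimization and nasal PK of rufinamide
# nanocrystals. Small published summary tables, shipped as constructors so
# the examples, tests and reproduction script run without external files.

#' Factors of the rufinamide nanocrystal CCD case study
#'
#' HPMC concentration 0.1-2.0 % w/v, ultrasonication time 5-15 min,
#' processing temperature 5-15 degC; rotatable axial distance
#' `alpha = 2^(3/4)` with the bounds mapped to the axial levels
#' (inscribed convention).
#'
#' @return List of three [doe_factor()] objects.
#' @export
rufi_ccd_factors <- function() {
  a <- 2^(3 / 4)
  list(doe_factor_from_bounds("hpmc", 0.1, 2.0, alpha = a, units = "% w/v"),
       doe_factor_from_bounds("sonication", 5, 15, alpha = a, units = "min"),
       doe_factor_from_bounds("temperature", 5, 15, alpha = a, units = "degC"))
}

#' CCD run table of the rufinamide nanocrystal case study
#'
#' The 20-run inscribed CCD (8 factorial + 6 axial + 6 center runs) with
#' the mean particle size measured in each run, in standard order. Natural
#' levels are as printed in the study report (2-3 significant figures), so
#' recoding them to the canonical coded scale requires level snapping
#' (see [to_coded()]).
#'
#' @return data.frame with columns `std_order`, `hpmc` (% w/v),
#'   `sonication` (min), `temperature` (degC), `particle_size` (nm).
#' @export
rufi_ccd_table <- function() {
  data.frame(
    std_order = 1:20,
    hpmc = c(0.48, 1.61, 0.48, 1.61, 0.48, 1.61, 0.48, 1.61,
             0.1, 2, rep(1.05, 10)),
    sonication = c(7.0, 7.0, 12.9, 12.9, 7.0, 7.02, 12.9, 12.9,
                   10, 10, 5, 15, rep(10, 8)),
    temperature = c(7.0, 7.0, 7.0, 7.0, 12.9, 12.9, 12.9, 12.9,
                    10, 10, 10, 10, 5, 15, rep(10, 6)),
    particle_size = c(299, 601.2, 256.8, 583.3, 314, 595.8, 261.5, 550.7,
                      234.1, 910, 480.9, 383.3, 475.8, 449.3, 474.2, 444.8,
                      518.8, 500.3, 510.9, 468.5)
  )
}

#' Case-study CCD recoded onto the canonical coded scale
#'
#' @param snap_tolerance passed to [to_coded()] via
#'   [design_from_natural()].
#' @return A `doe_design` for the 20 case-study runs.
#' @export
rufi_ccd_design <- function(snap_tolerance = 0.03) {
  tab <- rufi_ccd_table()
  design_from_natural(rufi_ccd_factors(),
                      tab[, c("hpmc", "sonication", "temperature")],
                      snap_tolerance = snap_tolerance)
}

#' Reduced particle-size model terms of the case study
#'
#' Intercept, linear HPMC, linear ultrasonication time and quadratic
#' ultrasonication time: the terms surviving hierarchy-preserving backward
#' elimination on the case-study responses.
#'
#' @return List of term specs.
#' @export
rufi_reduced_terms <- function() {
  list(term_intercept(), term_linear(1), term_linear(2), term_quadratic(2))
}

#' Published AUC summaries of the four nasal formulations
#'
#' Brain (min*ug/g, pooled destructive sampling, single values) and plasma
#' (min*ug/mL, mean of n = 4) AUC0-tlast after 1 mg/kg intranasal dosing,
#' for the nanocrystal suspension (NC-Susp), nanocrystal in situ gel
#' (NC-RXG), plain-drug suspension (Susp) and plain-drug in situ gel
#' (RXG), with the %DTE/%DTP values reported alongside them.
#'
#' @return data.frame with columns `name`, `brain_auc`, `plasma_auc`,
#'   `dte_reported`, `dtp_reported`.
#' @export
rufi_formulation_auc <- function() {
  data.frame(
    name = c("Rufi-NC-Susp", "Rufi-NC-RXG", "Rufi-Susp", "Rufi-RXG"),
    brain_auc = c(340.7, 471.3, 104.28, 201.8),
    plasma_auc = c(258.2, 192.3, 200.75, 53.34),
    dte_reported = c(373.16, 693.1, 146.8, 1069.9),
    dtp_reported = c(73.3, 85.5, 31.9, 90.6),
    stringsAsFactors = FALSE
  )
}

#' Stability series of the case-study formulations
#'
#' Particle size (nm) and % yield of the freeze-dried nanocrystals stored
#' at 25 degC / 60% RH and of the nanocrystal in situ gel stored
#' refrigerated, sampled every 15 days to day 60 (means of n = 3).
#'
#' @return data.frame with columns `formulation`, `parameter`, `day`,
#'   `value`.
#' @export
rufi_stability_table <- function() {
  days <- c(0, 15, 30, 45, 60)
  rbind(
    data.frame(formulation = "Rufi-NC", parameter = "particle_size",
               day = days, value = c(244, 243, 244, 254, 255)),
    data.frame(formulation = "Rufi-NC", parameter = "percent_yield",
               day = days, value = c(87.3, 86.3, 85.6, 83.6, 83)),
    data.frame(formulation = "Rufi-NC-RXG", parameter = "particle_size",
               day = days, value = c(248, 243, 244, 239, 253)),
    data.frame(formulation = "Rufi-NC-RXG", parameter = "percent_yield",
               day = days, value = c(89.6, 86, 87.6, 85, 85.3))
  )
}
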