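# Shared fixtures, built in code.

ccd3 <- function(n_center = 6) make_inscribed_ccd(list(
  list(name = "hpmc", low = 0.1, high = 2.0, units = "% w/v"),
  list(name = "sonication", low = 5, high = 15, units = "min"),
  list(name = "temperature", low = 5, high = 15, units = "degC")),
  n_center = n_center)

reduced_fit <- function() {
  rsm_fit(rufi_ccd_design(), rufi_ccd_table()$particle_size,
          rufi_reduced_terms())
}

anova_row <- function(fit, source) {
  fit$anova[fit$anova$source == source, , drop = FALSE]
}
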