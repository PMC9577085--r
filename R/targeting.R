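#' Per-formulation AUC pair for targeting indices
#'
#' @param name formulation label.
#' @param brain_auc brain AUC0-tlast, min*ug/g (nasal route).
#' @param plasma_auc plasma/blood AUC0-tlast, min*ug/mL (nasal route).
#' @return An object of class `formulation_pk`.
#' @export
formulation_pk <- function(name, brain_auc, plasma_auc) {
  if (!is.finite(brain_auc) || brain_auc <= 0 ||
      !is.finite(plasma_auc) || plasma_auc <= 0)
    stop("AUCs must be positive and finite", call. = FALSE)
  structure(list(name = as.character(name), brain_auc = brain_auc,
                 plasma_auc = plasma_auc), class = "formulation_pk")
}

#' Intravenous reference ratio for targeting indices
#'
#' Only the brain:plasma AUC ratio after intravenous dosing is identifiable
#' in the index formulas, so the reference is stored as a ratio; a
#' constructor from the AUC pair is provided.
#'
#' @param ratio brain:plasma AUC ratio after i.v. dosing (> 0).
#' @param brain_auc,plasma_auc alternatively, the i.v. AUC pair from which
#'   the ratio is derived.
#' @return An object of class `iv_reference`.
#' @export
iv_reference <- function(ratio = NULL, brain_auc = NULL, plasma_auc = NULL) {
  if (is.null(ratio)) {
    if (is.null(brain_auc) || is.null(plasma_auc))
      stop("give 'ratio' or both i.v. AUCs", call. = FALSE)
    if (plasma_auc <= 0 || brain_auc <= 0)
      stop("i.v. AUCs must be positive", call. = FALSE)
    ratio <- brain_auc / plasma_auc
  }
  if (!is.finite(ratio) || ratio <= 0)
    stop("'ratio' must be positive and finite", call. = FALSE)
  structure(list(ratio = ratio), class = "iv_reference")
}

#' Direct transport efficiency (%DTE)
#'
#' The nasal brain:plasma AUC ratio relative to the intravenous reference
#' ratio, as a percentage:
#' `%DTE = ((brain/plasma)_i.n. / (brain/plasma)_i.v.) * 100`.
#' 100 means the nasal formulation partitions into brain exactly as an
#' i.v. dose does; larger values indicate direct nose-to-brain transport.
#'
#' @param f a [formulation_pk()].
#' @param iv an [iv_reference()].
#' @return %DTE (numeric scalar).
#' @export
dte <- function(f, iv) {
  stopifnot(inherits(f, "formulation_pk"), inherits(iv, "iv_reference"))
  (f$brain_auc / f$plasma_auc) / iv$ratio * 100
}

#' Direct transport percentage (%DTP) and companion indices
#'
#' `Bx = ratio_i.v. * plasma_auc` estimates the brain exposure explained by
#' systemic-to-brain distribution; `%DTP = (brain_auc - Bx)/brain_auc * 100`
#' is the share of brain exposure attributed to direct nose-to-brain
#' transport. Satisfies the identity `%DTP = 100 - 10000/%DTE`.
#'
#' @inheritParams dte
#' @return An object of class `targeting_indices`: list with
#'   `dte_percent`, `dtp_percent`, `bx`.
#' @export
dtp <- function(f, iv) {
  stopifnot(inherits(f, "formulation_pk"), inherits(iv, "iv_reference"))
  bx <- iv$ratio * f$plasma_auc
  structure(list(name = f$name,
                 dte_percent = dte(f, iv),
                 dtp_percent = (f$brain_auc - bx) / f$brain_auc * 100,
                 bx = bx),
            class = "targeting_indices")
}

#' @export
print.targeting_indices <- function(x, ...) {
  cat(sprintf("%s: %%DTE %.1f | %%DTP %.1f | Bx %.4g min*ug/g\n",
              x$name, x$dte_percent, x$dtp_percent, x$bx))
  invisible(x)
}

#' Calibrate the i.v. reference ratio from a known %DTE
#'
#' When the intravenous AUCs are published elsewhere but a formulation's
#' %DTE is known, the reference ratio follows by inverting the %DTE
#' formula: `ratio = (brain/plasma)_i.n. / (%DTE/100)`. Round-trips through
#' [dte()] exactly.
#'
#' @param f a [formulation_pk()].
#' @param known_dte_percent the published %DTE of `f` (> 0).
#' @return An [iv_reference()].
#' @export
calibrate_iv_ratio <- function(f, known_dte_percent) {
  stopifnot(inherits(f, "formulation_pk"))
  if (!is.finite(known_dte_percent) || known_dte_percent <= 0)
    stop("'known_dte_percent' must be > 0", call. = FALSE)
  iv_reference(ratio = (f$brain_auc / f$plasma_auc) / (known_dte_percent / 100))
}
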