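#' Construct a concentration-time profile
#'
#' @param subject_id subject label.
#' @param matrix `"plasma"` or `"brain"`.
#' @param times sampling times in minutes, strictly increasing, first >= 0.
#' @param conc concentrations (ug/mL for plasma, ug/g for brain),
#'   non-negative.
#' @param blq logical flags, TRUE where the measurement is below the limit
#'   of quantification.
#' @param dose dose in mg/kg (informational).
#' @param pooled TRUE when the profile is a pooled mean of destructive
#'   samples (see [pool_destructive()]).
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, matrix = c("plasma", "brain"),
                         times, conc, blq = rep(FALSE, length(times)),
                         dose = NA_real_, pooled = FALSE) {
  matrix <- match.arg(matrix)
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc) || length(blq) != length(times))
    stop("'times', 'conc' and 'blq' must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (times[1] < 0) stop("first time must be >= 0", call. = FALSE)
  if (any(conc < 0 & !blq)) stop("quantifiable concentrations must be >= 0",
                                 call. = FALSE)
  structure(list(subject_id = as.character(subject_id), matrix = matrix,
                 dose = dose, times = times, conc = conc,
                 blq = as.logical(blq), pooled = pooled),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: subject %s, %s%s, %d points (%g-%g min)\n",
              x$subject_id, x$matrix, if (x$pooled) " (pooled)" else "",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Non-compartmental analysis of a single profile
#'
#' Computes Cmax, Tmax (earliest time attaining the maximum), AUC and AUMC
#' from the first sampled time to tlast (the last quantifiable point) by the
#' linear trapezoid rule on `C(t)` and `t*C(t)`, and `MRT = AUMC/AUC`.
#'
#' BLQ handling: points flagged BLQ before the first quantifiable point are
#' set to 0 and retained; BLQ points after tlast are excluded; embedded BLQ
#' points are treated as 0. If `t = 0` is not sampled, the pre-dose
#' concentration is assumed 0 for extravascular profiles and the profile is
#' left as given (no extrapolation is performed; AUC is from the first
#' sampled time).
#'
#' No extrapolation to infinity and no terminal-slope estimation is done:
#' AUC and MRT are the to-tlast quantities.
#'
#' @param profile a [conc_profile()].
#' @return An object of class `nca_result`: list with `cmax`, `tmax`,
#'   `tlast`, `auc_last`, `aumc_last`, `mrt`, and the units-bearing
#'   `matrix` tag.
#' @examples
#' p <- conc_profile("r1", "plasma", times = c(0, 60, 120),
#'                   conc = c(0, 1, 0))
#' nca(p)$auc_last  # triangle: 60
#' @export
nca <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  t <- profile$times; c_ <- profile$conc; blq <- profile$blq
  if (!any(!blq)) stop("all points are BLQ: no data", call. = FALSE)
  ilast <- max(which(!blq))
  keep <- seq_len(ilast)
  t <- t[keep]; c_ <- c_[keep]; blq <- blq[keep]
  c_[blq] <- 0
  if (length(t) < 2L) stop("need >= 2 points up to tlast", call. = FALSE)
  auc <- trapz(t, c_)
  aumc <- trapz(t, t * c_)
  cmax <- max(c_)
  tmax <- t[which.max(c_)]  # which.max takes the earliest maximum
  if (auc <= 0) stop("AUC to tlast is 0: MRT undefined", call. = FALSE)
  structure(list(cmax = cmax, tmax = tmax, tlast = t[length(t)],
                 auc_last = auc, aumc_last = aumc, mrt = aumc / auc,
                 matrix = profile$matrix, subject_id = profile$subject_id),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(paste0("NCA (%s, subject %s): Cmax %.4g, Tmax %g min, ",
                     "AUC0-tlast %.4g, MRT %.4g min\n"),
              x$matrix, x$subject_id, x$cmax, x$tmax, x$auc_last, x$mrt))
  invisible(x)
}

#' Pool destructive (sparse) samples into a mean profile
#'
#' Destructive sampling contributes one observation per animal: each time
#' point has its own group of subjects. The pooled profile is the mean
#' concentration per time, tagged `pooled`, with per-time `n` and SD kept
#' as metadata. Downstream NCA on the pooled profile yields point estimates
#' without a standard deviation.
#'
#' @param samples list, one element per time point, each a list with `time`
#'   (minutes) and `conc` (numeric vector of per-subject concentrations).
#' @param matrix matrix label, default `"brain"`.
#' @param dose dose in mg/kg.
#' @return A pooled [conc_profile()] with attributes `n` and `sd`
#'   (per-time vectors).
#' @export
pool_destructive <- function(samples, matrix = "brain", dose = NA_real_) {
  times <- vapply(samples, function(s) as.numeric(s$time), 0)
  if (anyDuplicated(times)) stop("duplicate time groups", call. = FALSE)
  if (any(vapply(samples, function(s) length(s$conc) < 1L, NA)))
    stop("each time needs >= 1 concentration", call. = FALSE)
  ord <- order(times)
  means <- vapply(samples, function(s) mean(s$conc), 0)[ord]
  ns <- vapply(samples, function(s) length(s$conc), 0L)[ord]
  sds <- vapply(samples, function(s) stats::sd(s$conc), 0)[ord]
  prof <- conc_profile("pooled", matrix, times[ord], means, dose = dose,
                       pooled = TRUE)
  attr(prof, "n") <- ns
  attr(prof, "sd") <- sds
  prof
}

#' Summarize NCA parameters over an arm (mean +/- SD)
#'
#' Runs [nca()] per subject and reports mean and SD of each parameter.
#' Tmax, conventionally reported as a median-like statistic, is given as a
#' range string (`"30-45"`) when subjects differ and the single value when
#' they agree.
#'
#' @param profiles list of [conc_profile()] objects sharing one matrix.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `label`
#'   (formatted `mean +/- sd`, or the range for Tmax) and attribute
#'   `n` (number of subjects).
#' @export
summarize_arm <- function(profiles) {
  if (!length(profiles)) stop("need >= 1 profile", call. = FALSE)
  mats <- unique(vapply(profiles, `[[`, "", "matrix"))
  if (length(mats) != 1L) stop("profiles must share one matrix", call. = FALSE)
  results <- lapply(profiles, nca)
  pars <- c("cmax", "tmax", "auc_last", "aumc_last", "mrt")
  vals <- vapply(results, function(r) unlist(r[pars]), numeric(length(pars)))
  vals <- matrix(vals, nrow = length(pars),
                 dimnames = list(pars, NULL))
  means <- rowMeans(vals)
  sds <- apply(vals, 1L, stats::sd)
  label <- sprintf("%.4g ± %.4g", means, sds)
  tmaxes <- vals["tmax", ]
  label[pars == "tmax"] <- if (min(tmaxes) == max(tmaxes))
    sprintf("%g", tmaxes[1]) else sprintf("%g-%g", min(tmaxes), max(tmaxes))
  out <- data.frame(parameter = pars, mean = means, sd = sds, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- length(profiles)
  attr(out, "matrix") <- mats
  out
}
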