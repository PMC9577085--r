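#' Percent yield of a nanocrystal batch
#'
#' The fraction of drug recovered in the pellet after centrifugation:
#' `w_pellet / w_total * 100`. Set `as_printed = TRUE` for the loss-fraction
#' form `(w_total - w_pellet)/w_total * 100`, i.e. 100 minus the yield.
#'
#' @param w_total total drug added, mg (> 0).
#' @param w_pellet drug recovered in the pellet, mg, in `[0, w_total]`.
#' @param as_printed report the loss fraction instead of the recovery.
#' @return Percentage in `[0, 100]`.
#' @export
percent_yield <- function(w_total, w_pellet, as_printed = FALSE) {
  if (!is.finite(w_total) || w_total <= 0)
    stop("'w_total' must be > 0", call. = FALSE)
  if (!is.finite(w_pellet) || w_pellet < 0 || w_pellet > w_total)
    stop("'w_pellet' must be in [0, w_total]", call. = FALSE)
  if (as_printed) (w_total - w_pellet) / w_total * 100
  else w_pellet / w_total * 100
}

#' Percent relative standard deviation
#'
#' Sample (n-1) standard deviation over the mean, as a percentage. Used for
#' dosing-precision assessment.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return %RSD (scalar).
#' @examples
#' percent_rsd(c(9, 10, 11))  # 10
#' @export
percent_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: %RSD undefined", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Construct a stability series
#'
#' @param parameter name of the monitored parameter.
#' @param days sampling days, non-negative, increasing; day 0 is the
#'   baseline.
#' @param values measured values; the first (day-0) value is the baseline.
#' @return An object of class `stability_series`.
#' @export
stability_series <- function(parameter, days, values) {
  days <- as.numeric(days); values <- as.numeric(values)
  if (length(days) != length(values)) stop("length mismatch", call. = FALSE)
  if (any(days < 0) || any(diff(days) <= 0))
    stop("'days' must be non-negative increasing", call. = FALSE)
  if (values[1] <= 0) stop("baseline must be > 0", call. = FALSE)
  structure(list(parameter = parameter, days = days, values = values,
                 baseline = values[1]), class = "stability_series")
}

#' Assess a stability series against a %-bias threshold
#'
#' Bias at each time point is `(value - baseline)/baseline * 100` with the
#' day-0 value as baseline; the series passes when every `|bias|` is below
#' the threshold.
#'
#' @param s a [stability_series()].
#' @param bias_threshold_percent maximum tolerated absolute %-bias
#'   (default 5).
#' @return data.frame with `day`, `value`, `bias_percent`, `within`, plus
#'   attributes `pass` (logical) and `max_abs_bias`.
#' @export
stability_assess <- function(s, bias_threshold_percent = 5) {
  stopifnot(inherits(s, "stability_series"))
  bias <- (s$values - s$baseline) / s$baseline * 100
  within <- abs(bias) < bias_threshold_percent
  out <- data.frame(day = s$days, value = s$values, bias_percent = bias,
                    within = within)
  attr(out, "pass") <- all(within)
  attr(out, "max_abs_bias") <- max(abs(bias))
  attr(out, "parameter") <- s$parameter
  out
}
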