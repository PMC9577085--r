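#' Define an experimental factor with its coding transform
#'
#' A factor is described by its natural-unit center, the step per coded unit,
#' and the axial distance `alpha`. The coding transform is
#' `coded = (natural - center) / step`, so `natural(0) == center` and
#' `natural(+/-alpha)` are the extreme levels of an inscribed design.
#'
#' @param name factor name.
#' @param center natural-unit value at coded zero.
#' @param step natural units per coded unit; must be > 0.
#' @param alpha axial distance in coded units; must be > 1.
#' @param units unit label (informational).
#' @return An object of class `doe_factor`.
#' @examples
#' doe_factor("HPMC", center = 1.05, step = 0.5649, alpha = 2^(3/4), units = "% w/v")
#' @export
doe_factor <- function(name, center, step, alpha = 2^(3/4), units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(center) || !is.finite(step) || !is.finite(alpha))
    stop("factor parameters must be finite", call. = FALSE)
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (alpha <= 1) stop("'alpha' must be > 1", call. = FALSE)
  structure(list(name = name, units = units, center = center,
                 step = step, alpha = alpha),
            class = "doe_factor")
}

#' Build a factor from natural-unit bounds (inscribed convention)
#'
#' Maps the bounds `[low, high]` to coded `+/-alpha`, so the factorial levels
#' `+/-1` lie strictly inside the bounds: `center = (low + high)/2` and
#' `step = (high - low) / (2 * alpha)`.
#'
#' @inheritParams doe_factor
#' @param low,high natural-unit bounds, `low < high`.
#' @return A `doe_factor`.
#' @export
doe_factor_from_bounds <- function(name, low, high, alpha = 2^(3/4), units = "") {
  if (!is.finite(low) || !is.finite(high))
    stop("bounds must be finite", call. = FALSE)
  if (low >= high) stop("'low' must be < 'high'", call. = FALSE)
  doe_factor(name, center = (low + high) / 2, step = (high - low) / (2 * alpha),
             alpha = alpha, units = units)
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: center %g, step %g, alpha %g\n",
              x$name, x$units, x$center, x$step, x$alpha))
  invisible(x)
}

canonical_levels <- function(alpha) c(-alpha, -1, 0, 1, alpha)

#' Convert a natural level to the coded scale
#'
#' Computes `(natural - center) / step` and, when the raw code lies within
#' `snap_tolerance` (relative) of a canonical level in `{0, +/-1, +/-alpha}`,
#' returns the canonical level exactly. Snapping makes rounded published
#' design tables recode to the exact design the software generated.
#'
#' @param factor a [doe_factor()].
#' @param natural natural-unit value(s).
#' @param snap_tolerance relative tolerance for snapping to a canonical
#'   level; `0` disables snapping. Default 0.03, wide enough to absorb the
#'   2-3 significant figures typical of printed design tables yet far below
#'   the gap between adjacent canonical levels.
#' @return Coded value(s).
#' @export
to_coded <- function(factor, natural, snap_tolerance = 0.03) {
  stopifnot(inherits(factor, "doe_factor"))
  if (snap_tolerance < 0) stop("'snap_tolerance' must be >= 0", call. = FALSE)
  if (factor$step == 0) stop("'step' must be non-zero", call. = FALSE)
  raw <- (natural - factor$center) / factor$step
  if (snap_tolerance > 0) {
    for (lev in canonical_levels(factor$alpha)) {
      hit <- abs(raw - lev) <= snap_tolerance * max(abs(lev), 1)
      raw[hit] <- lev
    }
  }
  raw
}

#' Convert a coded level to natural units
#'
#' Inverse of the un-snapped [to_coded()]: `center + step * coded`.
#'
#' @param factor a [doe_factor()].
#' @param coded coded value(s).
#' @return Natural-unit value(s).
#' @export
to_natural <- function(factor, coded) {
  stopifnot(inherits(factor, "doe_factor"))
  factor$center + factor$step * coded
}

new_doe_design <- function(factors, coded, point_type, design_type) {
  k <- length(factors)
  coded <- as.matrix(coded)
  colnames(coded) <- vapply(factors, `[[`, "", "name")
  natural <- coded
  for (j in seq_len(k)) natural[, j] <- to_natural(factors[[j]], coded[, j])
  key <- apply(coded, 1L, function(r) paste(format(r, digits = 12), collapse = "|"))
  structure(list(
    factors = factors,
    std_order = seq_len(nrow(coded)),
    point_type = point_type,
    coded = coded,
    natural = natural,
    replicate_group = match(key, unique(key)),
    design_type = design_type
  ), class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs, %d factors (%s)\n", x$design_type,
              nrow(x$coded), length(x$factors),
              paste(colnames(x$coded), collapse = ", ")))
  df <- data.frame(std_order = x$std_order, point_type = x$point_type,
                   round(x$natural, 4), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Number of runs in a design
#' @param design a `doe_design`.
#' @return Integer run count.
#' @export
n_runs <- function(design) nrow(design$coded)

#' Construct an inscribed central composite design
#'
#' Builds the standard CCD for `k >= 2` factors: the `2^k` factorial corners
#' in Yates order, then `2k` axial pairs in factor order (low then high),
#' then `n_center` center replicates. "Inscribed" means the user's natural
#' bounds map to the axial levels `+/-alpha`, so the factorial corners are
#' interior points of the experimental region.
#'
#' @param factors a list, one element per factor, each a list or vector with
#'   `name`, `low`, `high` and optionally `units`.
#' @param n_center number of center replicates appended last.
#' @param alpha axial distance in coded units, or `"rotatable"` for
#'   `2^(k/4)`.
#' @return A `doe_design` with coded and natural levels and replicate groups.
#' @examples
#' des <- make_inscribed_ccd(list(
#'   list(name = "HPMC", low = 0.1, high = 2.0, units = "% w/v"),
#'   list(name = "sonication", low = 5, high = 15, units = "min"),
#'   list(name = "temperature", low = 5, high = 15, units = "degC")),
#'   n_center = 6)
#' n_runs(des)  # 20
#' @export
make_inscribed_ccd <- function(factors, n_center = 6L, alpha = "rotatable") {
  k <- length(factors)
  if (k < 2L) stop("need at least 2 factors", call. = FALSE)
  if (k > 12L) stop("more than 12 factors: factorial enumeration refused",
                    call. = FALSE)
  if (n_center < 0L) stop("'n_center' must be >= 0", call. = FALSE)
  if (identical(alpha, "rotatable")) alpha <- 2^(k / 4)
  if (!is.numeric(alpha) || alpha <= 1)
    stop("'alpha' must be numeric > 1 or \"rotatable\"", call. = FALSE)

  facs <- lapply(factors, function(f) {
    f <- as.list(f)
    doe_factor_from_bounds(f$name, as.numeric(f$low), as.numeric(f$high),
                           alpha = alpha,
                           units = if (is.null(f$units)) "" else f$units)
  })

  # Yates order: first factor alternates fastest
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, center)
  point_type <- c(rep("factorial", 2^k), rep("axial", 2L * k),
                  rep("center", n_center))
  new_doe_design(facs, coded, point_type, "inscribed CCD")
}

# Standard N=12 Plackett-Burman generator row (first rows cycle this).
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Construct a 12-run Plackett-Burman screening design
#'
#' Builds the two-level 12-run design by cyclic rotation of the standard
#' 11-element generator row, plus the closing all-minus row. The first
#' `n_factors` columns carry the real factors; the rest are retained as
#' dummy columns (named `dummy1`, ...) for error estimation.
#'
#' @param n_factors number of real factors, between 2 and 11.
#' @param n_center number of center-point runs appended last.
#' @param factor_names optional character vector of length `n_factors`.
#' @return A `doe_design` whose coded matrix has 11 columns
#'   (real + dummy) and `12 + n_center` runs.
#' @export
make_plackett_burman <- function(n_factors, n_center = 0L, factor_names = NULL) {
  if (n_factors < 2L || n_factors > 11L)
    stop("'n_factors' must be between 2 and 11", call. = FALSE)
  if (n_center < 0L) stop("'n_center' must be >= 0", call. = FALSE)
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(n_factors))
  stopifnot(length(factor_names) == n_factors)

  rows <- lapply(0:10, function(s) pb12_generator[((0:10 + s) %% 11L) + 1L])
  m <- rbind(do.call(rbind, rows), rep(-1, 11L))
  coded <- rbind(m, matrix(0, n_center, 11L))
  nm <- c(factor_names,
          if (n_factors < 11L) paste0("dummy", seq_len(11L - n_factors)))
  facs <- lapply(nm, function(n)
    doe_factor(n, center = 0, step = 1, alpha = 1.0001))
  point_type <- c(rep("screening", 12L), rep("center", n_center))
  des <- new_doe_design(facs, coded, point_type, "Plackett-Burman")
  colnames(des$coded) <- colnames(des$natural) <- nm
  des$n_real_factors <- n_factors
  des
}

#' Recode a published design table onto the canonical coded scale
#'
#' Given natural-unit columns (possibly rounded for print), recodes each
#' factor with [to_coded()] and rebuilds a `doe_design` with replicate
#' groups. Point types are inferred from the snapped coded rows.
#'
#' @param factors list of [doe_factor()] objects.
#' @param natural matrix or data.frame of natural levels, one column per
#'   factor, one row per run in standard order.
#' @param snap_tolerance passed to [to_coded()].
#' @return A `doe_design`.
#' @export
design_from_natural <- function(factors, natural, snap_tolerance = 0.03) {
  natural <- as.matrix(natural)
  stopifnot(ncol(natural) == length(factors))
  coded <- natural
  for (j in seq_along(factors))
    coded[, j] <- to_coded(factors[[j]], natural[, j], snap_tolerance)
  point_type <- apply(coded, 1L, function(r) {
    if (all(r == 0)) "center"
    else if (all(abs(r) == 1)) "factorial"
    else if (sum(r != 0) == 1L) "axial"
    else "other"
  })
  new_doe_design(factors, coded, point_type, "recoded")
}
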