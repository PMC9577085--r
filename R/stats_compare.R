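#' One-way analysis of variance over groups
#'
#' Classic fixed-effects one-way ANOVA via [stats::aov()]. The degenerate
#' case of identical group means with zero within-group variance is
#' reported as `F = 0, p = 1` rather than `NaN`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations), or a data.frame with columns `group` and `value`.
#' @return List with `F`, `df_between`, `df_within`, `p`, `ss_between`,
#'   `ss_within`, and the underlying `aov` fit (`NULL` in the degenerate
#'   case).
#' @export
one_way_anova <- function(groups) {
  g <- as_group_data(groups)
  df <- data.frame(value = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), lengths(g))))
  means <- vapply(g, mean, 0)
  grand <- mean(df$value)
  ss_b <- sum(lengths(g) * (means - grand)^2)
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df_b <- length(g) - 1L
  df_w <- nrow(df) - length(g)
  if (ss_w == 0 && ss_b == 0)
    return(list(F = 0, df_between = df_b, df_within = df_w, p = 1,
                ss_between = 0, ss_within = 0, fit = NULL))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L], df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L], p = tab[["Pr(>F)"]][1L],
       ss_between = tab[["Sum Sq"]][1L], ss_within = tab[["Sum Sq"]][2L],
       fit = fit)
}

as_group_data <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(as.numeric(groups$value), groups$group)
  }
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  lapply(groups, as.numeric)
}

#' Tukey HSD pairwise comparisons after one-way ANOVA
#'
#' Studentized-range comparisons of all group pairs, using the
#' Tukey-Kramer standard error for unequal group sizes:
#' `SE = sqrt(MSE/2 * (1/n_i + 1/n_j))`, `q = |diff|/SE`, with p from
#' [stats::ptukey()].
#'
#' @inheritParams one_way_anova
#' @param alpha family significance level (default 0.05).
#' @return data.frame with `pair`, `difference`, `se`, `q`, `p`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  g <- as_group_data(groups)
  k <- length(g)
  ns <- lengths(g)
  means <- vapply(g, mean, 0)
  df_w <- sum(ns) - k
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / df_w
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    d <- unname(means[j] - means[i])
    se <- unname(sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j])))
    q <- if (se == 0) ifelse(d == 0, 0, Inf) else abs(d) / se
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    c(d, se, q, p)
  })
  res <- matrix(res, nrow = 4L,
                dimnames = list(c("difference", "se", "q", "p"), NULL))
  out <- data.frame(pair = apply(pairs, 2L, function(ij)
    paste(names(g)[rev(ij)], collapse = " - ")),  # "b - a": mean(b) - mean(a)
    t(res), row.names = NULL)
  out$significant <- out$p < alpha
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test. In `"exact"` mode the permutation null of the
#' rank-sum statistic is enumerated over all `choose(n1+n2, n1)` group
#' assignments using mid-ranks for ties, so exact p-values are available
#' with tied data. In `"approximate"` mode the normal approximation with
#' tie correction and continuity correction is used. `"auto"` picks exact
#' for combined n <= 20.
#'
#' @param x,y numeric samples (each length >= 1).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return List with `W` (rank-sum of `x`), `U` (Mann-Whitney statistic of
#'   `x`), `p` (two-sided), `mode` (the mode actually used).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (mode == "auto") mode <- if (N <= 20L) "exact" else "approximate"
  r <- rank(c(x, y))  # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * (N + 1) / 2
  if (mode == "exact") {
    if (N > 25L) stop("exact enumeration limited to combined n <= 25",
                      call. = FALSE)
    sums <- utils::combn(N, n1, FUN = function(idx) sum(r[idx]))
    eps <- 1e-8
    p <- mean(abs(sums - mu) >= abs(W - mu) - eps)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    }
  }
  list(W = W, U = U, p = p, mode = mode)
}
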