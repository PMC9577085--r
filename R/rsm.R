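#' Term constructors for polynomial response-surface models
#'
#' A model is a list of term specifications: the intercept, linear terms,
#' two-factor interactions (`i < j`) and pure quadratics, evaluated on the
#' coded factor levels.
#'
#' @param i,j factor indices (1-based); for interactions `i < j`.
#' @return A term spec (list with `kind` and indices).
#' @export
term_intercept <- function() structure(list(kind = "intercept"), class = "rsm_term")

#' @rdname term_intercept
#' @export
term_linear <- function(i) structure(list(kind = "linear", i = as.integer(i)),
                                     class = "rsm_term")

#' @rdname term_intercept
#' @export
term_interaction <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (i >= j) stop("interaction requires i < j", call. = FALSE)
  structure(list(kind = "interaction", i = i, j = j), class = "rsm_term")
}

#' @rdname term_intercept
#' @export
term_quadratic <- function(i) structure(list(kind = "quadratic", i = as.integer(i)),
                                        class = "rsm_term")

#' Full quadratic term set for k factors
#'
#' Intercept, all linear terms, all two-factor interactions and all pure
#' quadratics: `1 + 2k + choose(k,2)` terms.
#'
#' @param k number of factors.
#' @return List of term specs.
#' @export
full_quadratic_terms <- function(k) {
  terms <- list(term_intercept())
  for (i in seq_len(k)) terms <- c(terms, list(term_linear(i)))
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    terms <- c(terms, list(term_interaction(i, j)))
  for (i in seq_len(k)) terms <- c(terms, list(term_quadratic(i)))
  terms
}

term_label <- function(term, names = NULL) {
  nm <- function(i) if (is.null(names)) paste0("x", i) else names[i]
  switch(term$kind,
         intercept = "(Intercept)",
         linear = nm(term$i),
         interaction = paste0(nm(term$i), ":", nm(term$j)),
         quadratic = paste0(nm(term$i), "^2"))
}

term_factors <- function(term) {
  switch(term$kind,
         intercept = integer(0),
         linear = term$i,
         interaction = c(term$i, term$j),
         quadratic = term$i)
}

# ordering used to break ties in backward elimination:
# linear < interaction < quadratic, then factor index
term_rank <- function(term) {
  kind_ord <- c(intercept = 0, linear = 1, interaction = 2, quadratic = 3)
  kind_ord[[term$kind]] * 100 + sum(term_factors(term))
}

eval_term <- function(term, coded) {
  switch(term$kind,
         intercept = rep(1, nrow(coded)),
         linear = coded[, term$i],
         interaction = coded[, term$i] * coded[, term$j],
         quadratic = coded[, term$i]^2)
}

#' Build the model matrix of a term list on a design's coded levels
#'
#' @param design a `doe_design` (or a coded matrix).
#' @param terms list of term specs (see [term_intercept()]).
#' @return Numeric matrix, one column per term, labelled by term.
#' @export
build_model_matrix <- function(design, terms) {
  coded <- if (inherits(design, "doe_design")) design$coded else as.matrix(design)
  labs <- vapply(terms, term_label, "", names = colnames(coded))
  if (anyDuplicated(labs)) stop("duplicate terms in model", call. = FALSE)
  k <- ncol(coded)
  bad <- vapply(terms, function(t) any(term_factors(t) > k), NA)
  if (any(bad)) stop("term index exceeds number of factors", call. = FALSE)
  X <- vapply(terms, eval_term, numeric(nrow(coded)), coded = coded)
  X <- matrix(X, nrow = nrow(coded), dimnames = list(NULL, labs))
  X
}

#' Fit a polynomial response-surface model by ordinary least squares
#'
#' Fits the given terms on the design's coded levels, then populates the
#' ANOVA table (with the lack-of-fit / pure-error partition taken from the
#' design's replicate groups) and the R-squared diagnostics.
#'
#' Per-term sums of squares are partial (Type III):
#' `SS_j = beta_j^2 / [(X'X)^-1]_jj`, tested against the residual mean
#' square. Pure error is the within-group sum of squares over replicate
#' groups; lack of fit is the remainder of the residual.
#'
#' @param design a `doe_design`.
#' @param response numeric response vector, one value per run, in the
#'   design's standard order.
#' @param terms list of term specs; defaults to the full quadratic.
#' @return An object of class `rsm_fit` with components `coefficients`
#'   (named, coded scale), `anova` (data.frame), `r2`, `adjusted_r2`,
#'   `predicted_r2`, `press`, `residuals`, `leverage`, `fitted`, plus the
#'   design, terms and model matrix.
#' @examples
#' dat <- rufi_ccd_table()
#' des <- rufi_ccd_design()
#' fit <- rsm_fit(des, dat$particle_size,
#'                list(term_intercept(), term_linear(1), term_linear(2),
#'                     term_quadratic(2)))
#' round(coef(fit), 2)
#' @export
rsm_fit <- function(design, response, terms = full_quadratic_terms(ncol(design$coded))) {
  stopifnot(inherits(design, "doe_design"))
  response <- as.numeric(response)
  n <- n_runs(design)
  if (length(response) != n)
    stop(sprintf("response length %d does not match %d runs",
                 length(response), n), call. = FALSE)
  X <- build_model_matrix(design, terms)
  p <- ncol(X)
  if (n <= p) stop("more terms than runs", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("model matrix is rank deficient; collinear terms: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, response)
  fitted <- drop(X %*% beta)
  res <- response - fitted
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  leverage <- rowSums((X %*% XtX_inv) * X)

  fit <- structure(list(
    design = design, terms = terms, response = response,
    model_matrix = X, coefficients = beta, fitted = fitted,
    residuals = res, leverage = leverage, XtX_inv = XtX_inv,
    df_residual = n - p
  ), class = "rsm_fit")
  fit$anova <- rsm_anova(fit)
  d <- r2_diagnostics(fit)
  fit[names(d)] <- d
  fit
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' ANOVA table with lack-of-fit partition for a response-surface fit
#'
#' @param fit an `rsm_fit`.
#' @return data.frame with columns `source`, `sum_of_squares`, `df`,
#'   `mean_square`, `F`, `p`. Sources are `model`, each non-intercept term,
#'   `residual`, `lack_of_fit`, `pure_error`, `total`. When no replicate
#'   group has size >= 2 the lack-of-fit and pure-error rows are `NA`
#'   (undefined), not zero.
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$response
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_mod <- ss_tot - ss_res
  p <- length(fit$coefficients)
  df_mod <- p - 1L
  df_res <- fit$df_residual
  ms_res <- ss_res / df_res

  grp <- fit$design$replicate_group
  sizes <- table(grp)
  has_reps <- any(sizes >= 2L)
  if (has_reps) {
    ss_pe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- sum(sizes - 1L)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
  } else {
    ss_pe <- df_pe <- ss_lof <- df_lof <- NA_real_
  }

  labs <- names(fit$coefficients)
  keep <- which(labs != "(Intercept)")
  term_ss <- fit$coefficients[keep]^2 / diag(fit$XtX_inv)[keep]
  term_F <- term_ss / ms_res
  term_p <- stats::pf(term_F, 1, df_res, lower.tail = FALSE)

  if (df_mod > 0 && ms_res > 0) {
    F_mod <- (ss_mod / df_mod) / ms_res
    p_mod <- stats::pf(F_mod, df_mod, df_res, lower.tail = FALSE)
  } else {
    F_mod <- p_mod <- NA_real_
  }
  if (has_reps && df_lof > 0 && df_pe > 0 && ss_pe > 0) {
    F_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p_lof <- stats::pf(F_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    F_lof <- p_lof <- NA_real_
  }

  data.frame(
    source = c("model", labs[keep], "residual", "lack_of_fit", "pure_error",
               "total"),
    sum_of_squares = c(ss_mod, term_ss, ss_res, ss_lof, ss_pe, ss_tot),
    df = c(df_mod, rep(1L, length(keep)), df_res, df_lof, df_pe, n - 1L),
    mean_square = c(ss_mod / df_mod, term_ss, ms_res,
                    if (has_reps && df_lof > 0) ss_lof / df_lof else NA_real_,
                    if (has_reps && df_pe > 0) ss_pe / df_pe else NA_real_,
                    NA_real_),
    F = c(F_mod, term_F, NA_real_, F_lof, NA_real_, NA_real_),
    p = c(p_mod, term_p, NA_real_, p_lof, NA_real_, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' R-squared diagnostics: R2, adjusted, PRESS and predicted R2
#'
#' `adjusted = 1 - (SSres/(n-p)) / (SStot/(n-1))`;
#' `PRESS = sum((e_i / (1 - h_i))^2)` (the leave-one-out prediction error
#' sum of squares via the hat-matrix identity); `predicted = 1 - PRESS/SStot`.
#'
#' @param fit an `rsm_fit`.
#' @return List with `r2`, `adjusted_r2`, `press`, `predicted_r2`.
#' @export
r2_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$response
  n <- length(y)
  p <- length(fit$coefficients)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  if (any(fit$leverage >= 1 - 1e-12))
    stop("a leverage equals 1: PRESS is undefined", call. = FALSE)
  press <- sum((fit$residuals / (1 - fit$leverage))^2)
  list(r2 = 1 - ss_res / ss_tot,
       adjusted_r2 = 1 - (ss_res / (n - p)) / (ss_tot / (n - 1)),
       press = press,
       predicted_r2 = 1 - press / ss_tot)
}

#' Format a p-value in reporting style
#'
#' Values below 1e-4 print as `"<0.0001"`, matching common DoE software.
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' @export
print.rsm_fit <- function(x, digits = 2, ...) {
  cat("Response-surface fit (coded factors)\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  a <- x$anova
  a$sum_of_squares <- signif(a$sum_of_squares, 6)
  a$mean_square <- signif(a$mean_square, 6)
  a$F <- round(a$F, 2)
  a$p <- format_p(a$p)
  cat("\nANOVA:\n"); print(a, row.names = FALSE)
  cat(sprintf("\nR2 %.4f | adjusted R2 %.4f | predicted R2 %.4f | PRESS %.2f\n",
              x$r2, x$adjusted_r2, x$predicted_r2, x$press))
  invisible(x)
}

#' Predict the response at coded points
#'
#' @param object an `rsm_fit`.
#' @param coded numeric vector (one point) or matrix (one row per point) of
#'   coded levels.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.rsm_fit <- function(object, coded, ...) {
  k <- ncol(object$design$coded)
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = k, byrow = TRUE)
  stopifnot(ncol(coded) == k)
  X <- build_model_matrix(coded, object$terms)
  drop(X %*% object$coefficients)
}

#' Backward elimination preserving model hierarchy
#'
#' Starting from `full_terms`, iteratively refits and drops the
#' non-intercept term with the largest p-value above `alpha_keep`. A term is
#' not droppable while a higher-order term containing all its factors
#' remains (a linear term stays while its quadratic or any interaction
#' involving it is in the model). Ties in p are broken by term order
#' (linear < interaction < quadratic, then factor index, later dropped
#' first).
#'
#' @param design a `doe_design`.
#' @param response numeric response vector.
#' @param full_terms starting term list; default full quadratic.
#' @param alpha_keep significance level below which a term is kept.
#' @return The final `rsm_fit`.
#' @export
reduce_model <- function(design, response,
                         full_terms = full_quadratic_terms(ncol(design$coded)),
                         alpha_keep = 0.05) {
  terms <- full_terms
  repeat {
    fit <- rsm_fit(design, response, terms)
    a <- fit$anova
    labs <- vapply(terms, term_label, "", names = colnames(design$coded))
    cand <- which(vapply(terms, function(t) t$kind != "intercept", NA))
    # hierarchy: a term is protected if a strictly-larger term contains it
    protected <- vapply(cand, function(ci) {
      fi <- term_factors(terms[[ci]])
      any(vapply(cand, function(cj) {
        if (cj == ci) return(FALSE)
        fj <- term_factors(terms[[cj]])
        ti <- terms[[ci]]; tj <- terms[[cj]]
        higher <- (ti$kind == "linear" && tj$kind != "linear")
        higher && all(fi %in% fj)
      }, NA))
    }, NA)
    droppable <- cand[!protected]
    if (!length(droppable)) break
    pvals <- a$p[match(labs[droppable], a$source)]
    over <- pvals > alpha_keep
    if (!any(over, na.rm = TRUE)) break
    dd <- droppable[over]
    pp <- pvals[over]
    ranks <- vapply(terms[dd], term_rank, 0)
    ord <- order(-pp, -ranks)
    terms <- terms[-dd[ord[1L]]]
  }
  fit
}

# --- Desirability optimization -------------------------------------------

derringer_suich <- function(y, goal, lo, hi, target = NULL, s = 1, t = 1) {
  switch(goal,
    minimize = {
      d <- ((hi - y) / (hi - lo))^s
      pmin(pmax(d, 0), 1)
    },
    maximize = {
      d <- ((y - lo) / (hi - lo))^s
      pmin(pmax(d, 0), 1)
    },
    target = {
      d <- ifelse(y <= target, ((y - lo) / (target - lo))^s,
                  ((hi - y) / (hi - target))^t)
      d[y <= lo | y >= hi] <- 0
      pmin(pmax(d, 0), 1)
    })
}

#' Locate optimal factor settings by desirability maximization
#'
#' Transforms the model prediction into a Derringer-Suich desirability in
#' `[0, 1]` (one-sided ramp for minimize/maximize, two-sided for target) and
#' maximizes it over a coded box by dense grid search refined with a local
#' L-BFGS-B polish. The desirability anchors default to the predicted range
#' over the region, so for minimize/maximize the optimum coincides with the
#' constrained extremum of the predicted response.
#'
#' Factors that appear in no model term are unconstrained: they are reported
#' at the center of the search region.
#'
#' @param fit an `rsm_fit`.
#' @param goal `"minimize"`, `"maximize"` or `"target"`.
#' @param region 2 x k matrix (rows: lower, upper coded bounds) or `NULL`
#'   for the factorial cube `[-1, 1]^k`.
#' @param target target response value (goal `"target"` only).
#' @param anchors optional `c(lo, hi)` response anchors for the ramp;
#'   default: predicted range over the region grid.
#' @param exponents `c(s, t)` desirability shape exponents, default 1.
#' @param n_grid grid points per active dimension.
#' @return An `rsm_optimum`: list with `goal`, `optimum_coded`,
#'   `optimum_natural`, `predicted_response`, `desirability`,
#'   `search_region`, `degenerate` (TRUE when desirability is flat and the
#'   region center is returned).
#' @export
rsm_optimize <- function(fit, goal = c("minimize", "maximize", "target"),
                         region = NULL, target = NULL, anchors = NULL,
                         exponents = c(1, 1), n_grid = 41L) {
  goal <- match.arg(goal)
  if (goal == "target" && is.null(target))
    stop("goal \"target\" requires 'target'", call. = FALSE)
  k <- ncol(fit$design$coded)
  if (is.null(region)) region <- rbind(lower = rep(-1, k), upper = rep(1, k))
  stopifnot(nrow(region) == 2L, ncol(region) == k, all(region[1, ] <= region[2, ]))

  active <- sort(unique(unlist(lapply(fit$terms, term_factors))))
  inactive <- setdiff(seq_len(k), active)
  centers <- colMeans(region)

  eval_point <- function(x) {
    pt <- centers
    pt[active] <- x
    predict(fit, pt)
  }

  if (length(active)) {
    grids <- lapply(active, function(j) seq(region[1, j], region[2, j],
                                            length.out = n_grid))
    gm <- as.matrix(expand.grid(grids))
    pts <- matrix(rep(centers, each = nrow(gm)), nrow(gm), k)
    pts[, active] <- gm
    preds <- predict(fit, pts)
  } else {
    preds <- predict(fit, matrix(centers, 1))
  }

  if (is.null(anchors)) anchors <- range(preds)
  lo <- anchors[1]; hi <- anchors[2]
  flat <- (hi - lo) <= 1e-9 * max(abs(hi), 1)
  if (flat || !length(active)) {
    opt_coded <- centers
    return(new_rsm_optimum(fit, goal, opt_coded, region,
                           desirability = if (flat) NA_real_ else 1,
                           degenerate = TRUE))
  }

  desir <- function(y) derringer_suich(y, goal, lo, hi, target,
                                       exponents[1], exponents[2])
  d_grid <- desir(preds)
  best <- which.max(d_grid)
  x0 <- pts[best, active]

  # polish: maximize desirability (minimize negative) within the box
  obj <- function(x) -desir(eval_point(x))
  pol <- stats::optim(x0, obj, method = "L-BFGS-B",
                      lower = region[1, active], upper = region[2, active])
  x_best <- if (pol$value <= -d_grid[best]) pol$par else x0
  opt_coded <- centers
  opt_coded[active] <- x_best
  new_rsm_optimum(fit, goal, opt_coded, region,
                  desirability = desir(eval_point(x_best)),
                  degenerate = FALSE)
}

new_rsm_optimum <- function(fit, goal, opt_coded, region, desirability,
                            degenerate) {
  facs <- fit$design$factors
  nat <- vapply(seq_along(facs), function(j) to_natural(facs[[j]], opt_coded[j]),
                0)
  names(nat) <- names(opt_coded) <- colnames(fit$design$coded)
  structure(list(goal = goal, optimum_coded = opt_coded,
                 optimum_natural = nat,
                 predicted_response = unname(predict(fit, opt_coded)),
                 desirability = unname(desirability),
                 search_region = region, degenerate = degenerate),
            class = "rsm_optimum")
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat(sprintf("Desirability optimum (%s)%s\n", x$goal,
              if (x$degenerate) " [degenerate: flat desirability]" else ""))
  df <- data.frame(coded = round(x$optimum_coded, 4),
                   natural = round(x$optimum_natural, 4))
  print(df)
  cat(sprintf("predicted response %.4g | desirability %.4g\n",
              x$predicted_response, x$desirability))
  invisible(x)
}
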