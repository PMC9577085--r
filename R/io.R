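# Tabular interchange: RFC-4180 CSV, UTF-8, "." decimal, times in minutes.

#' Write / read a design as CSV
#'
#' Schema: `std_order`, `point_type`, then one `<factor>.coded` and one
#' `<factor>.natural` column per factor. On read, each factor's coding
#' transform is rebuilt from its coded/natural column pair (center =
#' natural at coded 0 via least squares, alpha = largest |coded| level).
#'
#' @param design a `doe_design`.
#' @param path file path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `doe_design`.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "doe_design"))
  nm <- colnames(design$coded)
  df <- data.frame(std_order = design$std_order,
                   point_type = design$point_type, check.names = FALSE)
  for (j in seq_along(nm)) {
    df[[paste0(nm[j], ".coded")]] <- design$coded[, j]
    df[[paste0(nm[j], ".natural")]] <- design$natural[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- names(df)
  nm <- sub("\\.coded$", "", grep("\\.coded$", cn, value = TRUE))
  facs <- vector("list", length(nm))
  coded <- matrix(NA_real_, nrow(df), length(nm))
  for (j in seq_along(nm)) {
    cc <- df[[paste0(nm[j], ".coded")]]
    nn <- df[[paste0(nm[j], ".natural")]]
    b <- stats::coef(stats::lm(nn ~ cc))
    alpha <- max(abs(cc))
    facs[[j]] <- doe_factor(nm[j], center = unname(b[1]),
                            step = if (is.na(b[2]) || b[2] == 0) 1
                                   else unname(b[2]),
                            alpha = if (alpha > 1) alpha else 2^(length(nm)/4))
    coded[, j] <- cc
  }
  des <- new_doe_design(facs, coded, as.character(df$point_type), "from CSV")
  des$std_order <- df$std_order
  des
}

#' Write / read a response table as CSV
#'
#' Schema: `std_order` plus one named response column. Rows are matched to
#' a design by `std_order` on read.
#'
#' @param std_order run identifiers.
#' @param response numeric responses.
#' @param name response column name.
#' @param path file path.
#' @param design optional `doe_design`; when given, responses are reordered
#'   to the design's standard order and unmatched runs raise an error.
#' @return `write_response_csv` returns `path` invisibly;
#'   `read_response_csv` a data.frame (`std_order`, response column).
#' @export
write_response_csv <- function(std_order, response, name, path) {
  df <- data.frame(std_order = std_order)
  df[[name]] <- response
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"std_order" %in% names(df))
    stop("response CSV needs a 'std_order' column", call. = FALSE)
  if (!is.null(design)) {
    idx <- match(design$std_order, df$std_order)
    if (anyNA(idx))
      stop("runs missing from response CSV: std_order ",
           paste(design$std_order[is.na(idx)], collapse = ", "),
           call. = FALSE)
    df <- df[idx, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write an ANOVA table as CSV
#'
#' Columns `source`, `sum_of_squares`, `df`, `mean_square`, `F`, `p` with
#' p formatted via [format_p()].
#'
#' @param fit an `rsm_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(fit, path) {
  a <- fit$anova
  a$p <- format_p(a$p)
  utils::write.csv(a, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read concentration-time data from CSV
#'
#' Schema: `subject_id`, `arm`, `matrix` (`plasma`/`brain`), `time_min`,
#' `conc`, `blq` (0/1). Returns one [conc_profile()] per
#' subject-arm-matrix combination, with the arm stored as attribute
#' `arm`. Subjects whose points are all BLQ are dropped with a warning.
#'
#' @param path file path.
#' @return List of [conc_profile()] objects.
#' @export
read_concentration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", "arm", "matrix", "time_min", "conc", "blq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("concentration CSV missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  keys <- split(seq_len(nrow(df)),
                interaction(df$arm, df$matrix, df$subject_id, drop = TRUE))
  out <- list()
  for (idx in keys) {
    d <- df[idx, ]
    d <- d[order(d$time_min), ]
    if (all(d$blq == 1)) {
      warning("subject ", d$subject_id[1], " (", d$arm[1], ", ", d$matrix[1],
              ") is all-BLQ: excluded", call. = FALSE)
      next
    }
    p <- conc_profile(d$subject_id[1], d$matrix[1], d$time_min, d$conc,
                      blq = d$blq == 1)
    attr(p, "arm") <- d$arm[1]
    out <- c(out, list(p))
  }
  out
}

#' Read a formulation PK summary table from CSV
#'
#' Schema: `name`, `brain_auc`, `plasma_auc`.
#'
#' @param path file path.
#' @return Named list of [formulation_pk()] objects.
#' @export
read_formulation_pk_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("name", "brain_auc", "plasma_auc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("formulation PK CSV missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    formulation_pk(df$name[i], df$brain_auc[i], df$plasma_auc[i]))
  names(out) <- df$name
  out
}

#' Write a targeting-index report as CSV
#'
#' One row per formulation: `name`, `brain_auc`, `plasma_auc`, `bx`,
#' `dte_percent`, `dtp_percent`.
#'
#' @param formulations list of [formulation_pk()].
#' @param iv an [iv_reference()].
#' @param path file path.
#' @return The report data.frame, invisibly; written to `path`.
#' @export
write_targeting_csv <- function(formulations, iv, path) {
  rows <- lapply(formulations, function(f) {
    ix <- dtp(f, iv)
    data.frame(name = f$name, brain_auc = f$brain_auc,
               plasma_auc = f$plasma_auc, bx = ix$bx,
               dte_percent = ix$dte_percent, dtp_percent = ix$dtp_percent)
  })
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  utils::write.csv(rep_, path, row.names = FALSE)
  invisible(rep_)
}

#' Write a complete miniature synthetic study to a directory
#'
#' Emits the CSV schemas the analysis functions consume: a 20-run CCD
#' design with simulated particle-size responses, and a concentration
#' table with per-subject plasma profiles and destructive brain samples.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  des <- make_inscribed_ccd(list(
    list(name = "hpmc", low = 0.1, high = 2.0, units = "% w/v"),
    list(name = "sonication", low = 5, high = 15, units = "min"),
    list(name = "temperature", low = 5, high = 15, units = "degC")),
    n_center = 6)
  terms <- list(term_intercept(), term_linear(1), term_linear(2),
                term_quadratic(2))
  y <- simulate_rsm(des, terms, c(480, 170, -24, -31), noise_sd = 25,
                    seed = seed)
  p_design <- file.path(dir, "design.csv")
  p_resp <- file.path(dir, "particle_size.csv")
  write_design_csv(des, p_design)
  write_response_csv(des$std_order, round(y, 1), "particle_size", p_resp)

  sim <- simulate_pk_study(pk_sim_spec(), seed = seed + 1L)
  rows <- list()
  for (p in sim$plasma)
    rows <- c(rows, list(data.frame(subject_id = p$subject_id, arm = "test",
                                    matrix = "plasma", time_min = p$times,
                                    conc = signif(p$conc, 5), blq = 0L)))
  bi <- 0L
  for (s in sim$brain_samples) {
    rows <- c(rows, list(data.frame(
      subject_id = sprintf("brain_%02d", bi + seq_along(s$conc)),
      arm = "test", matrix = "brain", time_min = s$time,
      conc = signif(s$conc, 5), blq = 0L)))
    bi <- bi + length(s$conc)
  }
  p_conc <- file.path(dir, "concentrations.csv")
  utils::write.csv(do.call(rbind, rows), p_conc, row.names = FALSE)
  invisible(c(p_design, p_resp, p_conc))
}
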