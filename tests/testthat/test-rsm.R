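test_that("model matrix evaluates terms on coded levels", {
  des <- ccd3()
  X <- build_model_matrix(des, full_quadratic_terms(3))
  expect_equal(ncol(X), 10L)
  # center runs: intercept 1, everything else 0
  expect_equal(unname(X[15, ]), c(1, rep(0, 9)))
  # axial high run of factor 1: quadratic column is alpha^2
  expect_equal(unname(X[10, "hpmc^2"]), 2^(3 / 2), tolerance = 1e-12)
  expect_equal(round(unname(X[10, "hpmc^2"]), 4), 2.8284)
  # interaction column is the product of the coded columns
  expect_equal(X[, "hpmc:sonication"], des$coded[, 1] * des$coded[, 2])
  expect_error(build_model_matrix(des, list(term_intercept(),
                                            term_linear(1), term_linear(1))),
               "duplicate")
  expect_error(build_model_matrix(des, list(term_intercept(),
                                            term_linear(4))),
               "exceeds")
})

test_that("noiseless data regenerates its coefficients to machine precision", {
  des <- ccd3()
  terms <- full_quadratic_terms(3)
  beta <- c(100, 10, -5, 3, 2, -1, 0.5, 4, -6, 1.5)
  y <- simulate_rsm(des, terms, beta, noise_sd = 0)
  fit <- rsm_fit(des, y, terms)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-10)
  expect_equal(sum(fit$residuals^2), 0, tolerance = 1e-16)
  expect_equal(fit$r2, 1)
  expect_equal(fit$adjusted_r2, 1)
})

test_that("constant response gives intercept-only signal", {
  des <- ccd3()
  fit <- rsm_fit(des, rep(42, 20), rufi_reduced_terms())
  expect_equal(unname(coef(fit)), c(42, 0, 0, 0), tolerance = 1e-12)
  expect_equal(anova_row(fit, "residual")$sum_of_squares, 0,
               tolerance = 1e-18)
})

test_that("normal-equation coefficients agree with brute-force RSS search", {
  # 2-term toy model: grid-minimize the residual sum of squares directly
  des <- ccd3(n_center = 2)
  y <- simulate_rsm(des, list(term_intercept(), term_linear(1)),
                    c(5, 2), noise_sd = 1, seed = 11)
  fit <- rsm_fit(des, y, list(term_intercept(), term_linear(1)))
  rss <- function(b0, b1) sum((y - b0 - b1 * des$coded[, 1])^2)
  grid <- expand.grid(b0 = seq(3, 7, by = 0.002),
                      b1 = seq(0, 4, by = 0.002))
  best <- grid[which.min(mapply(rss, grid$b0, grid$b1)), ]
  expect_equal(unname(coef(fit)[1]), best$b0, tolerance = 2e-3)
  expect_equal(unname(coef(fit)[2]), best$b1, tolerance = 2e-3)
})

test_that("case-study reduced fit reproduces the published coefficients and ANOVA", {
  fit <- reduced_fit()
  expect_equal(unname(round(coef(fit), 2)),
               c(486.73, 171.08, -23.57, -30.86))
  # published table rounds the HPMC SS in its 5th significant figure
  expect_equal(anova_row(fit, "hpmc")$sum_of_squares, 3.9977e5,
               tolerance = 2e-4)
  expect_equal(anova_row(fit, "sonication^2")$sum_of_squares, 13973.18,
               tolerance = 1e-6)
  pe <- anova_row(fit, "pure_error")
  expect_equal(pe$sum_of_squares, 4042.89, tolerance = 1e-5)
  expect_equal(pe$df, 5)
  lof <- anova_row(fit, "lack_of_fit")
  expect_equal(lof$sum_of_squares, 32171.45, tolerance = 1e-6)
  expect_equal(lof$df, 11)
  expect_gt(lof$p, 0.05)  # lack of fit not significant
  expect_equal(round(anova_row(fit, "model")$F, 2), 62.04)
  expect_lt(anova_row(fit, "model")$p, 1e-4)
  expect_equal(fit$adjusted_r2, 0.90, tolerance = 0.01)
})

test_that("ANOVA decomposition identities hold on noisy fits", {
  des <- ccd3()
  set.seed(4)
  for (rep in 1:5) {
    y <- simulate_rsm(des, rufi_reduced_terms(), c(500, 150, -20, -30),
                      noise_sd = 40)
    fit <- rsm_fit(des, y, rufi_reduced_terms())
    a <- fit$anova
    g <- function(s) a$sum_of_squares[a$source == s]
    expect_equal(g("model") + g("residual"), g("total"),
                 tolerance = 1e-6)
    expect_equal(g("lack_of_fit") + g("pure_error"), g("residual"),
                 tolerance = 1e-6)
    d <- function(s) a$df[a$source == s]
    expect_equal(d("model") + d("residual"), d("total"))
    expect_equal(d("lack_of_fit") + d("pure_error"), d("residual"))
    expect_lte(fit$predicted_r2, fit$r2)
    expect_lte(fit$adjusted_r2, fit$r2)
  }
})

test_that("lack of fit is undefined without replicates, not zero", {
  des <- ccd3(n_center = 1)
  y <- simulate_rsm(des, rufi_reduced_terms(), c(500, 150, -20, -30),
                    noise_sd = 10, seed = 3)
  fit <- rsm_fit(des, y, rufi_reduced_terms())
  expect_true(is.na(anova_row(fit, "lack_of_fit")$sum_of_squares))
  expect_true(is.na(anova_row(fit, "pure_error")$sum_of_squares))
})

test_that("PRESS equals explicit leave-one-out refits", {
  fit <- reduced_fit()
  des <- fit$design
  y <- fit$response
  X <- fit$model_matrix
  loo <- vapply(seq_along(y), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    y[i] - drop(X[i, ] %*% b)
  }, 0)
  expect_equal(fit$press, sum(loo^2), tolerance = 1e-9)
  expect_equal(fit$predicted_r2,
               1 - sum(loo^2) / sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("adding a term never increases residual SS", {
  des <- ccd3()
  y <- simulate_rsm(des, full_quadratic_terms(3),
                    c(500, 150, -20, 5, 3, -2, 1, 10, -30, 8),
                    noise_sd = 30, seed = 9)
  terms <- list(term_intercept())
  prev <- Inf
  for (add in list(term_linear(1), term_linear(2), term_quadratic(2),
                   term_interaction(1, 2), term_quadratic(1))) {
    terms <- c(terms, list(add))
    rss <- sum(rsm_fit(des, y, terms)$residuals^2)
    expect_lte(rss, prev + 1e-9)
    prev <- rss
  }
})

test_that("rank deficiency and length mismatches are reported by name", {
  des <- ccd3()
  y <- rnorm(20)
  # duplicate information: quadratic of a two-level pseudo factor
  pb <- make_plackett_burman(3)
  expect_error(rsm_fit(pb, rnorm(12),
                       list(term_intercept(), term_linear(1),
                            term_quadratic(1))),
               "collinear.*X1\\^2")
  expect_error(rsm_fit(des, y[1:10], rufi_reduced_terms()), "length")
})

test_that("backward elimination respects hierarchy and drops noise terms", {
  des <- rufi_ccd_design()
  y <- rufi_ccd_table()$particle_size
  red <- reduce_model(des, y, full_quadratic_terms(3), alpha_keep = 0.05)
  expect_setequal(names(coef(red)),
                  c("(Intercept)", "hpmc", "sonication", "sonication^2"))
  # linear sonication kept (p = 0.0859 > 0.05) because its quadratic stays
  expect_gt(anova_row(red, "sonication")$p, 0.05)
  expect_lt(anova_row(red, "sonication^2")$p, 0.05)
  # intercept-only signal: everything droppable goes
  set.seed(21)
  y0 <- rnorm(20, 100, 1)
  red0 <- reduce_model(des, y0, full_quadratic_terms(3))
  expect_equal(names(coef(red0)), "(Intercept)")
  # deterministic: identical rerun
  red2 <- reduce_model(des, y, full_quadratic_terms(3), alpha_keep = 0.05)
  expect_identical(coef(red), coef(red2))
})

test_that("prediction matches the published optimum arithmetic", {
  fit <- reduced_fit()
  b <- coef(fit)
  expect_equal(predict(fit, c(-1, 1, 0)),
               unname(b[1] - b[2] + b[3] + b[4]))
  expect_equal(round(predict(fit, c(-1, 1, 0)), 1), 261.2)
  # center point predicts the intercept
  expect_equal(predict(fit, c(0, 0, 0)), unname(b[1]))
  # prediction at a design run equals model-matrix row times coefficients
  expect_equal(predict(fit, fit$design$coded[4, ]),
               unname(drop(fit$model_matrix[4, ] %*% b)))
})

test_that("desirability minimization finds the published optimum settings", {
  fit <- reduced_fit()
  opt <- rsm_optimize(fit, "minimize")
  expect_equal(unname(opt$optimum_coded), c(-1, 1, 0), tolerance = 1e-6)
  # reported settings 0.48 % w/v and 12.9 min (printed truncations)
  expect_equal(unname(opt$optimum_natural[1]), 0.4851, tolerance = 1e-4)
  expect_equal(unname(opt$optimum_natural[2]), 12.973, tolerance = 1e-3)
  # the unconstrained temperature is reported at the region center
  expect_equal(unname(opt$optimum_natural[3]), 10)
  expect_equal(round(opt$predicted_response, 1), 261.2)
  expect_gte(opt$desirability, 0)
  expect_lte(opt$desirability, 1)
  expect_false(opt$degenerate)
})

test_that("grid-plus-polish optimum matches the analytic interior vertex", {
  des <- make_inscribed_ccd(list(list(name = "a", low = -1, high = 1),
                                 list(name = "b", low = -1, high = 1)),
                            n_center = 3)
  terms <- list(term_intercept(), term_linear(1), term_quadratic(1))
  beta <- c(10, -2, 4)  # vertex at -beta1/(2*beta11) = 0.25
  y <- simulate_rsm(des, terms, beta, noise_sd = 0)
  fit <- rsm_fit(des, y, terms)
  opt <- rsm_optimize(fit, "minimize")
  expect_equal(unname(opt$optimum_coded[1]), 0.25, tolerance = 1e-6)
  expect_equal(opt$predicted_response, 10 - 2 * 0.25 + 4 * 0.25^2,
               tolerance = 1e-9)
})

test_that("intercept-only model yields a degenerate optimum at the center", {
  des <- ccd3()
  fit <- rsm_fit(des, rnorm(20, 50, 1e-6), list(term_intercept()))
  opt <- rsm_optimize(fit, "minimize")
  expect_true(opt$degenerate)
  expect_equal(unname(opt$optimum_coded), c(0, 0, 0))
  expect_equal(opt$predicted_response, unname(coef(fit)[1]))
})

test_that("p-values format in reporting style", {
  expect_equal(format_p(c(0.5, 2e-5, NA)), c("0.5000", "<0.0001", NA))
})
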