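test_that("NCA matches closed forms for constant and triangular profiles", {
  # constant c over [0, T]: AUC = c*T, AUMC = c*T^2/2, MRT = T/2
  p <- conc_profile("c", "plasma", times = seq(0, 100, 10),
                    conc = rep(2, 11))
  r <- nca(p)
  expect_equal(r$auc_last, 200)
  expect_equal(r$aumc_last, 2 * 100^2 / 2)
  expect_equal(r$mrt, 50)
  expect_equal(r$tmax, 0)  # earliest time attaining the max
  # triangle 0 -> c at tau -> 0 at 2 tau: AUC = c*tau
  tr <- conc_profile("t", "plasma", c(0, 30, 60), c(0, 5, 0))
  rt <- nca(tr)
  expect_equal(rt$auc_last, 150)
  expect_equal(rt$cmax, 5)
  expect_equal(rt$tmax, 30)
  expect_equal(rt$tlast, 60)
})

test_that("NCA tracks quadrature of the one-compartment closed form", {
  ka <- 0.05; ke <- 0.006; c0 <- 1.2
  A <- c0 * ka / (ka - ke)
  tt <- seq(0, 2000, by = 1)  # well past 5/ke = 833 min
  p <- conc_profile("oc", "plasma", tt, one_compartment_conc(tt, ka, ke, c0))
  r <- nca(p)
  auc_inf <- A * (1 / ke - 1 / ka)
  expect_equal(r$auc_last, auc_inf, tolerance = 0.01)
  # truncation-corrected MRT via numerical quadrature on [0, tlast]
  f <- function(t) one_compartment_conc(t, ka, ke, c0)
  auc_q <- stats::integrate(f, 0, 2000, rel.tol = 1e-10)$value
  aumc_q <- stats::integrate(function(t) t * f(t), 0, 2000,
                             rel.tol = 1e-10)$value
  expect_equal(r$auc_last, auc_q, tolerance = 1e-4)
  expect_equal(r$mrt, aumc_q / auc_q, tolerance = 0.02)
  # noiseless Tmax at the closed-form peak (grid resolution 1 min)
  expect_equal(r$tmax, log(ka / ke) / (ka - ke), tolerance = 1)
})

test_that("BLQ rules: leading zeros kept, embedded zeroed, trailing excluded", {
  p <- conc_profile("b", "plasma",
                    times = c(0, 5, 15, 30, 60, 120, 240),
                    conc = c(0.01, 0.02, 1, 0.5, 0.02, 0.8, 0.01),
                    blq = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  r <- nca(p)
  expect_equal(r$tlast, 120)  # trailing BLQ excluded
  # hand trapezoid with leading/embedded BLQ as 0
  tt <- c(0, 5, 15, 30, 60, 120)
  cc <- c(0, 0, 1, 0.5, 0, 0.8)
  expect_equal(r$auc_last, sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2))
  expect_error(nca(conc_profile("x", "plasma", c(0, 10), c(1, 1),
                                blq = c(TRUE, TRUE))),
               "BLQ")
})

test_that("AUC is invariant to collinear insertion and monotone in tlast", {
  tt <- c(0, 30, 60, 120, 240)
  cc <- c(0, 1.0, 0.8, 0.5, 0.1)
  base <- nca(conc_profile("a", "plasma", tt, cc))$auc_last
  # insert a point exactly on the 60-120 segment
  ins <- nca(conc_profile("a", "plasma", c(0, 30, 60, 90, 120, 240),
                          c(0, 1.0, 0.8, 0.65, 0.5, 0.1)))$auc_last
  expect_equal(ins, base, tolerance = 1e-12)
  aucs <- vapply(3:5, function(k)
    nca(conc_profile("a", "plasma", tt[1:k], cc[1:k]))$auc_last, 0)
  expect_true(all(diff(aucs) >= 0))
})

test_that("time-shifting a zero-padded profile shifts MRT by exactly delta", {
  tau <- 45; cpk <- 3; delta <- 60
  orig <- nca(conc_profile("s", "plasma", c(0, tau, 2 * tau), c(0, cpk, 0)))
  shif <- nca(conc_profile("s", "plasma",
                           c(0, delta, delta + tau, delta + 2 * tau),
                           c(0, 0, cpk, 0)))
  expect_equal(shif$auc_last, orig$auc_last, tolerance = 1e-12)
  expect_equal(shif$mrt, orig$mrt + delta, tolerance = 1e-9)
})

test_that("destructive pooling averages per time and keeps n and SD", {
  pooled <- pool_destructive(list(list(time = 30, conc = c(1, 3)),
                                  list(time = 60, conc = c(2, 2))))
  expect_equal(pooled$times, c(30, 60))
  expect_equal(pooled$conc, c(2, 2))
  expect_true(pooled$pooled)
  expect_equal(attr(pooled, "n"), c(2L, 2L))
  expect_equal(attr(pooled, "sd"), c(sd(c(1, 3)), 0))
  # n = 1 per time: pooled equals input
  one <- pool_destructive(list(list(time = 30, conc = 5),
                               list(time = 60, conc = 4)))
  expect_equal(one$conc, c(5, 4))
  expect_error(pool_destructive(list(list(time = 30, conc = 1),
                                     list(time = 30, conc = 2))),
               "duplicate")
})

test_that("pooled AUC equals mean per-subject AUC on a shared schedule", {
  tt <- c(0, 30, 60, 120, 240, 480)
  set.seed(5)
  subj <- replicate(4, one_compartment_conc(tt, 0.05, 0.006, 1.2) *
                      exp(rnorm(1, 0, 0.2)), simplify = FALSE)
  samples <- lapply(seq_along(tt), function(i)
    list(time = tt[i], conc = vapply(subj, `[[`, 0, i)))
  pooled_auc <- nca(pool_destructive(samples))$auc_last
  per_subject <- vapply(subj, function(cc)
    nca(conc_profile("s", "brain", tt, cc))$auc_last, 0)
  expect_equal(pooled_auc, mean(per_subject), tolerance = 1e-12)
})

test_that("arm summaries report mean, SD and a Tmax range", {
  tt <- c(0, 15, 30, 45, 60, 120)
  p1 <- conc_profile("r1", "plasma", tt, c(0, 0.5, 1.0, 0.9, 0.7, 0.3))
  p2 <- conc_profile("r2", "plasma", tt, c(0, 0.4, 0.8, 0.9, 0.6, 0.2))
  s <- summarize_arm(list(p1, p2))
  expect_equal(s$label[s$parameter == "tmax"], "30-45")
  # identical profiles: SD 0 everywhere, mean AUC equals each AUC
  s2 <- summarize_arm(list(p1, p1))
  expect_equal(s2$sd, rep(0, 5))
  expect_equal(s2$mean[s2$parameter == "auc_last"], nca(p1)$auc_last)
  expect_equal(s2$label[s2$parameter == "tmax"], "30")
  expect_error(summarize_arm(list(p1, conc_profile("b", "brain", tt,
                                                   rep(1, 6)))),
               "one matrix")
})

test_that("concentration CSV round trip preserves profiles and drops all-BLQ", {
  dir <- withr::local_tempdir()
  sim <- simulate_pk_study(pk_sim_spec(), seed = 3)
  paths <- write_fixture_study(dir, seed = 3)
  profs <- read_concentration_csv(file.path(dir, "concentrations.csv"))
  mats <- vapply(profs, `[[`, "", "matrix")
  expect_equal(sum(mats == "plasma"), 4L)
  expect_equal(sum(mats == "brain"), 20L)  # 5 times x 4 destructive animals
  # all-BLQ subject excluded with a warning
  df <- data.frame(subject_id = "z", arm = "a", matrix = "plasma",
                   time_min = c(0, 10), conc = c(0, 0), blq = 1L)
  path <- file.path(dir, "blq.csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(out <- read_concentration_csv(path), "all-BLQ")
  expect_length(out, 0L)
})
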