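test_that("Kaplan-Meier estimates match product-limit hand values", {
  cl <- clin(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(cl)
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  cl4 <- clin(time = 1:4, event = rep(1, 4))
  km4 <- km_estimate(cl4)
  expect_equal(km4$survival[km4$n_event == 1], c(3 / 4, 1 / 2, 1 / 4, 0))

  allc <- clin(time = c(2, 5, 9), event = c(0, 0, 0))
  kmc <- km_estimate(allc)
  expect_true(all(kmc$survival == 1))
  expect_true(all(diff(km4$survival) <= 0))
  expect_true(all(diff(km4$n_risk) <= 0))
})

test_that("log-rank matches hand two-by-two tables and is symmetric", {
  a <- clin(time = c(1, 2, 3), event = c(1, 1, 1), ids = paste0("a", 1:3))
  b <- clin(time = c(4, 5, 6), event = c(1, 1, 1), ids = paste0("b", 1:3))
  res <- logrank_test(a, b)
  expect_equal(res$chi_square, weighted_logrank_by_hand(a, b),
               tolerance = 1e-10)

  # identical groups: no separation
  same <- clin(time = c(1, 3, 7), event = c(1, 0, 1))
  same2 <- same
  same2$patient_id <- paste0("x", 1:3)
  ident <- logrank_test(same, same2)
  expect_equal(ident$chi_square, 0)
  expect_equal(ident$p_value, 1)

  # label swap leaves the statistic unchanged
  swapped <- logrank_test(b, a)
  expect_equal(res$chi_square, swapped$chi_square)
  expect_equal(res$p_value, swapped$p_value)
})

test_that("log-rank agrees with survdiff and is invariant to time shifts", {
  set.seed(40)
  a <- clin(rexp(30, 0.1), rbinom(30, 1, 0.8), ids = paste0("a", 1:30))
  b <- clin(rexp(30, 0.25), rbinom(30, 1, 0.8), ids = paste0("b", 1:30))
  res <- logrank_test(a, b)
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = c(a$time, b$time), event = c(a$event, b$event),
                      grp = rep(c("a", "b"), each = 30))
  )
  expect_equal(res$chi_square, sd_fit$chisq, tolerance = 1e-10)

  a2 <- a; a2$time <- a2$time + 100
  b2 <- b; b2$time <- b2$time + 100
  expect_equal(logrank_test(a2, b2)$chi_square, res$chi_square,
               tolerance = 1e-12)
})

test_that("Gehan-Breslow-Wilcoxon weights at-risk counts and stresses early gaps", {
  a <- clin(time = c(1, 2, 3), event = c(1, 1, 1), ids = paste0("a", 1:3))
  b <- clin(time = c(4, 5, 6), event = c(1, 1, 1), ids = paste0("b", 1:3))
  res <- gehan_breslow_wilcoxon(a, b)
  expect_equal(res$chi_square, weighted_logrank_by_hand(a, b, gehan = TRUE),
               tolerance = 1e-10)

  # a single common event time: weights cancel, identical to log-rank
  a1 <- clin(time = c(2, 9), event = c(1, 0), ids = c("a1", "a2"))
  b1 <- clin(time = c(2, 7), event = c(0, 0), ids = c("b1", "b2"))
  expect_equal(gehan_breslow_wilcoxon(a1, b1)$chi_square,
               logrank_test(a1, b1)$chi_square, tolerance = 1e-12)

  # early separation is up-weighted relative to the log-rank statistic
  early_a <- clin(time = c(1, 1.5, 2, 30, 31, 32), event = c(1, 1, 1, 0, 0, 0),
                  ids = paste0("ea", 1:6))
  early_b <- clin(time = c(20, 21, 22, 23, 24, 25), event = c(1, 1, 1, 0, 0, 0),
                  ids = paste0("eb", 1:6))
  expect_gt(gehan_breslow_wilcoxon(early_a, early_b)$chi_square,
            logrank_test(early_a, early_b)$chi_square)
})

test_that("zero-variance event tables are rejected with a diagnostic", {
  a <- clin(time = 5, event = 1, ids = "a1")
  b <- clin(time = 5, event = 1, ids = "b1")
  expect_error(logrank_test(a, b), "variance")
})

test_that("hazard ratios are 1 for identical groups and antisymmetric", {
  set.seed(41)
  a <- clin(rexp(40, 0.1), rbinom(40, 1, 0.9), ids = paste0("a", 1:40))
  b <- clin(rexp(40, 0.3), rbinom(40, 1, 0.9), ids = paste0("b", 1:40))

  a2 <- a; a2$patient_id <- paste0("c", 1:40)
  for (meth in c("mantel_haenszel", "logrank_oe")) {
    expect_equal(hazard_ratio(a, a2, meth)$hr, 1, tolerance = 1e-12)
    hr_ab <- hazard_ratio(a, b, meth)
    hr_ba <- hazard_ratio(b, a, meth)
    expect_equal(hr_ab$hr, 1 / hr_ba$hr, tolerance = 1e-10)
    expect_true(hr_ab$ci_lo <= hr_ab$hr && hr_ab$hr <= hr_ab$ci_hi)
  }
})

test_that("hazard-ratio estimates recover a planted threefold hazard", {
  set.seed(42)
  n <- 2000
  # moderate administrative censoring keeps risk sets balanced, the regime
  # in which the (O-E)/V and O/E summary estimators are near-unbiased
  ta <- rexp(n, 0.3); tb <- rexp(n, 0.1)
  a <- clin(pmin(ta, 5), as.numeric(ta <= 5), ids = paste0("a", 1:n))
  b <- clin(pmin(tb, 5), as.numeric(tb <= 5), ids = paste0("b", 1:n))
  for (meth in c("mantel_haenszel", "logrank_oe")) {
    hr <- hazard_ratio(a, b, meth)$hr
    expect_equal(hr, 3, tolerance = 0.15)
  }
})

test_that("Cox fit matches coxph conventions, flags degenerate inputs", {
  set.seed(43)
  n <- 200
  x <- rnorm(n)
  t_raw <- rexp(n, 0.1 * exp(0.7 * x))
  cl <- clin(pmin(t_raw, 15), as.numeric(t_raw <= 15))
  fit <- cox_ph(cl, x)
  expect_s3_class(fit, "uro_cox")
  expect_gt(fit$hr, 0)
  expect_true(fit$ci_lo <= fit$hr && fit$hr <= fit$ci_hi)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$beta)
  expect_equal(glance(fit)$n_event, sum(cl$event))

  expect_error(cox_ph(cl, rep(1, n)), "Constant covariate")
  expect_error(cox_ph(cl, x[1:10]), "length")
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square without ties", {
  set.seed(44)
  n <- 60
  x <- rep(c(0, 1), each = n / 2)
  t_raw <- rexp(n, 0.1 * exp(-0.8 * x))
  # jitter guarantees no tied event times
  cl <- clin(pmin(t_raw, 25) + runif(n, 0, 1e-6), as.numeric(t_raw <= 25))
  fit <- cox_ph(cl, x)
  lr <- logrank_test(cl[x == 0, ], cl[x == 1, ])
  expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-6)

  # Efron and Breslow agree exactly when no event times are tied
  fit_b <- cox_ph(cl, x, ties = "breslow")
  expect_equal(fit$beta, fit_b$beta, tolerance = 1e-9)
})

test_that("monotone likelihood is flagged as non-convergence", {
  # perfect separation: all events in one covariate group before any other
  cl <- clin(time = c(1, 2, 3, 10, 11, 12), event = c(1, 1, 1, 0, 0, 0))
  fit <- suppressWarnings(cox_ph(cl, c(1, 1, 1, 0, 0, 0)))
  expect_false(fit$converged)
})
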