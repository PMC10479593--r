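test_that("AUC matches hand-counted and degenerate cases", {
  # pairs: (0.35 vs 0.1), (0.35 vs 0.4), (0.8 vs 0.1), (0.8 vs 0.4): 3 wins / 4
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  expect_identical(r$n_pos, 2L)
  expect_identical(r$n_neg, 2L)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals brute-force pair counting up to n = 200", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- round(rnorm(n, mean = labels), 1)  # rounding induces ties
    expect_equal(roc_auc(scores, labels)$auc, brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("DeLong variance and CI agree with an independent implementation", {
  set.seed(47)
  labels <- rbinom(300, 1, 0.3)
  scores <- labels * 0.8 + rnorm(300)
  r <- roc_auc(scores, labels)
  proc_obj <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(proc_obj)), tolerance = 1e-12)
  expect_equal(r$se^2, as.numeric(pROC::var(proc_obj)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(proc_obj, method = "delong"))
  expect_equal(r$ci_low, max(0, ci[1]), tolerance = 1e-9)
  expect_equal(r$ci_high, min(1, ci[3]), tolerance = 1e-9)
})

test_that("paired DeLong comparison agrees with an independent implementation", {
  set.seed(53)
  labels <- rbinom(400, 1, 0.25)
  a <- labels * 1.0 + rnorm(400)
  b <- labels * 0.5 + rnorm(400)
  cmp <- delong_paired(a, b, labels)
  rt <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, rt$p.value, tolerance = 1e-9)
  expect_equal(cmp$delta_auc,
               as.numeric(rt$estimate[1] - rt$estimate[2]), tolerance = 1e-12)
})

test_that("a score compared against itself is a null comparison", {
  labels <- rep(c(0, 1), 10)
  s <- seq(0, 1, length.out = 20)
  cmp <- delong_paired(s, s, labels)
  expect_equal(cmp$delta_auc, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$variance, 0)
})

test_that("DeLong confidence intervals cover the true AUC at nominal rate", {
  # scores = y*d + N(0,1) gives true AUC = pnorm(d/sqrt(2))
  set.seed(59)
  d <- 0.8
  truth <- pnorm(d / sqrt(2))
  covered <- logical(500)
  for (i in seq_along(covered)) {
    labels <- rbinom(500, 1, 0.3)
    scores <- labels * d + rnorm(500)
    r <- roc_auc(scores, labels)
    covered[i] <- r$ci_low <= truth && truth <= r$ci_high
  }
  mc_se <- sqrt(0.95 * 0.05 / length(covered))
  expect_gt(mean(covered), 0.95 - 2.5 * mc_se)
  expect_lt(mean(covered), 0.95 + 2.5 * mc_se)
})

test_that("gatekeeping never declares superiority without non-inferiority", {
  set.seed(61)
  for (i in 1:20) {
    n <- 150
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) < 2 || sum(labels) > n - 2) next
    a <- labels * runif(1, 0, 2) + rnorm(n)
    b <- labels * runif(1, 0, 2) + rnorm(n)
    v <- gatekeeping_test(a, b, labels)
    expect_true(!v$superior || v$noninferior)
  }
})

test_that("identical scores are non-inferior but never superior", {
  labels <- rep(c(0, 1), 100)
  s <- rnorm(200)
  v <- gatekeeping_test(s, s, labels)
  expect_true(v$noninferior)
  expect_false(v$superior)
})

test_that("the non-inferiority bound can be placed on the score's own AUC", {
  set.seed(67)
  labels <- rbinom(500, 1, 0.3)
  a <- labels * 1.5 + rnorm(500)
  b <- labels * 1.4 + rnorm(500)
  v <- gatekeeping_test(a, b, labels, ni_on_difference = FALSE)
  expect_true(v$noninferior)
  expect_match(v$notes[["noninferiority"]], "new AUC")
})

test_that("calibration bins partition the cohort and average to the incidence", {
  set.seed(71)
  pred <- runif(1000)
  labels <- rbinom(1000, 1, pred)
  ct <- calibration_by_quantile(pred, labels, k = 5)
  expect_equal(sum(ct$bins$n), 1000L)
  expect_true(all(abs(ct$bins$n - 200) <= 1))
  expect_equal(sum(ct$bins$n * ct$bins$observed) / 1000, mean(labels),
               tolerance = 1e-12)
  expect_length(ct$adjacent_risk_ratios, 4L)
})

test_that("calibration handles one bin, separations and heavy ties", {
  pred <- c(rep(0.1, 80), rep(0.9, 20))
  labels <- c(rep(0, 80), rep(1, 20))  # events exactly above the 80th pctile
  ct1 <- calibration_by_quantile(pred, labels, k = 1)
  expect_equal(ct1$bins$observed, 0.2)
  ct5 <- calibration_by_quantile(pred, labels, k = 5)
  expect_equal(ct5$bins$observed, c(0, 0, 0, 0, 1))
  expect_true(all(ct5$bins$n == 20))  # duplicated scores, no empty bins
  expect_true(all(is.na(ct5$adjacent_risk_ratios[1:3])))  # 0/0 flagged
})

test_that("exact Poisson incidence intervals match chi-square quantiles", {
  r <- incidence_density(10, 100)
  expect_equal(r$rate, 0.1, tolerance = 1e-12)
  expect_equal(r$ci_low, qchisq(0.025, 20) / 200, tolerance = 1e-12)
  expect_equal(r$ci_high, qchisq(0.975, 22) / 200, tolerance = 1e-12)
  expect_equal(r$ci_low, 0.0480, tolerance = 1e-3)
  expect_equal(r$ci_high, 0.1839, tolerance = 1e-3)

  r0 <- incidence_density(0, 50)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, 3.6889 / 50, tolerance = 1e-4)

  # scale equivariance: doubling person-time halves rate and both limits
  r1 <- incidence_density(7, 80)
  r2 <- incidence_density(7, 160)
  expect_equal(r2$rate, r1$rate / 2, tolerance = 1e-12)
  expect_equal(r2$ci_low, r1$ci_low / 2, tolerance = 1e-12)
  expect_equal(r2$ci_high, r1$ci_high / 2, tolerance = 1e-12)

  expect_error(incidence_density(-1, 10), "events")
  expect_error(incidence_density(3, 0), "person_years")
})
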