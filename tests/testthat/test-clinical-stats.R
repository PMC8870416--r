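test_that("response groupings follow the CR/PR vs SD/PD and 6-month rules", {
  cl <- simple_clinical(
    best = c("CR", "PR", "SD", "SD", "SD", "PD", "NE"),
    pfs = c(10, 3, 6, 6.01, 5, 2, 4)
  )
  orr <- group_patients(cl, "ORR")
  expect_equal(orr$label, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, NA))
  cbr <- group_patients(cl, "CBR")
  # SD at exactly 6.0 months is negative ("more than" is strict)
  expect_equal(cbr$label, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, NA))
  # labels are reproducible and order-independent
  shuffled <- cl[sample(nrow(cl)), ]
  orr2 <- group_patients(shuffled, "ORR")
  expect_equal(orr2$label[match(orr$patient_id, orr2$patient_id)],
               orr$label)
})

test_that("LTR uses an inclusive doubled-median threshold", {
  cl <- simple_clinical(rep("SD", 5), pfs = c(1, 2, 4.54, 9.07, 9.08))
  ltr <- group_patients(cl, "LTR", median_pfs = 4.54)
  expect_equal(ltr$label, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(ltr, "median_pfs"), 4.54)
  # unpinned: the cohort's own KM median (no censoring: 37th of 73 etc.)
  cl2 <- simple_clinical(rep("SD", 5), pfs = c(1, 2, 3, 4, 5))
  ltr2 <- group_patients(cl2, "LTR")
  expect_equal(attr(ltr2, "median_pfs"), 3)
  expect_equal(ltr2$label, c(FALSE, FALSE, FALSE, FALSE, FALSE))
  # all censored: no resolvable median
  cl3 <- simple_clinical(rep("SD", 3), pfs = c(1, 2, 3), event = FALSE)
  expect_error(group_patients(cl3, "LTR"), "median PFS")
})

test_that("exact binomial rates match the beta-quantile construction", {
  r <- response_rate(7, 73)
  expect_equal(round(r$rate, 1), 9.6)
  oracle <- oracle_clopper_pearson(7, 73)
  expect_equal(r$conf_low, 100 * oracle[1])
  expect_equal(r$conf_high, 100 * oracle[2])

  r0 <- response_rate(0, 10)
  expect_equal(r0$rate, 0)
  expect_equal(r0$conf_low, 0)
  rn <- response_rate(10, 10)
  expect_equal(rn$conf_high, 100)

  expect_error(response_rate(5, 4), "n_pos")
  expect_error(response_rate(-1, 4), "n_pos")
  expect_error(response_rate(0, 0), "n_pos")
})

test_that("exact CI coverage holds at nominal level in simulation", {
  set.seed(101)
  for (p in c(0.1, 0.5)) {
    n <- 40
    covered <- vapply(1:400, function(i) {
      k <- stats::rbinom(1, n, p)
      ci <- response_rate(k, n)
      ci$conf_low <= 100 * p && 100 * p <= ci$conf_high
    }, logical(1))
    expect_gte(mean(covered), 0.95 - 2 * sqrt(0.05 * 0.95 / 400))
  }
})

test_that("rank-sum branches agree with enumeration and each other", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)        # 2 / C(6,3) doubled
  expect_equal(w$method, "exact")

  expect_equal(wilcoxon_rank_sum(c(1, 2), c(100))$p_value,
               oracle_wilcoxon_exact(c(1, 2), c(100)))

  # identical multisets: p = 1 within tolerance (tie-corrected approx)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "normal_approx")
  expect_gte(same$p_value, 0.95)

  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-missing")

  # exact vs continuity-corrected normal approximation, exhaustively
  # over every tie-free n1 = n2 = 6 outcome: the worst-case deviation
  # of the approximation is just over 0.015, and most outcomes agree
  # to well under 0.01
  u <- 0:36
  p_exact <- vapply(u, function(x) {
    min(1, 2 * min(stats::pwilcox(x, 6, 6),
                   1 - stats::pwilcox(x - 1, 6, 6)))
  }, numeric(1))
  v_u <- 6 * 6 * 13 / 12
  p_approx <- vapply(u, function(x) {
    min(1, 2 * stats::pnorm(-(abs(x - 18) - 0.5) / sqrt(v_u)))
  }, numeric(1))
  expect_lt(max(abs(p_exact - p_approx)), 0.016)
  expect_lt(stats::median(abs(p_exact - p_approx)), 0.01)
})

test_that("Cohen's d is the pooled-SD standardized mean difference", {
  expect_equal(cohens_d(c(2, 4), c(0, 2)), 2 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -cohens_d(c(2, 4), c(0, 2)))
  expect_warning(d0 <- cohens_d(c(1, 1), c(1, 1)), "zero")
  expect_true(is.na(d0))
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("the KM estimate reproduces the empirical survivor function", {
  fit <- km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  td <- tidy(fit)
  expect_equal(td$estimate, c(0.75, 0.5, 0.25, 0))
  expect_equal(glance(fit)$median, 2)

  set.seed(121)
  for (i in 1:10) {
    t <- sample(100, 15)
    fit <- km_fit(t, rep(TRUE, 15))
    td <- tidy(fit)
    ecdf_surv <- 1 - seq_len(15) / 15
    expect_equal(td$estimate[order(td$time)], ecdf_surv)
  }

  # all-censored: fit returned, median undefined
  cens <- km_fit(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(is.na(glance(cens)$median))
  expect_s3_class(autoplot(cens), "ggplot")
})

test_that("the log-rank test matches the hand-built risk-table oracle", {
  identical_groups <- logrank_test(c(1, 2, 3, 1, 2, 3),
                                   rep(TRUE, 6), rep(c("a", "b"), 3))
  expect_equal(identical_groups$statistic, 0, tolerance = 1e-10)
  expect_equal(identical_groups$p_value, 1)

  # two 6-patient arms with censoring
  time <- c(6, 13, 21, 30, 31, 37, 38, 47, 49, 50, 63, 79)
  event <- c(1, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1) == 1
  group <- rep(c("ctrl", "trt"), each = 6)
  got <- logrank_test(time, event, group)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$statistic, unname(want["chisq"]), tolerance = 1e-10)
  expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-10)
  expect_error(logrank_test(1:3, rep(TRUE, 3), rep("a", 3)), "2 groups")
})
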