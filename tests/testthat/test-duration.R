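test_that("group split by AHI puts the cut value in the OSAHS group", {
  patients <- data.frame(exam_id = c("a", "b", "c", "d"),
                         ahi = c(0, 4.9, 5, 31))
  events <- data.frame(exam_id = rep(c("a", "b", "c", "d"), each = 2),
                       duration_s = rep(1, 8), label = "S")
  g <- split_groups(patients, events)
  expect_equal(unname(g$n_patients), c(2, 2))
  expect_equal(length(g$primary), 4)
  expect_equal(length(g$osahs), 4)
  # all patients below the cut: OSAHS empty, the comparison refuses
  p2 <- data.frame(exam_id = c("a", "b"), ahi = c(1, 2))
  e2 <- events[events$exam_id %in% c("a", "b"), ]
  expect_equal(length(split_groups(p2, e2)$osahs), 0)
  expect_error(duration_report(e2, p2), "no snore events")
})

test_that("duration summaries match a brute-force loop and the published SE", {
  s <- summarize_durations(c(1, 1, 1, 1))
  expect_equal(s$mean_s, 1); expect_equal(s$sd_s, 0); expect_equal(s$se_s, 0)

  # published OSAHS group: se = sd / sqrt(n) to 4 significant figures
  expect_equal(signif(0.271 / sqrt(9993), 4), 0.002711)
  expect_equal(signif(duration_summaries_fixture()$osahs$se_s, 4), 0.002711)

  set.seed(31)
  d <- rlnorm(30, meanlog = 0, sdlog = 0.3)
  s <- summarize_durations(d)
  m <- sum(d) / 30
  expect_equal(s$mean_s, m, tolerance = 1e-12)
  expect_equal(s$sd_s, sqrt(sum((d - m)^2) / 29), tolerance = 1e-12)
  expect_equal(s$se_s, s$sd_s / sqrt(30), tolerance = 1e-12)
  expect_equal(s$min_s, min(d)); expect_equal(s$max_s, max(d))
  expect_equal(s$median_s, median(d))
  expect_true(is.na(summarize_durations(1.5)$sd_s))
})

test_that("95% CI is mean +/- 1.96 se and reproduces the published interval", {
  osahs <- duration_summaries_fixture()$osahs
  expect_equal(round(ci95(osahs), 4), c(0.8583, 0.8689))
  # arithmetic oracle on the primary-snorer summary
  prim <- duration_summary(7691, 1.002, 0.3562)
  expect_equal(ci95(prim), 1.002 + c(-1, 1) * 1.96 * 0.3562 / sqrt(7691),
               tolerance = 1e-12)
  expect_equal(ci95(duration_summary(4, 2, 0)), c(2, 2))
  expect_error(ci95(duration_summary(1, 1, NA)), "undefined")
})

test_that("two-sample t from summaries matches the formulas and t.test", {
  s <- duration_summaries_fixture()
  for (m in c("welch", "pooled")) {
    res <- two_sample_t(s$osahs, s$primary, method = m)
    expect_lt(res$p.value, 1e-4)
    expect_gt(abs(res$statistic), 20)
  }
  # direct formula oracle on small groups
  a <- duration_summary(12, 0.9, 0.25)
  b <- duration_summary(17, 1.1, 0.40)
  w <- two_sample_t(a, b, "welch")
  v1 <- 0.25^2 / 12; v2 <- 0.40^2 / 17
  t_o <- (0.9 - 1.1) / sqrt(v1 + v2)
  df_o <- (v1 + v2)^2 / (v1^2 / 11 + v2^2 / 16)
  expect_equal(unname(w$statistic), t_o, tolerance = 1e-10)
  expect_equal(unname(w$parameter), df_o, tolerance = 1e-10)
  expect_equal(w$p.value, 2 * pt(-abs(t_o), df_o), tolerance = 1e-10)
  p <- two_sample_t(a, b, "pooled")
  sp2 <- (11 * 0.25^2 + 16 * 0.40^2) / 27
  expect_equal(unname(p$statistic), -0.2 / sqrt(sp2 * (1 / 12 + 1 / 17)),
               tolerance = 1e-10)
  expect_equal(unname(p$parameter), 27)

  # cross-check against stats::t.test on raw data via summaries
  set.seed(32)
  x <- rnorm(40, 1, 0.3); y <- rnorm(55, 1.15, 0.35)
  mine <- two_sample_t(summarize_durations(abs(x) + 0.1),
                       summarize_durations(abs(y) + 0.1))
  ref <- t.test(abs(x) + 0.1, abs(y) + 0.1)
  expect_equal(unname(mine$statistic), unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("t statistic has the expected symmetries", {
  a <- duration_summary(30, 0.8, 0.2)
  b <- duration_summary(45, 1.0, 0.3)
  ab <- two_sample_t(a, b); ba <- two_sample_t(b, a)
  expect_equal(unname(ab$statistic), -unname(ba$statistic))
  expect_equal(ab$p.value, ba$p.value)
  # shift invariance
  a2 <- duration_summary(30, 0.8 + 5, 0.2); b2 <- duration_summary(45, 1.0 + 5, 0.3)
  expect_equal(unname(two_sample_t(a2, b2)$statistic), unname(ab$statistic))
  # scale invariance
  a3 <- duration_summary(30, 0.8 * 3, 0.2 * 3); b3 <- duration_summary(45, 1.0 * 3, 0.3 * 3)
  expect_equal(unname(two_sample_t(a3, b3)$statistic), unname(ab$statistic),
               tolerance = 1e-12)
  # identical summaries: t = 0, p = 1
  eq <- two_sample_t(a, a)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)
})

test_that("the test is powerful at the published effect size", {
  # normal groups at the published means/sds, n = 500 each: rejection at
  # alpha = 1e-4 in >= 99% of 200 replicates
  set.seed(33)
  rejected <- replicate(200, {
    x <- rnorm(500, 0.86, 0.27)
    y <- rnorm(500, 1.00, 0.36)
    two_sample_t(summarize_durations(pmax(x, 0.01)),
                 summarize_durations(pmax(y, 0.01)))$p.value < 1e-4
  })
  expect_gte(mean(rejected), 0.99)
})
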