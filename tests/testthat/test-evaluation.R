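test_that("agreement metrics reproduce the published per-exam worked examples", {
  # EX07: perfect sensitivity, imperfect specificity
  ex07 <- confusion_counts(tp = 90, fp = 25, tn = 149, fn = 0)
  expect_equal(round(100 * sensitivity(ex07), 2), 100.00)
  expect_equal(round(100 * specificity(ex07), 2), 85.63)
  expect_equal(round(100 * accuracy(ex07), 2), 90.53)
  # EX02
  ex02 <- confusion_counts(tp = 865, fp = 25, tn = 965, fn = 1)
  expect_equal(round(100 * sensitivity(ex02), 2), 99.88)
  expect_equal(round(100 * specificity(ex02), 2), 97.47)
  expect_equal(round(100 * accuracy(ex02), 2), 98.60)
})

test_that("undefined metrics are reported as NA with a warning, never 0", {
  cc <- confusion_counts(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_warning(s <- sensitivity(cc), "undefined")
  expect_true(is.na(s))
  cc2 <- confusion_counts(tp = 4, fp = 0, tn = 0, fn = 2)
  expect_warning(sp <- specificity(cc2), "undefined")
  expect_true(is.na(sp))
})

test_that("metrics depend only on their own cells (locality)", {
  a <- confusion_counts(10, 2, 30, 4)
  b <- confusion_counts(10, 7, 99, 4)   # fp/tn changed
  expect_equal(sensitivity(a), sensitivity(b))
  expect_equal(npv(a) * (a$tn + a$fn), a$tn)  # npv uses tn/fn only
  c2 <- confusion_counts(99, 2, 30, 1)  # tp/fn changed
  expect_equal(specificity(a), specificity(c2))
  expect_equal(ppv(a), 10 / 12)
})

test_that("Cohen's kappa matches the marginal-product oracle and its fixed points", {
  cases <- rbind(c(43650, 1331, 48978, 326), c(90, 25, 149, 0),
                 c(5, 5, 5, 5), c(30, 1, 2, 40))
  for (i in seq_len(nrow(cases))) {
    cc <- confusion_counts(cases[i, 1], cases[i, 2], cases[i, 3], cases[i, 4])
    expect_equal(cohen_kappa(cc),
                 oracle_kappa(cases[i, 1], cases[i, 2], cases[i, 3],
                              cases[i, 4]),
                 tolerance = 1e-12)
  }
  # perfect agreement with both classes present is exactly 1
  expect_identical(cohen_kappa(confusion_counts(10, 0, 7, 0)), 1)
  # kappa = 1 requires fp = fn = 0
  expect_lt(cohen_kappa(confusion_counts(10, 1, 7, 0)), 1)
  # one-class table with full observed agreement still returns 1 exactly
  expect_identical(cohen_kappa(confusion_counts(5, 0, 0, 0)), 1)
})

test_that("event matching agrees with a brute-force all-pairs matcher", {
  # relabelings of identical intervals pair exactly
  tab <- data.frame(start_s = c(0, 2, 4), end_s = c(1, 3, 5), label = "S")
  m <- match_events(tab, tab)
  expect_equal(m$counts$tp, 3)
  expect_equal(m$counts$fp + m$counts$tn + m$counts$fn, 0)

  ref <- tab; ref$label <- c("S", "NS", "S")
  m <- match_events(tab, ref)
  expect_equal(m$counts$fp, 1)
  expect_equal(m$counts$tp, 2)

  set.seed(21)
  for (rep_i in 1:30) {
    n <- 20
    mk <- function() {
      s <- sort(runif(n, 0, 100))
      len <- runif(n, 0.2, 2)
      e <- pmin(s + len, c(s[-1] - 1e-3, Inf))
      keep <- e > s
      data.frame(start_s = s[keep], end_s = e[keep],
                 label = sample(c("S", "NS"), sum(keep), replace = TRUE))
    }
    pred <- mk(); ref <- mk()
    got <- match_events(pred, ref)$counts
    want <- oracle_match_counts(pred, ref)
    expect_equal(c(got$tp, got$fp, got$tn, got$fn),
                 unname(want[c("tp", "fp", "tn", "fn")]))
  }
})

test_that("malformed event tables are rejected", {
  bad <- data.frame(start_s = c(0, 0.5), end_s = c(1, 1.5), label = "S")
  ok <- data.frame(start_s = 0, end_s = 1, label = "S")
  expect_error(match_events(bad, ok), "malformed")
  expect_error(match_events(ok, data.frame(start_s = 0, end_s = 1,
                                           label = "X")), "malformed")
})

test_that("pooled report conserves counts and reproduces every printed row", {
  tab <- read_counts(validation_counts_path())
  rep <- agreement_report(tab)
  # pooled counts are the column sums
  expect_equal(rep$pooled_counts$tp, sum(tab$tp))
  expect_equal(rep$pooled_counts$fp, sum(tab$fp))
  expect_equal(rep$pooled_counts$tn, sum(tab$tn))
  expect_equal(rep$pooled_counts$fn, sum(tab$fn))
  # every per-exam percentage recomputed from its counts, half-up to 2 d.p.
  half_up <- function(x) floor(100 * x + 0.5) / 100
  for (i in seq_len(nrow(tab))) {
    cc <- confusion_counts(tab$tp[i], tab$fp[i], tab$tn[i], tab$fn[i])
    expect_equal(rep$per_exam$sensitivity_pct[i],
                 half_up(100 * tab$tp[i] / (tab$tp[i] + tab$fn[i])))
    expect_equal(rep$per_exam$specificity_pct[i],
                 half_up(100 * tab$tn[i] / (tab$tn[i] + tab$fp[i])))
    expect_equal(rep$per_exam$accuracy_pct[i],
                 half_up(100 * accuracy(cc)))
  }
  # single exam pools to itself; two identical exams add
  one <- agreement_report(tab[7, , drop = FALSE])
  expect_equal(unname(one$pooled["specificity"]),
               tab$tn[7] / (tab$tn[7] + tab$fp[7]))
  two <- agreement_report(data.frame(exam_id = c("a", "b"), tp = 1, fp = 0,
                                     tn = 1, fn = 0))
  expect_equal(unname(two$pooled["accuracy"]), 1)
  expect_equal(two$pooled_counts$tp, 2)
})

test_that("all pooled statistics lie in range and kappa is pooled, not averaged", {
  rep <- agreement_report(read_counts(validation_counts_path()))
  p <- rep$pooled
  expect_true(all(p[c("sensitivity", "specificity", "accuracy", "ppv",
                      "npv")] >= 0 &
                  p[c("sensitivity", "specificity", "accuracy", "ppv",
                      "npv")] <= 1))
  expect_lte(p["kappa"], 1)
  expect_equal(unname(p["kappa"]), cohen_kappa(rep$pooled_counts))
})
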