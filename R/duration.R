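#' Split snore durations into primary-snorer and OSAHS groups
#'
#' Pools snore-event durations across patients into two groups by the
#' apnea/hypopnea index: primary snorers have AHI below the cut (default 5
#' events/hour), OSAHS patients have AHI at or above it (an AHI of exactly 5
#' belongs to the OSAHS group).
#'
#' @param patients Data frame with columns `exam_id` and `ahi`.
#' @param events Data frame with columns `exam_id` and `duration_s` (only
#'   rows labelled `S` are used when a `label` column is present).
#' @param ahi_cut AHI threshold in events/hour (default 5).
#' @return A list with numeric vectors `primary` and `osahs` of pooled
#'   durations, and `n_patients` (named count per group).
#' @export
split_groups <- function(patients, events, ahi_cut = 5) {
  stopifnot(all(c("exam_id", "ahi") %in% names(patients)),
            all(c("exam_id", "duration_s") %in% names(events)))
  if (!nrow(patients)) stop("no patients")
  if (any(!is.finite(patients$ahi)) || any(patients$ahi < 0))
    stop("AHI must be finite and >= 0")
  if ("label" %in% names(events))
    events <- events[events$label %in% c("S", "snore"), , drop = FALSE]
  osahs_ids <- patients$exam_id[patients$ahi >= ahi_cut]
  primary_ids <- patients$exam_id[patients$ahi < ahi_cut]
  list(
    primary = events$duration_s[events$exam_id %in% primary_ids],
    osahs = events$duration_s[events$exam_id %in% osahs_ids],
    n_patients = c(primary = length(primary_ids), osahs = length(osahs_ids))
  )
}

#' Descriptive summary of snore-event durations
#'
#' @param durations Numeric vector of positive durations in seconds.
#' @return An object of class `duration_summary` with fields `n`, `mean_s`,
#'   `sd_s` (sample SD, n-1 denominator), `se_s` (= `sd_s / sqrt(n)`),
#'   `min_s`, `median_s`, `max_s`. With fewer than two values `sd_s` and
#'   `se_s` are `NA`.
#' @examples
#' summarize_durations(c(0.8, 1.1, 0.9, 1.4))
#' @export
summarize_durations <- function(durations) {
  durations <- as.numeric(durations)
  if (!length(durations)) stop("no durations")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be positive and finite")
  n <- length(durations)
  sd_s <- if (n >= 2L) stats::sd(durations) else NA_real_
  structure(
    list(n = n, mean_s = mean(durations), sd_s = sd_s,
         se_s = if (n >= 2L) sd_s / sqrt(n) else NA_real_,
         min_s = min(durations), median_s = stats::median(durations),
         max_s = max(durations)),
    class = "duration_summary"
  )
}

#' Build a duration summary from already-computed statistics
#'
#' Lets published group summaries (n, mean, SD) be used directly, e.g. when
#' raw event durations are not available.
#'
#' @param n Number of events.
#' @param mean_s,sd_s Mean and sample SD of the durations, in seconds.
#' @param min_s,median_s,max_s Optional order statistics.
#' @return A `duration_summary`.
#' @export
duration_summary <- function(n, mean_s, sd_s, min_s = NA_real_,
                             median_s = NA_real_, max_s = NA_real_) {
  stopifnot(n >= 1, is.finite(mean_s), is.na(sd_s) || sd_s >= 0)
  structure(
    list(n = as.integer(n), mean_s = mean_s, sd_s = sd_s,
         se_s = if (n >= 2L && !is.na(sd_s)) sd_s / sqrt(n) else NA_real_,
         min_s = min_s, median_s = median_s, max_s = max_s),
    class = "duration_summary"
  )
}

#' @export
print.duration_summary <- function(x, ...) {
  cat(sprintf("<duration_summary> n = %d events\n", x$n))
  cat(sprintf("  mean %.4f s  sd %.4f  se %.6f\n", x$mean_s, x$sd_s, x$se_s))
  cat(sprintf("  min %.2f  median %.2f  max %.2f\n",
              x$min_s, x$median_s, x$max_s))
  if (!is.na(x$se_s)) {
    ci <- ci95(x)
    cat(sprintf("  95%% CI [%.4f, %.4f]\n", ci[1], ci[2]))
  }
  invisible(x)
}

#' 95% confidence interval for a mean duration
#'
#' Normal-approximation interval `mean +/- 1.96 * se`; with the event counts
#' involved here (thousands of snores) the difference from a t-quantile is
#' below 1e-4 s.
#'
#' @param summary A `duration_summary` with a defined standard error.
#' @return Numeric vector `c(lo, hi)` in seconds.
#' @examples
#' ci95(duration_summary(n = 9993, mean_s = 0.8636, sd_s = 0.271))
#' @export
ci95 <- function(summary) {
  stopifnot(inherits(summary, "duration_summary"))
  if (is.na(summary$se_s)) stop("standard error undefined (n < 2)")
  summary$mean_s + c(-1, 1) * 1.96 * summary$se_s
}

#' Two-sample t-test from group summaries
#'
#' Tests the difference of mean snore durations between two groups using
#' only their summaries (n, mean, SD) - no raw data needed. The default is
#' Welch's unequal-variance statistic
#' `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with Satterthwaite degrees of
#' freedom; `method = "pooled"` gives the classic equal-variance Student
#' statistic. The p-value is two-sided.
#'
#' @param a,b `duration_summary` objects with `n >= 2` and defined SDs.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return An object of class `htest`.
#' @examples
#' osahs <- duration_summary(9993, 0.8636, 0.271)
#' primary <- duration_summary(7691, 1.002, 0.3562)
#' two_sample_t(osahs, primary)
#' @export
two_sample_t <- function(a, b, method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "duration_summary"), inherits(b, "duration_summary"))
  if (is.na(a$se_s) || is.na(b$se_s))
    stop("both groups need n >= 2 with defined standard errors")
  d <- a$mean_s - b$mean_s
  if (method == "welch") {
    v1 <- a$sd_s^2 / a$n; v2 <- b$sd_s^2 / b$n
    se <- sqrt(v1 + v2)
    df <- if (se > 0)
      (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1)) else a$n + b$n - 2
    meth <- "Welch two-sample t-test (from summaries)"
  } else {
    sp2 <- ((a$n - 1) * a$sd_s^2 + (b$n - 1) * b$sd_s^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    meth <- "Pooled two-sample t-test (from summaries)"
  }
  if (se == 0) {
    tstat <- if (d == 0) 0 else sign(d) * Inf
  } else {
    tstat <- d / se
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df),
         p.value = p,
         estimate = c(`mean of x` = a$mean_s, `mean of y` = b$mean_s),
         alternative = "two.sided", method = meth,
         data.name = sprintf("group summaries (n = %d, %d)", a$n, b$n)),
    class = "htest"
  )
}

#' Group comparison report for snore durations
#'
#' End-to-end duration analysis: splits pooled event durations by AHI group,
#' summarizes each group, forms 95% intervals and runs the two-sample test.
#'
#' @param events Data frame of snore events (`exam_id`, `duration_s`,
#'   optional `label`).
#' @param patients Data frame with `exam_id`, `ahi`.
#' @param ahi_cut AHI threshold (default 5).
#' @param method t-test flavour, `"welch"` or `"pooled"`.
#' @return An object of class `duration_report` with both group summaries,
#'   their intervals, and the `htest` result; `NULL` test when a group has
#'   fewer than two events.
#' @export
duration_report <- function(events, patients, ahi_cut = 5,
                            method = c("welch", "pooled")) {
  method <- match.arg(method)
  g <- split_groups(patients, events, ahi_cut)
  if (!length(g$primary) || !length(g$osahs))
    stop("a group has no snore events; cannot compare groups")
  s_prim <- summarize_durations(g$primary)
  s_osahs <- summarize_durations(g$osahs)
  test <- if (s_prim$n >= 2L && s_osahs$n >= 2L)
    two_sample_t(s_osahs, s_prim, method) else NULL
  structure(
    list(osahs = s_osahs, primary = s_prim,
         ci_osahs = if (!is.na(s_osahs$se_s)) ci95(s_osahs) else NULL,
         ci_primary = if (!is.na(s_prim$se_s)) ci95(s_prim) else NULL,
         test = test, ahi_cut = ahi_cut, n_patients = g$n_patients),
    class = "duration_report"
  )
}

#' @export
print.duration_report <- function(x, ...) {
  cat(sprintf(
    "<duration_report> AHI cut %g: %d primary snorers, %d OSAHS patients\n",
    x$ahi_cut, x$n_patients["primary"], x$n_patients["osahs"]))
  cat("OSAHS group:\n"); print(x$osahs)
  cat("Primary snorer group:\n"); print(x$primary)
  if (!is.null(x$test)) {
    cat(sprintf("Mean difference (OSAHS - primary): %.4f s\n",
                x$osahs$mean_s - x$primary$mean_s))
    print(x$test)
  }
  invisible(x)
}

#' Serialize a duration report to JSON
#'
#' @param report A [duration_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_duration_report <- function(report, path) {
  stopifnot(inherits(report, "duration_report"))
  summ <- function(s, ci) list(
    n = s$n, mean_s = s$mean_s, sd_s = s$sd_s, se_s = s$se_s,
    min_s = s$min_s, median_s = s$median_s, max_s = s$max_s,
    ci95 = if (is.null(ci)) NULL else round(ci, 4))
  obj <- list(
    ahi_cut = report$ahi_cut,
    osahs = summ(report$osahs, report$ci_osahs),
    primary = summ(report$primary, report$ci_primary),
    test = if (is.null(report$test)) NULL else list(
      method = report$test$method,
      t = unname(report$test$statistic),
      df = unname(report$test$parameter),
      p_two_sided = report$test$p.value)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
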