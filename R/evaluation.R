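#' Confusion counts for detector-vs-observer agreement
#'
#' Holds the 2x2 table comparing the automatic detector (positive = snore)
#' with the trained-observer reference: true positives (both say snore),
#' false positives (detector snore, observer non-snore), true negatives
#' (both non-snore) and false negatives (detector non-snore or missed,
#' observer snore). The number of reference snores is `tp + fn`.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param exam_id Optional exam label.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 90, fp = 25, tn = 149, fn = 0)
#' @export
confusion_counts <- function(tp, fp, tn, fn, exam_id = NA_character_) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x)))
    stop("counts must be non-negative integers")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn),
                 exam_id = as.character(exam_id)[1L]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts>%s tp=%g fp=%g tn=%g fn=%g (N=%g)\n",
              if (is.na(x$exam_id)) "" else paste0(" ", x$exam_id),
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

ratio_or_undefined <- function(num, den, what) {
  if (den <= 0) {
    warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Agreement metrics from a 2x2 confusion table
#'
#' Standard diagnostic-agreement proportions: sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, accuracy `(tp+tn)/N`, positive predictive value
#' `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`. A metric with a
#' zero denominator is undefined and returned as `NA` with a warning, never
#' silently 0.
#'
#' @param c A [confusion_counts()] object.
#' @return A proportion in \[0, 1\], or `NA` when undefined.
#' @examples
#' cc <- confusion_counts(tp = 43650, fp = 1331, tn = 48978, fn = 326)
#' 100 * sensitivity(cc)  # 99.26
#' @name agreement-metrics
NULL

#' @rdname agreement-metrics
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio_or_undefined(c$tp, c$tp + c$fn, "sensitivity")
}

#' @rdname agreement-metrics
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio_or_undefined(c$tn, c$tn + c$fp, "specificity")
}

#' @rdname agreement-metrics
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio_or_undefined(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")
}

#' @rdname agreement-metrics
#' @export
ppv <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio_or_undefined(c$tp, c$tp + c$fp, "positive predictive value")
}

#' @rdname agreement-metrics
#' @export
npv <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio_or_undefined(c$tn, c$tn + c$fn, "negative predictive value")
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between the detector and the observer:
#' `kappa = (Po - Pe) / (1 - Pe)`, where `Po = (tp + tn) / N` is the
#' observed agreement and
#' `Pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / N^2`
#' the agreement expected from the marginal label frequencies. Returns
#' exactly 1 when `Po = 1` and `NA` (with a warning) in the degenerate case
#' `Pe = 1`, where chance correction is undefined.
#'
#' @param c A [confusion_counts()] with total `N >= 1`.
#' @return Cohen's kappa, a real number `<= 1`.
#' @examples
#' cohen_kappa(confusion_counts(tp = 43650, fp = 1331, tn = 48978, fn = 326))
#' @export
cohen_kappa <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$tn + c$fn
  if (n < 1) stop("empty table")
  po <- (c$tp + c$tn) / n
  if (po == 1) return(1)
  pe <- ((c$tp + c$fp) * (c$tp + c$fn) + (c$fn + c$tn) * (c$fp + c$tn)) / n^2
  if (pe >= 1) {
    warning("kappa undefined: chance agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Match two event tables and count agreement
#'
#' Pairs predicted (detector) and reference (observer) events one-to-one,
#' greedily by largest temporal overlap, requiring the overlap to cover at
#' least `min_overlap_frac` of the shorter interval. Pairs contribute to the
#' 2x2 table by their labels (`S` = snore, `NS` = non-snore): (S, S) is a
#' true positive, (S, NS) a false positive, (NS, NS) a true negative and
#' (NS, S) a false negative. Unmatched reference snores are false negatives.
#' When the reference rows are relabelings of the very same intervals the
#' pairing is exact.
#'
#' @param predicted,reference Data frames with columns `start_s`, `end_s`,
#'   `label` (values `S` / `NS`). Intervals within each table must not
#'   overlap.
#' @param min_overlap_frac Required overlap as a fraction of the shorter
#'   interval, in (0, 1\] (default 0.5).
#' @return A list with `pairs` (data frame of matched indices and labels)
#'   and `counts` (a [confusion_counts()]).
#' @export
match_events <- function(predicted, reference, min_overlap_frac = 0.5) {
  check_table <- function(tab, nm) {
    need <- c("start_s", "end_s", "label")
    if (!all(need %in% names(tab)))
      stop(sprintf("%s table needs columns start_s, end_s, label", nm))
    if (nrow(tab) && any(tab$end_s <= tab$start_s))
      stop(sprintf("malformed event table (%s): non-positive intervals", nm))
    if (!all(tab$label %in% c("S", "NS")))
      stop(sprintf("malformed event table (%s): labels must be S or NS", nm))
    if (nrow(tab) > 1L) {
      o <- order(tab$start_s)
      if (any(tab$start_s[o][-1L] < tab$end_s[o][-nrow(tab)] - 1e-9))
        stop(sprintf("malformed event table (%s): overlapping intervals", nm))
    }
    tab
  }
  if (!(min_overlap_frac > 0 && min_overlap_frac <= 1))
    stop("'min_overlap_frac' must be in (0, 1]")
  predicted <- check_table(predicted, "predicted")
  reference <- check_table(reference, "reference")
  np <- nrow(predicted); nr <- nrow(reference)
  ov <- matrix(0, np, nr)
  if (np && nr) {
    for (i in seq_len(np)) {
      o <- pmin(predicted$end_s[i], reference$end_s) -
           pmax(predicted$start_s[i], reference$start_s)
      len_short <- pmin(predicted$end_s[i] - predicted$start_s[i],
                        reference$end_s - reference$start_s)
      frac <- o / len_short
      ov[i, ] <- ifelse(o > 0 & frac >= min_overlap_frac - 1e-9, o, 0)
    }
  }
  pairs <- data.frame(pred = integer(0), ref = integer(0),
                      pred_label = character(0), ref_label = character(0),
                      stringsAsFactors = FALSE)
  while (any(ov > 0)) {
    k <- arrayInd(which.max(ov), dim(ov))
    i <- k[1L]; j <- k[2L]
    pairs <- rbind(pairs, data.frame(
      pred = i, ref = j,
      pred_label = predicted$label[i], ref_label = reference$label[j],
      stringsAsFactors = FALSE))
    ov[i, ] <- 0; ov[, j] <- 0
  }
  tp <- sum(pairs$pred_label == "S" & pairs$ref_label == "S")
  fp <- sum(pairs$pred_label == "S" & pairs$ref_label == "NS")
  tn <- sum(pairs$pred_label == "NS" & pairs$ref_label == "NS")
  fn <- sum(pairs$pred_label == "NS" & pairs$ref_label == "S")
  unmatched_ref <- setdiff(seq_len(nr), pairs$ref)
  fn <- fn + sum(reference$label[unmatched_ref] == "S")
  list(pairs = pairs, counts = confusion_counts(tp, fp, tn, fn))
}

#' Pooled agreement report across exams
#'
#' Sums per-exam confusion counts into a pooled 2x2 table and computes
#' sensitivity, specificity, accuracy, PPV, NPV and Cohen's kappa both per
#' exam and pooled, plus the per-exam range of sensitivity and specificity.
#' Kappa is computed on the pooled table, not averaged over exams.
#'
#' @param per_exam A list of [confusion_counts()] objects (or a data frame
#'   with columns `exam_id`, `tp`, `fp`, `tn`, `fn`).
#' @return An object of class `agreement_report` with elements `per_exam`
#'   (data frame of counts and percentage metrics), `pooled_counts`,
#'   `pooled` (named numeric proportions + kappa) and `range` (min/max
#'   per-exam sensitivity and specificity, as proportions).
#' @examples
#' tab <- read_counts(system.file("extdata", "validation_confusion_counts.csv",
#'                                package = "snoredetect"))
#' rep <- agreement_report(tab)
#' rep
#' @export
agreement_report <- function(per_exam) {
  if (is.data.frame(per_exam)) {
    per_exam <- lapply(seq_len(nrow(per_exam)), function(i)
      confusion_counts(per_exam$tp[i], per_exam$fp[i], per_exam$tn[i],
                       per_exam$fn[i],
                       exam_id = if ("exam_id" %in% names(per_exam))
                         per_exam$exam_id[i] else NA))
  }
  if (!length(per_exam)) stop("need at least one exam")
  stopifnot(all(vapply(per_exam, inherits, logical(1), "confusion_counts")))
  pooled_counts <- Reduce(`+`, per_exam)
  per <- do.call(rbind, lapply(per_exam, function(cc) {
    data.frame(exam_id = cc$exam_id, tp = cc$tp, fp = cc$fp, tn = cc$tn,
               fn = cc$fn,
               sensitivity_pct = round_half_up(100 * sensitivity(cc), 2),
               specificity_pct = round_half_up(100 * specificity(cc), 2),
               accuracy_pct = round_half_up(100 * accuracy(cc), 2),
               stringsAsFactors = FALSE)
  }))
  pooled <- c(sensitivity = sensitivity(pooled_counts),
              specificity = specificity(pooled_counts),
              accuracy = accuracy(pooled_counts),
              ppv = ppv(pooled_counts), npv = npv(pooled_counts),
              kappa = cohen_kappa(pooled_counts))
  rng_or_na <- function(x)
    if (all(is.na(x))) c(NA_real_, NA_real_) else range(x, na.rm = TRUE)
  rng <- list(
    sensitivity = rng_or_na(per$sensitivity_pct / 100),
    specificity = rng_or_na(per$specificity_pct / 100))
  structure(list(per_exam = per, pooled_counts = pooled_counts,
                 pooled = pooled, range = rng),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<agreement_report> %d exams, N = %g candidate events\n",
              nrow(x$per_exam),
              with(x$pooled_counts, tp + fp + tn + fn)))
  cat(sprintf("  pooled: sensitivity %s%%  specificity %s%%  accuracy %s%%\n",
              fmt_pct(p["sensitivity"]), fmt_pct(p["specificity"]),
              fmt_pct(p["accuracy"])))
  cat(sprintf("          PPV %s%%  NPV %s%%  kappa %.2f\n",
              fmt_pct(p["ppv"]), fmt_pct(p["npv"]), p["kappa"]))
  cat(sprintf("  per-exam sensitivity %.2f%%-%.2f%%, specificity %.2f%%-%.2f%%\n",
              100 * x$range$sensitivity[1], 100 * x$range$sensitivity[2],
              100 * x$range$specificity[1], 100 * x$range$specificity[2]))
  invisible(x)
}

# round half away from zero (display convention for percentages)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_pct <- function(p) {
  if (is.na(p)) "undefined" else sprintf("%.2f", round_half_up(100 * p, 2))
}

#' Serialize an agreement report to JSON
#'
#' @param report An [agreement_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  p <- report$pooled
  obj <- list(
    n_exams = nrow(report$per_exam),
    pooled_counts = report$pooled_counts[c("tp", "fp", "tn", "fn")],
    pooled = list(
      sensitivity = unname(round(p[["sensitivity"]], 4)),
      specificity = unname(round(p[["specificity"]], 4)),
      accuracy = unname(round(p[["accuracy"]], 4)),
      ppv = unname(round(p[["ppv"]], 4)),
      npv = unname(round(p[["npv"]], 4)),
      kappa = unname(round(p[["kappa"]], 4)),
      sensitivity_pct = fmt_pct(p[["sensitivity"]]),
      specificity_pct = fmt_pct(p[["specificity"]]),
      accuracy_pct = fmt_pct(p[["accuracy"]]),
      ppv_pct = fmt_pct(p[["ppv"]]),
      npv_pct = fmt_pct(p[["npv"]])
    ),
    per_exam = report$per_exam
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score a detection against simulator ground truth
#'
#' Builds S/NS event tables from a [detect_snores()] result and a
#' ground-truth table (`kind` of `snore` / `artifact`) and matches them with
#' [match_events()]. Unlike the observer-relabelling convention - where
#' every reference row is one of the detector's own events - a predicted
#' snore that matches nothing in the truth is counted as a false positive
#' here, since against ground truth it is a hallucinated event.
#'
#' @param detection A `snore_detection`.
#' @param truth A ground-truth table with `start_s`, `end_s`, `kind`.
#' @param min_overlap_frac Overlap requirement passed to [match_events()].
#' @return A list with `pairs` and `counts` (a [confusion_counts()]).
#' @export
evaluate_detection <- function(detection, truth, min_overlap_frac = 0.5) {
  stopifnot(inherits(detection, "snore_detection"))
  ev <- detection$events
  pred <- data.frame(start_s = ev$start_s, end_s = ev$end_s,
                     label = ifelse(ev$label == "snore", "S", "NS"),
                     stringsAsFactors = FALSE)
  ref <- data.frame(start_s = truth$start_s, end_s = truth$end_s,
                    label = ifelse(truth$kind == "snore", "S", "NS"),
                    stringsAsFactors = FALSE)
  m <- match_events(pred, ref, min_overlap_frac)
  unmatched_pred <- setdiff(seq_len(nrow(pred)), m$pairs$pred)
  extra_fp <- sum(pred$label[unmatched_pred] == "S")
  cc <- m$counts
  list(pairs = m$pairs,
       counts = confusion_counts(cc$tp, cc$fp + extra_fp, cc$tn, cc$fn))
}
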