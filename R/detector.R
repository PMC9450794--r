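#' Windowed RMS envelope of a snore signal
#'
#' Tiles the signal into contiguous, non-overlapping windows of
#' `params$window_ms` milliseconds and computes the effective (root-mean-
#' square) value of each complete window. At the default 200 Hz / 100 ms this
#' gives one envelope value per 20 samples; a trailing partial window is
#' dropped, so the output length is `floor(n_samples / window_samples)`.
#'
#' @param trace A [snore_trace()].
#' @param params A [detector_params()] object (only `window_ms` is used).
#' @return An object of class `snore_envelope`: list with `values`
#'   (non-negative RMS per window), `frame_period_s` (= `window_ms / 1000`)
#'   and `start_offset` (seconds of the first frame's start).
#' @examples
#' tr <- snore_trace(rep(3, 1000), fs = 200)
#' rms_envelope(tr)$values  # all 3
#' @export
rms_envelope <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "snore_trace"), inherits(params, "detector_params"))
  ws <- as.integer(round(trace$fs * params$window_ms / 1000))
  if (ws < 1L) stop("window shorter than one sample at this sampling rate")
  n <- length(trace$samples)
  if (n < ws) stop("signal too short: fewer samples than one analysis window")
  nwin <- n %/% ws
  m <- matrix(trace$samples[seq_len(nwin * ws)]^2, nrow = ws)
  structure(
    list(values = sqrt(.colMeans(m, ws, nwin)),
         frame_period_s = params$window_ms / 1000,
         start_offset = trace$start_offset),
    class = "snore_envelope"
  )
}

#' @export
print.snore_envelope <- function(x, ...) {
  cat(sprintf("<snore_envelope> %d frames at %g s spacing (%.1f s)\n",
              length(x$values), x$frame_period_s,
              length(x$values) * x$frame_period_s))
  invisible(x)
}

#' Causal moving-average smoothing of an envelope
#'
#' Low-pass filters the envelope with a causal moving average over the last
#' `ma_len` envelope samples (1 s of smoothing at the default 10 samples of
#' 0.1 s each). Start-edge frames average over the shorter available history,
#' so the output has the same length and no zero-padding bias.
#'
#' @param env A `snore_envelope`.
#' @param ma_len Moving-average length in envelope samples (default 10).
#' @return A `snore_envelope` of the same length and frame period.
#' @export
smooth_envelope <- function(env, ma_len = 10) {
  stopifnot(inherits(env, "snore_envelope"))
  ma_len <- as.integer(ma_len)
  if (length(ma_len) != 1L || is.na(ma_len) || ma_len < 1L)
    stop("'ma_len' must be a single integer >= 1")
  v <- env$values
  n <- length(v)
  cs <- cumsum(v)
  i <- seq_len(n)
  lag <- pmin(i, ma_len)
  tot <- cs - c(rep(0, min(ma_len, n)), cs[seq_len(max(0L, n - ma_len))])
  env$values <- tot / lag
  env
}

#' Baseline ("silence") level of an envelope
#'
#' Estimates the background envelope level against which event thresholds
#' are set, as the median (robust when snoring occupies a minority of
#' frames) or an arbitrary percentile of the envelope. A strictly positive
#' floor at machine-epsilon scale is applied so that multiples of the
#' baseline are always well defined.
#'
#' @param env A `snore_envelope` (normally the smoothed one).
#' @param method `"median"` (default) or `"percentile"`.
#' @param percentile Percentile in (0, 100) when `method = "percentile"`.
#' @return A single positive baseline level.
#' @export
estimate_baseline <- function(env, method = c("median", "percentile"),
                              percentile = 50) {
  stopifnot(inherits(env, "snore_envelope"))
  method <- match.arg(method)
  v <- env$values
  if (length(v) == 0L) stop("empty envelope")
  level <- if (method == "median") stats::median(v)
           else stats::quantile(v, probs = percentile / 100, names = FALSE)
  max(level, .Machine$double.eps * max(1, max(v)))
}

#' Segment supra-threshold events in a smoothed envelope
#'
#' Hysteresis threshold crossing: an event opens at the first frame where
#' the envelope rises to at least `threshold_ratio` times the baseline and
#' closes when it falls below `release_ratio` times the baseline. Events
#' separated by a sub-threshold gap of at most `merge_gap_s` seconds are
#' merged. Boundaries are reported in seconds at frame resolution, as
#' half-open intervals `[start_s, end_s)` aligned to frame starts.
#'
#' @param env A smoothed `snore_envelope`.
#' @param params A [detector_params()].
#' @param baseline Baseline level; computed via [estimate_baseline()] with
#'   the params' baseline settings when `NULL`.
#' @return A data frame with columns `start_s`, `end_s` (and attribute
#'   `baseline`), one row per event, strictly ordered and non-overlapping.
#' @export
segment_events <- function(env, params = detector_params(), baseline = NULL) {
  stopifnot(inherits(env, "snore_envelope"), inherits(params, "detector_params"))
  v <- env$values
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(v) == 0L) return(empty)
  if (is.null(baseline))
    baseline <- estimate_baseline(env, params$baseline_method,
                                  params$baseline_percentile)
  enter <- params$threshold_ratio * baseline
  release <- params$release_ratio * baseline
  above_rel <- v >= release
  if (!any(above_rel)) {
    attr(empty, "baseline") <- baseline
    return(empty)
  }
  # maximal runs of frames >= release; an event is such a run that contains
  # at least one frame >= enter, starting at its first entering frame
  r <- rle(above_rel)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  starts <- integer(0); ends <- integer(0)
  for (k in which(r$values)) {
    idx <- run_start[k]:run_end[k]
    hit <- idx[v[idx] >= enter]
    if (length(hit)) {
      starts <- c(starts, hit[1L])
      ends <- c(ends, run_end[k])
    }
  }
  if (!length(starts)) {
    attr(empty, "baseline") <- baseline
    return(empty)
  }
  fp <- env$frame_period_s
  # merge events separated by a gap <= merge_gap_s
  if (length(starts) > 1L && params$merge_gap_s > 0) {
    keep_s <- starts[1L]; out_s <- integer(0); out_e <- integer(0)
    cur_e <- ends[1L]
    for (k in 2L:length(starts)) {
      gap_s <- (starts[k] - 1L - cur_e) * fp
      if (gap_s <= params$merge_gap_s + 1e-12) {
        cur_e <- ends[k]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- starts[k]; cur_e <- ends[k]
      }
    }
    out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
    starts <- out_s; ends <- out_e
  }
  out <- data.frame(
    start_s = env$start_offset + (starts - 1L) * fp,
    end_s = env$start_offset + ends * fp
  )
  attr(out, "baseline") <- baseline
  attr(out, "frame_index") <- cbind(start = starts, end = ends)
  out
}

#' Classify event durations as snore / non-snore
#'
#' An event is a snore if and only if its duration lies in the closed
#' interval `[min_dur_s, max_dur_s]` (default 0.6 to 2 s); anything shorter
#' or longer (voice, coughs, other artifacts) is a non-snore. Comparison
#' uses a 1e-9 s tolerance so frame-quantised durations sit on the
#' boundaries exactly.
#'
#' @param duration_s Numeric vector of positive event durations in seconds.
#' @param params A [detector_params()].
#' @return Character vector of `"snore"` / `"non_snore"`.
#' @examples
#' classify_event(c(0.3, 0.6, 1, 2, 2.5))
#' @export
classify_event <- function(duration_s, params = detector_params()) {
  if (!is.numeric(duration_s) || any(!is.finite(duration_s)) ||
      any(duration_s <= 0))
    stop("'duration_s' must be positive and finite")
  tol <- 1e-9
  ifelse(duration_s >= params$min_dur_s - tol &
         duration_s <= params$max_dur_s + tol, "snore", "non_snore")
}

# Refine segmented boundaries on the unsmoothed envelope: the causal moving
# average delays onsets and stretches offsets by up to ma_len frames, so the
# release-threshold crossings of the raw RMS envelope inside the segmented
# region (extended left by the filter length) locate the event edges.
refine_boundaries <- function(raw_values, seg_idx, ma_len, release_level) {
  n_ev <- nrow(seg_idx)
  out <- seg_idx
  prev_end <- 0L
  for (k in seq_len(n_ev)) {
    lo <- max(prev_end + 1L, seg_idx[k, 1L] - ma_len + 1L)
    hi <- seg_idx[k, 2L]
    idx <- lo:hi
    hot <- idx[raw_values[idx] >= release_level]
    if (length(hot)) {
      out[k, 1L] <- hot[1L]
      out[k, 2L] <- hot[length(hot)]
    }
    prev_end <- out[k, 2L]
  }
  out
}

#' Detect and classify snore events in a signal trace
#'
#' Runs the full four-step detector on a raw snore-channel trace: windowed
#' RMS envelope, causal moving-average smoothing, hysteresis segmentation
#' against a robust baseline, and duration gating into snore / non-snore.
#' Event boundaries found on the smoothed envelope are refined against the
#' unsmoothed envelope so that the moving-average group delay does not bias
#' onsets or stretch durations.
#'
#' @param trace A [snore_trace()].
#' @param params A [detector_params()].
#' @return An object of class `snore_detection`: a list with `events` (data
#'   frame `start_s`, `end_s`, `duration_s`, `peak_env`, `label`),
#'   `baseline`, `envelope` (raw), `smoothed` (smoothed envelope), `params`,
#'   `exam_id`, `fs` and `duration_s` (trace length in seconds).
#' @examples
#' sim <- simulate_exam(sim_config(duration_s = 60, seed = 1))
#' det <- detect_snores(sim$trace)
#' det
#' @export
detect_snores <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "snore_trace"))
  env <- rms_envelope(trace, params)
  sm <- smooth_envelope(env, params$ma_len)
  baseline <- estimate_baseline(sm, params$baseline_method,
                                params$baseline_percentile)
  seg <- segment_events(sm, params, baseline = baseline)
  fp <- env$frame_period_s
  if (nrow(seg) == 0L) {
    events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         duration_s = numeric(0), peak_env = numeric(0),
                         label = character(0), stringsAsFactors = FALSE)
  } else {
    idx <- attr(seg, "frame_index")
    idx <- refine_boundaries(env$values, idx, params$ma_len,
                             params$release_ratio * baseline)
    start_s <- env$start_offset + (idx[, 1L] - 1L) * fp
    end_s <- env$start_offset + idx[, 2L] * fp
    duration_s <- (idx[, 2L] - idx[, 1L] + 1L) * fp
    peak_env <- vapply(seq_len(nrow(idx)), function(k)
      max(sm$values[idx[k, 1L]:idx[k, 2L]]), numeric(1))
    events <- data.frame(start_s = start_s, end_s = end_s,
                         duration_s = duration_s, peak_env = peak_env,
                         label = classify_event(duration_s, params),
                         stringsAsFactors = FALSE)
  }
  structure(
    list(events = events, baseline = baseline, envelope = env, smoothed = sm,
         params = params, exam_id = trace$exam_id, fs = trace$fs,
         duration_s = trace_duration(trace)),
    class = "snore_detection"
  )
}

#' @export
print.snore_detection <- function(x, ...) {
  n_sn <- sum(x$events$label == "snore")
  n_ns <- sum(x$events$label == "non_snore")
  cat(sprintf("<snore_detection> exam '%s' (%.1f s at %g Hz)\n",
              x$exam_id, x$duration_s, x$fs))
  cat(sprintf("  baseline envelope level: %.4g\n", x$baseline))
  cat(sprintf("  events: %d snores, %d non-snore events\n", n_sn, n_ns))
  invisible(x)
}

#' @export
summary.snore_detection <- function(object, ...) {
  ev <- object$events
  sn <- ev$duration_s[ev$label == "snore"]
  out <- list(exam_id = object$exam_id, n_events = nrow(ev),
              n_snores = length(sn),
              snore_summary = if (length(sn)) summarize_durations(sn) else NULL,
              snore_rate_per_min = length(sn) / (object$duration_s / 60))
  class(out) <- "summary.snore_detection"
  out
}

#' @export
print.summary.snore_detection <- function(x, ...) {
  cat(sprintf("Exam '%s': %d events, %d snores (%.2f snores/min)\n",
              x$exam_id, x$n_events, x$n_snores, x$snore_rate_per_min))
  if (!is.null(x$snore_summary)) print(x$snore_summary)
  invisible(x)
}

#' @export
as.data.frame.snore_detection <- function(x, ...) {
  if (nrow(x$events) == 0L)
    return(cbind(data.frame(exam_id = character(0)), x$events))
  cbind(data.frame(exam_id = x$exam_id, stringsAsFactors = FALSE), x$events)
}

#' Plot a detection: smoothed envelope, thresholds and events
#'
#' @param x A `snore_detection`.
#' @param xlim Optional time range (seconds) to display.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.snore_detection <- function(x, xlim = NULL, ...) {
  fp <- x$smoothed$frame_period_s
  t <- x$smoothed$start_offset + (seq_along(x$smoothed$values) - 1) * fp
  if (is.null(xlim)) xlim <- range(t)
  graphics::plot(t, x$smoothed$values, type = "l", xlim = xlim,
                 xlab = "time (s)", ylab = "smoothed RMS envelope",
                 main = sprintf("Exam '%s'", x$exam_id), ...)
  graphics::abline(h = x$params$threshold_ratio * x$baseline,
                   col = "red", lty = 2)
  graphics::abline(h = x$params$release_ratio * x$baseline,
                   col = "orange", lty = 3)
  ev <- x$events
  if (nrow(ev)) {
    col <- ifelse(ev$label == "snore",
                  grDevices::adjustcolor("forestgreen", 0.3),
                  grDevices::adjustcolor("grey40", 0.3))
    graphics::rect(ev$start_s, 0, ev$end_s, max(x$smoothed$values),
                   col = col, border = NA)
  }
  invisible(x)
}
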