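#' Construct a snore-channel signal trace
#'
#' A `snore_trace` holds one exam's single-channel electric snore signal:
#' the raw voltage-like samples from a contact microphone fed through a
#' polysomnograph auxiliary channel, typically digitised at 200 Hz.
#'
#' @param samples Numeric vector of finite signal samples (arbitrary units,
#'   signed). Length must be at least 1.
#' @param fs Sampling rate in Hz (default 200).
#' @param exam_id Character label for the exam.
#' @param start_offset Time in seconds of the first sample relative to the
#'   recording start (default 0).
#'
#' @return An object of class `snore_trace`: a list with elements
#'   `samples`, `fs`, `exam_id`, `start_offset`.
#' @examples
#' tr <- snore_trace(sin(2 * pi * 40 * seq(0, 1, by = 1 / 200)), fs = 200)
#' tr
#' @export
snore_trace <- function(samples, fs = 200, exam_id = "exam", start_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must contain at least one value")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (!is.numeric(start_offset) || length(start_offset) != 1L ||
      !is.finite(start_offset) || start_offset < 0)
    stop("'start_offset' must be a single non-negative number")
  structure(
    list(samples = samples, fs = fs,
         exam_id = as.character(exam_id)[1L],
         start_offset = start_offset),
    class = "snore_trace"
  )
}

#' @export
print.snore_trace <- function(x, ...) {
  cat(sprintf("<snore_trace> exam '%s': %d samples at %g Hz (%.1f s)\n",
              x$exam_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.snore_trace <- function(x) length(x$samples)

#' Duration of a trace in seconds
#' @param trace A [snore_trace()].
#' @return Length of the recording in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "snore_trace"))
  length(trace$samples) / trace$fs
}

#' Detector parameters
#'
#' Bundles the tunable constants of the snore detector. Defaults follow the
#' published algorithm: 100 ms analysis windows, a 10-sample moving average
#' on the envelope (1 s of smoothing), a 0.6-2 s snore duration gate, and an
#' event threshold of twice the baseline ("silence") level.
#'
#' @param window_ms Analysis window length in milliseconds (default 100).
#' @param ma_len Moving-average length in envelope samples (default 10).
#' @param min_dur_s,max_dur_s Closed duration interval, in seconds, inside
#'   which an event is classified as a snore (defaults 0.6 and 2.0).
#' @param threshold_ratio Event onset threshold as a multiple of the baseline
#'   envelope level (default 2.0).
#' @param release_ratio Hysteresis release threshold as a multiple of the
#'   baseline; must satisfy `threshold_ratio >= release_ratio > 1`
#'   (default 1.5).
#' @param merge_gap_s Maximum sub-threshold gap, in seconds, across which two
#'   supra-threshold runs are merged into one event (default 0.2).
#' @param baseline_method `"median"` (default) or `"percentile"`.
#' @param baseline_percentile Percentile in (0, 100) used when
#'   `baseline_method = "percentile"` (default 50).
#'
#' @return An object of class `detector_params`.
#' @examples
#' detector_params()
#' detector_params(threshold_ratio = 3, merge_gap_s = 0)
#' @export
detector_params <- function(window_ms = 100, ma_len = 10,
                            min_dur_s = 0.6, max_dur_s = 2.0,
                            threshold_ratio = 2.0, release_ratio = 1.5,
                            merge_gap_s = 0.2,
                            baseline_method = c("median", "percentile"),
                            baseline_percentile = 50) {
  baseline_method <- match.arg(baseline_method)
  chk1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  chk1(window_ms, "window_ms"); chk1(ma_len, "ma_len")
  chk1(min_dur_s, "min_dur_s"); chk1(max_dur_s, "max_dur_s")
  chk1(threshold_ratio, "threshold_ratio"); chk1(release_ratio, "release_ratio")
  chk1(merge_gap_s, "merge_gap_s")
  if (window_ms <= 0) stop("'window_ms' must be > 0")
  if (ma_len < 1) stop("'ma_len' must be >= 1")
  if (!(min_dur_s > 0 && min_dur_s < max_dur_s))
    stop("need 0 < min_dur_s < max_dur_s")
  if (!(threshold_ratio >= release_ratio && release_ratio > 1))
    stop("need threshold_ratio >= release_ratio > 1")
  if (merge_gap_s < 0) stop("'merge_gap_s' must be >= 0")
  if (baseline_method == "percentile") {
    chk1(baseline_percentile, "baseline_percentile")
    if (baseline_percentile <= 0 || baseline_percentile >= 100)
      stop("'baseline_percentile' must be in (0, 100)")
  }
  structure(
    list(window_ms = window_ms, ma_len = as.integer(ma_len),
         min_dur_s = min_dur_s, max_dur_s = max_dur_s,
         threshold_ratio = threshold_ratio, release_ratio = release_ratio,
         merge_gap_s = merge_gap_s, baseline_method = baseline_method,
         baseline_percentile = baseline_percentile),
    class = "detector_params"
  )
}

#' @export
print.detector_params <- function(x, ...) {
  cat("<detector_params>\n")
  cat(sprintf("  window: %g ms; moving average: %d envelope samples\n",
              x$window_ms, x$ma_len))
  cat(sprintf("  snore duration gate: [%g, %g] s\n", x$min_dur_s, x$max_dur_s))
  cat(sprintf("  thresholds: enter %gx / release %gx baseline (%s); merge gap %g s\n",
              x$threshold_ratio, x$release_ratio, x$baseline_method,
              x$merge_gap_s))
  invisible(x)
}
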