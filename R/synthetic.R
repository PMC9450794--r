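# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# truncated-normal draws by rejection (bounds are a few sd from the mean here,
# so acceptance is high; falls back to runif over the range if needed)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 1000L) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
    tries <- tries + 1L
  }
  if (length(out) < n)
    out <- c(out, stats::runif(n - length(out), lo, hi))
  out[seq_len(n)]
}

# Tukey (tapered-cosine) window, taper fraction a per the full window
tukey_window <- function(n, a = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- a / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / a - 1)))
  w
}

#' Configuration of the synthetic snore-channel simulator
#'
#' Describes a 200 Hz electric snore channel as recorded through a
#' polysomnograph auxiliary input: Gaussian baseline noise, at most one
#' band-limited snore burst per respiratory cycle, and occasional
#' out-of-duration artifact bursts (voice- or cough-like).
#'
#' @param fs Sampling rate in Hz (default 200).
#' @param duration_s Recording length in seconds (default 600).
#' @param resp_period_s Mean respiratory cycle length in seconds
#'   (default 4).
#' @param resp_jitter Relative jitter of the cycle length (default 0.15).
#' @param snore_prob Probability that a cycle contains a snore (default 0.5).
#' @param snore_dur_range_s Closed range of snore durations in seconds
#'   (default `c(0.6, 2)`).
#' @param snore_dur_mean_s,snore_dur_sd_s Mean and SD of the truncated-normal
#'   duration draw (defaults 1.0 and 0.3 s).
#' @param carrier_band_hz Oscillation band of the burst carrier in Hz
#'   (default `c(20, 80)`; upper edge must stay below `fs / 2`).
#' @param snr Burst-to-baseline RMS ratio measured on the trace (default 4;
#'   must exceed 1).
#' @param artifact_rate_per_min Poisson rate of artifact bursts per minute
#'   (default 0.5); artifact durations are drawn uniformly from
#'   `[0.1, 0.55] U [2.1, 4]` s, outside the snore gate.
#' @param noise_sd Baseline noise standard deviation (default 1).
#' @param seed Integer seed; identical seeds give bitwise-identical exams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 200, duration_s = 600, resp_period_s = 4,
                       resp_jitter = 0.15, snore_prob = 0.5,
                       snore_dur_range_s = c(0.6, 2),
                       snore_dur_mean_s = 1.0, snore_dur_sd_s = 0.3,
                       carrier_band_hz = c(20, 80), snr = 4,
                       artifact_rate_per_min = 0.5, noise_sd = 1,
                       seed = NULL) {
  if (fs <= 0) stop("'fs' must be positive")
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (carrier_band_hz[2] >= fs / 2)
    stop("carrier band upper edge must be below the Nyquist frequency fs/2")
  if (carrier_band_hz[1] <= 0 || carrier_band_hz[1] >= carrier_band_hz[2])
    stop("'carrier_band_hz' must be an increasing positive pair")
  if (snr <= 1) stop("'snr' must be > 1")
  if (snore_prob < 0 || snore_prob > 1) stop("'snore_prob' must be in [0, 1]")
  if (artifact_rate_per_min < 0) stop("rates must be >= 0")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (any(snore_dur_range_s <= 0) ||
      snore_dur_range_s[1] >= snore_dur_range_s[2])
    stop("'snore_dur_range_s' must be an increasing positive pair")
  structure(
    list(fs = fs, duration_s = duration_s, resp_period_s = resp_period_s,
         resp_jitter = resp_jitter, snore_prob = snore_prob,
         snore_dur_range_s = snore_dur_range_s,
         snore_dur_mean_s = snore_dur_mean_s,
         snore_dur_sd_s = snore_dur_sd_s,
         carrier_band_hz = carrier_band_hz, snr = snr,
         artifact_rate_per_min = artifact_rate_per_min,
         noise_sd = noise_sd, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %g s at %g Hz; resp %g s; P(snore)=%g; snr %g; artifacts %g/min\n",
    x$duration_s, x$fs, x$resp_period_s, x$snore_prob, x$snr,
    x$artifact_rate_per_min))
  invisible(x)
}

# draw one artifact duration, uniform over [0.1,0.55] U [2.1,4.0]
draw_artifact_duration <- function(n) {
  ranges <- rbind(c(0.1, 0.55), c(2.1, 4.0))
  w <- ranges[, 2] - ranges[, 1]
  pick <- sample.int(2L, n, replace = TRUE, prob = w / sum(w))
  stats::runif(n, ranges[pick, 1], ranges[pick, 2])
}

# render a trace from baseline noise plus one band-limited Tukey-shaped burst
# per truth row; burst gain is set so the *total* RMS inside the event equals
# snr * noise_sd on the generated trace
render_signal <- function(truth, config) {
  fs <- config$fs
  n <- round(config$duration_s * fs)
  x <- stats::rnorm(n, 0, config$noise_sd)
  if (nrow(truth)) {
    ny <- fs / 2
    bf <- signal::butter(4, config$carrier_band_hz / ny, type = "pass")
    target_rms <- sqrt(config$snr^2 - 1) * config$noise_sd
    for (k in seq_len(nrow(truth))) {
      i0 <- floor(truth$start_s[k] * fs) + 1L
      i1 <- min(n, floor(truth$end_s[k] * fs))
      len <- i1 - i0 + 1L
      if (len < 4L) next
      pad <- 64L
      raw <- stats::rnorm(len + 2L * pad)
      band <- signal::filtfilt(bf, raw)[(pad + 1L):(pad + len)]
      burst <- band * tukey_window(len, 0.25)
      r <- sqrt(mean(burst^2))
      if (r > 0) x[i0:i1] <- x[i0:i1] + burst * (target_rms / r)
    }
  }
  x
}

#' Simulate one synthetic snore-channel exam with ground truth
#'
#' Generates baseline Gaussian noise plus, per respiratory cycle (with
#' probability `snore_prob`), a band-limited burst whose duration is drawn
#' from a truncated normal inside the snore gate, at the configured
#' burst-to-baseline SNR. Artifact bursts with out-of-gate durations are
#' injected as a Poisson process; injections that cannot be placed without
#' overlap after bounded retries are dropped with a warning. Identical seeds
#' give bitwise-identical exams.
#'
#' @param config A [sim_config()].
#' @param exam_id Label for the simulated exam.
#' @return A list with `trace` (a [snore_trace()]) and `truth` (data frame
#'   `start_s`, `end_s`, `duration_s`, `kind` in `snore` / `artifact`,
#'   ordered and non-overlapping).
#' @examples
#' sim <- simulate_exam(sim_config(duration_s = 120, seed = 42))
#' nrow(sim$truth)
#' @export
simulate_exam <- function(config = sim_config(), exam_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    dr <- config$snore_dur_range_s
    # one candidate snore per respiratory cycle, phase-locked to inspiration:
    # at least min_gap of expiratory silence separates consecutive events
    min_gap <- 1.0
    starts <- numeric(0); ends <- numeric(0); kinds <- character(0)
    t <- 0; prev_end <- -Inf
    while (t < config$duration_s) {
      period <- config$resp_period_s *
        (1 + stats::runif(1, -config$resp_jitter, config$resp_jitter))
      if (stats::runif(1) < config$snore_prob) {
        dur <- rtrunc_norm(1, config$snore_dur_mean_s, config$snore_dur_sd_s,
                           dr[1], dr[2])
        lo <- max(t + 0.1 * period, prev_end + min_gap)
        hi <- t + period - dur - min_gap
        if (hi >= lo) {
          s <- stats::runif(1, lo, hi)
          if (s + dur <= config$duration_s) {
            starts <- c(starts, s); ends <- c(ends, s + dur)
            kinds <- c(kinds, "snore")
            prev_end <- s + dur
          }
        }
      }
      t <- t + period
    }
    # artifacts: Poisson process with out-of-gate durations, no overlaps
    n_art <- stats::rpois(1, config$artifact_rate_per_min *
                             config$duration_s / 60)
    dropped <- 0L
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        placed <- FALSE
        for (try in 1:25) {
          dur <- draw_artifact_duration(1)
          if (dur >= config$duration_s) next
          s <- stats::runif(1, 0, config$duration_s - dur)
          e <- s + dur
          margin <- min_gap
          if (!any(s < ends + margin & e > starts - margin)) {
            starts <- c(starts, s); ends <- c(ends, e)
            kinds <- c(kinds, "artifact")
            placed <- TRUE
            break
          }
        }
        if (!placed) dropped <- dropped + 1L
      }
    }
    if (dropped > 0L)
      warning(sprintf("dropped %d artifact injection(s) that could not be placed without overlap",
                      dropped), call. = FALSE)
    o <- order(starts)
    truth <- data.frame(start_s = starts[o], end_s = ends[o],
                        duration_s = ends[o] - starts[o],
                        kind = kinds[o], stringsAsFactors = FALSE)
    samples <- render_signal(truth, config)
    list(trace = snore_trace(samples, fs = config$fs, exam_id = exam_id),
         truth = truth)
  })
}

#' Measured burst-to-baseline SNR of a simulated trace
#'
#' Ratio of the RMS of the trace inside ground-truth events to the RMS
#' outside them; used to verify that the simulator realises its configured
#' SNR.
#'
#' @param trace A [snore_trace()].
#' @param truth A ground-truth event table (`start_s`, `end_s`).
#' @return A single positive ratio.
#' @export
measured_snr <- function(trace, truth) {
  stopifnot(inherits(trace, "snore_trace"))
  n <- length(trace$samples)
  inside <- rep(FALSE, n)
  for (k in seq_len(nrow(truth))) {
    i0 <- floor(truth$start_s[k] * trace$fs) + 1L
    i1 <- min(n, floor(truth$end_s[k] * trace$fs))
    if (i1 >= i0) inside[i0:i1] <- TRUE
  }
  if (!any(inside) || all(inside)) stop("need samples both inside and outside events")
  sqrt(mean(trace$samples[inside]^2)) / sqrt(mean(trace$samples[!inside]^2))
}

#' Simulate a two-group cohort of snore-event durations
#'
#' Emulates a study cohort of primary snorers (AHI below the cut) and OSAHS
#' patients (AHI at or above it): assigns each patient an AHI, then draws
#' per-event snore durations from group-specific truncated normals. The
#' output feeds the duration-statistics pipeline end-to-end; optionally each
#' exam is also rendered as a signal trace.
#'
#' @param n_primary,n_osahs Number of patients per group.
#' @param events_per_patient Snore events drawn per patient (default 150).
#' @param primary_dur_mean_s,primary_dur_sd_s Duration mean / SD for primary
#'   snorers (defaults 1.002 and 0.3562 s).
#' @param osahs_dur_mean_s,osahs_dur_sd_s Duration mean / SD for OSAHS
#'   patients (defaults 0.8636 and 0.271 s).
#' @param dur_range_s Truncation range of the duration draws (default
#'   `c(0.1, 4)` s; wider than the detector's snore gate, as observer-
#'   validated snores may fall outside it).
#' @param ahi_cut AHI threshold separating the groups (default 5).
#' @param seed Integer seed.
#' @param traces If `TRUE`, render a signal trace per exam (slow for large
#'   cohorts); events are then spaced one respiratory cycle apart.
#' @param config A [sim_config()] used for trace rendering.
#' @return A list with `patients` (data frame `exam_id`, `ahi`, `group`),
#'   `events` (data frame `exam_id`, `start_s`, `end_s`, `duration_s`,
#'   `label = "S"`), and `traces` (named list of [snore_trace()] or `NULL`).
#' @examples
#' coh <- simulate_cohort(n_primary = 3, n_osahs = 3,
#'                        events_per_patient = 50, seed = 7)
#' duration_report(coh$events, coh$patients)
#' @export
simulate_cohort <- function(n_primary = 13, n_osahs = 18,
                            events_per_patient = 150,
                            primary_dur_mean_s = 1.002,
                            primary_dur_sd_s = 0.3562,
                            osahs_dur_mean_s = 0.8636,
                            osahs_dur_sd_s = 0.271,
                            dur_range_s = c(0.1, 4), ahi_cut = 5,
                            seed = NULL, traces = FALSE,
                            config = sim_config()) {
  stopifnot(n_primary >= 1, n_osahs >= 0, events_per_patient >= 1)
  with_seed(seed, {
    ids <- sprintf("SIM%02d", seq_len(n_primary + n_osahs))
    group <- c(rep("primary", n_primary), rep("osahs", n_osahs))
    ahi <- c(stats::runif(n_primary, 0, ahi_cut * 0.98),
             stats::runif(n_osahs, ahi_cut, 60))
    patients <- data.frame(exam_id = ids, ahi = ahi, group = group,
                           stringsAsFactors = FALSE)
    ev <- lapply(seq_along(ids), function(i) {
      if (group[i] == "primary") {
        d <- rtrunc_norm(events_per_patient, primary_dur_mean_s,
                         primary_dur_sd_s, dur_range_s[1], dur_range_s[2])
      } else {
        d <- rtrunc_norm(events_per_patient, osahs_dur_mean_s,
                         osahs_dur_sd_s, dur_range_s[1], dur_range_s[2])
      }
      gap <- config$resp_period_s
      start <- cumsum(c(1, utils::head(d, -1) + gap))
      data.frame(exam_id = ids[i], start_s = start, end_s = start + d,
                 duration_s = d, label = "S", stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, ev)
    tr <- NULL
    if (traces) {
      tr <- lapply(seq_along(ids), function(i) {
        tt <- ev[[i]]
        cfg <- config
        cfg$duration_s <- max(tt$end_s) + config$resp_period_s
        truth <- data.frame(start_s = tt$start_s, end_s = tt$end_s,
                            duration_s = tt$duration_s, kind = "snore",
                            stringsAsFactors = FALSE)
        snore_trace(render_signal(truth, cfg), fs = cfg$fs, exam_id = ids[i])
      })
      names(tr) <- ids
    }
    list(patients = patients, events = events, traces = tr)
  })
}
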