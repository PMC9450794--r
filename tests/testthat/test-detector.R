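test_that("RMS envelope matches closed forms and a brute-force loop", {
  # constant signal: RMS of each window is the constant
  tr <- snore_trace(rep(3, 1000), fs = 200)
  expect_equal(rms_envelope(tr)$values, rep(3, 50))

  # whole periods of a sine: RMS = A / sqrt(2)
  fs <- 200; A <- 2.5
  t <- seq(0, by = 1 / fs, length.out = fs)  # 1 s, 100 ms windows
  tr <- snore_trace(A * sin(2 * pi * 50 * t[-length(t)]), fs = fs)
  expect_true(all(abs(rms_envelope(tr)$values - A / sqrt(2)) < 1e-9))

  # random signal vs an independent windowed loop
  set.seed(11)
  x <- rnorm(1234)
  tr <- snore_trace(x, fs = 200)
  env <- rms_envelope(tr)
  expect_equal(env$values, oracle_rms(x, 20), tolerance = 1e-12)
  expect_equal(length(env$values), floor(1234 / 20))
  expect_equal(env$frame_period_s, 0.1)
})

test_that("RMS envelope respects scale and sign symmetries", {
  set.seed(12)
  x <- rnorm(800)
  tr <- function(v) snore_trace(v, fs = 200)
  e <- rms_envelope(tr(x))$values
  expect_equal(rms_envelope(tr(-x))$values, e)
  expect_equal(rms_envelope(tr(3.7 * x))$values, 3.7 * e)
})

test_that("an 8-hour 200 Hz trace yields 288000 envelope frames", {
  # length contract at study scale, cross-checked against the floor formula
  n <- 5760000
  tr <- snore_trace(numeric(n) + 1, fs = 200)
  env <- rms_envelope(tr)
  expect_equal(length(env$values), n %/% 20)
  expect_identical(length(env$values), 288000L)
})

test_that("RMS envelope rejects degenerate input", {
  expect_error(rms_envelope(snore_trace(1:5, fs = 200)), "too short")
  expect_error(snore_trace(c(1, NA), fs = 200), "finite")
})

test_that("moving average matches its FIR impulse response and a loop", {
  # constants are invariant
  env <- make_envelope(rep(2.5, 40))
  expect_equal(smooth_envelope(env, 10)$values, rep(2.5, 40))

  # unit impulse spreads as 1/k over k frames
  v <- numeric(60); v[30] <- 1
  sm <- smooth_envelope(make_envelope(v), 10)$values
  expect_equal(sm[30:39], rep(0.1, 10))
  expect_equal(sm[-(30:39)], numeric(50))

  # random envelope vs brute-force windowed mean, shrinking start edge
  set.seed(13)
  v <- runif(50)
  for (k in c(1, 3, 10, 50)) {
    expect_equal(smooth_envelope(make_envelope(v), k)$values,
                 oracle_moving_average(v, k), tolerance = 1e-12)
  }
})

test_that("moving average stays within the running min/max of its window", {
  set.seed(14)
  v <- rexp(200)
  sm <- smooth_envelope(make_envelope(v), 10)$values
  for (i in seq_along(v)) {
    w <- v[max(1, i - 9):i]
    expect_gte(sm[i], min(w) - 1e-12)
    expect_lte(sm[i], max(w) + 1e-12)
  }
})

test_that("baseline estimation is robust and floored", {
  expect_equal(estimate_baseline(make_envelope(rep(1, 4))), 1)
  # bursts in 10% of frames do not move the median
  v <- c(rep(1, 90), rep(10, 10))
  expect_equal(estimate_baseline(make_envelope(v)), 1)
  expect_equal(estimate_baseline(make_envelope(v), "percentile", 25), 1)
  # all-zero envelope: positive floor, and segmentation stays empty
  z <- make_envelope(numeric(100))
  expect_gt(estimate_baseline(z), 0)
  expect_equal(nrow(segment_events(z, detector_params())), 0)
  expect_error(estimate_baseline(make_envelope(numeric(0))), "empty")
})

test_that("segmentation handles pulses, hysteresis and gap merging", {
  p <- detector_params()
  # flat at baseline: nothing
  expect_equal(nrow(segment_events(make_envelope(rep(1, 100)), p)), 0)

  # one rectangular 10-frame pulse at 5x baseline: one event of ~1 s
  v <- rep(1, 100); v[41:50] <- 5
  ev <- segment_events(make_envelope(v), p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_s - ev$start_s, 1.0, tolerance = 0.1 + 1e-9)
  expect_equal(ev$start_s, 4.0)

  # two 1 s pulses with a 0.1 s sub-threshold gap: merged iff gap allowed
  v <- rep(1, 100); v[31:40] <- 5; v[42:51] <- 5
  merged <- segment_events(make_envelope(v), p)
  expect_equal(nrow(merged), 1)
  split2 <- segment_events(make_envelope(v), detector_params(merge_gap_s = 0))
  expect_equal(nrow(split2), 2)

  # hysteresis: frames between release and entry extend but never open events
  v <- rep(1, 100); v[50] <- 2.5; v[51:54] <- 1.8; v[70:72] <- 1.8
  ev <- segment_events(make_envelope(v), p, baseline = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 4.9)
  expect_equal(ev$end_s, 5.4)  # trailing 1.8x frames stay above release
})

test_that("segmentation equals the brute-force hysteresis oracle on random envelopes", {
  set.seed(15)
  for (rep_i in 1:300) {
    n <- sample(20:120, 1)
    v <- rexp(n, rate = 1)
    burst_at <- sample(n, sample(0:3, 1))
    for (b in burst_at) {
      len <- sample(1:12, 1)
      idx <- b:min(n, b + len - 1)
      v[idx] <- v[idx] + runif(1, 1, 8)
    }
    gap <- sample(c(0, 0.1, 0.2, 0.3), 1)
    p <- detector_params(merge_gap_s = gap)
    b <- estimate_baseline(make_envelope(v))
    got <- segment_events(make_envelope(v), p, baseline = b)
    want <- oracle_segment(v, 0.1, b, p$threshold_ratio, p$release_ratio, gap)
    expect_equal(got$start_s, want$start_s, tolerance = 1e-12)
    expect_equal(got$end_s, want$end_s, tolerance = 1e-12)
  }
})

test_that("duration gate is a closed interval with exact boundaries", {
  expect_equal(classify_event(1.0), "snore")
  expect_equal(classify_event(0.3), "non_snore")
  expect_equal(classify_event(c(0.6, 2.0)), c("snore", "snore"))
  expect_equal(classify_event(c(0.599, 2.001)), c("non_snore", "non_snore"))
  # frame-quantised durations sit exactly on the bounds
  expect_equal(classify_event(6 * 0.1), "snore")
  expect_equal(classify_event(20 * 0.1), "snore")
  expect_error(classify_event(0), "positive")
  # the label is a pure function of duration and params
  p2 <- detector_params(min_dur_s = 0.3, max_dur_s = 1.0)
  expect_equal(classify_event(0.4, p2), "snore")
  expect_equal(classify_event(1.5, p2), "non_snore")
})

test_that("detection recovers injected events and their onsets", {
  sim <- simulate_exam(sim_config(duration_s = 300, seed = 42))
  det <- detect_snores(sim$trace)
  truth_sn <- sim$truth[sim$truth$kind == "snore", ]
  expect_gt(nrow(truth_sn), 20)
  m <- evaluate_detection(det, sim$truth)
  expect_gte(sensitivity(m$counts), 0.95)
  p <- m$pairs[m$pairs$ref_label == "S" & m$pairs$pred_label == "S", ]
  onset_err <- det$events$start_s[p$pred] - sim$truth$start_s[p$ref]
  expect_true(all(abs(onset_err) <= 0.2))
})

test_that("detection is amplitude-scale invariant and deterministic", {
  sim <- simulate_exam(sim_config(duration_s = 180, seed = 7))
  det1 <- detect_snores(sim$trace)
  scaled <- snore_trace(7.3 * sim$trace$samples, fs = sim$trace$fs,
                        exam_id = sim$trace$exam_id)
  det2 <- detect_snores(scaled)
  expect_identical(det1$events[c("start_s", "end_s", "duration_s", "label")],
                   det2$events[c("start_s", "end_s", "duration_s", "label")])
  # same input, same params: bitwise-equal event tables
  det3 <- detect_snores(sim$trace)
  expect_identical(det1$events, det3$events)
})

test_that("pure-noise traces produce no events", {
  set.seed(16)
  tr <- snore_trace(rnorm(200 * 60), fs = 200)
  det <- detect_snores(tr)
  expect_equal(nrow(det$events), 0)
})
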