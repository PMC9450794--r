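# Brute-force reference implementations, kept deliberately independent of
# the package internals (plain loops, no shared helpers).

oracle_rms <- function(x, ws) {
  nwin <- floor(length(x) / ws)
  out <- numeric(nwin)
  for (i in seq_len(nwin)) {
    w <- x[((i - 1) * ws + 1):(i * ws)]
    out[i] <- sqrt(sum(w^2) / ws)
  }
  out
}

oracle_moving_average <- function(v, k) {
  out <- numeric(length(v))
  for (i in seq_along(v)) out[i] <- mean(v[max(1, i - k + 1):i])
  out
}

# hysteresis state machine + gap merging, frame by frame
oracle_segment <- function(v, fp, baseline, enter_ratio, release_ratio,
                           merge_gap_s) {
  enter <- enter_ratio * baseline
  release <- release_ratio * baseline
  ev <- NULL
  open <- FALSE
  s <- NA_integer_
  for (i in seq_along(v)) {
    if (!open) {
      if (v[i] >= enter) { open <- TRUE; s <- i }
    } else if (v[i] < release) {
      ev <- rbind(ev, c(s, i - 1L)); open <- FALSE
    }
  }
  if (open) ev <- rbind(ev, c(s, length(v)))
  if (is.null(ev)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (nrow(ev) > 1L && merge_gap_s > 0) {
    merged <- ev[1, , drop = FALSE]
    for (r in 2:nrow(ev)) {
      gap <- (ev[r, 1] - 1L - merged[nrow(merged), 2]) * fp
      if (gap <= merge_gap_s + 1e-12) {
        merged[nrow(merged), 2] <- ev[r, 2]
      } else {
        merged <- rbind(merged, ev[r, ])
      }
    }
    ev <- merged
  }
  data.frame(start_s = (ev[, 1] - 1L) * fp, end_s = ev[, 2] * fp)
}

# all-pairs greedy interval matcher + confusion counting
oracle_match_counts <- function(pred, ref, min_frac = 0.5) {
  used_p <- rep(FALSE, nrow(pred)); used_r <- rep(FALSE, nrow(ref))
  tp <- fp <- tn <- fn <- 0L
  repeat {
    best <- 0; bi <- bj <- 0L
    for (i in seq_len(nrow(pred))) for (j in seq_len(nrow(ref))) {
      if (used_p[i] || used_r[j]) next
      o <- min(pred$end_s[i], ref$end_s[j]) - max(pred$start_s[i], ref$start_s[j])
      short <- min(pred$end_s[i] - pred$start_s[i], ref$end_s[j] - ref$start_s[j])
      if (o > 0 && o / short >= min_frac - 1e-9 && o > best) {
        best <- o; bi <- i; bj <- j
      }
    }
    if (best <= 0) break
    used_p[bi] <- TRUE; used_r[bj] <- TRUE
    pl <- pred$label[bi]; rl <- ref$label[bj]
    if (pl == "S" && rl == "S") tp <- tp + 1L
    else if (pl == "S" && rl == "NS") fp <- fp + 1L
    else if (pl == "NS" && rl == "NS") tn <- tn + 1L
    else fn <- fn + 1L
  }
  fn <- fn + sum(ref$label[!used_r] == "S")
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  p_yes <- ((tp + fp) / n) * ((tp + fn) / n)
  p_no <- ((fn + tn) / n) * ((fp + tn) / n)
  (po - (p_yes + p_no)) / (1 - (p_yes + p_no))
}

make_envelope <- function(values, fp = 0.1, offset = 0) {
  structure(list(values = values, frame_period_s = fp, start_offset = offset),
            class = "snore_envelope")
}

validation_counts_path <- function() {
  system.file("extdata", "validation_confusion_counts.csv",
              package = "snoredetect")
}

duration_summaries_fixture <- function() {
  s <- read.csv(system.file("extdata", "duration_group_summaries.csv",
                            package = "snoredetect"))
  lapply(split(s, s$group), function(r)
    duration_summary(r$n, r$mean_s, r$sd_s, r$min_s, r$median_s, r$max_s))
}
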