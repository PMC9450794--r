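---
title: "Detecting snores in a 200 Hz electric channel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting snores in a 200 Hz electric channel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoredetect)
```

## The problem

Acoustic snore analysis (LPC, sub-band energy, hidden Markov models) needs
microphone recordings sampled well above 7.5 kHz. Polysomnographs, however,
usually digitise every channel at a few hundred hertz. A contact microphone
on the neck wired into a spare channel yields a 200 Hz *electric snore
signal*: the audio content is aliased and unusable as sound, but snoring
still appears as bursts of elevated signal energy, one per respiratory
cycle. `snoredetect` finds those bursts and decides which of them are
snores purely from their timing.

## The detection model

The detector makes three assumptions, each of which maps to one stage of
the pipeline:

1. **Snores are energy bursts.** The signal is tiled into contiguous,
   non-overlapping 100 ms windows and each window reduced to its RMS
   ("effective value"). 100 ms is short against the shortest snore (0.6 s,
   i.e. 6 frames) and long enough to average out the carrier oscillation.
   The trailing partial window is dropped, so an $n$-sample exam yields
   $\lfloor n/20 \rfloor$ frames at 200 Hz.
2. **Bursts are sustained.** A causal 10-frame moving average (1 s)
   suppresses single-frame noise spikes before thresholding. The start edge
   averages over the shorter available history rather than zero-padding,
   which would bias early frames downward.
3. **Snores stand out from silence and last 0.6–2 s.** Events are segmented
   by hysteresis on the smoothed envelope — open at
   `threshold_ratio` (default 2) times the baseline, close below
   `release_ratio` (default 1.5) times it — and the event duration decides
   the label: inside the closed interval $[0.6, 2]$ s it is a snore,
   outside (voice, coughs, movement artifacts) a non-snore.

The 2× entry threshold encodes the visual criterion trained observers use
("amplitude at least double that of silence"). The algorithm needs an
estimator for "silence": we use the **median of the smoothed envelope**,
which is robust as long as snoring occupies a minority of frames, with a
percentile alternative for unusual duty cycles and a machine-epsilon floor
so the thresholds are defined even for an all-zero channel (which then
yields no events rather than an error). Because both thresholds are
multiples of the baseline, the event list is invariant under amplitude
scaling of the trace — recording gain cannot change the result.

### Boundary refinement

A causal 1 s moving average delays onsets and prolongs decays: measured on
simulated ground truth, raw hysteresis boundaries arrive ~0.3–0.4 s late
and stretch durations by ~0.5 s — enough to push a genuine 1.8 s snore past
the 2 s gate. `detect_snores()` therefore refines each segmented event
against the *unsmoothed* RMS envelope: within the event region extended
left by the filter length, the first and last frames at or above the
release threshold become the reported boundaries. Smoothing still decides
*whether* a region is an event (its noise robustness is kept); the raw
envelope decides *where* it starts and ends. `segment_events()` itself
remains pure hysteresis + gap merging, which is what the brute-force
property tests check. With refinement, onsets land within ±0.2 s of the
injected truth and duration bias drops to under one frame on average.

### Numerical conventions

* Event times are reported at frame resolution (0.1 s), as half-open
  `[start_s, end_s)` intervals in seconds from recording start; no
  sub-frame interpolation.
* The duration gate is closed, `[0.6, 2.0]` s, compared with a 1 ns
  tolerance so frame-quantised durations (e.g. $20 \times 0.1$ s) sit on
  the boundary exactly despite floating-point representation.
* Sub-threshold gaps of at most `merge_gap_s` (default 0.2 s) between
  supra-threshold runs are bridged, so brief intra-snore dips do not split
  an event; `merge_gap_s = 0` disables merging.
* Hysteresis frames between the release and entry levels extend an open
  event but never open one.

## Agreement statistics

Detector and observer labels form a 2×2 table per exam (TP, FP, TN, FN,
with "snore" positive; the reference snore count is TP + FN). The package
reports sensitivity, specificity, accuracy, PPV and NPV — any metric with a
zero denominator is *undefined* (`NA` with a warning), never silently 0 —
and Cohen's kappa

$$\kappa = \frac{P_o - P_e}{1 - P_e},\qquad
  P_o = \frac{TP + TN}{N},\qquad
  P_e = \frac{(TP{+}FP)(TP{+}FN) + (FN{+}TN)(FP{+}TN)}{N^2},$$

computed on the **pooled** table across exams (not averaged per exam),
which is the convention that yields a single study-level kappa. Perfect
observed agreement returns exactly 1. Display percentages round half-up to
2 decimals, matching how such validation tables are conventionally printed
(e.g. 90.625 → 90.63).

When detector and observer event lists are produced independently rather
than by relabelling, intervals are paired greedily by largest temporal
overlap, requiring the overlap to cover at least half of the shorter
interval (`min_overlap_frac = 0.5`). Unmatched reference snores count as
false negatives. In `evaluate_detection()` — scoring against simulator
ground truth — an unmatched *predicted* snore additionally counts as a
false positive, since there is no observer to have relabelled it.

## Duration statistics

Snore durations are pooled across patients within a group (an event-level
analysis; the group `n` is an event count). Groups are split by the
apnea/hypopnea index at 5 events/hour, with AHI = 5 assigned to the OSAHS
group. Summaries use the sample SD ($n-1$), SE = SD/√n, and a normal-
approximation 95% CI (mean ± 1.96 SE): with thousands of events per group
the difference from a t-quantile is below $10^{-4}$ s, and the 1.96
multiplier is the convention the reference intervals follow.

`two_sample_t()` works from summaries alone. Welch's statistic is the
default because the groups compared here have unequal sizes and spreads;
the pooled (equal-variance) Student statistic is available and, at the
published group summaries, both reject overwhelmingly ($|t| \approx 28$).
Degenerate inputs are handled explicitly: identical summaries give
$t = 0, p = 1$; an undefined SE is an error rather than a silent zero.

## What the simulator emulates — and what it does not

`simulate_exam()` generates: Gaussian baseline noise (`noise_sd`); per
respiratory cycle (mean 4 s, ±15% jitter), with probability `snore_prob`,
one band-limited noise burst shaped by a Tukey (taper 0.25) amplitude
window, duration drawn from a truncated normal inside the 0.6–2 s gate;
and Poisson artifacts whose durations fall outside the gate (uniform over
$[0.1, 0.55] \cup [2.1, 4]$ s). Design choices worth stating:

* **Carrier band 20–80 Hz.** The spectral content a 200 Hz acquisition
  retains from a neck microphone is not well characterised; this band is a
  modelling choice that respects the 100 Hz Nyquist limit, not a claim
  about real spectra. Since the detector uses only energy, results are
  insensitive to the exact band.
* **Burst gain is calibrated to the trace.** The additive burst is scaled
  so the *total* RMS inside the event is `snr` × `noise_sd` (the additive
  component has RMS $\sqrt{snr^2-1}\,\sigma$), making the measured
  burst-to-baseline ratio match the configured SNR for any `snr` > 1.
* **Tukey rather than full raised-cosine envelope.** With a fully cosine
  burst the threshold crossing sits ~14% of the duration inside the event,
  shrinking short snores below the 0.6 s gate; the Tukey window keeps the
  crossing within ~3% of the true edge.
* **Phase locking.** At most one snore per cycle, and a minimum 1 s
  expiratory gap separates consecutive injected events. Without that gap,
  uniformly placed snores could land back-to-back across cycle boundaries —
  unphysiological, and the 1 s smoothing window then merges them into one
  over-long event.
* **Determinism.** One seed governs all draws; identical seeds give
  bitwise-identical traces and truth tables.

Default study-scale conditions: `snore_prob = 0.5` at a 4 s cycle gives
roughly 450 snores/hour in heavy snorers (~3600 over 8 h);
`artifact_rate_per_min = 0.5` a handful of artifacts per 10 minutes;
`snr = 4` a clearly visible burst, consistent with signals observers can
validate by eye.

What the simulator does **not** model: real snore waveform morphology and
its between-patient variability, amplitude drift across the night,
non-Gaussian or non-stationary background (mains interference, movement),
apnea-related breathing pauses, and co-recorded airflow/effort channels.
Passing the recovery tests therefore shows the pipeline is correct *under
the stated signal model*, not that the clinical operating point (99.26%
sensitivity, kappa 0.96) transfers to any particular laboratory's
hardware.

The cohort generator draws event durations from group-specific truncated
normals on $[0.1, 4]$ s — deliberately wider than the detector's gate,
because observer-validated snores include events the duration gate would
reject (published group minima/maxima of 0.55 and 2.95 s). AHI values are
drawn uniformly below the cut for primary snorers and on $[5, 60]$ for
OSAHS patients; only their side of the cut matters downstream.

## Problem sizes and test design

The test suite checks every operator against an independent brute-force
oracle (windowed RMS loop, shrinking-window mean, a frame-by-frame
hysteresis state machine with merging, an all-pairs greedy matcher, the
kappa marginal formula) on randomised inputs — 1000 random envelopes for
the segmentation oracle — plus the published fixtures: all 31 validation
rows recompute to their printed percentages, and the pooled row yields
sensitivity 99.26%, specificity 97.35%, accuracy 98.24%, NPV 99.34% and
kappa 0.96. Simulation-backed properties use 5 × 10-minute exams for
sensitivity/PPV (≥ 0.95 / ≥ 0.90 at SNR 4), 20 seeds × 2-minute exams per
SNR level for monotonicity over SNR ∈ {1.5, 2, 4, 8}, one full 8-hour exam
(5.76 M samples, detected in about a second), 2000 events per group for
cohort recovery, and 200 replicates of a 1000-vs-1000-event null cohort
for the type-I check (accepting a rejection rate in [0.01, 0.10] at
α = 0.05, i.e. within binomial noise of the nominal 5%). These sizes give
each property enough events to be stable across seeds while keeping the
whole suite fast.

## Known limitations

* Event timing is frame-quantised (0.1 s); duration estimates for edge-of-
  gate events can flip their label (a true 0.62 s snore measured at 0.5 s
  becomes a non-snore).
* The baseline estimator assumes snoring occupies a minority of frames; in
  continuous, unbroken snoring the median rises and sensitivity falls —
  the percentile option exists for such recordings.
* Detection degrades below SNR ≈ 2 by design: the entry threshold *is* 2×
  baseline, so bursts weaker than the observers' own amplitude criterion
  are not considered snores.
* The group comparison pools events across patients and ignores
  within-patient correlation, mirroring the event-level convention of the
  reference analysis; a clustered or mixed-effects analysis is out of
  scope.
* The hypnogram ("patient asleep") criterion is not modelled; all events
  in a trace are candidates.
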