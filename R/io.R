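# --- signal I/O -------------------------------------------------------------
# Minimal single-channel WAV (PCM16 / float32) and EDF readers/writers.
# EDF: 256-byte fixed header + 256 bytes per signal, int16 little-endian
# records with linear physical scaling.

#' Read a snore-channel signal from WAV, CSV or EDF
#'
#' Format is inferred from the file extension. CSV files may have either two
#' columns `time_s,value` (the rate is taken from the time spacing) or a
#' single `value` column, in which case `fs` must be given. EDF channels are
#' selected by label, case-insensitively; WAV files must be single-channel.
#'
#' @param path Input file (`.wav`, `.csv` or `.edf`).
#' @param channel Channel label for EDF input (default: first channel).
#' @param fs Sampling-rate override in Hz; an override that contradicts a
#'   rate declared by the container is an error.
#' @param exam_id Exam label; defaults to the file name without extension.
#' @return A [snore_trace()].
#' @export
read_signal <- function(path, channel = NULL, fs = NULL, exam_id = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (is.null(exam_id)) exam_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  tr <- switch(ext,
    wav = read_wav(path, exam_id = exam_id),
    csv = read_signal_csv(path, fs = fs, exam_id = exam_id),
    edf = read_edf(path, channel = channel, exam_id = exam_id),
    stop(sprintf("unknown signal format '.%s' (expected wav, csv or edf)", ext))
  )
  if (!is.null(fs) && ext != "csv" && abs(tr$fs - fs) > 1e-6)
    stop(sprintf("sampling-rate mismatch: container declares %g Hz, override is %g Hz",
                 tr$fs, fs))
  tr
}

read_signal_csv <- function(path, fs = NULL, exam_id = "exam") {
  d <- utils::read.csv(path)
  if (all(c("time_s", "value") %in% names(d))) {
    dt <- diff(d$time_s)
    if (length(dt) < 1L || any(dt <= 0))
      stop("CSV time column must be strictly increasing")
    fs_est <- 1 / stats::median(dt)
    if (!is.null(fs) && abs(fs_est - fs) / fs > 0.01)
      stop(sprintf("sampling-rate mismatch: time column implies %g Hz, override is %g Hz",
                   fs_est, fs))
    snore_trace(d$value, fs = if (is.null(fs)) fs_est else fs,
                exam_id = exam_id, start_offset = d$time_s[1])
  } else if ("value" %in% names(d)) {
    if (is.null(fs))
      stop("CSV has no time column; a sampling rate ('fs') is required")
    snore_trace(d$value, fs = fs, exam_id = exam_id)
  } else stop("signal CSV needs a 'value' column (optionally with 'time_s')")
}

#' Write a signal trace as a two-column CSV
#'
#' @param trace A [snore_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "snore_trace"))
  t <- trace$start_offset + (seq_along(trace$samples) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, value = trace$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a single-channel WAV file
#'
#' @param trace A [snore_trace()].
#' @param path Output path.
#' @param bits 16 for PCM (samples must be integer-valued in
#'   \[-32768, 32767\]) or 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(trace, path, bits = 32) {
  stopifnot(inherits(trace, "snore_trace"), bits %in% c(16, 32))
  x <- trace$samples
  fs <- as.integer(round(trace$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- if (bits == 32) 3L else 1L
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    if (any(x != round(x)) || any(x < -32768) || any(x > 32767))
      stop("16-bit PCM WAV requires integer-valued samples in [-32768, 32767]")
    writeBin(as.integer(x), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a single-channel WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE-float mono files.
#'
#' @param path Input path.
#' @param exam_id Exam label.
#' @return A [snore_trace()].
#' @export
read_wav <- function(path, exam_id = "exam") {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a RIFF/WAV file")
  fmt <- NULL; samples <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")     # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")     # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (nch != 1L) stop("only single-channel WAV files are supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      if (fmt == 1L && bits == 16L) {
        samples <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                           endian = "little")
      } else if (fmt == 3L && bits == 32L) {
        samples <- readBin(con, "double", sz / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  snore_trace(samples, fs = fs, exam_id = exam_id)
}

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(paste0(s, strrep(" ", width)), 1, width)
}

#' Write traces to a minimal EDF file
#'
#' European Data Format: 16-bit integer records with linear physical
#' scaling. One data record per second; each trace's length is truncated to
#' a whole number of records.
#'
#' @param traces A [snore_trace()] or a list of them (channel labels are the
#'   exam ids); all must share a common duration for a valid file.
#' @param path Output path.
#' @param labels Optional channel labels (default: exam ids).
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path, labels = NULL) {
  if (inherits(traces, "snore_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "snore_trace")))
  ns <- length(traces)
  if (is.null(labels))
    labels <- vapply(traces, function(tr) tr$exam_id, character(1))
  rec_dur <- 1
  n_rec <- min(vapply(traces, function(tr)
    floor(length(tr$samples) / (tr$fs * rec_dur)), numeric(1)))
  if (n_rec < 1) stop("traces shorter than one EDF record (1 s)")
  spr <- vapply(traces, function(tr) as.integer(round(tr$fs * rec_dur)),
                integer(1))
  pmin_ <- pmax_ <- numeric(ns)
  scaled <- vector("list", ns)
  for (k in seq_len(ns)) {
    x <- traces[[k]]$samples[seq_len(n_rec * spr[k])]
    lim <- max(abs(x), 1e-12)
    pmin_[k] <- -lim; pmax_[k] <- lim
    scaled[[k]] <- as.integer(round((x + lim) / (2 * lim) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("synthetic snore exam", 80),
    edf_field("snoredetect", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(format(rec_dur), 8), edf_field(ns, 4),
    paste(vapply(labels, edf_field, character(1), width = 16), collapse = ""),
    strrep(edf_field("", 80), ns),                        # transducer
    strrep(edf_field("uV", 8), ns),                       # physical dim
    paste(vapply(pmin_, function(v) edf_field(signif(v, 7), 8),
                 character(1)), collapse = ""),
    paste(vapply(pmax_, function(v) edf_field(signif(v, 7), 8),
                 character(1)), collapse = ""),
    strrep(edf_field(-32768, 8), ns),
    strrep(edf_field(32767, 8), ns),
    strrep(edf_field("", 80), ns),                        # prefiltering
    paste(vapply(spr, edf_field, character(1), width = 8), collapse = ""),
    strrep(edf_field("", 32), ns))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      idx <- ((r - 1) * spr[k] + 1):(r * spr[k])
      writeBin(scaled[[k]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path Input path.
#' @param channel Channel label (case-insensitive, trimmed); default: first
#'   channel.
#' @param exam_id Exam label.
#' @return A [snore_trace()] with the header-declared sampling rate.
#' @export
read_edf <- function(path, channel = NULL, exam_id = "exam") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  if (is.null(channel)) {
    k <- 1L
  } else {
    k <- which(tolower(labels) == tolower(trimws(channel)))
    if (!length(k))
      stop(sprintf("channel '%s' not found (available: %s)", channel,
                   paste(labels, collapse = ", ")))
    k <- k[1L]
  }
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- readBin(con, "integer", sum(spr), size = 2, signed = TRUE,
                   endian = "little")
    off <- if (k > 1L) sum(spr[seq_len(k - 1L)]) else 0L
    out[[r]] <- rec[(off + 1L):(off + spr[k])]
  }
  dig <- unlist(out)
  gain <- (pmax_[k] - pmin_[k]) / (dmax_[k] - dmin_[k])
  phys <- pmin_[k] + (dig - dmin_[k]) * gain
  snore_trace(phys, fs = spr[k] / rec_dur, exam_id = exam_id)
}

# --- event, counts and patients tables --------------------------------------

to_SN <- function(label) {
  out <- ifelse(label %in% c("S", "snore"), "S",
         ifelse(label %in% c("NS", "non_snore"), "NS", NA_character_))
  if (any(is.na(out))) stop("labels must be S/NS (or snore/non_snore)")
  out
}

#' Write an event table to CSV
#'
#' Fixed dialect: comma-separated, header
#' `exam_id,start_s,end_s,duration_s,label`, labels `S` / `NS`, times in
#' seconds with 3 decimals. Round-trips losslessly at that precision.
#'
#' @param events A data frame with those columns (labels may also be
#'   `snore` / `non_snore`), or a `snore_detection` object.
#' @param path Output path.
#' @param extra Optional extra columns (e.g. `kind`) to carry through.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, extra = NULL) {
  if (inherits(events, "snore_detection")) events <- as.data.frame(events)
  need <- c("exam_id", "start_s", "end_s", "label")
  if (!all(need %in% names(events)))
    stop("event table needs columns exam_id, start_s, end_s, label")
  out <- data.frame(
    exam_id = events$exam_id,
    start_s = sprintf("%.3f", events$start_s),
    end_s = sprintf("%.3f", events$end_s),
    duration_s = sprintf("%.3f", events$end_s - events$start_s),
    label = to_SN(events$label),
    stringsAsFactors = FALSE)
  for (nm in extra) out[[nm]] <- events[[nm]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Validates the header, the `S` / `NS` label vocabulary and interval
#' monotonicity; a bad label or interval is reported with its row number.
#'
#' @param path Input path.
#' @return A data frame `exam_id`, `start_s`, `end_s`, `duration_s`,
#'   `label` (plus any extra columns present).
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam_id", "start_s", "end_s", "duration_s", "label")
  if (!all(need %in% names(d)))
    stop(sprintf("bad event CSV header: need columns %s",
                 paste(need, collapse = ", ")))
  bad <- which(!d$label %in% c("S", "NS"))
  if (length(bad))
    stop(sprintf("invalid label '%s' at row %d (must be S or NS)",
                 d$label[bad[1]], bad[1]))
  bad <- which(!(d$end_s > d$start_s))
  if (length(bad))
    stop(sprintf("non-monotone interval at row %d", bad[1]))
  d
}

#' Read per-exam confusion counts from CSV
#'
#' Expects columns `exam_id,tp,fp,tn,fn` (extra columns are kept).
#'
#' @param path Input path.
#' @return A data frame of counts.
#' @export
read_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam_id", "tp", "fp", "tn", "fn")
  if (!all(need %in% names(d)))
    stop("counts CSV needs columns exam_id, tp, fp, tn, fn")
  d
}

#' Read a patients table (exam_id, ahi) from CSV
#'
#' @param path Input path.
#' @return A data frame with at least `exam_id` and `ahi`.
#' @export
read_patients <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("exam_id", "ahi") %in% names(d)))
    stop("patients CSV needs columns exam_id, ahi")
  d
}
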