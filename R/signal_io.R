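# Continuous-recording I/O, zero-phase band-pass filtering, robust noise
# estimation, threshold detection and waveform extraction.

#' Continuous extracellular recording
#'
#' A single-channel voltage trace with its sampling rate. This is the object
#' every preprocessing stage operates on.
#'
#' @param samples numeric vector of voltages (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds (default 0).
#' @return an object of class `recording` with fields `samples`, `fs`, `t0`.
#' @export
recording <- function(samples, fs, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_config("fs must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) abort_config("recording needs at least one sample")
  if (any(!is.finite(samples))) abort_config("samples must be finite")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a continuous recording from disk
#'
#' Supports the package's flat binary format (little-endian `int16` or
#' `float32` plus a JSON sidecar declaring `fs`, `dtype` and `scale`) and
#' single-column CSV with the sampling rate given in `fs`.
#'
#' @param path file to read.
#' @param sidecar path to the JSON sidecar; defaults to `paste0(path, ".json")`
#'   for binary files. Ignored for CSV input.
#' @param fs sampling rate, required for CSV input (CSV has no sidecar).
#' @return a [recording].
#' @export
read_recording <- function(path, sidecar = NULL, fs = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(fs)) abort_config("CSV input needs an explicit fs")
    v <- utils::read.csv(path, header = FALSE)[[1L]]
    return(recording(v, fs))
  }
  sidecar <- sidecar %||% paste0(path, ".json")
  if (!file.exists(sidecar)) abort_config(sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs)) abort_config("sidecar does not declare fs")
  dtype <- meta$dtype %||% "float32"
  scale <- meta$scale %||% 1
  sz <- file.size(path)
  bytes <- switch(dtype, int16 = 2L, float32 = 4L,
                  abort_config(sprintf("unknown dtype: %s", dtype)))
  if (sz %% bytes != 0L)
    abort_io(sprintf("truncated file: %d bytes not a multiple of %d", sz, bytes))
  n <- sz %/% bytes
  raw <- if (dtype == "int16") {
    readBin(path, what = "integer", n = n, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(path, what = "double", n = n, size = 4L, endian = "little")
  }
  if (length(raw) != n) abort_io("truncated file: fewer samples than declared size")
  recording(raw * scale, meta$fs, meta$t0 %||% 0)
}

#' Write a continuous recording to disk
#'
#' Writes the flat binary format read by [read_recording()]: little-endian
#' samples plus a JSON sidecar. `float32` round-trips bit-exactly (within
#' float32 precision of the stored values); `int16` stores
#' `round(samples / scale)`.
#'
#' @param sig a [recording].
#' @param path output file.
#' @param dtype `"float32"` (default) or `"int16"`.
#' @param scale volts-per-unit scale recorded in the sidecar (samples are
#'   divided by it before storage).
#' @param sidecar sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(sig, path, dtype = c("float32", "int16"),
                            scale = 1, sidecar = paste0(path, ".json")) {
  dtype <- match.arg(dtype)
  x <- sig$samples / scale
  if (dtype == "int16") {
    writeBin(as.integer(round(x)), path, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), path, size = 4L, endian = "little")
  }
  jsonlite::write_json(
    list(fs = sig$fs, dtype = dtype, scale = scale, t0 = sig$t0, channel = 1L),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Band-pass filter specification
#'
#' Defaults follow common practice for extracellular spike bands: a
#' fourth-order Butterworth between 300 and 3000 Hz, applied forward and
#' backward for zero net phase shift.
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth design order (the band-pass realization has
#'   `2 * order` poles).
#' @param zero_phase apply the filter forward and backward (default `TRUE`).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 300, high_hz = 3000, order = 4,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) abort_config("need 0 < low_hz < high_hz")
  if (order < 1) abort_config("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

# odd ("reflect about the end value") extension used to suppress start-up
# transients of the IIR filter; same idea as common filtfilt implementations
pad_odd <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  left <- 2 * x[1L] - x[seq(n_pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  c(left, x, right)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the Butterworth band-pass of `spec` in the forward and then the
#' reverse direction (offline zero-phase filtering), so in-band components
#' keep their timing exactly. Edges are protected by odd-reflection padding
#' of three times the realized filter order.
#'
#' @param sig a [recording].
#' @param spec a [filter_spec].
#' @return the filtered [recording] (same length).
#' @export
zero_phase_bandpass <- function(sig, spec = filter_spec()) {
  fs <- sig$fs
  if (spec$high_hz >= fs / 2)
    abort_config("high_hz must be below the Nyquist frequency fs/2")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  n_coef <- max(length(bf$b), length(bf$a)) - 1L
  n_pad <- 3L * n_coef
  if (length(sig$samples) <= n_pad)
    abort_config("signal too short for the filter's padding contract")
  x <- pad_odd(sig$samples, n_pad)
  y <- as.numeric(signal::filter(bf, x))
  if (spec$zero_phase) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  out <- y[seq(n_pad + 1L, n_pad + length(sig$samples))]
  recording(out, fs, sig$t0)
}

#' Robust noise estimate and detection threshold
#'
#' Estimates the noise standard deviation of a band-passed trace from the
#' median absolute sample value, `sigma_n = median(|r_f|) / 0.6745` (the
#' classic robust rule: spikes are sparse, so the median is dominated by
#' noise). The detection threshold is `c_t * sigma_n`.
#'
#' @param filtered a band-passed [recording].
#' @param c_t threshold multiplier (default 3).
#' @return a `noise_model` list with `sigma_n`, `threshold`, `c_t`.
#' @export
estimate_noise_std <- function(filtered, c_t = 3) {
  if (length(filtered$samples) < 1L) abort_config("empty signal")
  sigma_n <- stats::median(abs(filtered$samples)) / 0.6745
  structure(list(sigma_n = sigma_n, threshold = c_t * sigma_n, c_t = c_t),
            class = "noise_model")
}

#' Detection configuration
#'
#' @param c_t threshold multiplier on the noise std (default 3).
#' @param m_d number of additional consecutive samples that must stay beyond
#'   the threshold after the first crossing (default 2, i.e. three sub-threshold
#'   samples in a row at 40 kHz).
#' @param localmin_window_s horizon of the local-minimum snap: a sample is the
#'   event minimum if no smaller value occurs within this window after it
#'   (default 1 ms).
#' @param pre_s,post_s extraction window before/after the event minimum
#'   (defaults 0.5 ms and 1 ms).
#' @param polarity `"negative"` (default) detects downward deflections;
#'   `"positive"` mirrors the rule on the sign-flipped trace.
#' @param snap_local_min snap each event to the first local minimum after the
#'   crossing (default `TRUE`); `FALSE` keeps the raw crossing sample, as in
#'   classic threshold detectors.
#' @return a `detection_config` list.
#' @export
detection_config <- function(c_t = 3, m_d = 2, localmin_window_s = 1e-3,
                             pre_s = 0.5e-3, post_s = 1e-3,
                             polarity = c("negative", "positive"),
                             snap_local_min = TRUE) {
  polarity <- match.arg(polarity)
  if (c_t <= 0) abort_config("c_t must be positive")
  if (m_d < 0) abort_config("m_d must be >= 0")
  if (localmin_window_s <= 0 || pre_s <= 0 || post_s <= 0)
    abort_config("window lengths must be positive")
  structure(list(c_t = c_t, m_d = m_d, localmin_window_s = localmin_window_s,
                 pre_s = pre_s, post_s = post_s, polarity = polarity,
                 snap_local_min = snap_local_min),
            class = "detection_config")
}

#' Threshold spike detection with consecutive-sample rule and minimum snap
#'
#' An event starts at the first sample `m_s` for which the filtered trace is
#' strictly below `-threshold` for `m_d + 1` consecutive samples. The event
#' index is then the first local minimum at or after `m_s`, where a local
#' minimum is a sample with no smaller value within `localmin_window_s` after
#' it. Events snapping to the same minimum are merged, and events too close to
#' the signal edges for waveform extraction are dropped.
#'
#' Indices are stored 1-based (R convention); `times_s = (index - 1) / fs`.
#'
#' @param filtered band-passed [recording].
#' @param noise a `noise_model` from [estimate_noise_std()]; its threshold is
#'   recomputed as `cfg$c_t * sigma_n` so that `c_t` sweeps need only change
#'   the config.
#' @param cfg a [detection_config].
#' @return a `spike_events` list: integer `indices` (strictly increasing),
#'   `times_s`, `threshold`, and `n_dropped_edge`.
#' @export
detect_spikes <- function(filtered, noise, cfg = detection_config()) {
  x <- filtered$samples
  if (cfg$polarity == "positive") x <- -x
  fs <- filtered$fs
  thr <- cfg$c_t * noise$sigma_n
  n <- length(x)
  below <- x < -thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= (cfg$m_d + 1L)
  starts <- starts[ok]
  if (length(starts) == 0L) {
    return(structure(list(indices = integer(0), times_s = numeric(0),
                          threshold = thr, n_dropped_edge = 0L),
                     class = "spike_events"))
  }
  W <- max(1L, round(cfg$localmin_window_s * fs))
  snap <- function(k) {
    repeat {
      lo <- k + 1L
      hi <- min(k + W, n)
      if (lo > hi) return(k)
      j <- lo - 1L + which.min(x[lo:hi])
      if (x[j] < x[k]) k <- j else return(k)
    }
  }
  idx <- if (isTRUE(cfg$snap_local_min)) vapply(starts, snap, integer(1)) else starts
  idx <- sort(unique(idx))
  pre <- round(cfg$pre_s * fs)
  post <- round(cfg$post_s * fs)
  keep <- idx - pre >= 1L & idx + post <= n
  n_drop <- sum(!keep)
  idx <- idx[keep]
  structure(list(indices = as.integer(idx), times_s = (idx - 1) / fs,
                 threshold = thr, n_dropped_edge = n_drop),
            class = "spike_events")
}

#' Build a waveform set from a matrix
#'
#' Internal constructor shared by extraction and alignment: records per-row
#' extremum amplitudes (absolute values of the row minimum and maximum) and
#' their column indices.
#'
#' @keywords internal
waveform_set <- function(W, event_indices, fs, pre, post, sigma_n) {
  W <- as.matrix(W)
  idx_min <- max.col(-W, ties.method = "first")
  idx_max <- max.col(W, ties.method = "first")
  n <- nrow(W)
  a_min <- abs(W[cbind(seq_len(n), idx_min)])
  a_max <- abs(W[cbind(seq_len(n), idx_max)])
  if (n == 0L) a_min <- a_max <- numeric(0)
  structure(list(W = W, event_indices = as.integer(event_indices), fs = fs,
                 pre = as.integer(pre), post = as.integer(post),
                 a_min = a_min, a_max = a_max,
                 idx_min = as.integer(idx_min), idx_max = as.integer(idx_max),
                 sigma_n = sigma_n),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d waveforms x %d samples (pre %d, post %d) @ %g Hz\n",
              nrow(x$W), ncol(x$W), x$pre, x$post, x$fs))
  invisible(x)
}

#' Extract spike waveforms around detected events
#'
#' Each row spans `round(pre_s * fs)` samples before through
#' `round(post_s * fs)` samples after the event index, inclusive of the event
#' sample itself (61 samples at 40 kHz with the defaults). Events whose window
#' would leave the signal are dropped (count reported via attribute
#' `n_dropped`).
#'
#' @param filtered band-passed [recording].
#' @param events `spike_events` from [detect_spikes()].
#' @param cfg a [detection_config].
#' @param sigma_n noise std used downstream for normalization (default `NA`).
#' @return a `waveform_set`.
#' @export
extract_waveforms <- function(filtered, events, cfg = detection_config(),
                              sigma_n = NA_real_) {
  x <- filtered$samples
  fs <- filtered$fs
  pre <- round(cfg$pre_s * fs)
  post <- round(cfg$post_s * fs)
  idx <- events$indices
  keep <- idx - pre >= 1L & idx + post <= length(x)
  dropped <- sum(!keep)
  idx <- idx[keep]
  Tlen <- pre + post + 1L
  W <- matrix(0, nrow = length(idx), ncol = Tlen)
  if (length(idx) > 0L) {
    offs <- seq(-pre, post)
    W <- t(vapply(idx, function(k) x[k + offs], numeric(Tlen)))
  }
  ws <- waveform_set(W, idx, fs, pre, post, sigma_n)
  attr(ws, "n_dropped") <- dropped
  ws
}

#' Write detected events as CSV
#'
#' Columns `index` (0-based, matching the on-disk sample layout) and `time_s`.
#'
#' @param events `spike_events` (or any list with `indices`, `times_s`).
#' @param path output CSV path.
#' @param labels optional cluster labels column.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, labels = NULL) {
  df <- data.frame(index = events$indices - 1L, time_s = events$times_s)
  if (!is.null(labels)) df$cluster <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
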