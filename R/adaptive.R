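# Adaptive post-detection cleanup: statistical filtering of abnormal
# waveforms and multi-point alignment with tail trimming.

#' Statistical-filter configuration
#'
#' Thresholds on the absolute mean and the standard deviation of each
#' waveform, in noise-sigma units: pure noise then has mean ~ 0 and std ~ 1,
#' which makes the defaults (1 and 3) meaningful across recordings.
#'
#' @param thr_mean removal threshold on `|mean(row)|` (default 1).
#' @param thr_std removal threshold on `sd(row)` (default 3).
#' @param normalize_by_sigma divide rows by the recording's noise std before
#'   testing (default `TRUE`); with `FALSE` the thresholds act on raw units.
#' @return a `stat_filter_config` list.
#' @export
stat_filter_config <- function(thr_mean = 1, thr_std = 3,
                               normalize_by_sigma = TRUE) {
  if (thr_mean <= 0 || thr_std <= 0) abort_config("thresholds must be positive")
  structure(list(thr_mean = thr_mean, thr_std = thr_std,
                 normalize_by_sigma = normalize_by_sigma),
            class = "stat_filter_config")
}

#' Remove statistically abnormal waveforms
#'
#' A row is removed iff `|mean| > thr_mean` OR `sd > thr_std`, computed on the
#' row normalized by the noise std. Surviving rows are untouched and keep
#' their order (pure selection). Mistakenly detected noise stretches and
#' artifacts (offset baselines, wild amplitudes) fail these tests; regular
#' spikes pass.
#'
#' @param ws a `waveform_set`.
#' @param cfg a [stat_filter_config].
#' @return list with the filtered `ws` and a `report` (`kept_idx`,
#'   `removed_idx`, per-row `mean` and `sd` in normalized units).
#' @export
statistical_filter <- function(ws, cfg = stat_filter_config()) {
  n <- nrow(ws$W)
  if (n == 0L) {
    return(list(ws = ws, report = list(kept_idx = integer(0),
                                       removed_idx = integer(0),
                                       mean = numeric(0), sd = numeric(0))))
  }
  Wn <- ws$W
  if (cfg$normalize_by_sigma) {
    if (!is.finite(ws$sigma_n) || ws$sigma_n <= 0)
      abort_config("sigma_n must be positive for normalized filtering")
    Wn <- Wn / ws$sigma_n
  }
  m <- rowMeans(Wn)
  Tlen <- ncol(Wn)
  s <- if (Tlen > 1L) sqrt(rowSums((Wn - m)^2) / (Tlen - 1L)) else rep(0, n)
  removed <- abs(m) > cfg$thr_mean | s > cfg$thr_std
  kept <- which(!removed)
  out <- waveform_set(ws$W[kept, , drop = FALSE], ws$event_indices[kept],
                      ws$fs, ws$pre, ws$post, ws$sigma_n)
  list(ws = out,
       report = list(kept_idx = kept, removed_idx = which(removed),
                     mean = m, sd = s))
}

#' Multi-point alignment configuration
#'
#' @param m_peak number of aligning points retained per group (default 3).
#' @param m_shift maximum allowed shift in samples (default 10, i.e. 0.25 ms
#'   at 40 kHz).
#' @param spline_smoothing smoothing parameter (`spar`) of the cubic smoothing
#'   spline fitted to the unit-bin extremum histogram (default 0.5).
#' @return an `alignment_config` list.
#' @export
alignment_config <- function(m_peak = 3, m_shift = 10, spline_smoothing = 0.5) {
  if (m_peak < 1) abort_config("m_peak must be >= 1")
  if (m_shift < 0) abort_config("m_shift must be >= 0")
  structure(list(m_peak = m_peak, m_shift = m_shift,
                 spline_smoothing = spline_smoothing),
            class = "alignment_config")
}

# local maxima of the spline-smoothed unit-bin histogram of extremum indices;
# ranked by smoothed height, ties toward the smaller index
smoothed_histogram_peaks <- function(idx, Tlen, m_peak, spar) {
  if (length(idx) == 0L) return(integer(0))
  if (m_peak >= Tlen) return(sort(unique(idx)))  # alignment becomes identity
  counts <- tabulate(idx, nbins = Tlen)
  y <- tryCatch(
    stats::predict(stats::smooth.spline(seq_len(Tlen), counts, spar = spar),
                   seq_len(Tlen))$y,
    error = function(e) counts)
  n <- length(y)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || y[i] > y[i - 1L]
    right_ok <- i == n || y[i] >= y[i + 1L]
    is_peak[i] <- left_ok && right_ok
  }
  pk <- which(is_peak)
  # spline ringing around a sharp mode creates small spurious local maxima;
  # peaks below 5% of the top peak are not aligning points
  pk <- pk[y[pk] > 0]
  if (length(pk) > 0L) pk <- pk[y[pk] >= 0.05 * max(y[pk])]
  if (length(pk) == 0L) pk <- which.max(y)
  ord <- order(-y[pk], pk)
  sort(pk[ord[seq_len(min(m_peak, length(pk)))]])
}

#' Data-driven aligning points from extremum histograms
#'
#' Waveforms are split by which extremum dominates: group MAX holds rows with
#' `a_min < a_max` (the positive peak dominates), group MIN the rest. For each
#' group, the unit-bin histogram of the relevant extremum column indices is
#' smoothed by a cubic smoothing spline and the `m_peak` largest local maxima
#' of the smoothed curve become the group's aligning points. With
#' `m_peak >= T` every occupied index is an aligning point and alignment is
#' the identity.
#'
#' @param ws a `waveform_set`.
#' @param cfg an [alignment_config].
#' @return list with integer vectors `max_points` and `min_points` and the
#'   logical group indicator `is_max_group`.
#' @export
find_alignment_points <- function(ws, cfg = alignment_config()) {
  Tlen <- ncol(ws$W)
  is_max <- ws$a_min < ws$a_max
  list(
    max_points = smoothed_histogram_peaks(ws$idx_max[is_max], Tlen,
                                          cfg$m_peak, cfg$spline_smoothing),
    min_points = smoothed_histogram_peaks(ws$idx_min[!is_max], Tlen,
                                          cfg$m_peak, cfg$spline_smoothing),
    is_max_group = is_max
  )
}

# nearest aligning point; equidistant candidates resolve to the earlier point
nearest_point <- function(e, points) {
  if (length(points) == 0L) return(NA_integer_)
  d <- abs(points - e)
  points[which.min(d)]
}

#' Align waveforms to their nearest aligning point
#'
#' Each row whose group-relevant extremum lies within `m_shift` samples of its
#' nearest aligning point is shifted by a whole number of samples so the
#' extremum lands on that point (index slicing, no interpolation); rows
#' farther away are left unshifted. All rows are then trimmed to the column
#' range valid under every applied shift, so the matrix stays rectangular
#' (at most `m_shift` columns lost per end) and the uninformative tails are
#' discarded. Event indices are updated by the applied shift so spike times
#' track the aligned waveform.
#'
#' @param ws a `waveform_set`.
#' @param points result of [find_alignment_points()] on the same set.
#' @param cfg an [alignment_config].
#' @return the aligned, trimmed `waveform_set`, with attribute `shifts`.
#' @export
align_waveforms <- function(ws, points, cfg = alignment_config()) {
  n <- nrow(ws$W)
  if (n == 0L) return(ws)
  Tlen <- ncol(ws$W)
  is_max <- points$is_max_group
  shifts <- integer(n)
  for (i in seq_len(n)) {
    e <- if (is_max[i]) ws$idx_max[i] else ws$idx_min[i]
    p <- nearest_point(e, if (is_max[i]) points$max_points else points$min_points)
    if (!is.na(p) && abs(e - p) <= cfg$m_shift) shifts[i] <- e - p
  }
  # valid target columns t require t + shift in [1, T] for every applied shift
  lo <- 1L - min(c(shifts, 0L))
  hi <- Tlen - max(c(shifts, 0L))
  cols <- seq.int(lo, hi)
  W2 <- matrix(0, n, length(cols))
  for (i in seq_len(n)) W2[i, ] <- ws$W[i, cols + shifts[i]]
  new_pre <- ws$pre - (lo - 1L)
  new_post <- ws$post - (Tlen - hi)
  out <- waveform_set(W2, ws$event_indices + shifts, ws$fs, new_pre, new_post,
                      ws$sigma_n)
  attr(out, "shifts") <- shifts
  out
}

#' Adaptive detection: statistical filtering then multi-point alignment
#'
#' Composite cleanup applied to any detected waveform set, including
#' externally supplied detections. Disabling both stages reproduces the
#' input unchanged.
#'
#' @param ws a `waveform_set`.
#' @param sf a [stat_filter_config].
#' @param ac an [alignment_config].
#' @param apply_filter,apply_alignment stage switches (both default `TRUE`).
#' @return list with the cleaned `ws`, the filter `report`, and the aligning
#'   `points`.
#' @export
adaptive_detect <- function(ws, sf = stat_filter_config(),
                            ac = alignment_config(),
                            apply_filter = TRUE, apply_alignment = TRUE) {
  report <- list(kept_idx = seq_len(nrow(ws$W)), removed_idx = integer(0))
  if (apply_filter) {
    st <- statistical_filter(ws, sf)
    ws <- st$ws
    report <- st$report
  }
  points <- NULL
  if (apply_alignment && nrow(ws$W) > 0L) {
    points <- find_alignment_points(ws, ac)
    ws <- align_waveforms(ws, points, ac)
  }
  list(ws = ws, report = report, points = points)
}

#' Single-point extremum alignment (classic baseline)
#'
#' Re-centers every waveform window on its global minimum by re-extracting
#' from the trace: the traditional alignment used by threshold-based sorters,
#' kept as the baseline detection mode. Duplicate events created when several
#' windows collapse onto one extremum are merged.
#'
#' @param filtered band-passed [recording].
#' @param ws a `waveform_set` extracted from `filtered`.
#' @param cfg the [detection_config] used for extraction.
#' @return a re-extracted `waveform_set`.
#' @export
extremum_align <- function(filtered, ws, cfg = detection_config()) {
  if (nrow(ws$W) == 0L) return(ws)
  new_idx <- ws$event_indices - (ws$pre + 1L) + ws$idx_min
  new_idx <- sort(unique(new_idx))
  ev <- structure(list(indices = new_idx, times_s = (new_idx - 1) / filtered$fs),
                  class = "spike_events")
  extract_waveforms(filtered, ev, cfg, sigma_n = ws$sigma_n)
}
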