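# Recording I/O, zero-phase filtering, noise estimation and threshold
# detection.

test_that("binary recordings round-trip through the sidecar format", {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  sig <- recording(as.numeric(round(rnorm(1000), 4) * 2^10) / 2^10, fs = 40000)
  # values representable in float32 round-trip exactly
  sig$samples <- as.numeric(readBin(writeBin(as.numeric(sig$samples), raw(),
                                             size = 4L), "double",
                                    n = 1000, size = 4L))
  write_recording(sig, tmp)
  back <- read_recording(tmp)
  expect_identical(back$samples, sig$samples)
  expect_equal(back$fs, 40000)
})

test_that("int16 input honours the declared scale", {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  writeBin(c(4L, -8L, 100L), tmp, size = 2L, endian = "little")
  jsonlite::write_json(list(fs = 1000, dtype = "int16", scale = 0.25),
                       paste0(tmp, ".json"), auto_unbox = TRUE)
  sig <- read_recording(tmp)
  expect_equal(sig$samples, c(1, -2, 25))
})

test_that("missing sidecar fields raise configuration errors", {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  writeBin(1:4 / 2, tmp, size = 4L)
  jsonlite::write_json(list(dtype = "float32"), paste0(tmp, ".json"),
                       auto_unbox = TRUE)
  expect_config_error(read_recording(tmp))
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  writeLines(c("0.1", "0.2"), csv)
  expect_config_error(read_recording(csv, fs = NULL))
})

test_that("zero-phase band-pass keeps in-band timing and kills out-of-band", {
  fs <- 40000
  t <- seq(0, 2, by = 1 / fs)
  # all-zero signal stays zero
  z <- zero_phase_bandpass(recording(rep(0, 1000), fs))
  expect_equal(z$samples, rep(0, 1000))
  # 1 kHz is in-band: amplitude within 1%, peak positions unchanged
  s1 <- sin(2 * pi * 1000 * t)
  f1 <- zero_phase_bandpass(recording(s1, fs))$samples
  core <- seq(2000, length(t) - 2000)
  expect_lt(abs(max(f1[core]) - 1), 0.01)
  # zero-phase: the cross-correlation between input and output peaks at lag 0
  lags <- -5:5
  xc <- sapply(lags, function(L) sum(s1[core] * f1[core + L]))
  expect_equal(lags[which.max(xc)], 0L)
  # 10 Hz is far out of band; oracle = squared magnitude response of the
  # designed coefficients at 10 Hz, applied twice (forward and backward)
  s2 <- sin(2 * pi * 10 * t)
  f2 <- zero_phase_bandpass(recording(s2, fs))$samples
  bf <- signal::butter(4, c(300, 3000) / (fs / 2), type = "pass")
  zz <- exp(1i * 2 * pi * 10 / fs)
  H <- sum(bf$b * zz^-(seq_along(bf$b) - 1)) /
    sum(bf$a * zz^-(seq_along(bf$a) - 1))
  gain2 <- Mod(H)^2   # forward-backward squares the magnitude
  rms_ratio <- sqrt(mean(f2[core]^2)) / sqrt(mean(s2[core]^2))
  expect_lt(rms_ratio, 0.01)
  expect_lt(abs(rms_ratio - gain2), 0.005)
  # config guard
  expect_config_error(zero_phase_bandpass(recording(rnorm(100), 5000),
                                          filter_spec(300, 3000)))
})

test_that("noise estimate follows the median rule", {
  nm <- estimate_noise_std(recording(c(0.6745, -0.6745, 0.6745, -0.6745), 1))
  expect_equal(nm$sigma_n, 1.0)
  expect_equal(nm$threshold, 3.0)
  expect_equal(estimate_noise_std(recording(rep(0, 10), 1))$sigma_n, 0)
  set.seed(11)
  big <- estimate_noise_std(recording(rnorm(1e6, sd = 2), 1))
  expect_gt(big$sigma_n, 1.98)
  expect_lt(big$sigma_n, 2.02)
})

test_that("detection needs m_d + 1 consecutive sub-threshold samples", {
  fs <- 1000
  nm <- structure(list(sigma_n = 1, threshold = 3, c_t = 3),
                  class = "noise_model")
  cfg <- detection_config(m_d = 1, localmin_window_s = 3 / fs,
                          pre_s = 1 / fs, post_s = 1 / fs)
  x1 <- c(0, -4, 0, 0, 0, 0)
  expect_length(detect_spikes(recording(x1, fs), nm, cfg)$indices, 0)
  x2 <- c(0, -4, -5, 0, 0, 0)
  ev <- detect_spikes(recording(x2, fs), nm, cfg)
  expect_equal(ev$indices, 3L)  # the -5 sample
  # all-zero signal: nothing
  expect_length(detect_spikes(recording(rep(0, 100), fs), nm, cfg)$indices, 0)
  # ties at exactly -t_s do not trigger (strict inequality)
  x3 <- c(0, -3, -3, -3, 0, 0)
  expect_length(detect_spikes(recording(x3, fs), nm, cfg)$indices, 0)
})

test_that("detection matches an exhaustive naive scan on simulated data", {
  ses <- small_session(duration_s = 6, snr_db = 15, seed = 3)
  filt <- zero_phase_bandpass(ses$signal)
  nm <- estimate_noise_std(filt)
  cfg <- detection_config()
  ev <- detect_spikes(filt, nm, cfg)
  W <- round(cfg$localmin_window_s * filt$fs)
  oracle <- naive_detect(filt$samples, nm$threshold, cfg$m_d, W)
  pre <- round(cfg$pre_s * filt$fs)
  post <- round(cfg$post_s * filt$fs)
  oracle <- oracle[oracle - pre >= 1 & oracle + post <= length(filt$samples)]
  expect_gt(length(ev$indices), 50)
  expect_true(all(abs(ev$indices - oracle) <= 1))
})

test_that("detection is idempotent and monotone in the threshold multiplier", {
  ses <- small_session(duration_s = 4, snr_db = 11, seed = 5)
  filt <- zero_phase_bandpass(ses$signal)
  nm <- estimate_noise_std(filt)
  e1 <- detect_spikes(filt, nm)
  e2 <- detect_spikes(filt, nm)
  expect_identical(e1$indices, e2$indices)
  counts <- sapply(c(2, 3, 4, 5), function(ct)
    length(detect_spikes(filt, nm, detection_config(c_t = ct))$indices))
  expect_true(all(diff(counts) <= 0))
})

test_that("waveform extraction geometry follows the window definition", {
  fs <- 40000
  cfg <- detection_config()
  expect_equal(round(cfg$pre_s * fs) + round(cfg$post_s * fs) + 1, 61)
  # single event in a ramp: row equals samples 80..140
  x <- seq_len(200)
  ev <- structure(list(indices = 100L, times_s = 99 / fs),
                  class = "spike_events")
  ws <- extract_waveforms(recording(x, fs), ev, cfg)
  expect_equal(dim(ws$W), c(1, 61))
  expect_equal(as.numeric(ws$W[1, ]), as.numeric(x[80:140]))
  # in the simulator, every detected row's global minimum sits at the
  # alignment column (construction of the snap rule)
  ses <- small_session(duration_s = 4, snr_db = 15, seed = 2)
  filt <- zero_phase_bandpass(ses$signal)
  nm <- estimate_noise_std(filt)
  ev2 <- detect_spikes(filt, nm)
  ws2 <- extract_waveforms(filt, ev2, cfg, nm$sigma_n)
  # a deeper trough of an earlier overlapping spike can sit in the pre-window,
  # so the alignment column holds the global minimum for nearly all rows
  expect_gt(mean(ws2$idx_min == round(cfg$pre_s * fs) + 1), 0.9)
})

test_that("events CSV uses 0-based indices with matching times", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  ev <- structure(list(indices = c(5L, 10L), times_s = c(4, 9) / 100),
                  class = "spike_events")
  write_events_csv(ev, tmp)
  df <- read.csv(tmp)
  expect_equal(df$index, c(4, 9))
  expect_equal(df$time_s, df$index / 100)
})

test_that("waveform binaries round-trip through the sidecar", {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  W <- matrix(round(rnorm(5 * 61), 3), 5, 61)
  ws <- skewsort:::waveform_set(W, 1:5 * 100L, 40000, 20, 40, 1)
  write_waveforms_bin(ws, tmp)
  back <- read_waveforms_bin(tmp)
  expect_equal(back$W, W, tolerance = 1e-6)  # float32 storage
  expect_equal(back$pre, 20L)
  expect_equal(ncol(back$W), 61)
})
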