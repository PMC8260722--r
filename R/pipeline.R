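# End-to-end orchestration: filter -> noise estimate -> detect -> adaptive
# cleanup -> PCA -> backward mixture search -> labels, plus scaled
# reproductions of the synthetic-data experiments.

#' Pipeline configuration
#'
#' `mode` selects the processing variant:
#' * `"mstd"` — full pipeline: statistical filtering, multi-point alignment,
#'   skew-t mixture clustering;
#' * `"mtd"` — classic baseline: plain threshold-crossing detection (no
#'   consecutive-sample rule, no local-minimum snap), single-point extremum
#'   alignment, no statistical filtering, skewness clamped to zero
#'   (t-mixture) — the traditional procedure the full pipeline is compared
#'   against;
#' * `"base"` — no statistical filtering, no alignment, skew-t clustering.
#'
#' @param mode one of `"mstd"`, `"mtd"`, `"base"`.
#' @param filter a [filter_spec].
#' @param detection a [detection_config].
#' @param stat_filter a [stat_filter_config].
#' @param alignment an [alignment_config].
#' @param pca a [pca_config].
#' @param search a [search_config].
#' @param em an [em_config].
#' @param cluster run the clustering stage (default `TRUE`; `FALSE` stops
#'   after adaptive detection, for detection-only experiments).
#' @param seed master seed for FCM starts and fitting subsamples.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("mstd", "mtd", "base"),
                            filter = filter_spec(),
                            detection = detection_config(),
                            stat_filter = stat_filter_config(),
                            alignment = alignment_config(),
                            pca = pca_config(),
                            search = search_config(),
                            em = em_config(),
                            cluster = TRUE,
                            seed = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, filter = filter, detection = detection,
                 stat_filter = stat_filter, alignment = alignment,
                 pca = pca, search = search, em = em, cluster = cluster,
                 seed = seed), class = "pipeline_config")
}

#' Run the spike-sorting pipeline on a recording
#'
#' Executes band-pass filtering, robust noise estimation, consecutive-sample
#' threshold detection, the mode-dependent adaptive-detection stage, adaptive
#' PCA, and the backward mixture search. Fully reproducible from
#' `(input, config)`.
#'
#' @param input a [recording] or a `synthetic_session` (its `signal` is used).
#' @param cfg a [pipeline_config].
#' @return a `sorting_result`: `mode`, `noise`, `events_initial` (after
#'   threshold detection), `events` (after the adaptive stage; these are the
#'   spike times the mode reports), `waveforms`, `filter_report`, `features`,
#'   `search`, `labels`, `g_opt`, and `log` (the defaults in force).
#' @export
run_pipeline <- function(input, cfg = pipeline_config()) {
  sig <- if (inherits(input, "synthetic_session")) input$signal else input
  if (!inherits(sig, "recording")) abort_config("input must be a recording or session")

  filtered <- zero_phase_bandpass(sig, cfg$filter)
  noise <- estimate_noise_std(filtered, c_t = cfg$detection$c_t)
  det_cfg <- cfg$detection
  if (cfg$mode == "mtd") {
    det_cfg$m_d <- 0
    det_cfg$snap_local_min <- FALSE
  }
  ev0 <- detect_spikes(filtered, noise, det_cfg)
  ws <- extract_waveforms(filtered, ev0, det_cfg, sigma_n = noise$sigma_n)

  filter_report <- NULL
  points <- NULL
  if (cfg$mode == "mstd") {
    ad <- adaptive_detect(ws, cfg$stat_filter, cfg$alignment)
    ws <- ad$ws
    filter_report <- ad$report
    points <- ad$points
  } else if (cfg$mode == "mtd") {
    ws <- extremum_align(filtered, ws, det_cfg)
  }
  events <- structure(list(indices = ws$event_indices,
                           times_s = (ws$event_indices - 1) / sig$fs,
                           threshold = ev0$threshold),
                      class = "spike_events")

  features <- NULL
  search <- NULL
  labels <- NULL
  if (cfg$cluster && nrow(ws$W) > max(2, cfg$search$g_min + 1)) {
    features <- extract_features(ws, cfg$pca)
    search <- backward_search(features$X, cfg$search, cfg$em,
                              seed = cfg$seed,
                              fix_lambda = (cfg$mode == "mtd"))
    labels <- search$labels
  }

  structure(list(mode = cfg$mode, noise = noise, events_initial = ev0,
                 events = events, waveforms = ws,
                 filter_report = filter_report, align_points = points,
                 features = features, search = search, labels = labels,
                 g_opt = if (!is.null(search)) search$g_opt else NA_integer_,
                 log = list(m_d = cfg$detection$m_d,
                            c_t = cfg$detection$c_t,
                            m_peak = cfg$alignment$m_peak,
                            m_shift = cfg$alignment$m_shift,
                            thr_mean = cfg$stat_filter$thr_mean,
                            thr_std = cfg$stat_filter$thr_std,
                            g_range = c(cfg$search$g_min, cfg$search$g_max),
                            criterion = cfg$search$criterion,
                            l_em = cfg$em$l_em, v_init = cfg$em$v_init,
                            seed = cfg$seed)),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("<sorting_result> mode %s: %d events, g_opt = %s\n",
              x$mode, length(x$events$indices),
              if (is.na(x$g_opt)) "-" else x$g_opt))
  invisible(x)
}

#' Score a sorting result against a session's ground truth
#'
#' Convenience wrapper used by the experiment reproductions: matches spike
#' times within `tol_s`, then computes precision/recall and, when cluster
#' labels are present, accuracy/purity over matched spikes, the SSI, and the
#' Bayes reference accuracies on the matched spikes.
#'
#' @param result a `sorting_result`.
#' @param session the `synthetic_session` it was run on.
#' @param tol_s matching tolerance (default 1 ms).
#' @param ssi_reps,ssi_seed SSI miss-randomization controls.
#' @return a one-row data frame of metrics.
#' @export
score_session <- function(result, session, tol_s = 1e-3, ssi_reps = 20,
                          ssi_seed = 1) {
  m <- match_spike_times(result$events$times_s, session$truth$time_s, tol_s)
  pr <- suppressWarnings(detection_metrics(m))
  out <- data.frame(mode = result$mode, n_detected = length(result$events$times_s),
                    n_true = nrow(session$truth), tp = m$tp, fp = m$fp,
                    fn = m$fn, precision = pr[["precision"]],
                    recall = pr[["recall"]], accuracy = NA_real_,
                    purity = NA_real_, g_opt = result$g_opt, ssi = NA_real_,
                    ca_method = NA_real_, ca_bayes = NA_real_)
  if (!is.null(result$labels) && m$tp > 1) {
    pred <- result$labels[m$pairs$det]
    tru <- session$truth$neuron[m$pairs$tru]
    cm <- clustering_metrics(pred, tru)
    out$accuracy <- cm[["accuracy"]]
    out$purity <- cm[["purity"]]
    out$ssi <- ssi(session$truth$time_s, session$truth$neuron,
                   result$events$times_s, result$labels,
                   tol_s = tol_s, reps = ssi_reps, seed = ssi_seed)
    ba <- bayes_reference_accuracy(session, spike_idx = m$pairs$tru,
                                   method_labels = pred)
    out$ca_method <- ba$ca_method
    out$ca_bayes <- ba$ca_bayes
  }
  out
}

#' Scaled reproduction of the synthetic-data experiments
#'
#' Reruns the package's synthetic evaluation designs at a chosen scale:
#' * `"fig4"` — detection precision/recall per SNR for the full (`mstd`) and
#'   baseline (`mtd`) modes on matched sessions (detection stage only);
#' * `"fig5"` — clustering accuracy/purity/estimated cluster count per SNR,
#'   both mixture variants on the same detected spikes;
#' * `"fig3"` — SSI per SNR plus the CA-CA regression of pipeline accuracy
#'   on the Bayes reference.
#'
#' @param name `"fig3"`, `"fig4"` or `"fig5"`.
#' @param scale fraction of the full design (200 sessions x 200 s); session
#'   count and duration both scale (default 0.05).
#' @param seed master seed.
#' @param snr_db SNR grid; defaults per experiment.
#' @param n_sessions,duration_s explicit overrides of the scaled sizes.
#' @param base_cfg base [session_config] for everything else.
#' @param pipe_cfg base [pipeline_config]; its mode is overridden as needed.
#' @return for `"fig4"`/`"fig5"`: data frame with one row per session x SNR
#'   x mode plus an aggregate attribute `summary`; for `"fig3"`: list with
#'   the per-session table and the CA-CA fit.
#' @export
reproduce_experiment <- function(name = c("fig4", "fig5", "fig3"),
                                 scale = 0.05, seed = 1, snr_db = NULL,
                                 n_sessions = NULL, duration_s = NULL,
                                 base_cfg = session_config(),
                                 pipe_cfg = pipeline_config()) {
  name <- match.arg(name)
  n_sessions <- n_sessions %||% max(2L, round(scale * 200))
  duration_s <- duration_s %||% max(10, scale * 200)
  snr_db <- snr_db %||% switch(name,
    fig4 = c(1, 3, 5, 7, 9, 11, 13, 15),
    fig5 = c(5, 7, 9, 11, 13),
    fig3 = c(1, 3, 5, 7, 9, 11, 13, 15))

  rows <- list()
  for (s in seq_len(n_sessions)) {
    for (snr in snr_db) {
      cfg <- base_cfg
      cfg$duration_s <- duration_s
      cfg$seed <- seed + s
      cfg$snr_db <- snr
      session <- generate_session(cfg)
      modes <- if (name == "fig4") c("mstd", "mtd")
               else if (name == "fig5") c("mstd", "mtd")
               else "mstd"
      for (mode in modes) {
        pc <- pipe_cfg
        pc$mode <- mode
        pc$cluster <- name != "fig4"
        pc$seed <- seed + s
        res <- run_pipeline(session, pc)
        sc <- score_session(res, session, ssi_seed = seed + s)
        sc$snr_db <- snr
        sc$session <- s
        rows[[length(rows) + 1L]] <- sc
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (name == "fig3") {
    ok <- stats::complete.cases(tab[, c("ca_method", "ca_bayes")])
    fit <- if (sum(ok) >= 3 && stats::var(tab$ca_bayes[ok]) > 0)
      ca_ca_fit(tab$ca_method[ok], tab$ca_bayes[ok]) else NULL
    return(list(table = tab, ca_ca = fit))
  }
  agg_stats <- function(v, by) {
    m <- tapply(v, by, mean, na.rm = TRUE)
    s <- tapply(v, by, stats::sd, na.rm = TRUE)
    list(mean = m, sd = s)
  }
  by <- interaction(tab$snr_db, tab$mode, drop = TRUE)
  attr(tab, "summary") <- data.frame(
    group = levels(by),
    precision_mean = as.numeric(agg_stats(tab$precision, by)$mean),
    precision_sd = as.numeric(agg_stats(tab$precision, by)$sd),
    recall_mean = as.numeric(agg_stats(tab$recall, by)$mean),
    recall_sd = as.numeric(agg_stats(tab$recall, by)$sd),
    accuracy_mean = as.numeric(agg_stats(tab$accuracy, by)$mean),
    purity_mean = as.numeric(agg_stats(tab$purity, by)$mean),
    g_opt_mean = as.numeric(agg_stats(tab$g_opt, by)$mean))
  tab
}
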