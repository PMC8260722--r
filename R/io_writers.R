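# On-disk artifact writers for the pipeline stages: flat binary waveforms,
# filter reports, feature tables and search results.

#' Write a waveform set as flat binary with a JSON sidecar
#'
#' Row-major float32 matrix plus a sidecar declaring `n`, `T`, `fs`, `pre_s`,
#' `post_s`, so the matrix can be reconstructed without guessing shapes.
#'
#' @param ws a `waveform_set`.
#' @param path output binary path.
#' @param sidecar sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_waveforms_bin <- function(ws, path, sidecar = paste0(path, ".json")) {
  writeBin(as.numeric(t(ws$W)), path, size = 4L, endian = "little")
  jsonlite::write_json(list(n = nrow(ws$W), T = ncol(ws$W), fs = ws$fs,
                            pre_s = ws$pre / ws$fs, post_s = ws$post / ws$fs),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a waveform matrix written by [write_waveforms_bin()]
#'
#' @param path binary path.
#' @param sidecar sidecar path; default `paste0(path, ".json")`.
#' @return a `waveform_set` (event indices unknown, set to `NA`).
#' @export
read_waveforms_bin <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (!file.exists(sidecar)) abort_config(sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  vals <- readBin(path, "double", n = meta$n * meta$T, size = 4L,
                  endian = "little")
  if (length(vals) != meta$n * meta$T)
    abort_io("truncated file: fewer values than the sidecar declares")
  W <- matrix(vals, nrow = meta$n, byrow = TRUE)
  waveform_set(W, rep(NA_integer_, meta$n), meta$fs,
               round(meta$pre_s * meta$fs), round(meta$post_s * meta$fs),
               NA_real_)
}

#' Serialize a statistical-filter report to JSON
#'
#' Optionally writes the removed waveforms to a binary side file for audit,
#' mirroring a manual-review workflow.
#'
#' @param report the `report` element returned by [statistical_filter()].
#' @param path output JSON path.
#' @param removed_ws optional `waveform_set` of the rows before filtering;
#'   when given, the removed rows are written next to the report as
#'   `<path>.removed.bin`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path, removed_ws = NULL) {
  jsonlite::write_json(list(kept_idx = report$kept_idx,
                            removed_idx = report$removed_idx,
                            mean = report$mean, sd = report$sd),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(removed_ws) && length(report$removed_idx) > 0L) {
    sub <- waveform_set(removed_ws$W[report$removed_idx, , drop = FALSE],
                        removed_ws$event_indices[report$removed_idx],
                        removed_ws$fs, removed_ws$pre, removed_ws$post,
                        removed_ws$sigma_n)
    write_waveforms_bin(sub, paste0(path, ".removed.bin"))
  }
  invisible(path)
}

#' Write extracted features as CSV plus JSON metadata
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param csv_path scores CSV (n rows x n_c columns).
#' @param json_path metadata JSON (`eigenvalues`, `n_c`); default derived
#'   from `csv_path`.
#' @return `csv_path`, invisibly.
#' @export
write_features <- function(fm, csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(as.data.frame(fm$X), csv_path, row.names = FALSE)
  jsonlite::write_json(list(eigenvalues = fm$eigenvalues, n_c = fm$n_c),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write a model-order search result to a directory
#'
#' Emits `labels.csv` (event index, time, cluster), `score_table.csv`
#' (per-order selection scores) and `model.json` (the selected mixture).
#'
#' @param sr a `search_result` from [backward_search()].
#' @param dir output directory (created if needed).
#' @param events optional `spike_events` aligned with the labels.
#' @return `dir`, invisibly.
#' @export
write_search_result <- function(sr, dir, events = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- data.frame(cluster = sr$labels)
  if (!is.null(events)) {
    lab <- data.frame(index = events$indices - 1L, time_s = events$times_s,
                      cluster = sr$labels)
  }
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(sr$table, file.path(dir, "score_table.csv"),
                   row.names = FALSE)
  write_mixture_json(sr$best, file.path(dir, "model.json"))
  invisible(dir)
}
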