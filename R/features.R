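# Adaptive PCA feature extraction.

#' PCA configuration
#'
#' @param var_target cumulative explained-variance target deciding how many
#'   components are kept (default 0.95).
#' @param n_pca_max hard cap on the number of components (default 15), guarding
#'   against the curse of dimensionality when waveform variance is diffuse.
#' @param center mean-center waveforms before the decomposition (default TRUE).
#' @return a `pca_config` list.
#' @export
pca_config <- function(var_target = 0.95, n_pca_max = 15, center = TRUE) {
  if (var_target <= 0 || var_target > 1) abort_config("var_target must be in (0, 1]")
  if (n_pca_max < 1) abort_config("n_pca_max must be >= 1")
  structure(list(var_target = var_target, n_pca_max = n_pca_max,
                 center = center), class = "pca_config")
}

#' Number of components needed for the variance target
#'
#' The smallest `n_c` with `sum(ev[1:n_c]) / sum(ev) >= var_target`, capped at
#' `n_pca_max`.
#'
#' @param eigenvalues principal-component variances, sorted descending.
#' @param cfg a [pca_config].
#' @return integer `n_c`.
#' @export
select_num_components <- function(eigenvalues, cfg = pca_config()) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) == 0L || any(ev < -1e-12 * max(ev, 0)) || sum(ev) <= 0)
    abort_degenerate("eigenvalues must be nonnegative with positive sum")
  if (is.unsorted(rev(ev) - 1e-12 * max(ev)))
    abort_config("eigenvalues must be sorted in decreasing order")
  frac <- cumsum(ev) / sum(ev)
  n_c <- which(frac >= cfg$var_target - 1e-12)[1L]
  if (is.na(n_c)) n_c <- length(ev)
  min(n_c, cfg$n_pca_max)
}

#' Project waveforms onto an adaptively sized principal-component space
#'
#' Covariance PCA on (optionally) mean-centered waveforms. The retained
#' dimension is chosen by [select_num_components()]. Component signs follow a
#' deterministic convention (the largest-magnitude loading entry of each
#' component is positive) so repeated runs agree exactly.
#'
#' @param ws a `waveform_set` or a plain numeric matrix (rows = waveforms).
#' @param cfg a [pca_config].
#' @return a `feature_matrix` list: `X` (n x n_c scores), `eigenvalues` (all
#'   components), `n_c`, `explained` (cumulative variance ratios), `loadings`,
#'   and `center`.
#' @export
extract_features <- function(ws, cfg = pca_config()) {
  W <- if (inherits(ws, "waveform_set")) ws$W else as.matrix(ws)
  if (nrow(W) < 2L || ncol(W) < 2L)
    abort_degenerate("need at least 2 waveforms and 2 samples for PCA")
  ctr <- if (cfg$center) colMeans(W) else rep(0, ncol(W))
  Wc <- sweep(W, 2L, ctr)
  sv <- svd(Wc)
  ev <- sv$d^2 / (nrow(W) - 1L)
  # deterministic sign: largest |loading| entry positive per component
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  n_c <- select_num_components(ev, cfg)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  structure(list(X = scores[, seq_len(n_c), drop = FALSE],
                 eigenvalues = ev, n_c = n_c,
                 explained = cumsum(ev) / sum(ev),
                 loadings = sv$v[, seq_len(n_c), drop = FALSE],
                 center = ctr),
            class = "feature_matrix")
}
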