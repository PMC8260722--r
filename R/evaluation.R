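# Detection and clustering metrics: time matching, precision/recall,
# accuracy/purity, the spike sorting index (SSI), the Bayes-optimal
# reference classifier and the CA-CA robustness fit.

#' Match detected to true spike times
#'
#' One-to-one matching within a tolerance window. Detections are scanned in
#' time order and each is paired with the earliest still-unmatched true
#' spike within `tol_s`; for sorted event times this yields a maximum
#' cardinality one-to-one matching (no valid pairing can recover more true
#' positives), so duplicate detections of one spike cannot inflate the true
#' positive count and no achievable match is dropped.
#'
#' @param detected numeric vector of detected spike times (s), sorted.
#' @param truth numeric vector of true spike times (s), sorted.
#' @param tol_s matching tolerance (default 1 ms vicinity).
#' @return a `detection_match`: counts `tp`, `fp`, `fn` and a data frame
#'   `pairs` with columns `det`, `tru`, `dt` (indices into the inputs).
#' @export
match_spike_times <- function(detected, truth, tol_s = 1e-3) {
  nd <- length(detected)
  nt <- length(truth)
  pair_d <- integer(0)
  pair_t <- integer(0)
  j <- 1L
  for (i in seq_len(nd)) {
    while (j <= nt && truth[j] < detected[i] - tol_s) j <- j + 1L
    if (j > nt) break
    if (truth[j] <= detected[i] + tol_s) {
      pair_d <- c(pair_d, i)
      pair_t <- c(pair_t, j)
      j <- j + 1L
    }
  }
  pairs <- data.frame(det = pair_d, tru = pair_t,
                      dt = if (length(pair_d)) detected[pair_d] - truth[pair_t]
                           else numeric(0))
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs),
                 fn = nt - nrow(pairs), pairs = pairs),
            class = "detection_match")
}

#' Detection precision and recall
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. Empty
#' denominators yield `NaN` with a warning.
#'
#' @param m a `detection_match`.
#' @return named numeric vector `c(precision, recall)`.
#' @export
detection_metrics <- function(m) {
  precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warning("precision undefined: no detections")
    NaN
  }
  recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else {
    warning("recall undefined: no true spikes")
    NaN
  }
  c(precision = precision, recall = recall)
}

#' Clustering accuracy and purity against ground truth
#'
#' Both metrics work on the contingency table of predicted clusters versus
#' true units over matched spikes. Purity is the normalized sum of
#' per-cluster maximum overlaps, `sum_c max_d |c ∩ d| / N`. Accuracy
#' assigns each cluster (processed in order of decreasing size, ties to the
#' smaller index) its most frequent not-yet-assigned true unit, and counts
#' the spikes of that unit inside the cluster.
#'
#' @param pred integer/factor vector of predicted cluster labels.
#' @param truth vector of true unit labels, same length.
#' @return named numeric vector `c(accuracy, purity)`.
#' @export
clustering_metrics <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("pred and truth must be nonempty and of equal length")
  tab <- table(pred, truth)
  N <- sum(tab)
  purity <- sum(apply(tab, 1L, max)) / N
  sizes <- rowSums(tab)
  order_c <- order(-sizes, seq_along(sizes))
  assigned <- rep(FALSE, ncol(tab))
  correct <- 0
  for (ci in order_c) {
    counts <- tab[ci, ]
    counts[assigned] <- -1
    if (all(counts < 0)) next
    di <- which.max(counts)
    if (counts[di] < 0) next
    assigned[di] <- TRUE
    correct <- correct + tab[ci, di]
  }
  c(accuracy = correct / N, purity = purity)
}

# mutual information (nats) of a joint label contingency table
mutual_information <- function(a, b) {
  tab <- table(a, b)
  N <- sum(tab)
  pij <- tab / N
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
}

#' Spike sorting index
#'
#' A single number capturing detection and clustering quality together:
#' the normalized mutual information between true and predicted labelings
#' over the union of events. False alarms (unmatched detections) all receive
#' one new hypothetical ground-truth label; each missed true spike receives
#' a uniformly random predicted label among the existing clusters (repeated
#' `reps` times, seeded, and averaged). `SSI = I(C, C') / max(H(C), H(C'))`;
#' 1 for perfect sorting, near 0 for unrelated labelings.
#'
#' @param truth_times,truth_labels ground-truth spike times (s) and unit ids.
#' @param pred_times,pred_labels detected spike times (s) and cluster labels.
#' @param tol_s matching tolerance (default 1 ms).
#' @param reps number of random miss-assignment repetitions (default 20).
#' @param seed integer seed for the miss randomization.
#' @return scalar SSI in `[0, 1]`.
#' @export
ssi <- function(truth_times, truth_labels, pred_times, pred_labels,
                tol_s = 1e-3, reps = 20, seed = NULL) {
  stopifnot(length(truth_times) == length(truth_labels),
            length(pred_times) == length(pred_labels))
  m <- match_spike_times(pred_times, truth_times, tol_s)
  truth_labels <- as.integer(factor(truth_labels))
  pred_labels <- as.integer(factor(pred_labels))
  clusters <- sort(unique(pred_labels))
  fa <- setdiff(seq_along(pred_times), m$pairs$det)
  miss <- setdiff(seq_along(truth_times), m$pairs$tru)
  hypothetical <- max(truth_labels, 0L) + 1L
  C_base <- c(truth_labels[m$pairs$tru], rep(hypothetical, length(fa)),
              truth_labels[miss])
  Cp_fixed <- c(pred_labels[m$pairs$det], pred_labels[fa])
  one_rep <- function() {
    Cp <- c(Cp_fixed, sample(clusters, length(miss), replace = TRUE))
    if (length(unique(C_base)) < 2L || length(unique(Cp)) < 2L) {
      return(as.numeric(identical(as.integer(factor(C_base)),
                                  as.integer(factor(Cp)))))
    }
    I <- mutual_information(C_base, Cp)
    I / max(mutual_information(C_base, C_base), mutual_information(Cp, Cp))
  }
  if (length(miss) == 0L || length(clusters) == 1L) reps <- 1L
  vals <- with_seed(seed, replicate(reps, one_rep()))
  mean(vals)
}

#' Bayes-optimal reference classification accuracy
#'
#' Builds the Bayes classifier for the simulator's generative model (known
#' templates, firing priors, iid Gaussian noise of known std) and scores it
#' on raw-signal windows around true spike times:
#' `argmax_k [log prior_k - ||w - template_k||^2 / (2 sigma^2)]`. Returns the
#' reference accuracy together with the accuracy of the method's labels on
#' the same spikes, giving an upper-bound yardstick for any waveform
#' classifier on that session.
#'
#' @param session a `synthetic_session` (from [generate_session()]).
#' @param spike_idx indices into the session's ground-truth spike table for
#'   the spikes being scored (default: all).
#' @param method_labels optional predicted cluster labels for those spikes;
#'   scored with the dominant-unit rule of [clustering_metrics()].
#' @return list with `ca_bayes`, `ca_method` (NA when no labels given),
#'   and the per-spike `bayes_labels`.
#' @export
bayes_reference_accuracy <- function(session, spike_idx = NULL,
                                     method_labels = NULL) {
  if (is.null(session$templates) || is.null(session$sigma_noise))
    stop("session lacks generative metadata (templates, noise std)")
  truth <- session$truth
  if (is.null(spike_idx)) spike_idx <- seq_len(nrow(truth))
  fs <- session$signal$fs
  x <- session$signal$samples
  tw <- session$template_windows  # n_neurons x T clean windows, trough-centered
  pre <- session$template_pre
  Tlen <- ncol(tw)
  prior <- session$priors
  sig2 <- session$sigma_noise^2
  offs <- seq(-pre, Tlen - pre - 1L)
  n <- length(spike_idx)
  bayes_labels <- integer(n)
  for (i in seq_len(n)) {
    k <- round(truth$time_s[spike_idx[i]] * fs) + 1L
    idx <- k + offs
    idx <- pmin(pmax(idx, 1L), length(x))
    w <- x[idx]
    d2 <- colSums((t(tw) - w)^2)
    score <- log(prior) - d2 / (2 * sig2)
    bayes_labels[i] <- which.max(score)
  }
  true_units <- truth$neuron[spike_idx]
  ca_bayes <- mean(bayes_labels == true_units)
  ca_method <- NA_real_
  if (!is.null(method_labels))
    ca_method <- clustering_metrics(method_labels, true_units)[["accuracy"]]
  list(ca_bayes = ca_bayes, ca_method = ca_method,
       bayes_labels = bayes_labels)
}

#' Least-squares CA-CA robustness fit
#'
#' Ordinary least squares of the method's classification accuracy on the
#' Bayes reference accuracy across sessions. A slope near 1 with high R^2
#' means the method degrades no faster than the information in the signal.
#'
#' @param ca_method,ca_bayes numeric vectors (one value per session).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
ca_ca_fit <- function(ca_method, ca_bayes) {
  if (length(ca_method) < 3L) stop("need at least 3 points")
  if (stats::var(ca_bayes) == 0) stop("zero variance in the reference accuracy")
  fit <- stats::lm(ca_method ~ ca_bayes)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}
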