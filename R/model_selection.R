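# Automatic choice of the number of clusters: FCM-seeded fit at g_max,
# backward pruning of the smallest component, per-g selection score, and
# posterior label assignment.

#' Initialize mixture parameters from fuzzy c-means
#'
#' Runs FCM (fuzzifier `m`) and converts its centers and fuzzy partition
#' matrix `U` into mixture parameters: `mu_j` are the centers,
#' `Sigma_j = sum_i U_ij (x_i - mu_j)(x_i - mu_j)' / sum_i U_ij`,
#' `lambda_j = sign(sum_i U_ij (x_i - mu_j)^3)` element-wise (the third-power
#' sign picks the initial skew direction), `pi_j = sum_i U_ij / n`, and `v`
#' is `v_init`. A failed FCM run is retried once with a different seed.
#'
#' @param X data matrix (n x p).
#' @param g number of clusters (`g = 1` degenerates to moment estimates).
#' @param seed integer seed for the FCM start (optional).
#' @param v_init initial degrees of freedom (default 10).
#' @param fuzzifier FCM fuzzifier (default 2).
#' @param tol FCM convergence tolerance (default 1e-5).
#' @param max_iter FCM iteration cap (default 300).
#' @return a parameter list (`pi`, `mu`, `Sigma`, `lam`, `v`) with the FCM
#'   partition attached as attribute `U`.
#' @export
init_from_fcm <- function(X, g, seed = NULL, v_init = 10, fuzzifier = 2,
                          tol = 1e-5, max_iter = 300) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= g) abort_config("need more observations than clusters")
  if (g == 1L) {
    U <- matrix(1, n, 1L)
    centers <- matrix(colMeans(X), 1L, p)
  } else {
    run_fcm <- function(s) {
      with_seed(s, e1071::cmeans(X, centers = g, m = fuzzifier,
                                 iter.max = max_iter, method = "cmeans",
                                 control = list(reltol = tol)))
    }
    fit <- tryCatch(run_fcm(seed), error = function(e) NULL)
    if (is.null(fit) || nrow(fit$centers) < g)
      fit <- tryCatch(run_fcm(if (is.null(seed)) NULL else seed + 1L),
                      error = function(e)
                        abort_numeric("fuzzy c-means failed twice"))
    U <- fit$membership
    centers <- fit$centers
  }
  Sigma <- vector("list", g)
  lam <- matrix(0, g, p)
  for (j in seq_len(g)) {
    Dif <- sweep(X, 2L, centers[j, ])
    w <- U[, j]
    Sigma[[j]] <- crossprod(Dif, w * Dif) / sum(w)
    lam[j, ] <- sign(colSums(w * Dif^3))
  }
  out <- list(pi = colSums(U) / n, mu = centers, Sigma = Sigma, lam = lam,
              v = v_init)
  attr(out, "U") <- U
  out
}

#' Remove the component with the smallest mixing probability
#'
#' Drops `argmin_j pi_j` (ties: the smallest index), renormalizes the
#' remaining mixing probabilities, and carries `v` forward — the warm start
#' used by the backward search.
#'
#' @param model a fitted `skewt_mixture` or a parameter list.
#' @return a parameter list with `g - 1` components.
#' @export
prune_component <- function(model) {
  pars <- as_par_list(model)
  g <- length(pars$pi)
  if (g < 2L) abort_config("cannot prune a single-component model")
  m <- which.min(pars$pi)
  keep <- setdiff(seq_len(g), m)
  list(pi = pars$pi[keep] / sum(pars$pi[keep]),
       mu = pars$mu[keep, , drop = FALSE],
       Sigma = pars$Sigma[keep],
       lam = pars$lam[keep, , drop = FALSE],
       v = pars$v)
}

#' Backward-search configuration
#'
#' @param g_min,g_max search interval for the number of components
#'   (defaults 1 and 9).
#' @param early_stop stop descending once the selection score drops below the
#'   best seen (default `FALSE`; the full sweep is cheap and unambiguous).
#' @param criterion `"bic"` (default): `L_g = loglik - 0.5 * k * log(n)`;
#'   `"loglik"`: the raw converged observed log-likelihood.
#' @param max_fit_n cap on the number of observations used for fitting
#'   (default 6000); larger sets are subsampled (seeded) for the EM and all
#'   observations are labeled from the selected model afterwards. The
#'   penalized order score needs a few thousand spikes to resolve close
#'   units, so lowering this trades cluster-count reliability for speed.
#' @return a `search_config` list.
#' @export
search_config <- function(g_min = 1, g_max = 9, early_stop = FALSE,
                          criterion = c("bic", "loglik"), max_fit_n = 6000) {
  criterion <- match.arg(criterion)
  if (g_min < 1 || g_min > g_max) abort_config("need 1 <= g_min <= g_max")
  structure(list(g_min = g_min, g_max = g_max, early_stop = early_stop,
                 criterion = criterion, max_fit_n = max_fit_n),
            class = "search_config")
}

n_free_parameters <- function(g, p, fix_lambda) {
  (g - 1) + g * p + g * p * (p + 1) / 2 + (if (fix_lambda) 0 else g * p) + 1
}

#' Backward model-order search over skew-t mixtures
#'
#' Fits the mixture at `g_max` from an FCM initialization, then repeatedly
#' prunes the smallest-weight component and refits down to `g_min`, recording
#' a selection score `L_g` per examined order. The selected model maximizes
#' `L_g` (ties resolve to the smaller order), and every observation receives
#' the posterior-argmax label of the selected model.
#'
#' @param X data matrix (n x p).
#' @param cfg a [search_config].
#' @param em an [em_config].
#' @param seed seed for the FCM start and the fitting subsample.
#' @param fix_lambda clamp skewness at zero (t-mixture baseline).
#' @return a `search_result`: `models` (per examined g), `table`
#'   (g, g_eff, loglik, k, L_g, converged), `g_opt`, `best`, `labels`,
#'   `posterior`.
#' @export
backward_search <- function(X, cfg = search_config(), em = em_config(),
                            seed = NULL, fix_lambda = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  g_max <- cfg$g_max
  while (g_max > cfg$g_min && n <= g_max * (p + 1)) g_max <- g_max - 1L
  if (g_max < cfg$g_max)
    message(sprintf("g_max lowered to %d for n = %d, p = %d", g_max, n, p))

  fit_idx <- seq_len(n)
  if (n > cfg$max_fit_n) {
    fit_idx <- with_seed(seed, sample.int(n, cfg$max_fit_n))
  }
  Xf <- X[fit_idx, , drop = FALSE]
  nf <- nrow(Xf)

  gs <- seq.int(g_max, cfg$g_min)
  models <- list()
  rows <- list()
  init <- init_from_fcm(Xf, g_max, seed = seed, v_init = em$v_init)
  prev <- NULL
  for (g in gs) {
    if (!is.null(prev)) init <- prune_component(prev)
    fit <- tryCatch(fit_skewt_mixture(Xf, g, init = init, cfg = em,
                                      fix_lambda = fix_lambda),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(g = g, g_eff = NA_integer_, loglik = NA_real_,
                   k = NA_real_, L_g = NA_real_, converged = NA,
                   error = conditionMessage(fit))
      next
    }
    prev <- fit
    k <- n_free_parameters(fit$g, p, fix_lambda)
    L_g <- if (cfg$criterion == "bic") fit$loglik - 0.5 * k * log(nf)
           else fit$loglik
    models[[as.character(g)]] <- fit
    rows[[length(rows) + 1L]] <-
      data.frame(g = g, g_eff = fit$g, loglik = fit$loglik, k = k,
                 L_g = L_g, converged = fit$converged, error = NA_character_)
    if (cfg$early_stop && length(rows) >= 2L) {
      Ls <- vapply(rows, function(r) r$L_g, numeric(1))
      if (!is.na(Ls[length(Ls)]) && Ls[length(Ls)] < max(Ls, na.rm = TRUE))
        break
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$L_g))) {
    stop(paste(c("all mixture fits failed:",
                 stats::na.omit(tab$error)), collapse = "\n  "))
  }
  # argmax of L_g; ties resolve to the smaller effective order
  cand <- which(tab$L_g >= max(tab$L_g, na.rm = TRUE) - 1e-9)
  best_row <- cand[which.min(tab$g_eff[cand])]
  best <- models[[as.character(tab$g[best_row])]]
  post <- posterior_responsibilities(best, X)
  labels <- max.col(post, ties.method = "first")
  structure(list(models = models, table = tab, g_opt = best$g, best = best,
                 labels = labels, posterior = post, fit_idx = fit_idx),
            class = "search_result")
}

posterior_responsibilities <- function(model, X) {
  pars <- as_par_list(model)
  md <- mixture_logdens(as.matrix(X), pars)
  lw <- sweep(md$logf, 2L, log(pars$pi), `+`)
  exp(lw - row_logsumexp(lw))
}

#' Posterior-argmax cluster labels
#'
#' `c_i = argmax_j p_ij` with ties broken toward the smaller component index.
#'
#' @param model a `skewt_mixture` (or parameter list).
#' @param X data matrix compatible with the model dimension.
#' @return integer labels in `1..g`.
#' @export
assign_labels <- function(model, X) {
  max.col(posterior_responsibilities(model, X), ties.method = "first")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> g_opt = %d over g in [%d, %d]\n",
              x$g_opt, min(x$table$g), max(x$table$g)))
  print(x$table[, c("g", "g_eff", "loglik", "L_g", "converged")],
        row.names = FALSE)
  invisible(x)
}
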