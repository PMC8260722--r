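# Multivariate skew-t density, sampling, and EM fitting of a g-component
# mixture with shared degrees of freedom.
#
# The skew-t used here is the Gamma-scaled skew-normal: Y = mu + U^{-1/2} Z
# with U ~ Gamma(v/2, v/2) independent of Z ~ SN(0, Sigma, lambda). Its
# density is
#   ST_p(y) = 2 t_p(y | mu, Sigma, v) *
#             T( sqrt((v+p)/(v+d)) * lambda' Sigma^{-1/2} (y-mu) | v+p )
# with d the Mahalanobis form and T the standard univariate t CDF. The EM
# uses the convenient reparameterization Delta = Sigma^{1/2} delta,
# delta = lambda / sqrt(1 + lambda'lambda), Gamma = Sigma - Delta Delta',
# under which Y | t, u ~ N(mu + Delta t, Gamma / u) with t | u a positive
# half-normal of variance 1/u.

#' Skew-t mixture component
#'
#' @param mu location vector (length p).
#' @param Sigma p x p symmetric positive-definite dispersion matrix.
#' @param lam skewness vector (length p); `0` recovers the symmetric t.
#' @param pi_j mixing probability.
#' @return a `skewt_component` list.
#' @export
skewt_component <- function(mu, Sigma, lam = rep(0, length(mu)), pi_j = 1) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != length(mu) || ncol(Sigma) != length(mu))
    abort_config("Sigma dimensions must match mu")
  structure(list(mu = as.numeric(mu), Sigma = Sigma, lam = as.numeric(lam),
                 pi_j = pi_j), class = "skewt_component")
}

# v-independent per-component geometry: centered data, Mahalanobis form and
# skew projection; reused by the density, the E-step and the v line search
skewt_geom <- function(X, mu, dec, lam) {
  Dif <- sweep(X, 2L, mu)
  d <- rowSums((Dif %*% dec$inv) * Dif)
  A <- as.numeric(Dif %*% (dec$inv_sqrt %*% lam))
  list(dec = dec, Dif = Dif, d = d, A = A)
}

# log density given cached geometry
skewt_logf_geom <- function(geom, v, p) {
  logt <- lgamma((v + p) / 2) - lgamma(v / 2) - (p / 2) * log(v * pi) -
    0.5 * geom$dec$logdet - ((v + p) / 2) * log1p(geom$d / v)
  logcdf <- stats::pt(sqrt((v + p) / (v + geom$d)) * geom$A, df = v + p,
                      log.p = TRUE)
  list(logf = log(2) + logt + logcdf, logcdf = logcdf)
}

# per-component log density plus the quantities the E-step reuses
skewt_parts <- function(X, mu, dec, lam, v) {
  g <- skewt_geom(X, mu, dec, lam)
  lf <- skewt_logf_geom(g, v, ncol(X))
  list(logf = lf$logf, d = g$d, A = g$A, logcdf = lf$logcdf)
}

#' Multivariate skew-t log-density
#'
#' @param y observation vector, or matrix with observations in rows.
#' @param comp a [skewt_component] (its `pi_j` is ignored).
#' @param v degrees of freedom (> 0).
#' @param log return the log-density (default `TRUE`).
#' @return numeric vector of (log-)densities, finite for all finite `y`.
#' @export
skewt_logpdf <- function(y, comp, v, log = TRUE) {
  if (v <= 0) abort_config("v must be positive")
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  dec <- sigma_decomp(comp$Sigma)
  out <- skewt_parts(Y, comp$mu, dec, comp$lam, v)$logf
  if (log) out else exp(out)
}

#' Sample from a multivariate skew-t distribution
#'
#' Draws via the hierarchical representation: `U ~ Gamma(v/2, v/2)`,
#' `Z = Delta |N(0,1)| + Gamma^{1/2} N(0, I)` (a skew-normal), and
#' `Y = mu + Z / sqrt(U)`. Reproducible under `seed`; the draw order is
#' fixed (U, then the half-normal, then the Gaussian block).
#'
#' @param comp a [skewt_component].
#' @param v degrees of freedom.
#' @param n number of draws.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return an `n x p` matrix.
#' @export
sample_skewt <- function(comp, v, n, seed = NULL) {
  p <- length(comp$mu)
  dec <- sigma_decomp(comp$Sigma)
  delta <- comp$lam / sqrt(1 + sum(comp$lam^2))
  Delta <- as.numeric(dec$sqrt %*% delta)
  Gam <- dec$Sigma - tcrossprod(Delta)
  Gs <- sigma_decomp(Gam + diag(1e-12 * mean(diag(dec$Sigma)), p))$sqrt
  with_seed(seed, {
    U <- stats::rgamma(n, shape = v / 2, rate = v / 2)
    T0 <- abs(stats::rnorm(n))
    E <- matrix(stats::rnorm(n * p), n, p) %*% Gs
    Z <- tcrossprod(T0, Delta) + E
    sweep(Z / sqrt(U), 2L, comp$mu, `+`)
  })
}

#' EM configuration for the skew-t mixture
#'
#' @param l_em stop threshold on the maximum absolute parameter change
#'   (default 1e-3; parameters live on the PCA feature scale).
#' @param max_iter iteration cap (default 500).
#' @param v_bounds search interval for the shared degrees of freedom
#'   (default `c(2.1, 100)`, keeping the finite-covariance regime).
#' @param reg_eps ridge factor for near-singular dispersion matrices, scaled
#'   by `trace(Sigma)/p` (default 1e-6).
#' @param v_init initial degrees of freedom (default 10).
#' @param v_update update the degrees of freedom at all (default `TRUE`;
#'   `FALSE` keeps `v` at `v_init`, e.g. for controlled comparisons).
#' @param v_every update `v` every this many iterations (default 5; the
#'   one-dimensional likelihood line search is the costly step and `v` moves
#'   slowly, so staggering it loses nothing while keeping ascent exact).
#' @param relative use relative instead of absolute parameter change in the
#'   stop rule (default `FALSE`).
#' @param seed optional seed (reserved for stochastic restarts; the EM itself
#'   is deterministic given its initialization).
#' @return an `em_config` list.
#' @export
em_config <- function(l_em = 1e-3, max_iter = 500, v_bounds = c(2.1, 100),
                      reg_eps = 1e-6, v_init = 10, v_update = TRUE,
                      v_every = 5, relative = FALSE, seed = NULL) {
  if (l_em <= 0) abort_config("l_em must be positive")
  if (max_iter < 1) abort_config("max_iter must be >= 1")
  structure(list(l_em = l_em, max_iter = max_iter, v_bounds = v_bounds,
                 reg_eps = reg_eps, v_init = v_init, v_update = v_update,
                 v_every = v_every, relative = relative, seed = seed),
            class = "em_config")
}

# flatten parameters for the stop rule (max change over all parameters)
flatten_pars <- function(pars) {
  c(pars$pi, as.numeric(pars$mu), unlist(pars$Sigma), as.numeric(pars$lam),
    pars$v)
}

mixture_logdens <- function(X, pars, reg_eps = 1e-6) {
  g <- length(pars$pi)
  n <- nrow(X)
  logf <- matrix(0, n, g)
  parts <- vector("list", g)
  for (j in seq_len(g)) {
    dec <- sigma_decomp(pars$Sigma[[j]], reg_eps)
    parts[[j]] <- skewt_parts(X, pars$mu[j, ], dec, pars$lam[j, ], pars$v)
    parts[[j]]$dec <- dec
    logf[, j] <- parts[[j]]$logf
  }
  list(logf = logf, parts = parts)
}

#' Observed-data log-likelihood of a skew-t mixture
#'
#' `sum_i log sum_j pi_j ST_p(x_i | theta_j)`, evaluated stably through
#' log-sum-exp.
#'
#' @param X data matrix (n x p).
#' @param model a fitted `skewt_mixture` or a parameter list with fields
#'   `pi`, `mu` (g x p), `Sigma` (list), `lam` (g x p), `v`.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(X, model) {
  X <- as.matrix(X)
  pars <- as_par_list(model)
  md <- mixture_logdens(X, pars)
  sum(row_logsumexp(sweep(md$logf, 2L, log(pars$pi), `+`)))
}

as_par_list <- function(model) {
  if (!is.null(model$components)) {
    g <- length(model$components)
    p <- length(model$components[[1L]]$mu)
    list(pi = vapply(model$components, `[[`, numeric(1), "pi_j"),
         mu = do.call(rbind, lapply(model$components, `[[`, "mu")),
         Sigma = lapply(model$components, `[[`, "Sigma"),
         lam = do.call(rbind, lapply(model$components, `[[`, "lam")),
         v = model$v)
  } else model
}

#' Fit a skew-t mixture by EM
#'
#' Expectation-conditional-maximization for the finite mixture of
#' multivariate skew-t distributions with a single shared degrees-of-freedom
#' parameter. The E-step computes component responsibilities together with
#' the conditional expectations of the latent Gamma scale and the truncated
#' skewing variable; the CM-steps update `pi`, `mu`, the skewness loading
#' `Delta` and the residual dispersion in closed form, then recover
#' `(Sigma, lambda)`; `v` is updated by a bounded one-dimensional
#' maximization of the observed log-likelihood. Every step increases the
#' observed log-likelihood, so the trace is monotone up to round-off.
#'
#' Components whose mixing probability falls below `1/n` or whose dispersion
#' collapses are removed and the fit continues with `g - 1` (recorded in
#' `events`).
#'
#' @param X data matrix (n x p).
#' @param g number of components.
#' @param init parameter list (`pi`, `mu` g x p, `Sigma` list, `lam` g x p,
#'   `v`), e.g. from [init_from_fcm()]; `NULL` runs FCM initialization.
#' @param cfg an [em_config].
#' @param fix_lambda clamp all skewness vectors to zero, yielding the
#'   symmetric t-mixture baseline (default `FALSE`).
#' @return a `skewt_mixture`: `g`, `v`, `pi`, `mu`, `Sigma`, `lam`,
#'   `loglik`, `loglik_trace`, `converged`, `n_iter`, `responsibilities`,
#'   `events`.
#' @export
fit_skewt_mixture <- function(X, g, init = NULL, cfg = em_config(),
                              fix_lambda = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= g * (p + 1))
    abort_config("too few observations for the requested number of components")
  if (is.null(init)) init <- init_from_fcm(X, g, seed = cfg$seed,
                                           v_init = cfg$v_init)
  pars <- init
  if (fix_lambda) pars$lam <- matrix(0, length(pars$pi), p)
  pars$mu <- matrix(pars$mu, ncol = p)
  pars$lam <- matrix(pars$lam, ncol = p)
  events <- character(0)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  cube_to_list <- function(S, g) {
    lapply(seq_len(g), function(j) as.matrix(S[, , j]))
  }
  geom <- cpp_geom(X, pars$mu, pars$Sigma, pars$lam, cfg$reg_eps)
  v_freeze <- FALSE
  v_small <- 0L

  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    g_cur <- length(pars$pi)
    pass <- cpp_em_pass(X, pars$pi, pars$mu, pars$lam, pars$v, geom,
                        fix_lambda)
    trace <- c(trace, pass$loglik)
    n_j <- as.numeric(pass$n_j)

    # collapse guard
    bad <- which(n_j < max(1, p + 1) | pars$pi < 1 / n)
    if (length(bad) > 0L && g_cur > 1L) {
      keep <- setdiff(seq_len(g_cur), bad[1L])
      events <- c(events,
                  sprintf("iteration %d: removed component %d (collapsed)",
                          iter, bad[1L]))
      pars <- list(pi = pars$pi[keep] / sum(pars$pi[keep]),
                   mu = pars$mu[keep, , drop = FALSE],
                   Sigma = pars$Sigma[keep],
                   lam = pars$lam[keep, , drop = FALSE], v = pars$v)
      geom <- cpp_geom(X, pars$mu, pars$Sigma, pars$lam, cfg$reg_eps)
      next
    }

    old_flat <- flatten_pars(pars)
    new <- list(pi = as.numeric(pass$pi), mu = pass$mu,
                Sigma = cube_to_list(pass$Sigma, g_cur), lam = pass$lam,
                v = pars$v)
    geom <- cpp_geom(X, new$mu, new$Sigma, new$lam, cfg$reg_eps)

    # CML-step for the shared degrees of freedom. The line search is the
    # expensive part (every evaluation is a full density pass), so after a
    # one-off global bracketing the update is a guarded parabolic step, and
    # v freezes once two consecutive updates move less than l_em.
    if (isTRUE(cfg$v_update) && !v_freeze &&
        (iter %% cfg$v_every == 0L || iter == 1L)) {
      obj <- function(vv) cpp_profile_ll(geom$d, geom$A, geom$logdet,
                                         log(new$pi), vv, p)
      lb <- cfg$v_bounds[1L]
      ub <- cfg$v_bounds[2L]
      v_old <- new$v
      if (iter == 1L) {
        opt <- stats::optimize(obj, interval = cfg$v_bounds, maximum = TRUE,
                               tol = 0.05)
        if (opt$objective >= obj(new$v)) new$v <- opt$maximum
      } else {
        h <- max(10 * cfg$l_em, 0.02)
        vm <- max(lb, new$v - h)
        vp <- min(ub, new$v + h)
        f0 <- obj(new$v)
        fm <- obj(vm)
        fp <- obj(vp)
        denom <- fm - 2 * f0 + fp
        cand <- if (denom < 0) {
          new$v + 0.5 * h * (fm - fp) / denom
        } else if (fp > fm) vp + h else vm - h
        cand <- min(max(cand, max(lb, new$v - 1)), min(ub, new$v + 1))
        fc <- obj(cand)
        vals <- c(f0, fm, fp, fc)
        new$v <- c(new$v, vm, vp, cand)[which.max(vals)]
      }
      if (abs(new$v - v_old) < cfg$l_em) {
        v_small <- v_small + 1L
        if (v_small >= 2L) v_freeze <- TRUE
      } else v_small <- 0L
    }

    delta_par <- abs(flatten_pars(new) - old_flat)
    if (cfg$relative) delta_par <- delta_par / pmax(abs(old_flat), 1)
    pars <- new
    if (max(delta_par) < cfg$l_em) {
      converged <- TRUE
      break
    }
  }

  md <- mixture_logdens(X, pars, cfg$reg_eps)
  lw <- sweep(md$logf, 2L, log(pars$pi), `+`)
  lse <- row_logsumexp(lw)
  trace <- c(trace, sum(lse))
  structure(list(g = length(pars$pi), v = pars$v, pi = pars$pi, mu = pars$mu,
                 Sigma = pars$Sigma, lam = pars$lam,
                 loglik = sum(lse), loglik_trace = trace,
                 converged = converged, n_iter = iter,
                 responsibilities = exp(lw - lse), events = events),
            class = "skewt_mixture")
}

#' @export
print.skewt_mixture <- function(x, ...) {
  cat(sprintf("<skewt_mixture> g = %d, v = %.2f, loglik = %.2f (%s in %d iter)\n",
              x$g, x$v, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Serialize a fitted mixture to JSON
#'
#' @param model a `skewt_mixture`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixture_json <- function(model, path) {
  comps <- lapply(seq_len(model$g), function(j) {
    list(pi = model$pi[j], mu = model$mu[j, ],
         Sigma = model$Sigma[[j]], lam = model$lam[j, ])
  })
  jsonlite::write_json(list(g = model$g, v = model$v, components = comps,
                            loglik = model$loglik, n_iter = model$n_iter,
                            converged = model$converged),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
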