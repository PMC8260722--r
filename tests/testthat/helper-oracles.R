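# Independent oracles used across the test files. These deliberately use
# naive, direct implementations so they stay independent of the package's
# optimized code paths.

# exhaustive O(n * w) scan implementing the detection rule literally:
# an event starts at the first sample of a run of m_d + 1 strictly
# sub-threshold samples; the event index is the first local minimum after it
# (no smaller value within `win` samples)
naive_detect <- function(x, thr, m_d, win) {
  n <- length(x)
  starts <- integer(0)
  i <- 1L
  while (i <= n) {
    if (x[i] < -thr) {
      j <- i
      while (j < n && x[j + 1L] < -thr) j <- j + 1L
      if (j - i >= m_d) starts <- c(starts, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx <- integer(0)
  for (s in starts) {
    k <- s
    repeat {
      hi <- min(k + win, n)
      if (hi <= k) break
      cand <- (k + 1L):hi
      j <- cand[which.min(x[cand])]
      if (x[j] < x[k]) k <- j else break
    }
    idx <- c(idx, k)
  }
  sort(unique(idx))
}

# hand-coded p-variate student-t log-density (for the lambda = 0 reduction)
naive_mvt_logpdf <- function(y, mu, Sigma, v) {
  p <- length(mu)
  d <- mahalanobis(matrix(y, ncol = p), mu, Sigma)
  lgamma((v + p) / 2) - lgamma(v / 2) - (p / 2) * log(v * pi) -
    0.5 * determinant(as.matrix(Sigma))$modulus[1] -
    ((v + p) / 2) * log1p(d / v)
}

# direct evaluation of the skew-normal density (normal pdf times scaled
# normal cdf), for the large-v limit of the skew-t
naive_skewnormal_pdf <- function(y, mu, Sigma, lam) {
  p <- length(mu)
  Sigma <- as.matrix(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  inv_sqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dif <- y - mu
  quad <- sum(dif * solve(Sigma, dif))
  dens <- exp(-quad / 2) / sqrt((2 * pi)^p * prod(e$values))
  2 * dens * pnorm(sum(lam * (inv_sqrt %*% dif)))
}

# minimal from-scratch EM for a mixture of multivariate t distributions with
# shared v (fixed); the standard scale-mixture weights, no skewness
naive_t_mixture_em <- function(X, g, mu0, v, iters = 200) {
  n <- nrow(X)
  p <- ncol(X)
  mu <- mu0
  Sigma <- replicate(g, cov(X) + diag(1e-6, p), simplify = FALSE)
  pi_j <- rep(1 / g, g)
  for (it in seq_len(iters)) {
    logf <- sapply(seq_len(g), function(j)
      naive_mvt_logpdf(X, mu[j, ], Sigma[[j]], v))
    lw <- sweep(logf, 2, log(pi_j), `+`)
    mx <- apply(lw, 1, max)
    z <- exp(lw - mx)
    z <- z / rowSums(z)
    for (j in seq_len(g)) {
      d <- mahalanobis(X, mu[j, ], Sigma[[j]])
      u <- (v + p) / (v + d)
      w <- z[, j] * u
      mu[j, ] <- colSums(w * X) / sum(w)
      Dif <- sweep(X, 2, mu[j, ])
      Sigma[[j]] <- crossprod(Dif, w * Dif) / sum(z[, j]) + diag(1e-9, p)
    }
    pi_j <- colMeans(z)
  }
  logf <- sapply(seq_len(g), function(j)
    naive_mvt_logpdf(X, mu[j, ], Sigma[[j]], v))
  lw <- sweep(logf, 2, log(pi_j), `+`)
  mx <- apply(lw, 1, max)
  list(mu = mu, Sigma = Sigma, pi = pi_j,
       loglik = sum(mx + log(rowSums(exp(lw - mx)))))
}

# contingency-table mutual information in nats, direct formula
naive_mutual_information <- function(a, b) {
  tab <- table(a, b) / length(a)
  out <- 0
  pa <- rowSums(tab)
  pb <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0)
      out <- out + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  out
}

# tiny deterministic session for fast pipeline tests
small_session <- function(duration_s = 10, snr_db = 13, seed = 7) {
  generate_session(session_config(duration_s = duration_s, snr_db = snr_db,
                                  seed = seed))
}

expect_config_error <- function(expr) {
  testthat::expect_error(expr, class = "skewsort_config_error")
}
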