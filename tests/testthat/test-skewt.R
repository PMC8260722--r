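# Skew-t density, sampler, and mixture EM.

test_that("zero skewness reduces the density to the multivariate t", {
  set.seed(1)
  for (p in c(1, 3)) {
    mu <- rnorm(p)
    A <- matrix(rnorm(p * p), p)
    Sigma <- crossprod(A) + diag(p)
    comp <- skewt_component(mu, Sigma, rep(0, p))
    Y <- matrix(rnorm(20 * p, sd = 2), 20, p)
    expect_equal(skewt_logpdf(Y, comp, v = 7),
                 naive_mvt_logpdf(Y, mu, Sigma, 7), tolerance = 1e-10)
  }
})

test_that("the univariate skew-t density integrates to one", {
  comp <- skewt_component(0, matrix(1), 2)
  f <- function(y) skewt_logpdf(matrix(y, ncol = 1), comp, v = 5, log = FALSE)
  q <- integrate(f, -40, 40, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("large degrees of freedom approach the skew-normal density", {
  set.seed(2)
  p <- 2
  mu <- c(1, -1)
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  lam <- c(1.5, -0.5)
  comp <- skewt_component(mu, Sigma, lam)
  Y <- matrix(rnorm(200, sd = 1.5), 100, 2) + rep(mu, each = 100)
  st <- skewt_logpdf(Y, comp, v = 1e6, log = FALSE)
  sn <- apply(Y, 1, naive_skewnormal_pdf, mu = mu, Sigma = Sigma, lam = lam)
  expect_equal(st, sn, tolerance = 1e-4)
})

test_that("sampler matches its density and is seed-reproducible", {
  comp1 <- skewt_component(c(2, -1), diag(2), c(0, 0))
  expect_identical(sample_skewt(comp1, 8, 50, seed = 42),
                   sample_skewt(comp1, 8, 50, seed = 42))
  # Gaussian limit: mean near mu
  X <- sample_skewt(comp1, 1e6, 4000, seed = 7)
  expect_lt(max(abs(colMeans(X) - c(2, -1))), 4 / sqrt(4000))
  # p = 1: histogram vs density, total-variation on 50 bins < 0.02
  comp2 <- skewt_component(0, matrix(1), 2)
  y <- sample_skewt(comp2, 5, 1e5, seed = 9)
  br <- seq(-8, 12, length.out = 51)
  h <- hist(pmin(pmax(y, -7.9), 11.9), breaks = br, plot = FALSE)
  dens <- sapply(h$mids, function(m)
    skewt_logpdf(matrix(m), comp2, 5, log = FALSE))
  p_emp <- h$counts / sum(h$counts)
  p_th <- dens * diff(br)
  p_th <- p_th / sum(p_th)
  expect_lt(0.5 * sum(abs(p_emp - p_th)), 0.02)
})

test_that("observed log-likelihood matches naive summation", {
  set.seed(3)
  X <- matrix(rnorm(10), 5, 2)
  pars <- list(pi = c(0.3, 0.7),
               mu = rbind(c(0, 0), c(1, 1)),
               Sigma = list(diag(2), matrix(c(1, .3, .3, 1), 2)),
               lam = rbind(c(1, 0), c(0, -2)), v = 6)
  naive <- sum(log(
    pars$pi[1] * skewt_logpdf(X, skewt_component(pars$mu[1, ], pars$Sigma[[1]],
                                                 pars$lam[1, ]), 6,
                              log = FALSE) +
    pars$pi[2] * skewt_logpdf(X, skewt_component(pars$mu[2, ], pars$Sigma[[2]],
                                                 pars$lam[2, ]), 6,
                              log = FALSE)))
  expect_equal(observed_loglik(X, pars), naive, tolerance = 1e-10)
  # single component reduces to the sum of log densities
  p1 <- list(pi = 1, mu = rbind(c(0, 0)), Sigma = list(diag(2)),
             lam = rbind(c(1, 0)), v = 6)
  expect_equal(observed_loglik(X, p1),
               sum(skewt_logpdf(X, skewt_component(c(0, 0), diag(2),
                                                   c(1, 0)), 6)))
  # two identical components collapse to the same value
  p2 <- list(pi = c(0.5, 0.5), mu = rbind(c(0, 0), c(0, 0)),
             Sigma = list(diag(2), diag(2)),
             lam = rbind(c(1, 0), c(1, 0)), v = 6)
  expect_equal(observed_loglik(X, p2), observed_loglik(X, p1),
               tolerance = 1e-10)
})

test_that("single-component fit recovers Gaussian data", {
  set.seed(4)
  X <- matrix(rnorm(4000), 2000, 2)
  fit <- fit_skewt_mixture(X, 1, cfg = em_config(max_iter = 200))
  # the location and skewness trade off near lambda = 0 (flat information),
  # so the stable invariant is the model-implied mean:
  # E[Y] = mu + sqrt(v/pi) * gamma((v-1)/2)/gamma(v/2) * Delta
  delta <- fit$lam[1, ] / sqrt(1 + sum(fit$lam[1, ]^2))
  Delta <- as.numeric(skewsort:::sigma_decomp(fit$Sigma[[1]])$sqrt %*% delta)
  b_v <- sqrt(fit$v / pi) * exp(lgamma((fit$v - 1) / 2) - lgamma(fit$v / 2))
  model_mean <- fit$mu[1, ] + b_v * Delta
  expect_lt(max(abs(model_mean - colMeans(X))), 0.1)
  expect_lt(sqrt(sum(fit$lam^2)), 0.5)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("two-component skew-t parameters are recovered", {
  c1 <- skewt_component(c(0, 0), diag(2), c(3, 0))
  c2 <- skewt_component(c(6, 0), diag(2), c(0, 0))
  X <- rbind(sample_skewt(c1, 6, 2000, seed = 1),
             sample_skewt(c2, 6, 2000, seed = 2))
  fit <- fit_skewt_mixture(X, 2, cfg = em_config(seed = 3, max_iter = 300))
  ord <- order(fit$mu[, 1])
  expect_lt(max(abs(fit$mu[ord[1], ] - c(0, 0))), 0.15)
  expect_lt(max(abs(fit$mu[ord[2], ] - c(6, 0))), 0.15)
  expect_lt(max(abs(fit$pi - 0.5)), 0.05)
  expect_gt(fit$lam[ord[1], 1], 0)  # skew direction recovered
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # responsibilities are a proper partition
  expect_equal(rowSums(fit$responsibilities), rep(1, 4000),
               tolerance = 1e-10)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
})

test_that("fitting is equivariant under recentring", {
  set.seed(5)
  X <- rbind(matrix(rnorm(600), 300, 2),
             matrix(rnorm(600, 4), 300, 2))
  shift <- c(100, -50)
  init <- init_from_fcm(X, 2, seed = 1)
  init2 <- init
  init2$mu <- sweep(init2$mu, 2, -shift)
  f1 <- fit_skewt_mixture(X, 2, init = init, cfg = em_config(max_iter = 120))
  f2 <- fit_skewt_mixture(sweep(X, 2, -shift), 2, init = init2,
                          cfg = em_config(max_iter = 120))
  ord1 <- order(f1$mu[, 1])
  ord2 <- order(f2$mu[, 1])
  expect_equal(f1$mu[ord1, ] + rep(shift, each = 2), f2$mu[ord2, ],
               tolerance = 1e-4)
  expect_equal(f1$pi[ord1], f2$pi[ord2], tolerance = 1e-6)
  expect_equal(f1$lam[ord1, ], f2$lam[ord2, ], tolerance = 1e-3)
})

test_that("lambda clamped to zero reproduces a t-mixture fit", {
  set.seed(6)
  X <- rbind(matrix(rnorm(800, 0, 1), 400, 2),
             matrix(rnorm(800, 5, 1), 400, 2))
  mu0 <- rbind(c(-0.2, 0.1), c(5.2, -0.1))
  init <- list(pi = c(0.5, 0.5), mu = mu0,
               Sigma = list(diag(2), diag(2)),
               lam = matrix(0, 2, 2), v = 8)
  ours <- fit_skewt_mixture(X, 2, init = init,
                            cfg = em_config(max_iter = 300,
                                            v_update = FALSE, v_init = 8),
                            fix_lambda = TRUE)
  oracle <- naive_t_mixture_em(X, 2, mu0, v = 8, iters = 300)
  expect_equal(ours$loglik, oracle$loglik, tolerance = 1e-4)
  ord_a <- order(ours$mu[, 1])
  ord_b <- order(oracle$mu[, 1])
  expect_equal(ours$mu[ord_a, ], oracle$mu[ord_b, ], tolerance = 1e-3)
  expect_true(all(ours$lam == 0))
})

test_that("model JSON serialization round-trips the parameters", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  set.seed(7)
  X <- matrix(rnorm(600), 300, 2)
  fit <- fit_skewt_mixture(X, 1, cfg = em_config(max_iter = 50))
  write_mixture_json(fit, tmp)
  back <- jsonlite::fromJSON(tmp, simplifyMatrix = TRUE)
  expect_equal(back$g, fit$g)
  expect_equal(back$v, fit$v, tolerance = 1e-12)
  expect_equal(unlist(back$components$mu[1]), as.numeric(fit$mu[1, ]),
               tolerance = 1e-12)
})
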