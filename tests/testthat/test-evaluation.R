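# Matching, detection/clustering metrics, SSI, Bayes reference, CA-CA fit.

test_that("time matching is one-to-one within the tolerance", {
  # identical lists: perfect
  m <- match_spike_times(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))
  # one detection 0.4 ms from one true spike: matched
  m2 <- match_spike_times(0.1004, 0.1000)
  expect_equal(m2$tp, 1)
  # two detections near one true spike: one tp, one fp
  m3 <- match_spike_times(c(0.0998, 0.1003), 0.1)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))
  expect_equal(m3$pairs$det, 1L)  # the scan pairs the earliest admissible
  # beyond tolerance: nothing
  m4 <- match_spike_times(0.105, 0.1)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 1))
})

test_that("greedy matching agrees with exhaustive optimal matching", {
  # all instances with <= 4 detections / 4 truths on a coarse grid
  set.seed(1)
  for (rep in 1:25) {
    det <- sort(runif(sample(0:4, 1), 0, 6e-3))
    tru <- sort(runif(sample(1:4, 1), 0, 6e-3))
    m <- match_spike_times(det, tru, tol_s = 1e-3)
    # exhaustive max-cardinality matching
    best <- 0
    nd <- length(det)
    if (nd > 0) {
      assignments <- expand.grid(rep(list(0:length(tru)), nd))
      for (r in seq_len(nrow(assignments))) {
        asg <- as.numeric(assignments[r, ])
        used <- asg[asg > 0]
        if (anyDuplicated(used)) next
        okk <- all(abs(det[which(asg > 0)] - tru[used]) <= 1e-3)
        if (okk) best <- max(best, length(used))
      }
    }
    expect_equal(m$tp, best)
  }
})

test_that("precision and recall follow their definitions", {
  m <- structure(list(tp = 8, fp = 2, fn = 0), class = "detection_match")
  expect_equal(detection_metrics(m)[["precision"]], 0.8)
  m2 <- structure(list(tp = 8, fp = 0, fn = 2), class = "detection_match")
  expect_equal(detection_metrics(m2)[["recall"]], 0.8)
  m3 <- structure(list(tp = 5, fp = 0, fn = 0), class = "detection_match")
  expect_equal(unname(detection_metrics(m3)), c(1, 1))
  m4 <- structure(list(tp = 0, fp = 0, fn = 3), class = "detection_match")
  expect_warning(pr <- detection_metrics(m4), "precision")
  expect_true(is.nan(pr[["precision"]]))
})

test_that("accuracy and purity match hand-enumerated cases", {
  perfect <- clustering_metrics(rep(1:3, each = 5), rep(1:3, each = 5))
  expect_equal(unname(perfect), c(1, 1))
  # clusters {A:9,B:1} and {A:1,B:4}: both 13/15
  pred <- c(rep(1, 10), rep(2, 5))
  tru <- c(rep("A", 9), "B", "A", rep("B", 4))
  cm <- clustering_metrics(pred, tru)
  expect_equal(unname(cm), c(13 / 15, 13 / 15))
  # clusters {A:9,B:1} and {A:3,B:2}: purity 12/15, accuracy 11/15
  tru2 <- c(rep("A", 9), "B", rep("A", 3), rep("B", 2))
  cm2 <- clustering_metrics(pred, tru2)
  expect_equal(cm2[["accuracy"]], 11 / 15)
  expect_equal(cm2[["purity"]], 12 / 15)
  # both equal 1 iff the contingency table is a permutation matrix
  cm3 <- clustering_metrics(c(1, 1, 2, 2), c("x", "x", "x", "x"))
  expect_lt(cm3[["accuracy"]], 1)
})

test_that("SSI is 1 for perfect sorting and ~0 for shuffled labels", {
  set.seed(2)
  n <- 10000
  tt <- sort(runif(n, 0, 500))
  tt <- tt[c(diff(tt) > 2.5e-3, TRUE)]
  labs <- sample(1:4, length(tt), replace = TRUE)
  expect_equal(ssi(tt, labs, tt, labs), 1)
  shuffled <- sample(labs)
  expect_lt(ssi(tt, labs, tt, shuffled, seed = 1), 0.01)
  # SSI strictly decreases when false alarms are injected
  fa_times <- runif(500, 600, 700)
  s_clean <- ssi(tt, labs, tt, labs, seed = 1)
  s_fa <- ssi(tt, labs, c(tt, fa_times), c(labs, sample(1:4, 500, TRUE)),
              seed = 1)
  expect_lt(s_fa, s_clean)
})

test_that("SSI equals exhaustive enumeration on a small worked case", {
  # 12 true spikes in 3 units, 1 miss, 1 false alarm
  tru_t <- (1:12) / 10
  tru_l <- rep(1:3, each = 4)
  det_t <- c(tru_t[-5], 5.5)      # miss the 5th, add one false alarm
  det_l <- c(tru_l[-5], 2)        # otherwise perfect labels
  # oracle: average the direct NMI over every possible miss assignment
  vals <- sapply(1:3, function(miss_lab) {
    C <- c(tru_l[-5], 4, tru_l[5])          # fa -> hypothetical unit 4
    Cp <- c(tru_l[-5], 2, miss_lab)
    I <- naive_mutual_information(C, Cp)
    I / max(naive_mutual_information(C, C),
            naive_mutual_information(Cp, Cp))
  })
  oracle <- mean(vals)
  got <- ssi(tru_t, tru_l, det_t, det_l, reps = 4000, seed = 3)
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("Bayes reference is exact without noise and chance with equal templates", {
  ses <- small_session(duration_s = 5, snr_db = 15, seed = 11)
  # zero noise: classify the clean signal
  clean_ses <- ses
  clean_ses$signal <- ses$clean
  ba <- bayes_reference_accuracy(clean_ses)
  expect_gt(ba$ca_bayes, 0.94)  # only overlapping spikes can confuse it
  # equal templates: accuracy collapses to the largest prior
  eq <- ses
  eq$template_windows <- eq$template_windows[c(1, 1, 1, 1), ]
  ba2 <- bayes_reference_accuracy(eq)
  expect_lt(abs(ba2$ca_bayes - max(table(ses$truth$neuron) /
                                     nrow(ses$truth))), 0.05)
})

test_that("Bayes reference dominates simple waveform classifiers", {
  ses <- small_session(duration_s = 5, snr_db = 9, seed = 12)
  ba <- bayes_reference_accuracy(ses)
  x <- ses$signal$samples
  pre <- ses$template_pre
  Tlen <- ncol(ses$template_windows)
  offs <- seq(-pre, Tlen - pre - 1)
  W <- t(sapply(round(ses$truth$time_s * ses$signal$fs) + 1,
                function(k) x[pmin(pmax(k + offs, 1), length(x))]))
  tru <- ses$truth$neuron
  # alternative 1: nearest template by amplitude only
  a1 <- apply(W, 1, function(w)
    which.min(abs(min(w) - apply(ses$template_windows, 1, min))))
  # alternative 2: correlation with templates
  a2 <- apply(W, 1, function(w)
    which.max(cor(w, t(ses$template_windows))[1, ]))
  # alternative 3: random guessing
  set.seed(1)
  a3 <- sample(1:4, nrow(W), replace = TRUE)
  for (alt in list(a1, a2, a3)) {
    expect_gte(ba$ca_bayes + 0.02, mean(alt == tru))
  }
})

test_that("CA-CA fit matches closed-form least squares", {
  x <- c(0.5, 0.7, 0.9, 0.95)
  y <- x  # identity (lm warns about the perfect fit; that is the point)
  f <- suppressWarnings(ca_ca_fit(y, x))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  set.seed(3)
  xb <- runif(10)
  yb <- 0.8 * xb + 0.05 + rnorm(10, 0, 0.01)
  f2 <- ca_ca_fit(yb, xb)
  beta <- cov(xb, yb) / var(xb)
  alpha <- mean(yb) - beta * mean(xb)
  r2 <- cor(xb, yb)^2
  expect_equal(f2$slope, beta, tolerance = 1e-12)
  expect_equal(f2$intercept, alpha, tolerance = 1e-12)
  expect_equal(f2$r_squared, r2, tolerance = 1e-12)
  expect_error(ca_ca_fit(c(1, 2, 3), c(1, 1, 1)), "variance")
})
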