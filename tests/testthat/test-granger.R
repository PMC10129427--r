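simVAR2 <- function(n, seed) {
  set.seed(seed)
  burn <- 200
  N <- n + burn
  x <- numeric(N); y <- numeric(N)
  ex <- rnorm(N); ey <- rnorm(N)
  for (t in 3:N) {
    x[t] <- 0.4 * x[t - 1] - 0.3 * x[t - 2] + 0.3 * y[t - 2] + ex[t]
    y[t] <- 0.5 * y[t - 1] - 0.35 * y[t - 2] + 0.3 * x[t - 2] + ey[t]
  }
  EEGRecording(rbind(x[-(1:burn)], y[-(1:burn)]), 250, c("C3", "C4"))
}

test_that("BIC recovers the generating VAR(2) order", {
  hits <- vapply(1:30, function(s) {
    rec <- simVAR2(5000, s)
    m <- fitVAR(epochAndReject(rec, 20, 1e6), c("C3", "C4"))
    m@order == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("VAR on independent white noise recovers the innovation covariance", {
  rec <- toyRecording(2, 20000, seed = 21)
  m <- fitVAR(epochAndReject(rec, 10, 1e6), c("C3", "C4"))
  sample_cov <- cov(t(samples(rec)))
  expect_lt(max(abs(m@residCov - sample_cov) / diag(sample_cov)), 0.05)
  expect_true(m@stable)
})

test_that("epochs too short for the lag order raise a precondition error", {
  rec <- toyRecording(2, 250, seed = 1)   # 1 s -> 50-sample epochs
  eps <- epochAndReject(rec, 0.2, 1e6)
  expect_error(fitVAR(eps, c("C3", "C4"), maxOrder = 6), "precondition")
})

test_that("GC detects a lagged influence and rejects the reverse direction", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateRecording(pairSpec(strength = 0.7, lag = 1, seed = s))
    r <- grangerPairwise(sim$recording)
    b <- connValues(r$binary)
    c(fwd = b["C3", "C4"] == 1, rev = b["C4", "C3"] == 0)
  }, logical(2))
  expect_gte(mean(hits["fwd", ]), 0.9)
  expect_gte(mean(hits["rev", ]), 0.85)
})

test_that("the GC estimate converges to the analytic log-variance ratio", {
  # y[t] = 0.8 x[t-1] + e with x, e unit white noise: y alone is white with
  # variance 1.64, the full model leaves variance 1, so GC = ln(1.64).
  set.seed(99)
  n <- 1e5
  x <- rnorm(n); e <- rnorm(n)
  y <- e; y[-1] <- y[-1] + 0.8 * x[-n]
  rec <- EEGRecording(rbind(x, y), 250, c("C3", "C4"))
  r <- grangerPairwise(rec)
  expect_lt(abs(connValues(r$gc)["C3", "C4"] / log(1.64) - 1), 0.2)
  expect_lt(connValues(r$gc)["C4", "C3"], 0.01)
})

test_that("GC F-test agrees with an independent implementation at fixed order", {
  skip_if_not_installed("lmtest")
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.5), 800))
  y <- as.numeric(arima.sim(list(ar = 0.4), 800))
  rec <- EEGRecording(rbind(x, y), 250, c("C3", "C4"))
  r <- grangerPairwise(rec, maxOrder = 1)
  ref_xy <- lmtest::grangertest(y ~ x, order = 1)$`Pr(>F)`[2]
  ref_yx <- lmtest::grangertest(x ~ y, order = 1)$`Pr(>F)`[2]
  expect_equal(r$pvalues["C3", "C4"], ref_xy, tolerance = 1e-10)
  expect_equal(r$pvalues["C4", "C3"], ref_yx, tolerance = 1e-10)
})

test_that("duplicated channels fail per pair and are reported as missing", {
  set.seed(2)
  x <- rnorm(3000)
  rec <- EEGRecording(rbind(x, x, rnorm(3000)), 250, c("C3", "C4", "F3"))
  r <- grangerPairwise(rec)
  expect_true(is.na(connValues(r$gc)["C3", "C4"]))
  expect_true(is.na(connValues(r$binary)["C4", "C3"]))
  expect_false(anyNA(connValues(r$gc)["C3", "F3"]))
  expect_match(r$gc@params$failed, "C3~C4")
})

test_that("GC is invariant to channel amplitude rescaling", {
  sim <- simulateRecording(pairSpec(strength = 0.5, lag = 2, seed = 12))
  r1 <- grangerPairwise(sim$recording)
  scaled <- EEGRecording(samples(sim$recording) * c(13, 0.4), 250,
                         c("C3", "C4"))
  r2 <- grangerPairwise(scaled)
  expect_equal(connValues(r1$gc), connValues(r2$gc), tolerance = 1e-8)
})

test_that("GC and Pearson matrices respect their structural invariants", {
  sim <- simulateRecording(makeProfile("cg_like", durationS = 10, seed = 3))
  eps <- epochAndReject(sim$recording, 2, 1e6)
  p <- pearsonConnectivity(eps, band = c(8, 13))
  v <- connValues(p)
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 1))
  expect_true(all(abs(v) <= 1 + 1e-12))
  r <- grangerPairwise(sim$recording)
  g <- connValues(r$gc)
  expect_true(all(diag(g) == 0))
  expect_true(all(g[is.finite(g)] >= 0))
})
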