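test_that("exact Mann-Whitney matches hand enumeration on the textbook case", {
  r <- mannWhitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r@u, 0)
  expect_equal(r@p, 1 / 3)
  same <- mannWhitney(c(5, 1, 3), c(3, 1, 5), mode = "exact")
  expect_equal(same@z, 0)
})

test_that("exact p equals brute-force enumeration on random small samples", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # integer draws force ties regularly
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    r <- mannWhitney(a, b, mode = "exact")
    ref <- bruteMannWhitney(a, b)
    expect_equal(r@u, ref$u)
    expect_equal(r@p, ref$p)
  }
})

test_that("normal mode matches the tie-corrected reference test", {
  set.seed(23)
  a <- sample(1:40, 30, replace = TRUE)
  b <- sample(5:45, 35, replace = TRUE)
  r <- mannWhitney(a, b, mode = "normal")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r@p, ref$p.value, tolerance = 1e-12)
  expect_equal(r@u, unname(ref$statistic))
  # |Z| consistent with p under the normal approximation
  expect_equal(2 * pnorm(-abs(r@z)), r@p, tolerance = 1e-12)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  r <- mannWhitney(rep(2, 4), rep(2, 6))
  expect_true(r@degenerate)
  expect_equal(r@z, 0)
  expect_equal(r@p, 1)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
  expect_error(mannWhitney(1:15, 1:15, mode = "exact"), "precondition")
})

test_that("qq pairing scores normality and rejects degenerate input", {
  q <- qqNormal(qnorm((1:100 - 0.5) / 100))
  expect_gte(q$linearity, 0.999)
  set.seed(31)
  skewed <- -rexp(200)
  normal <- rnorm(200)
  expect_lt(qqNormal(skewed)$linearity, qqNormal(normal)$linearity)
  expect_error(qqNormal(c(1, 2)), "precondition")
  expect_error(qqNormal(rep(3, 10)), "degeneracy")
})

test_that("ROC: perfect separation, chance level, and the U identity", {
  perfect <- rocAuc(c(1, 2, 3, 10, 11, 12), rep(c("n", "p"), each = 3), "p")
  expect_equal(perfect@auc, 1)
  set.seed(13)
  chance <- rocAuc(rnorm(1000), rep(c("n", "p"), 500), "p")
  expect_lt(abs(chance@auc - 0.5), 0.06)
  for (i in 1:20) {
    set.seed(100 + i)
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    scores <- c(sample(1:10, n1, TRUE) + 2, sample(1:10, n2, TRUE))
    labels <- rep(c("p", "n"), c(n1, n2))
    roc <- rocAuc(scores, labels, "p")
    u <- mannWhitney(scores[labels == "p"], scores[labels == "n"],
                     mode = "normal")@u
    expect_lt(abs(roc@auc - u / (n1 * n2)), 1e-9)
  }
  expect_error(rocAuc(1:4, rep("p", 4), "p"), "label error")
})

test_that("AUC and CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- c(rnorm(40, 1), rnorm(50))
  labels <- rep(c(1, 0), c(40, 50))
  ours <- rocAuc(scores, labels, "1")
  ref <- suppressMessages(pROC::auc(labels, scores))
  expect_equal(ours@auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("connectivity contrasts pool edges and respect invariances", {
  mk <- function(fill, labels = c("C3", "C4", "F3")) {
    v <- matrix(fill, 3, 3, dimnames = list(labels, labels))
    diag(v) <- 0
    new("ConnMatrix", values = v, metric = "pte", band = "alpha",
        directed = TRUE, params = list())
  }
  a <- lapply(c(0.9, 0.92, 0.88), mk)
  b <- lapply(c(0.1, 0.12, 0.08), mk)
  ct <- contrastConnectivity(a, b)
  expect_equal(ct$roc@auc, 0)    # positive class B scores lower
  expect_lt(ct$test@p, 0.01)
  expect_equal(ct$nA, 18)        # 6 off-diagonal entries x 3 subjects
  same <- contrastConnectivity(a, a)
  expect_equal(same$test@z, 0)
  # subject order invariance
  ct2 <- contrastConnectivity(a[c(3, 1, 2)], b[c(2, 3, 1)])
  expect_equal(ct2$test@p, ct$test@p)
  # consistent node relabeling leaves the contrast unchanged
  relabel <- function(m) {
    dimnames(m@values) <- list(c("P3", "P4", "O1"), c("P3", "P4", "O1"))
    m
  }
  ct3 <- contrastConnectivity(lapply(a, relabel), lapply(b, relabel))
  expect_equal(ct3$test@u, ct$test@u)
  # per-subject mean mode reduces to one value per subject
  ps <- contrastConnectivity(a, b, pooling = "per_subject_mean")
  expect_equal(ps$nA, 3)
  expect_error(contrastConnectivity(a, list()), "non-empty")
  bBad <- b
  bBad[[1]]@band <- "beta"
  expect_error(contrastConnectivity(a, bBad), "contract error")
})
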