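test_that("simulation is deterministic given the spec seed", {
  s1 <- simulateRecording(makeProfile("cg_like", durationS = 5, seed = 7))
  s2 <- simulateRecording(makeProfile("cg_like", durationS = 5, seed = 7))
  expect_identical(samples(s1$recording), samples(s2$recording))
  s3 <- simulateRecording(makeProfile("cg_like", durationS = 5, seed = 8))
  expect_false(identical(samples(s1$recording), samples(s3$recording)))
  p1 <- simulatePhaseCoupledPair(durationS = 5, seed = 4)
  p2 <- simulatePhaseCoupledPair(durationS = 5, seed = 4)
  expect_identical(samples(p1), samples(p2))
})

test_that("cohort profiles encode the intended group structure", {
  cg <- makeProfile("cg_like")
  doc <- makeProfile("doc_like")
  # control: alpha outweighs delta in every region
  expect_true(all(cg@bandWeights[, "alpha"] > cg@bandWeights[, "delta"]))
  # patient: delta outweighs alpha in every region
  expect_true(all(doc@bandWeights[, "delta"] > doc@bandWeights[, "alpha"]))
  rm <- standardRegionMap()
  hemi <- function(g) cbind(hemisphereOf(rm, g$source),
                            hemisphereOf(rm, g$target))
  hDoc <- hemi(doc@couplingGraph)
  expect_true(all(!(hDoc[, 1] != hDoc[, 2] &
                    hDoc[, 1] != "midline" & hDoc[, 2] != "midline")))
  hCg <- hemi(cg@couplingGraph)
  expect_gt(sum(hCg[, 1] != hCg[, 2] & hCg[, 1] != "midline" &
                hCg[, 2] != "midline"), 0)
  expect_gt(nrow(cg@couplingGraph), nrow(doc@couplingGraph))
  expect_identical(cg@labels, doc@labels)
  expect_identical(cg@rate, doc@rate)
  expect_error(makeProfile("unknown"), "arg")
})

test_that("an unstable coupling graph is rejected at construction", {
  W <- matrix(0.25, 1, 4, dimnames = list("central", names(defaultBands())))
  bad <- data.frame(source = c("C3", "C4"), target = c("C4", "C3"),
                    lag = c(1, 1), strength = c(1.1, 1.1))
  expect_error(syntheticSpec(labels = c("C3", "C4"), bandWeights = W,
                             couplingGraph = bad), "unstable")
})

test_that("a pure-alpha spec leaves under 5% of its power outside the band", {
  W <- matrix(c(0, 0, 1, 0), 1, 4,
              dimnames = list("central", names(defaultBands())))
  spec <- syntheticSpec(labels = c("C3", "C4"), durationS = 30,
                        bandWeights = W, noiseSd = 0, seed = 5)
  rec <- simulateRecording(spec)$recording
  sp <- welchPsd(epochAndReject(rec, 2, 1e9))
  inBand <- sp@freqs >= 8 & sp@freqs <= 13
  frac <- sum(sp@psd[, !inBand]) / sum(sp@psd)
  expect_lt(frac, 0.05)
})

test_that("realized band ratios match the generating weights within 15%", {
  W <- matrix(c(0.3, 0.2, 0.4, 0.1), 1, 4,
              dimnames = list("central", names(defaultBands())))
  spec <- syntheticSpec(labels = c("C3", "C4"), durationS = 120,
                        bandWeights = W, noiseSd = 0, sharedAlphaGain = 0,
                        seed = 2)
  rec <- simulateRecording(spec)$recording
  sp <- welchPsd(epochAndReject(rec, 2, 1e9))
  f <- sp@freqs
  bandP <- vapply(defaultBands(), function(b) {
    ix <- f >= b[1] & f <= b[2]
    sum(sp@psd[, ix])
  }, numeric(1))
  realized <- bandP / sum(bandP)
  expected <- W[1, ] / sum(W[1, ])
  expect_true(all(abs(realized / expected - 1) < 0.15))
})

test_that("only ground-truth edges clear the GC threshold envelope", {
  labels <- c("C3", "C4", "F3", "F4", "P3", "P4")
  W <- matrix(0.25, 1, 4, dimnames = list("central", names(defaultBands())))
  graph <- data.frame(source = c("C3", "F3", "P3"),
                      target = c("C4", "F4", "P4"),
                      lag = c(2, 4, 6), strength = 0.6)
  trueKey <- paste(graph$source, graph$target)
  prec <- rec_ <- numeric(15)
  for (s in 1:15) {
    spec <- syntheticSpec(labels = labels, durationS = 20, bandWeights = W,
                          couplingGraph = graph, noiseSd = 1, seed = 400 + s)
    sim <- simulateRecording(spec)
    gc <- grangerPairwise(sim$recording)
    edges <- thresholdDirected(gc$gc, 0.02)$edges
    found <- paste(edges$from, edges$to)
    prec[s] <- if (nrow(edges)) mean(found %in% trueKey) else 1
    rec_[s] <- mean(trueKey %in% found)
  }
  expect_gte(mean(rec_), 0.9)
  expect_gte(mean(prec), 0.8)
})

test_that("cohort generation is order-independent and jitter-controlled", {
  c1 <- makeCohorts(2, 2, seed = 5, durationS = 5)
  c2 <- makeCohorts(2, 2, seed = 5, durationS = 5)
  expect_identical(samples(c1$doc[[2]]$recording),
                   samples(c2$doc[[2]]$recording))
  expect_length(c1$cg, 2)
  expect_length(c1$doc, 2)
  expect_equal(c1$cg[[1]]$recording@meta$group, "CG")
  # default cohort sizes mirror the study: 9 controls, 11 patients
  expect_equal(eval(formals(makeCohorts)$nCg), 9)
  expect_equal(eval(formals(makeCohorts)$nDoc), 11)
  # zero jitter: subjects in a group share identical generative weights
  c0 <- makeCohorts(2, 1, seed = 5, durationS = 5, jitter = 0)
  expect_identical(c0$cg[[1]]$spec@bandWeights, c0$cg[[2]]$spec@bandWeights)
  expect_false(identical(samples(c0$cg[[1]]$recording),
                         samples(c0$cg[[2]]$recording)))
})
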