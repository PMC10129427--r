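# Build a SpectrumTable with prescribed band powers on a 0.5 Hz grid over
# all 19 standard channels; power is spread uniformly inside each band.
specWithBandPowers <- function(powers, fs = 250) {
  freqs <- seq(0, fs / 2, by = 0.5)
  labels <- standardChannels19()
  psd <- matrix(0, length(labels), length(freqs),
                dimnames = list(labels, NULL))
  for (b in names(powers)) {
    edges <- defaultBands()[[b]]
    ix <- which(freqs >= edges[1] & freqs <= edges[2])
    # constant density whose trapezoidal integral equals powers[b] per channel
    psd[, ix] <- powers[[b]] / (freqs[max(ix)] - freqs[min(ix)])
  }
  new("SpectrumTable", freqs = freqs, psd = psd,
      params = list(window_s = 2, overlap = 0.5, window = "hann", rate = fs))
}

test_that("Welch PSD peaks at the tone frequency and satisfies Parseval", {
  rec <- sineRecording(10, fs = 256, durationS = 60)
  sp <- welchPsd(rec, windowS = 2)
  expect_equal(sp@freqs[which.max(sp@psd[1, ])], 10)
  expect_equal(range(sp@freqs), c(0, 128))
  set.seed(11)
  noise <- EEGRecording(matrix(rnorm(256 * 60, sd = 2), 1), 256, "Cz")
  spn <- welchPsd(noise, windowS = 2)
  integral <- sum(diff(spn@freqs) *
                  (head(spn@psd[1, ], -1) + tail(spn@psd[1, ], -1)) / 2)
  expect_lt(abs(integral / var(noise@samples[1, ]) - 1), 0.10)
  zero <- EEGRecording(matrix(0, 1, 2560), 256, "Cz")
  expect_true(all(welchPsd(zero)@psd == 0))
  expect_error(welchPsd(epochAndReject(toyRecording(1, 500, labels = "Cz"),
                                       1, 1e6), windowS = 4),
               "parameter error")
})

test_that("Welch PSD matches an independent reference implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(42)
  x <- rnorm(256 * 30)
  rec <- EEGRecording(matrix(x, 1), 256, "Cz")
  sp <- welchPsd(rec, windowS = 2, overlap = 0.5)
  dir <- withr::local_tempdir()
  writeLines(sprintf("%.17g", x), file.path(dir, "x.txt"))
  script <- file.path(dir, "w.py")
  writeLines(c(
    "import numpy as np",
    "from scipy.signal import welch",
    "import sys",
    "x = np.loadtxt(sys.argv[1])",
    "f, p = welch(x, fs=256, nperseg=512, noverlap=256, window='hann',",
    "             detrend='constant')",
    "np.savetxt(sys.argv[2], p, fmt='%.17g')"), script)
  status <- system2("python", c(script, file.path(dir, "x.txt"),
                                file.path(dir, "p.txt")))
  skip_if(status != 0, "scipy unavailable")
  ref <- scan(file.path(dir, "p.txt"), quiet = TRUE)
  expect_equal(unname(sp@psd[1, ]), ref, tolerance = 1e-10)
})

test_that("DTABR and ratios follow the defining arithmetic", {
  ps <- summarizePower(specWithBandPowers(list(delta = 2, theta = 2,
                                               alpha = 1, beta = 1)))
  expect_equal(dtabr(ps), 2.0)
  expect_equal(sum(bandRatio(ps)), 1, tolerance = 1e-9)
  expect_equal(sum(regionRatio(ps)), 1, tolerance = 1e-9)
  # all mass in alpha: alpha ratio 1, the rest 0, DTABR 0
  psA <- summarizePower(specWithBandPowers(list(alpha = 3)))
  expect_equal(unname(bandRatio(psA)["alpha"]), 1)
  expect_equal(unname(bandRatio(psA)[c("delta", "theta", "beta")]),
               c(0, 0, 0))
  expect_equal(dtabr(psA), 0)
})

test_that("DTABR is scale-invariant and increases with delta mass", {
  rec <- simulateRecording(makeProfile("cg_like", durationS = 10))$recording
  eps <- epochAndReject(rec, 2, 1e6)
  base <- summarizePower(welchPsd(eps))
  scaled <- EEGRecording(samples(rec) * 3.7, samplingRate(rec),
                         channelLabels(rec))
  psScaled <- summarizePower(welchPsd(epochAndReject(scaled, 2, 1e9)))
  expect_equal(dtabr(psScaled), dtabr(base), tolerance = 1e-9)
  powers <- list(delta = 1, theta = 1, alpha = 2, beta = 1)
  d0 <- dtabr(summarizePower(specWithBandPowers(powers)))
  powers$delta <- 1.5
  expect_gt(dtabr(summarizePower(specWithBandPowers(powers))), d0)
})

test_that("a region with no present channels raises a missing-channel error", {
  rec <- toyRecording(2, 2500, labels = c("C3", "C4"))
  sp <- welchPsd(epochAndReject(rec, 2, 1e6))
  expect_error(summarizePower(sp), "missing-channel.*frontal|frontal.*missing",
               ignore.case = TRUE)
})

test_that("synthetic patient-profile spectra are delta-dominant across seeds", {
  ratios <- vapply(1:20, function(s) {
    rec <- simulateRecording(makeProfile("doc_like", durationS = 20,
                                         seed = s))$recording
    bandRatio(summarizePower(welchPsd(epochAndReject(rec, 2, 1e6))))
  }, numeric(4))
  med <- apply(ratios, 1, stats::median)
  expect_equal(names(which.max(med)), "delta")
  expect_true(all(apply(ratios, 2, which.max) == which(names(med) == "delta")))
})

test_that("cohort table aggregates per-subject ratios by group", {
  rec1 <- simulateRecording(makeProfile("cg_like", durationS = 10,
                                        seed = 1))$recording
  ps1 <- summarizePower(welchPsd(epochAndReject(rec1, 2, 1e6)))
  tab1 <- cohortPowerTable(list(ps1), "CG")
  expect_equal(tab1$value[tab1$quantity == "dtabr"], dtabr(ps1))
  tab2 <- cohortPowerTable(list(ps1, ps1), c("CG", "CG"))
  expect_equal(tab2$value, tab1$value)
  expect_error(cohortPowerTable(list(ps1), c("CG", "DOC")), "label error")
  # group contrast direction: patient-like DTABR exceeds control-like
  summaries <- list(); groups <- character()
  for (s in 1:3) {
    for (p in c("cg_like", "doc_like")) {
      rec <- simulateRecording(makeProfile(p, durationS = 20,
                                           seed = s))$recording
      summaries <- c(summaries,
                     summarizePower(welchPsd(epochAndReject(rec, 2, 1e6))))
      groups <- c(groups, p)
    }
  }
  tab <- cohortPowerTable(summaries, groups)
  dt <- tab$value[tab$quantity == "dtabr"]
  names(dt) <- tab$group[tab$quantity == "dtabr"]
  expect_gt(dt["doc_like"], dt["cg_like"])
  # pooled mode also yields valid, normalized ratios
  pooled <- cohortPowerTable(summaries, groups, pooled = TRUE)
  br <- pooled$value[grepl("band_ratio", pooled$quantity) &
                     pooled$group == "doc_like"]
  expect_equal(sum(br), 1, tolerance = 1e-9)
})
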