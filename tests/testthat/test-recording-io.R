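test_that("matrix format round-trips samples, rate and labels", {
  rec <- toyRecording(3, 1000, fs = 100, labels = c("C3", "C4", "Cz"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_equal(samples(back), samples(rec), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(samplingRate(back), 100)
  expect_equal(channelLabels(back), c("C3", "C4", "Cz"))
})

test_that("matrix format accepts an inline header instead of a sidecar", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# rate=100; labels=C3,C4",
               paste(1:5, collapse = "\t"),
               paste(6:10, collapse = "\t")), path)
  rec <- readRecording(path)
  expect_equal(samplingRate(rec), 100)
  expect_equal(channelLabels(rec), c("C3", "C4"))
  expect_equal(unname(samples(rec)[2, ]), as.numeric(6:10))
})

test_that("EDF files written by the suite read back correctly", {
  rec <- toyRecording(19, 250 * 4, fs = 250, labels = standardChannels19(),
                      seed = 7)
  rec@samples <- rec@samples * 40   # realistic microvolt scale
  path <- withr::local_tempfile(fileext = ".edf")
  writeRecording(rec, path, format = "edf")
  back <- readRecording(path)
  expect_equal(nChannels(back), 19)
  expect_equal(samplingRate(back), 250)
  expect_equal(channelLabels(back), standardChannels19())
  # 16-bit quantization: error bounded by one digitization step
  step <- (2 * max(abs(samples(rec))) * 1.0001) / 65535
  expect_lt(max(abs(samples(back) - samples(rec))), step)
})

test_that("malformed inputs fail loudly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# rate=100; labels=C3,C3",
               paste(1:5, collapse = "\t"),
               paste(6:10, collapse = "\t")), path)
  expect_error(readRecording(path), "duplicate")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(1:5, collapse = "\t")), path2)
  expect_error(readRecording(path2), "rate")
  expect_error(readRecording("no/such/file.tsv"), "not found")
  expect_error(EEGRecording(matrix(0, 2, 10), 250, c("C3", "C3")),
               "duplicate")
  expect_error(EEGRecording(matrix(c(1, NA), 2, 10), 250, c("C3", "C4")),
               "finite")
})

test_that("labels are normalized to canonical 10-20 form and unknowns flagged", {
  nl <- normalizeLabels(c("FP1", "t7", "p8", "cz", "EKG"))
  expect_equal(nl$labels, c("Fp1", "T3", "T6", "Cz", "EKG"))
  expect_equal(nl$unknown, "EKG")
  rec <- toyRecording(2, 100, labels = c("FP1", "EKG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_equal(channelLabels(back)[1], "Fp1")
  expect_equal(recordingMeta(back)$unknown_labels, "EKG")
})

test_that("region map matches the montage partition and hemisphere rule", {
  rm <- standardRegionMap()
  expect_setequal(names(rm@assignment)[rm@assignment == "frontal"],
                  c("Fp1", "Fp2", "F3", "Fz", "F4", "F7", "F8"))
  expect_setequal(names(rm@assignment)[rm@assignment == "central"],
                  c("C3", "Cz", "C4"))
  expect_setequal(names(rm@assignment)[rm@assignment == "temporal"],
                  c("T3", "T4", "T5", "T6"))
  expect_setequal(names(rm@assignment)[rm@assignment == "parietal"],
                  c("P3", "Pz", "P4"))
  expect_setequal(names(rm@assignment)[rm@assignment == "occipital"],
                  c("O1", "Oz", "O2"))
  expect_equal(hemisphereOf(rm, c("C3", "C4", "Cz", "Fp1", "T6")),
               c("left", "right", "midline", "left", "right"))
  expect_error(regionOf(rm, "EKG"), "unmapped")
})
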