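test_that("matching score has the centered-correlation identities", {
  set.seed(51)
  A <- matrix(rnorm(20, 100, 15), 5, 4)
  expect_equal(matchScore(A, A), 1)
  # mean-preserving negation anti-correlates perfectly
  expect_equal(matchScore(A, -A + 2 * mean(A)), -1)
  # affine invariance
  expect_equal(matchScore(A, 3.7 * A + 12), 1)
  expect_equal(matchScore(A, -0.4 * A + 5), -1)
  # flatten-and-correlate oracle
  for (i in 1:50) {
    A <- matrix(rnorm(20, -150, 30), 5, 4)
    B <- matrix(rnorm(20, -150, 30), 5, 4)
    expect_equal(matchScore(A, B), cor(as.vector(A), as.vector(B)),
                 tolerance = 1e-12)
    expect_true(abs(matchScore(A, B)) <= 1)
  }
  expect_error(matchScore(A, matrix(0, 4, 5)), "same shape")
  expect_warning(s <- matchScore(matrix(1, 3, 3), matrix(rnorm(9), 3)),
                 "zero-variance")
  expect_equal(s, 0)
})

test_that("scan scores equal the brute-force sub-matrix loop", {
  spec <- spectrogram(noiseClip(52, durationS = 1), 256, 64)
  f <- extractFeature(spec, 0.2, 0.5, 80, 400, "black_drum", "t")
  # rescan the same spectrogram with threshold -1 to get every offset
  det <- scanFeature(spec, f, threshold = -1,
                     nmsWindowS = 1e-9)  # 1-frame suppression: keep all
  B <- splLevels(spec)[, bandBinIndices(80, 400, 8000, 256) + 1]
  m <- nrow(f@surface)
  offsets <- seq_len(nrow(B) - m + 1)
  brute <- vapply(offsets, function(t0)
    suppressWarnings(matchScore(f@surface, B[t0:(t0 + m - 1), ])),
    numeric(1))
  # dense scan at threshold -1 with minimal suppression returns the score
  # at every offset that is a local winner; check the full vector via the
  # detection subset instead: every detection's score equals brute force
  idx <- round(det$timeOffset / (64 / 8000)) + 1
  expect_equal(det$score, brute[idx], tolerance = 1e-12)
  # and the template matches itself at its own offset with s = 1
  self <- which.max(brute)
  expect_equal(brute[self], 1, tolerance = 1e-9)
  expect_equal(self, round(0.2 / (64 / 8000)) + 1)
})

test_that("template self-match is recovered at the injection offset", {
  clip <- callInNoiseClip(53, onsetS = 0.8)
  spec <- spectrogram(clip, 256, 64)
  callDur <- length(callWaveTiny()) / 8000
  f <- extractFeature(spec, 0.8, 0.8 + callDur, 80, 400, "black_drum", "t")
  det <- scanFeature(spec, f, threshold = 0.99)
  expect_equal(nrow(det), 1)
  expect_equal(det$timeOffset, 0.8, tolerance = 64 / 8000)
  expect_gte(det$score, 0.99)
})

test_that("stationary noise yields no detections at a high threshold", {
  # template from one noise realization scanned over independent noise:
  # 100 seeded trials, theta = 0.9
  spec0 <- spectrogram(noiseClip(54, durationS = 1), 256, 64)
  f <- extractFeature(spec0, 0.2, 0.6, 80, 400, "black_drum", "t")
  hits <- 0
  for (seed in 1:100) {
    spec <- spectrogram(noiseClip(1000 + seed, durationS = 1), 256, 64)
    hits <- hits + nrow(scanFeature(spec, f, threshold = 0.9))
  }
  expect_equal(hits, 0)
})

test_that("two well-separated identical calls give exactly two detections", {
  wave <- callWaveTiny()
  fs <- 8000
  x <- withr::with_seed(55, rnorm(3 * fs, 0, 0.05))
  for (on in c(0.5, 2.0)) {
    i <- round(on * fs) + 1
    x[i:(i + length(wave) - 1)] <- x[i:(i + length(wave) - 1)] + 0.5 * wave
  }
  clip <- AudioClip(x, fs)
  spec <- spectrogram(clip, 256, 64)
  callDur <- length(wave) / fs
  f <- extractFeature(spec, 0.5, 0.5 + callDur, 80, 400, "black_drum", "t")
  det <- scanFeature(spec, f, threshold = 0.6)
  expect_equal(nrow(det), 2)
  expect_equal(det$timeOffset, c(0.5, 2.0), tolerance = callDur)
})

test_that("injection shifted by whole hops moves the detection in frames", {
  wave <- callWaveTiny()
  fs <- 8000; p <- 64; k <- 5
  base <- withr::with_seed(56, rnorm(2 * fs, 0, 0.05))
  inject <- function(x, at) {
    i <- at + 1
    x[i:(i + length(wave) - 1)] <- x[i:(i + length(wave) - 1)] + 0.5 * wave
    x
  }
  at0 <- 4000
  spec1 <- spectrogram(AudioClip(inject(base, at0), fs), 256, p)
  spec2 <- spectrogram(AudioClip(inject(base, at0 + k * p), fs), 256, p)
  callDur <- length(wave) / fs
  f <- extractFeature(spec1, at0 / fs, at0 / fs + callDur, 80, 400,
                      "black_drum", "t")
  d1 <- scanFeature(spec1, f, threshold = 0.5)
  d2 <- scanFeature(spec2, f, threshold = 0.5)
  top1 <- d1[which.max(d1$score), ]
  top2 <- d2[which.max(d2$score), ]
  expect_equal(top2$timeOffset - top1$timeOffset, k * p / fs)
})

test_that("scan rejects mismatched framing and bands", {
  spec <- spectrogram(noiseClip(57), 256, 64)
  f <- extractFeature(spec, 0, 0.5, 80, 400, "black_drum", "t")
  other <- spectrogram(noiseClip(57), 128, 64)
  expect_error(scanFeature(other, f), "framing mismatch")
})

test_that("detectFile counts per species and is deterministic", {
  cfg <- tinyConfig()
  spec <- spectrogram(callInNoiseClip(58, onsetS = 0.6), 256, 64)
  callDur <- length(callWaveTiny()) / 8000
  lib <- FeatureLibrary(list(
    extractFeature(spec, 0.6, 0.6 + callDur, 80, 400, "black_drum", "bd"),
    extractFeature(spec, 0.6, 0.6 + callDur, 80, 400, "silver_perch",
                   "sp")),
    cfg)
  clip <- callInNoiseClip(59, onsetS = 1.0)
  s1 <- detectFile(clip, lib, sourceFile = "a")
  s2 <- detectFile(clip, lib, sourceFile = "a")
  expect_identical(callCounts(s1), callCounts(s2))
  expect_identical(detections(s1), detections(s2))
  expect_named(callCounts(s1), c("black_drum", "silver_perch"))
  # a silent clip detects nothing for any species
  silent <- detectFile(AudioClip(numeric(16000), 8000), lib)
  expect_true(all(callCounts(silent) == 0))
  expect_equal(nrow(detections(silent)), 0)
  # monotone counts: adding a second well-separated call never decreases
  wave <- callWaveTiny()
  x <- samples(clip)
  i <- round(1.55 * 8000) + 1  # clip is 2 s; call ends inside it
  x[i:(i + length(wave) - 1)] <- x[i:(i + length(wave) - 1)] + 0.5 * wave
  more <- detectFile(AudioClip(x, 8000), lib)
  expect_gte(callCounts(more)[["black_drum"]],
             callCounts(s1)[["black_drum"]])
  expect_error(detectFile(AudioClip(rnorm(100), 8000), lib), "shorter")
  expect_error(detectFile(clip, FeatureLibrary(list(), cfg)), "empty")
})

test_that("batch detection records failures without aborting", {
  cfg <- tinyConfig()
  spec <- spectrogram(callInNoiseClip(60, onsetS = 0.6), 256, 64)
  callDur <- length(callWaveTiny()) / 8000
  lib <- FeatureLibrary(list(
    extractFeature(spec, 0.6, 0.6 + callDur, 80, 400, "black_drum", "bd")),
    cfg)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, sprintf("clip%d.wav", 1:3))
  for (i in 1:2) writeWav(callInNoiseClip(60 + i), paths[i])
  writeLines("corrupt", paths[3])
  res <- batchDetect(paths, lib)
  expect_equal(nrow(res$summaries), 2)
  expect_equal(nrow(res$failures), 1)
  expect_equal(res$failures$sourceFile, "clip3.wav")
  expect_equal(res$status, 1L)
  # batch equals the union of single-file runs
  single <- lapply(paths[1:2], function(pp)
    detectFile(readWav(pp), lib, sourceFile = basename(pp)))
  expect_equal(res$summaries$black_drum,
               vapply(single, function(s) unname(callCounts(s)["black_drum"]),
                      numeric(1)))
  clean <- batchDetect(paths[1:2], lib)
  expect_equal(clean$status, 0L)
  expect_equal(nrow(clean$summaries), 2)
})
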