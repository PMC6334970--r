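test_that("black drum calls are harmonic and band-limited", {
  fs <- 80000
  x <- synthBlackDrum(f0 = 100, nHarmonics = 3, durationS = 1,
                      sampleRate = fs)
  spec <- spectrogram(AudioClip(x, fs), 4096, 1024)
  # energy concentrated at the 100/200/300 Hz bins in every frame
  lev <- splLevels(spec)
  df <- fs / 4096
  harmonicBins <- round(c(100, 200, 300) / df) + 1
  midFrames <- 3:(nrow(lev) - 3)
  for (r in midFrames) {
    top <- order(lev[r, ], decreasing = TRUE)[1:6]
    expect_true(all(vapply(harmonicBins, function(b)
      any(abs(top - b) <= 1), logical(1))))
  }
  # >= 90% of energy below 400 Hz (periodogram partition)
  X <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  inBand <- sum(X[f <= 400]) / sum(X[f <= fs / 2])
  expect_gte(inBand, 0.9)
  expect_identical(synthBlackDrum(durationS = 0), numeric(0))
  expect_warning(synthBlackDrum(f0 = 150, nHarmonics = 4), "band")
})

test_that("pulse trains carry the requested number of envelope peaks", {
  fs <- 80000
  countPeaks <- function(x, minGapS = 0.02) {
    env <- abs(x)
    # smooth with a moving average, then count well-separated maxima
    k <- max(3, min(round(0.005 * fs), floor(length(x) / 4)))
    env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
    env[is.na(env)] <- 0
    th <- 0.3 * max(env)
    above <- env > th
    runs <- rle(above)
    sum(runs$values)
  }
  for (n in c(1, 5, 13)) {
    x <- synthPulseTrain("silver_perch", nPulses = n, pulseRate = 12,
                         centerFreq = 1600, bandwidth = 2200,
                         sampleRate = fs)
    expect_equal(countPeaks(x), n)
  }
  x1 <- synthPulseTrain("s", 1, 10, 400, 300, sampleRate = fs)
  expect_lt(length(x1) / fs, 0.05)  # single pulse is just the pulse width
  expect_error(synthPulseTrain("s", 0, 10, 400, 300), "nPulses")
})

test_that("staccato inter-pulse intervals strictly decrease", {
  fs <- 80000
  x <- synthPulseTrain("spotted_seatrout", nPulses = 21, pulseRate = 16,
                       centerFreq = 350, bandwidth = 450, sampleRate = fs,
                       staccato = TRUE)
  # peak-picking oracle on the envelope
  env <- abs(x)
  k <- round(0.004 * fs)
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  th <- 0.3 * max(env)
  runs <- rle(env > th)
  starts <- cumsum(c(1, runs$lengths))[which(runs$values)]
  expect_equal(length(starts), 21)
  gaps <- diff(starts)
  expect_true(all(diff(gaps) < 0))
})

test_that("snapping shrimp snaps follow a seeded Poisson process", {
  expect_identical(synthSnappingShrimp(0, 1, seed = 1), numeric(80000))
  a <- synthSnappingShrimp(10, 2, seed = 9)
  b <- synthSnappingShrimp(10, 2, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, synthSnappingShrimp(10, 2, seed = 10)))
  # snap count over 120 s at 10 snaps/s: within 3 sd of 1200. Count
  # activity runs separated by silent gaps (snaps are ~0.6 ms, mean gap
  # 100 ms, so collisions are rare).
  x <- synthSnappingShrimp(10, 120, seed = 11)
  active <- abs(x) > 0.01
  runs <- rle(active)
  # merge gaps shorter than 1 ms into their neighbors
  gapTooShort <- !runs$values & runs$lengths < 80
  snapCount <- sum(runs$values & c(TRUE, !gapTooShort[-length(gapTooShort)]))
  expect_lt(abs(snapCount - 1200), 3 * sqrt(1200))
})

test_that("an injected call hits its requested in-band SNR", {
  res <- assembleSoundscape(
    events = list(list(species = "silver_perch", onsetS = 2, snrDb = 20)),
    background = list(noiseRms = 0.01, shrimpRate = 0),
    durationS = 6, sampleRate = 80000, seed = 77)
  ev <- res$manifest$events
  x <- samples(res$clip)
  fs <- 80000
  bandMs <- function(seg, lo, hi) {
    X <- Mod(fft(seg))^2 / length(seg)^2
    f <- (seq_along(seg) - 1) * fs / length(seg)
    2 * sum(X[f >= lo & f <= hi & f <= fs / 2])
  }
  i0 <- round(ev$onsetS * fs) + 1
  i1 <- i0 + round(ev$durationS * fs) - 1
  callWin <- bandMs(x[i0:i1], 80, 5000)
  bgWin <- bandMs(x[1:(i0 - 1)], 80, 5000)
  measured <- 10 * log10(callWin / bgWin - 1)  # subtract background share
  expect_lt(abs(measured - 20), 1)
  # and the raw level difference is ~ 10*log10(10^2 + 1)
  expect_lt(abs(10 * log10(callWin / bgWin) - 20.04), 1)
})

test_that("soundscape assembly is seed-deterministic and warns on overlap", {
  ev <- list(list(species = "red_drum", onsetS = 1, snrDb = 15),
             list(species = "red_drum", onsetS = 1.1, snrDb = 15))
  r1 <- suppressWarnings(assembleSoundscape(ev, durationS = 4, seed = 5))
  r2 <- suppressWarnings(assembleSoundscape(ev, durationS = 4, seed = 5))
  expect_identical(samples(r1$clip), samples(r2$clip))
  expect_warning(assembleSoundscape(ev, durationS = 4, seed = 5),
                 "overlap")
  expect_silent(assembleSoundscape(ev, durationS = 4, seed = 5,
                                   chorus = TRUE))
  # no events, no background: digital silence
  quiet <- assembleSoundscape(
    list(), background = list(noiseRms = 0, shrimpRate = 0),
    durationS = 1, seed = 1)
  expect_identical(samples(quiet$clip), numeric(80000))
  expect_equal(nrow(quiet$manifest$events), 0)
  # events must fit inside the clip
  expect_error(assembleSoundscape(
    list(list(species = "red_drum", onsetS = 3.8, snrDb = 10)),
    durationS = 4, seed = 1), "fit")
})

test_that("manifests round-trip through JSON", {
  res <- assembleSoundscape(
    list(list(species = "silver_perch", onsetS = 1, snrDb = 20)),
    durationS = 4, seed = 3, clipId = "rt")
  path <- withr::local_tempfile(fileext = ".json")
  writeManifest(res$manifest, path)
  m <- readManifest(path)
  expect_equal(m$clipId, "rt")
  expect_equal(m$rngSeed, 3)
  expect_equal(m$events$onsetS, res$manifest$events$onsetS)
  expect_equal(m$events$scale, res$manifest$events$scale)
})

test_that("the benchmark suite is complete and reproducible", {
  b1 <- makeBenchmark(NULL, seed = 3, durationS = 8, nIsolated = 1,
                      nMulti = 1, nChorus = 1, nShrimp = 1, nNoise = 1,
                      nSilent = 1, species = c("red_drum", "black_drum"),
                      writeWavFiles = FALSE)
  b2 <- makeBenchmark(NULL, seed = 3, durationS = 8, nIsolated = 1,
                      nMulti = 1, nChorus = 1, nShrimp = 1, nNoise = 1,
                      nSilent = 1, species = c("red_drum", "black_drum"),
                      writeWavFiles = FALSE)
  expect_identical(b1$index, b2$index)
  expect_identical(b1$manifests, b2$manifests)
  expect_identical(lapply(b1$clips, samples), lapply(b2$clips, samples))
  # one clip per species per condition
  tab <- table(b1$index$species, b1$index$condition)
  expect_true(all(tab == 1))
  # chorus clips contain overlapping events by construction
  for (id in b1$index$clipId[b1$index$condition == "chorus"])
    expect_equal(intensityFromManifest(b1$manifests[[id]]$events), 3L)
  # silent clips have no events; isolated exactly one
  for (id in b1$index$clipId[b1$index$condition == "silent"])
    expect_equal(nrow(b1$manifests[[id]]$events), 0)
  for (id in b1$index$clipId[b1$index$condition == "isolated"])
    expect_equal(nrow(b1$manifests[[id]]$events), 1)
})
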