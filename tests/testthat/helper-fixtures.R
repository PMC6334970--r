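# Small in-code fixtures shared across tests. Tests that exercise the
# scanner use a reduced sampling rate (8 kHz) and small frame windows so
# whole pipelines run in milliseconds; the arithmetic under test is
# scale-free.

# A small per-species configuration on an 8 kHz grid.
tinyConfig <- function() {
  data.frame(
    species = c("black_drum", "silver_perch", "spotted_seatrout",
                "red_drum"),
    windowW = 256L, repetitionP = 64L, threshold = 0.6,
    nmsWindowS = NA_real_, bandLo = 80, bandHi = 400,
    stringsAsFactors = FALSE)
}

# White-noise clip at a given seed.
noiseClip <- function(seed, durationS = 2, sampleRate = 8000, rms = 0.1) {
  withr::with_seed(seed,
    AudioClip(rnorm(durationS * sampleRate, 0, rms), sampleRate))
}

# A clip containing one deterministic band-limited chirp-like call over
# noise, plus the frame offset it was injected at.
callInNoiseClip <- function(seed, onsetS = 0.5, durationS = 2,
                            sampleRate = 8000, callAmp = 0.5) {
  wave <- callWaveTiny(sampleRate)
  withr::with_seed(seed, {
    x <- rnorm(durationS * sampleRate, 0, 0.05)
    i0 <- round(onsetS * sampleRate) + 1
    x[i0:(i0 + length(wave) - 1)] <- x[i0:(i0 + length(wave) - 1)] +
      callAmp * wave
    AudioClip(x, sampleRate)
  })
}

# Deterministic test call: short pulse train inside 80-400 Hz.
callWaveTiny <- function(sampleRate = 8000) {
  synthPulseTrain("test", nPulses = 4, pulseRate = 10, centerFreq = 200,
                  bandwidth = 150, sampleRate = sampleRate)
}

# Independent slice oracle for frame contents.
frameOracle <- function(x, w, p) {
  nF <- (length(x) - w) %/% p + 1
  vapply(seq_len(nF) - 1, function(n) x[(n * p + 1):(n * p + w)],
         numeric(w))
}

# Direct DFT magnitude (matrix multiply, no fft) for one frame.
dftMagOracle <- function(frame) {
  w <- length(frame)
  k <- 0:floor(w / 2)
  M <- exp(-2i * pi * outer(k, 0:(w - 1)) / w)
  Mod(as.vector(M %*% frame))
}

expectDataFrameEqual <- function(a, b, tol = 1e-12) {
  expect_equal(names(a), names(b))
  expect_equal(nrow(a), nrow(b))
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], tolerance = tol)
}
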