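## Call synthesis. Morphology defaults (fundamentals, pulse widths, damping)
## follow the qualitative structure of sciaenid calls — harmonic tonal black
## drum calls below 400 Hz, broadband silver perch pulse trains reaching
## 5 kHz, seatrout grunts/drums/staccatos (staccato inter-pulse interval
## shrinking toward the end), slow 3-5 pulse red drum knocks — and are all
## configurable; they are synthesis conventions, not measured field values.

#' Synthesize a black drum call
#'
#' A tonal, harmonic call: energy at `f0` and its first `nHarmonics - 1`
#' overtones with geometrically decaying harmonic amplitudes, under a
#' smooth rise/fall envelope. Black drum calls occupy a narrow band
#' between 80 and 400 Hz; a warning (not an error) is issued when the
#' requested harmonics leave that band.
#'
#' @param f0 fundamental frequency, Hz (>= 80 recommended).
#' @param nHarmonics number of harmonic components including `f0`.
#' @param durationS call duration, seconds (0 gives an empty waveform).
#' @param sampleRate Hz.
#' @param harmonicDecay amplitude ratio between successive harmonics.
#' @return numeric waveform with peak amplitude 1 (empty for
#'   `durationS = 0`).
#' @export
synthBlackDrum <- function(f0 = 100, nHarmonics = 3, durationS = 0.9,
                           sampleRate = 80000, harmonicDecay = 0.55) {
  if (durationS <= 0) return(numeric(0))
  if (f0 * nHarmonics > 400)
    warning("harmonics extend above the nominal 80-400 Hz black drum band")
  t <- seq(0, durationS, by = 1 / sampleRate)
  t <- t[-length(t)]
  x <- numeric(length(t))
  for (k in seq_len(nHarmonics))
    x <- x + harmonicDecay^(k - 1) * sin(2 * pi * k * f0 * t + 0.4 * k)
  env <- sin(pi * t / durationS)^0.7
  x <- x * env
  x / max(abs(x))
}

## One damped band-limited pulse: exponentially damped sinusoid whose decay
## constant follows the requested bandwidth (bw ~ 1/(pi*tau)).
.synthPulse <- function(centerFreq, bandwidth, sampleRate,
                        widthS = NULL) {
  tau <- 1 / (pi * bandwidth)
  if (is.null(widthS)) widthS <- 8 * tau
  t <- seq(0, widthS, by = 1 / sampleRate)
  exp(-t / tau) * sin(2 * pi * centerFreq * t)
}

#' Synthesize a pulsed sciaenid call
#'
#' `nPulses` damped band-limited pulses at `pulseRate` pulses per second.
#' In staccato mode (the spotted seatrout staccato call) the inter-pulse
#' interval shrinks geometrically toward the end of the call, so
#' successive intervals are strictly decreasing.
#'
#' @param species species label stored for reference (any string).
#' @param nPulses number of pulses (>= 1).
#' @param pulseRate initial pulse rate, pulses per second.
#' @param centerFreq pulse carrier frequency, Hz.
#' @param bandwidth pulse bandwidth, Hz (wider = shorter click).
#' @param durationS optional total duration; default is the span of the
#'   pulse train plus one pulse width.
#' @param sampleRate Hz.
#' @param staccato logical; shrink inter-pulse intervals toward the end.
#' @param intervalRatio geometric ratio of successive intervals in
#'   staccato mode (< 1).
#' @return numeric waveform with peak amplitude 1.
#' @export
synthPulseTrain <- function(species, nPulses, pulseRate, centerFreq,
                            bandwidth, durationS = NULL, sampleRate = 80000,
                            staccato = FALSE, intervalRatio = 0.93) {
  if (nPulses < 1) stop("'nPulses' must be >= 1")
  pulse <- .synthPulse(centerFreq, bandwidth, sampleRate)
  if (nPulses == 1) {
    onsets <- 0
  } else {
    base <- 1 / pulseRate
    gaps <- if (staccato) base * intervalRatio^(seq_len(nPulses - 1L) - 1L)
            else rep(base, nPulses - 1L)
    onsets <- c(0, cumsum(gaps))
  }
  span <- max(onsets) + length(pulse) / sampleRate
  if (is.null(durationS)) durationS <- span
  if (durationS < span) stop("'durationS' too short for the pulse train")
  n <- round(durationS * sampleRate)
  x <- numeric(n)
  for (o in onsets) {
    i0 <- round(o * sampleRate) + 1L
    i1 <- min(n, i0 + length(pulse) - 1L)
    x[i0:i1] <- x[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
  }
  x / max(abs(x))
}

#' Synthesize snapping-shrimp background
#'
#' Broadband impulsive snaps at Poisson-distributed times. Snaps are
#' short damped broadband clicks with log-normally varying amplitude;
#' output is seed-deterministic.
#'
#' @param rate snaps per second (0 gives silence).
#' @param durationS seconds.
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @param sampleRate Hz.
#' @return numeric waveform (unnormalized; snap peaks around 1).
#' @export
synthSnappingShrimp <- function(rate, durationS, seed = NULL,
                                sampleRate = 80000) {
  gen <- function() {
    n <- round(durationS * sampleRate)
    x <- numeric(n)
    if (rate <= 0 || n == 0L) return(x)
    k <- stats::rpois(1, rate * durationS)
    if (k == 0L) return(x)
    onsets <- sort(stats::runif(k, 0, durationS))
    snapLen <- round(0.0006 * sampleRate)
    decay <- exp(-(seq_len(snapLen) - 1) / (0.12 * snapLen))
    for (o in onsets) {
      amp <- exp(stats::rnorm(1, 0, 0.4))
      click <- amp * decay * stats::rnorm(snapLen)
      i0 <- round(o * sampleRate) + 1L
      i1 <- min(n, i0 + snapLen - 1L)
      x[i0:i1] <- x[i0:i1] + click[seq_len(i1 - i0 + 1L)]
    }
    x
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## Default call synthesis per species/call type. Variants deliberately span
## the pulse-count ranges of each species' repertoire (silver perch 5-13
## pulses, red drum 3-5, seatrout grunt/drum/staccato with ~21 pulses).
.speciesCall <- function(species, callType = "", params = list(),
                         sampleRate = 80000) {
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  switch(species,
    black_drum = synthBlackDrum(
      f0 = p("f0", 100), nHarmonics = p("nHarmonics", 3),
      durationS = p("durationS", 0.9), sampleRate = sampleRate),
    silver_perch = synthPulseTrain(
      species, nPulses = p("nPulses", 7), pulseRate = p("pulseRate", 12),
      centerFreq = p("centerFreq", 1600), bandwidth = p("bandwidth", 2200),
      sampleRate = sampleRate),
    spotted_seatrout = {
      if (identical(callType, "staccato"))
        synthPulseTrain(species, nPulses = p("nPulses", 21),
                        pulseRate = p("pulseRate", 16),
                        centerFreq = p("centerFreq", 350),
                        bandwidth = p("bandwidth", 450),
                        sampleRate = sampleRate, staccato = TRUE)
      else
        synthPulseTrain(species, nPulses = p("nPulses", 8),
                        pulseRate = p("pulseRate", 22),
                        centerFreq = p("centerFreq", 350),
                        bandwidth = p("bandwidth", 450),
                        sampleRate = sampleRate)
    },
    red_drum = synthPulseTrain(
      species, nPulses = p("nPulses", 4), pulseRate = p("pulseRate", 7),
      centerFreq = p("centerFreq", 180), bandwidth = p("bandwidth", 220),
      sampleRate = sampleRate),
    stop("no default synthesizer for species '", species, "'"))
}

## Mean-square power of x restricted to [fLo, fHi] via the periodogram.
.bandPower <- function(x, fLo, fHi, sampleRate) {
  n <- length(x)
  nPad <- stats::nextn(n)  # composite FFT length; zero-padding keeps energy
  X <- stats::fft(c(x, numeric(nPad - n)))
  p <- Mod(X)^2 / (as.numeric(nPad) * n)
  f <- (seq_len(nPad) - 1) * sampleRate / nPad
  half <- f <= sampleRate / 2
  inBand <- half & f >= fLo & f <= fHi
  sum(p[inBand]) * 2  # fold the conjugate half
}

#' Assemble a calibrated synthetic soundscape clip
#'
#' Sums synthesized calls at their onsets over a background of Gaussian
#' noise plus snapping shrimp, scaling each call so its in-band SNR
#' (call band power over background band power inside the species band)
#' equals the requested value. The returned manifest records every event
#' with its achieved scale, the background description, and the seed, so
#' detector output can be scored exactly without re-listening.
#'
#' @param events list of events; each a list with `species`, optional
#'   `callType`, `onsetS`, `snrDb`, optional `params` (passed to the
#'   species synthesizer).
#' @param background list: `noiseRms` (Gaussian background RMS amplitude),
#'   `shrimpRate` (snaps/s), `shrimpLevel` (snap amplitude scale). Set all
#'   to 0 for digital silence.
#' @param durationS clip length, seconds (default 120, the 2-min file
#'   schedule).
#' @param sampleRate Hz (default 80000, the study recorder rate).
#' @param seed integer RNG seed; recorded in the manifest.
#' @param chorus logical; when `FALSE` a warning is issued if events
#'   overlap in time.
#' @param clipId label stored in the manifest.
#' @param station station label stored on the clip.
#' @return list with `clip` (an [AudioClip-class]) and `manifest` (a list:
#'   `clipId`, `events` data.frame with columns `species`, `callType`,
#'   `onsetS`, `durationS`, `snrDb`, `scale`, `background`, `rngSeed`,
#'   `sampleRate`, `durationS`, `normalization`).
#' @export
assembleSoundscape <- function(events = list(),
                               background = list(noiseRms = 0.01,
                                                 shrimpRate = 2,
                                                 shrimpLevel = 0.05),
                               durationS = 120, sampleRate = 80000,
                               seed = 1, chorus = FALSE, clipId = "clip",
                               station = NA_character_) {
  noiseRms <- if (is.null(background$noiseRms)) 0 else background$noiseRms
  shrimpRate <- if (is.null(background$shrimpRate)) 0 else background$shrimpRate
  shrimpLevel <- if (is.null(background$shrimpLevel)) 0.05 else
    background$shrimpLevel
  build <- function() {
    n <- round(durationS * sampleRate)
    bg <- if (noiseRms > 0) stats::rnorm(n, 0, noiseRms) else numeric(n)
    if (shrimpRate > 0)
      bg <- bg + shrimpLevel *
        synthSnappingShrimp(shrimpRate, durationS, seed = NULL,
                            sampleRate = sampleRate)
    x <- bg
    cfg <- defaultSpeciesConfig(sampleRate)
    bandPowerCache <- list()
    rows <- list()
    for (ev in events) {
      callType <- if (is.null(ev$callType)) "" else ev$callType
      wave <- .speciesCall(ev$species, callType,
                           if (is.null(ev$params)) list() else ev$params,
                           sampleRate)
      evDur <- length(wave) / sampleRate
      if (ev$onsetS < 0 || ev$onsetS + evDur > durationS + 1e-9)
        stop("event does not fit inside the clip: ", ev$species, " at ",
             ev$onsetS, " s")
      row <- cfg[cfg$species == ev$species, , drop = FALSE]
      band <- if (nrow(row)) c(row$bandLo, row$bandHi) else
        c(10, sampleRate / 2)
      key <- paste(band, collapse = "-")
      if (is.null(bandPowerCache[[key]]))
        bandPowerCache[[key]] <- if (any(bg != 0))
          .bandPower(bg, band[1], band[2], sampleRate) else 0
      pBg <- bandPowerCache[[key]]
      pCall <- .bandPower(wave, band[1], band[2], sampleRate)
      scale <- if (pBg > 0) sqrt(pBg * 10^(ev$snrDb / 10) / pCall) else 1
      i0 <- round(ev$onsetS * sampleRate) + 1L
      i1 <- i0 + length(wave) - 1L
      x[i0:i1] <- x[i0:i1] + scale * wave
      rows[[length(rows) + 1L]] <- data.frame(
        species = ev$species, callType = callType, onsetS = ev$onsetS,
        durationS = evDur, snrDb = ev$snrDb, scale = scale,
        stringsAsFactors = FALSE)
    }
    evDf <- if (length(rows)) do.call(rbind, rows) else
      data.frame(species = character(0), callType = character(0),
                 onsetS = numeric(0), durationS = numeric(0),
                 snrDb = numeric(0), scale = numeric(0),
                 stringsAsFactors = FALSE)
    evDf <- evDf[order(evDf$onsetS), , drop = FALSE]
    rownames(evDf) <- NULL
    if (!chorus && nrow(evDf) > 1L) {
      ends <- evDf$onsetS + evDf$durationS
      if (any(evDf$onsetS[-1L] < ends[-nrow(evDf)] - 1e-9))
        warning("events overlap in time but chorus mode was not requested")
    }
    norm <- 1
    peak <- if (length(x)) max(abs(x)) else 0
    if (peak > 0.99) {
      norm <- 0.99 / peak
      x <- x * norm
    }
    list(clip = AudioClip(x, sampleRate, station = station),
         manifest = list(clipId = clipId, events = evDf,
                         background = list(noiseRms = noiseRms,
                                           shrimpRate = shrimpRate,
                                           shrimpLevel = shrimpLevel),
                         rngSeed = seed, sampleRate = sampleRate,
                         durationS = durationS, normalization = norm))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write / read a ground-truth manifest
#'
#' Manifests are stored as JSON next to their clips.
#'
#' @param manifest manifest list from [assembleSoundscape()].
#' @param path JSON path.
#' @return `writeManifest()`: `path` invisibly; `readManifest()`: the
#'   manifest list (events as a data.frame).
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$events) || length(m$events) == 0L ||
      (is.data.frame(m$events) && nrow(m$events) == 0L))
    m$events <- data.frame(species = character(0), callType = character(0),
                           onsetS = numeric(0), durationS = numeric(0),
                           snrDb = numeric(0), scale = numeric(0),
                           stringsAsFactors = FALSE)
  m
}
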