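setOldClass(c("POSIXct", "POSIXt"))

#' Hydrophone calibration chain
#'
#' Holds the constants of the recorder calibration chain used to convert
#' dimensionless ADC amplitude to sound pressure level: hydrophone
#' sensitivity `h` (dBV per uPa), recorder gain `g` (dB), and the
#' analog-to-digital full-scale voltage `Vadc` (volts). The correction
#' factor is `S = h + g + 20*log10(1/Vadc)`; calibrated level is the
#' uncalibrated dB level minus `S`.
#'
#' Defaults are the DSG-Ocean / High Tech Inc. chain used in May River
#' estuary monitoring: `h = -186` dBV/uPa, `g = 20` dB, `Vadc = 1` V,
#' giving `S = -166` dB.
#'
#' @slot sensitivity hydrophone sensitivity `h`, dBV per uPa.
#' @slot gain recorder gain `g`, dB.
#' @slot adcFullScale ADC full-scale voltage `Vadc`, volts (> 0).
#'
#' @seealso [correctionFactor()], [broadbandSPL()]
#' @export
setClass("CalibrationSpec",
  representation(sensitivity = "numeric", gain = "numeric",
                 adcFullScale = "numeric"),
  prototype(sensitivity = -186, gain = 20, adcFullScale = 1))

setValidity("CalibrationSpec", function(object) {
  msg <- character()
  for (s in c("sensitivity", "gain", "adcFullScale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(object@adcFullScale) == 1L &&
      is.finite(object@adcFullScale) && object@adcFullScale <= 0)
    msg <- c(msg, "'adcFullScale' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn CalibrationSpec-class Constructor.
#' @param sensitivity,gain,adcFullScale see slots.
#' @export
CalibrationSpec <- function(sensitivity = -186, gain = 20, adcFullScale = 1) {
  new("CalibrationSpec", sensitivity = sensitivity, gain = gain,
      adcFullScale = adcFullScale)
}

#' A mono audio clip
#'
#' A waveform of dimensionless ADC amplitudes in `[-1, 1]` together with
#' its sampling rate, and optionally a recording start time and a station
#' label. Duration is derived as `length(samples)/sampleRate`.
#'
#' @slot samples numeric vector of amplitudes (finite, nominally in
#'   `[-1, 1]`).
#' @slot sampleRate sampling frequency `fs`, Hz (> 0).
#' @slot startTime `POSIXct` recording start (may be empty).
#' @slot station free-text station label (may be `NA`).
#'
#' @seealso [readWav()], [writeWav()], [AudioClip()]
#' @export
setClass("AudioClip",
  representation(samples = "numeric", sampleRate = "numeric",
                 startTime = "POSIXct", station = "character"),
  prototype(samples = numeric(0), sampleRate = 80000,
            startTime = as.POSIXct(character(0), tz = "UTC"),
            station = NA_character_))

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must all be finite")
  if (length(object@startTime) > 1L)
    msg <- c(msg, "'startTime' must have length 0 or 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn AudioClip-class Constructor.
#' @param samples,sampleRate,startTime,station see slots.
#' @export
AudioClip <- function(samples, sampleRate, startTime = NULL,
                      station = NA_character_) {
  if (is.null(startTime)) startTime <- as.POSIXct(character(0), tz = "UTC")
  new("AudioClip", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate), startTime = startTime,
      station = station)
}

#' Frame matrix: a signal reorganized into overlapping analysis frames
#'
#' Columns are consecutive data frames of `windowW` samples; successive
#' frames start `repetitionP` samples apart, so the time step between
#' frames is `dtau = repetitionP/sampleRate` and adjacent frames share
#' `windowW - repetitionP` samples. Trailing samples that cannot fill a
#' complete window are dropped.
#'
#' @slot frames numeric matrix, `windowW` rows by frame count columns.
#' @slot windowW frame window size `w`, samples.
#' @slot repetitionP repetition (hop) parameter `p`, samples,
#'   `1 <= p <= w`.
#' @slot sampleRate Hz.
#'
#' @seealso [frameSignal()], [frameTimes()]
#' @export
setClass("FrameMatrix",
  representation(frames = "matrix", windowW = "integer",
                 repetitionP = "integer", sampleRate = "numeric"))

setValidity("FrameMatrix", function(object) {
  msg <- character()
  w <- object@windowW; p <- object@repetitionP
  if (length(w) != 1L || w < 1L) msg <- c(msg, "'windowW' must be >= 1")
  if (length(p) != 1L || p < 1L || p > w)
    msg <- c(msg, "'repetitionP' must satisfy 1 <= p <= w")
  if (nrow(object@frames) != w)
    msg <- c(msg, "frame matrix must have 'windowW' rows")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be positive")
  if (length(msg)) msg else TRUE
})

#' Calibrated time-by-frequency sound pressure level matrix
#'
#' Rows are time frames (step `dtau = p/fs`), columns are frequency bins
#' at centers `n*df`, `n = 0 .. floor(w/2)`, with `df = fs/w`. Element
#' values are calibrated SPL in dB re 1 uPa; zero-magnitude bins are
#' clamped to a finite dB floor so every element is finite.
#'
#' @slot levels numeric matrix, frames by bins, dB re 1 uPa.
#' @slot sampleRate Hz.
#' @slot windowW frame window `w`, samples.
#' @slot repetitionP hop `p`, samples.
#' @slot correction calibration correction factor `S`, dB.
#' @slot dbFloor floor applied to `20*log10(magnitude)` before
#'   calibration, dB.
#'
#' @seealso [splSpectrogram()], [spectrogram()], [freqBinCenters()]
#' @export
setClass("SPLSpectrogram",
  representation(levels = "matrix", sampleRate = "numeric",
                 windowW = "integer", repetitionP = "integer",
                 correction = "numeric", dbFloor = "numeric"))

setValidity("SPLSpectrogram", function(object) {
  msg <- character()
  w <- object@windowW
  if (ncol(object@levels) != floor(w / 2) + 1L)
    msg <- c(msg, "'levels' must have floor(w/2)+1 frequency columns")
  if (!all(is.finite(object@levels)))
    msg <- c(msg, "'levels' must be finite (dB floor should have clamped)")
  if (object@repetitionP < 1L || object@repetitionP > w)
    msg <- c(msg, "'repetitionP' must satisfy 1 <= p <= w")
  if (length(msg)) msg else TRUE
})

#' A species call template ("3D feature")
#'
#' A time-by-frequency surface of SPL values cut from a calibrated
#' spectrogram around one representative call, restricted to the species'
#' frequency band. Rows span the call duration, columns the frequency bins
#' whose centers lie inside `[bandLo, bandHi]`; the SPL values form the
#' third axis of the 3D surface. Matching is by normalized centered
#' correlation, so the surface must not be constant.
#'
#' @slot species species label, e.g. `"black_drum"`.
#' @slot featureId unique template identifier.
#' @slot surface numeric matrix (time frames by frequency bins), SPL dB.
#' @slot bandLo,bandHi frequency band limits, Hz.
#' @slot framingW,framingP the framing `(w, p)` the surface was built
#'   with; a spectrogram must use the same framing to be scanned.
#' @slot sampleRate Hz of the source recording.
#' @slot callType free text, e.g. `"grunt"`, `"drum"`, `"staccato"`.
#' @slot pulseCount number of pulses in the templated call (`NA` when not
#'   applicable).
#'
#' @seealso [extractFeature()], [applyPartitionPlane()]
#' @export
setClass("CallFeature",
  representation(species = "character", featureId = "character",
                 surface = "matrix", bandLo = "numeric", bandHi = "numeric",
                 framingW = "integer", framingP = "integer",
                 sampleRate = "numeric", callType = "character",
                 pulseCount = "numeric"))

setValidity("CallFeature", function(object) {
  msg <- character()
  s <- object@surface
  if (nrow(s) < 2L || ncol(s) < 2L)
    msg <- c(msg, "feature surface must be at least 2 x 2")
  if (!all(is.finite(s)))
    msg <- c(msg, "feature surface must be finite")
  else if (stats::var(as.vector(s)) == 0)
    msg <- c(msg, "feature surface must not be constant (zero variance)")
  if (object@bandLo >= object@bandHi)
    msg <- c(msg, "'bandLo' must be < 'bandHi'")
  if (object@bandHi > object@sampleRate / 2 + 1e-9)
    msg <- c(msg, "'bandHi' must be <= Nyquist")
  nb <- binsInBand(object@bandLo, object@bandHi, object@sampleRate,
                   object@framingW)
  if (ncol(s) != nb)
    msg <- c(msg, sprintf(
      "surface has %d frequency columns but band contains %d bin centers",
      ncol(s), nb))
  if (length(msg)) msg else TRUE
})

#' A library of call templates with per-species detector configuration
#'
#' Bundles [CallFeature-class] templates with a per-species configuration
#' table: framing `(w, p)`, detection threshold `theta`, non-maximum
#' suppression window (seconds; `NA` means one feature duration), and the
#' species frequency band.
#'
#' @slot features named list of [CallFeature-class] objects (names =
#'   feature ids).
#' @slot config data.frame with columns `species`, `windowW`,
#'   `repetitionP`, `threshold`, `nmsWindowS`, `bandLo`, `bandHi`.
#'
#' @seealso [FeatureLibrary()], [defaultSpeciesConfig()], [saveLibrary()]
#' @export
setClass("FeatureLibrary",
  representation(features = "list", config = "data.frame"))

setValidity("FeatureLibrary", function(object) {
  msg <- character()
  need <- c("species", "windowW", "repetitionP", "threshold",
            "nmsWindowS", "bandLo", "bandHi")
  if (!all(need %in% names(object@config)))
    msg <- c(msg, paste("config must have columns:",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(object@config$species))
    msg <- c(msg, "config has duplicated species rows")
  ids <- vapply(object@features, function(f) f@featureId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "feature ids must be unique")
  if (length(object@features) &&
      all(need %in% names(object@config))) {
    for (f in object@features) {
      row <- object@config[object@config$species == f@species, , drop = FALSE]
      if (nrow(row) == 0L) {
        msg <- c(msg, sprintf("species '%s' missing from config", f@species))
      } else if (row$windowW[1] != f@framingW ||
                 row$repetitionP[1] != f@framingP) {
        msg <- c(msg, sprintf(
          "feature '%s' framing (w=%d, p=%d) does not match its species config (w=%d, p=%d)",
          f@featureId, f@framingW, f@framingP,
          as.integer(row$windowW[1]), as.integer(row$repetitionP[1])))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureLibrary-class Constructor; names the feature list by
#'   feature id and keeps only config rows for species that need them.
#' @param features list of [CallFeature-class] objects.
#' @param config per-species configuration data.frame (defaults to
#'   [defaultSpeciesConfig()]).
#' @export
FeatureLibrary <- function(features, config = defaultSpeciesConfig()) {
  features <- as.list(features)
  names(features) <- vapply(features, function(f) f@featureId, character(1))
  new("FeatureLibrary", features = features, config = config)
}

#' Per-file detection summary
#'
#' Detector output for one audio file: per-species call counts after
#' non-maximum suppression, the best matching score per species, and the
#' table of surviving detections.
#'
#' @slot sourceFile file label.
#' @slot counts named integer vector, calls per species.
#' @slot bestScores named numeric vector, highest matching score per
#'   species (`NA` when no window was scored).
#' @slot detections data.frame with columns `species`, `featureId`,
#'   `timeOffset`, `score`, `bandLo`, `bandHi`, `sourceFile`.
#'
#' @seealso [detectFile()], [batchDetect()]
#' @export
setClass("FileDetectionSummary",
  representation(sourceFile = "character", counts = "integer",
                 bestScores = "numeric", detections = "data.frame"))

setValidity("FileDetectionSummary", function(object) {
  msg <- character()
  det <- object@detections
  if (nrow(det)) {
    tab <- table(det$species)
    for (sp in names(object@counts)) {
      n <- if (sp %in% names(tab)) as.integer(tab[[sp]]) else 0L
      if (object@counts[[sp]] != n)
        msg <- c(msg, sprintf("count for '%s' disagrees with detections", sp))
    }
  } else if (length(object@counts) && any(object@counts != 0L)) {
    msg <- c(msg, "nonzero counts with empty detection table")
  }
  if (length(msg)) msg else TRUE
})
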