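#' @rdname AudioClip-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname AudioClip-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname AudioClip-class
#' @export
setGeneric("station", function(x) standardGeneric("station"))
#' @rdname AudioClip-class
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname AudioClip-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname SPLSpectrogram-class
#' @export
setGeneric("splLevels", function(x) standardGeneric("splLevels"))
#' @rdname SPLSpectrogram-class
#' @export
setGeneric("freqBinCenters", function(x) standardGeneric("freqBinCenters"))
#' @rdname FrameMatrix-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname FeatureLibrary-class
#' @export
setGeneric("libFeatures", function(x) standardGeneric("libFeatures"))
#' @rdname FeatureLibrary-class
#' @export
setGeneric("speciesConfig", function(x) standardGeneric("speciesConfig"))

#' @rdname FileDetectionSummary-class
#' @export
setGeneric("callCounts", function(x) standardGeneric("callCounts"))
#' @rdname FileDetectionSummary-class
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

setMethod("samples", "AudioClip", function(x) x@samples)
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)
setMethod("station", "AudioClip", function(x) x@station)
setMethod("startTime", "AudioClip",
          function(x) if (length(x@startTime)) x@startTime else NULL)
setMethod("duration", "AudioClip",
          function(x) length(x@samples) / x@sampleRate)

setMethod("sampleRate", "FrameMatrix", function(x) x@sampleRate)
setMethod("sampleRate", "SPLSpectrogram", function(x) x@sampleRate)
setMethod("splLevels", "SPLSpectrogram", function(x) x@levels)
setMethod("freqBinCenters", "SPLSpectrogram", function(x)
  (0:floor(x@windowW / 2)) * x@sampleRate / x@windowW)
setMethod("freqBinCenters", "CallFeature", function(x)
  bandBinIndices(x@bandLo, x@bandHi, x@sampleRate, x@framingW) *
    x@sampleRate / x@framingW)

setMethod("libFeatures", "FeatureLibrary", function(x) x@features)
setMethod("speciesConfig", "FeatureLibrary", function(x) x@config)
setMethod("callCounts", "FileDetectionSummary", function(x) x@counts)
setMethod("detections", "FileDetectionSummary", function(x) x@detections)

#' @rdname CallFeature-class
#' @param x a `CallFeature`.
#' @export
featureDuration <- function(x) nrow(x@surface) * x@framingP / x@sampleRate

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %d samples @ %g Hz (%.3f s)",
              length(object@samples), object@sampleRate, duration(object)))
  if (!is.na(object@station)) cat(sprintf(", station %s", object@station))
  if (length(object@startTime))
    cat(sprintf(", start %s", format(object@startTime)))
  cat("\n")
})

setMethod("show", "CalibrationSpec", function(object) {
  cat(sprintf(
    "CalibrationSpec: h = %g dBV/uPa, g = %g dB, Vadc = %g V (S = %.2f dB)\n",
    object@sensitivity, object@gain, object@adcFullScale,
    correctionFactor(object)))
})

setMethod("show", "FrameMatrix", function(object) {
  cat(sprintf(
    "FrameMatrix: %d frames of w = %d samples, p = %d (overlap %d), fs = %g Hz, dtau = %g s\n",
    ncol(object@frames), object@windowW, object@repetitionP,
    object@windowW - object@repetitionP, object@sampleRate,
    object@repetitionP / object@sampleRate))
})

setMethod("show", "SPLSpectrogram", function(object) {
  cat(sprintf(
    "SPLSpectrogram: %d frames x %d bins, df = %g Hz, dtau = %g s, S = %.2f dB\n",
    nrow(object@levels), ncol(object@levels),
    object@sampleRate / object@windowW,
    object@repetitionP / object@sampleRate, object@correction))
})

setMethod("show", "CallFeature", function(object) {
  cat(sprintf(
    "CallFeature '%s' (%s%s): %d frames x %d bins, band %g-%g Hz, w = %d, p = %d\n",
    object@featureId, object@species,
    if (nzchar(object@callType) && !is.na(object@callType))
      paste0(", ", object@callType) else "",
    nrow(object@surface), ncol(object@surface), object@bandLo,
    object@bandHi, object@framingW, object@framingP))
})

setMethod("show", "FeatureLibrary", function(object) {
  sp <- vapply(object@features, function(f) f@species, character(1))
  cat(sprintf("FeatureLibrary: %d features\n", length(object@features)))
  if (length(sp)) {
    tab <- table(sp)
    for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  }
})

setMethod("show", "FileDetectionSummary", function(object) {
  cat(sprintf("FileDetectionSummary: %s\n", object@sourceFile))
  for (sp in names(object@counts))
    cat(sprintf("  %s: %d call(s)%s\n", sp, object@counts[[sp]],
                if (is.na(object@bestScores[[sp]])) "" else
                  sprintf(" (best s = %.3f)", object@bestScores[[sp]])))
})
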