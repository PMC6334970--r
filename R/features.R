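#' Default per-species detector configuration
#'
#' One row per species: framing `(w, p)`, detection threshold `theta`,
#' non-maximum suppression window (seconds; `NA` = one feature duration),
#' and the species frequency band. Framing choices follow the usual
#' trade-off: long narrowband callers (black drum) get a large window for
#' fine frequency resolution and a large hop, short pulsed callers
#' (silver perch, red drum) a small window and hop for fine time
#' resolution, spotted seatrout in between. All values are configuration,
#' not ground truth, and can be overridden per library.
#'
#' @param sampleRate Hz the framing is intended for (default 80000, the
#'   study recorder schedule).
#' @return data.frame with columns `species`, `windowW`, `repetitionP`,
#'   `threshold`, `nmsWindowS`, `bandLo`, `bandHi`.
#' @export
defaultSpeciesConfig <- function(sampleRate = 80000) {
  data.frame(
    species = c("black_drum", "silver_perch", "spotted_seatrout", "red_drum"),
    windowW = c(8192L, 2048L, 4096L, 2048L),
    repetitionP = c(2048L, 256L, 512L, 256L),
    threshold = c(0.5, 0.6, 0.6, 0.6),
    nmsWindowS = NA_real_,
    bandLo = c(80, 80, 80, 80),
    bandHi = c(400, 5000, 1000, 800),
    stringsAsFactors = FALSE)
}

#' Extract a call template from a spectrogram
#'
#' Cuts the sub-matrix of calibrated SPL covering time `[tStart, tEnd)`
#' (frame starts, half-open) and frequency `[bandLo, bandHi]` (bin
#' centers, inclusive) and labels it as a species call feature. The
#' selection must contain at least 2 frames and 2 bins and must not be
#' constant, because matching divides by the surface's centered sum of
#' squares.
#'
#' @param spec an [SPLSpectrogram-class].
#' @param tStart,tEnd time window in seconds (frame start times).
#' @param bandLo,bandHi frequency band in Hz.
#' @param species species label.
#' @param featureId unique identifier for the template.
#' @param callType free text (e.g. `"grunt"`, `"staccato"`).
#' @param pulseCount optional pulse count of the templated call.
#' @return a [CallFeature-class].
#' @export
extractFeature <- function(spec, tStart, tEnd, bandLo, bandHi, species,
                           featureId, callType = "", pulseCount = NA_real_) {
  stopifnot(is(spec, "SPLSpectrogram"))
  tt <- frameTimes(spec)
  rows <- which(tt >= tStart - 1e-12 & tt < tEnd - 1e-12)
  cols <- bandBinIndices(bandLo, bandHi, spec@sampleRate, spec@windowW) + 1L
  if (length(rows) == 0L || length(cols) == 0L)
    stop("empty selection: requested window lies outside the spectrogram")
  if (max(cols) > ncol(spec@levels))
    stop("band extends beyond the spectrogram's frequency range")
  surface <- spec@levels[rows, cols, drop = FALSE]
  if (stats::var(as.vector(surface)) == 0)
    stop("constant selection: feature surface would have zero variance")
  new("CallFeature", species = species, featureId = featureId,
      surface = surface, bandLo = as.numeric(bandLo),
      bandHi = as.numeric(bandHi), framingW = spec@windowW,
      framingP = spec@repetitionP, sampleRate = spec@sampleRate,
      callType = callType, pulseCount = as.numeric(pulseCount))
}

#' Restrict a template with a frequency partition plane
#'
#' Removes all frequency columns above the cut-off `fCut` and lowers the
#' template's upper band limit to `fCut`. Useful when a template's upper
#' frequency exceeds that of the calls it should detect (e.g. a black drum
#' template reaching 350 Hz cut at 250 Hz to match 280-Hz calls): the
#' retained lower-frequency structure generalizes across calls whose
#' maximum frequency varies. Applying the same cut twice is a no-op, and
#' cutting an extracted feature equals extracting with the reduced band
#' directly.
#'
#' @param feature a [CallFeature-class].
#' @param fCut cut-off frequency, Hz, `bandLo < fCut <= bandHi`.
#' @return a new [CallFeature-class]; the input is unchanged.
#' @export
applyPartitionPlane <- function(feature, fCut) {
  stopifnot(is(feature, "CallFeature"))
  if (fCut <= feature@bandLo || fCut > feature@bandHi + 1e-9)
    stop("'fCut' must lie in (bandLo, bandHi]")
  centers <- freqBinCenters(feature)
  keep <- centers <= fCut + 1e-9
  if (!any(keep)) stop("'fCut' removes every frequency column")
  surface <- feature@surface[, keep, drop = FALSE]
  if (ncol(surface) < 2L)
    stop("partition plane would leave fewer than 2 frequency columns")
  if (stats::var(as.vector(surface)) == 0)
    stop("partition plane would leave a constant surface")
  new("CallFeature", species = feature@species, featureId = feature@featureId,
      surface = surface, bandLo = feature@bandLo,
      bandHi = min(feature@bandHi, as.numeric(fCut)),
      framingW = feature@framingW, framingP = feature@framingP,
      sampleRate = feature@sampleRate, callType = feature@callType,
      pulseCount = feature@pulseCount)
}

#' Feature metadata as a data.frame
#'
#' One row per template: id, species, call type, pulse count, band,
#' framing, and surface dimensions. Used for CSV export and by the library
#' manifest.
#'
#' @param lib a [FeatureLibrary-class].
#' @return data.frame.
#' @export
featureMetadata <- function(lib) {
  stopifnot(is(lib, "FeatureLibrary"))
  do.call(rbind, c(list(data.frame(
    featureId = character(0), species = character(0), callType = character(0),
    pulseCount = numeric(0), bandLo = numeric(0), bandHi = numeric(0),
    framingW = integer(0), framingP = integer(0), sampleRate = numeric(0),
    nFrames = integer(0), nBins = integer(0), stringsAsFactors = FALSE)),
    lapply(lib@features, function(f) data.frame(
      featureId = f@featureId, species = f@species, callType = f@callType,
      pulseCount = f@pulseCount, bandLo = f@bandLo, bandHi = f@bandHi,
      framingW = f@framingW, framingP = f@framingP, sampleRate = f@sampleRate,
      nFrames = nrow(f@surface), nBins = ncol(f@surface),
      stringsAsFactors = FALSE))))
}
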