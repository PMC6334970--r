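#' Reorganize a signal into a matrix of data frames
#'
#' Column `n` (0-based) of the result holds samples `[n*p, n*p + w)` of
#' the signal (0-based, half-open), so successive frames start `p` samples
#' apart and adjacent frames share `w - p` samples. The frame count is
#' `floor((N - w)/p) + 1` for signal length `N >= w`; trailing samples
#' that cannot fill a complete window are dropped rather than zero-padded.
#' `p = 1` gives maximal overlap (frame time step equal to the sample
#' period); `p = w` tiles the signal without overlap.
#'
#' @param x an [AudioClip-class] or a numeric vector (then `sampleRate`
#'   must be given).
#' @param windowW frame window size `w` in samples (>= 1).
#' @param repetitionP repetition (hop) parameter `p` in samples,
#'   `1 <= p <= w`.
#' @param sampleRate Hz; ignored when `x` is an [AudioClip-class].
#' @return a [FrameMatrix-class].
#' @examples
#' fm <- frameSignal(1:7, windowW = 4, repetitionP = 1, sampleRate = 10)
#' dim(fm@frames)  # 4 x 4
#' @export
frameSignal <- function(x, windowW, repetitionP, sampleRate = NULL) {
  if (is(x, "AudioClip")) {
    sampleRate <- x@sampleRate
    x <- x@samples
  }
  if (is.null(sampleRate)) stop("'sampleRate' required for a bare vector")
  w <- as.integer(windowW)
  p <- as.integer(repetitionP)
  if (is.na(w) || w < 1L) stop("'windowW' must be a positive integer")
  if (is.na(p) || p < 1L) stop("'repetitionP' must be a positive integer")
  if (p > w) stop("'repetitionP' must not exceed 'windowW'")
  n <- length(x)
  if (n < w) stop("signal shorter than one frame window (", n, " < ", w, ")")
  nFrames <- (n - w) %/% p + 1L
  idx <- rep.int(seq_len(w), nFrames) +
    rep((seq_len(nFrames) - 1L) * p, each = w)
  new("FrameMatrix", frames = matrix(x[idx], nrow = w),
      windowW = w, repetitionP = p, sampleRate = as.numeric(sampleRate))
}

#' @describeIn frameSignal Frame start times `tau_n = n*p/fs` (seconds,
#'   0-based; `tau_0 = 0`). With `p = 1` the frame step equals the sample
#'   period `1/fs`.
#' @param x a [FrameMatrix-class] or [SPLSpectrogram-class].
#' @export
setMethod("frameTimes", "FrameMatrix", function(x)
  (seq_len(ncol(x@frames)) - 1L) * x@repetitionP / x@sampleRate)

setMethod("frameTimes", "SPLSpectrogram", function(x)
  (seq_len(nrow(x@levels)) - 1L) * x@repetitionP / x@sampleRate)

#' Frequency resolution of a frame matrix
#'
#' `df = fs/w`: the spacing of the frequency bin centers obtained from a
#' `w`-point transform of each data frame. Acoustic energy between bin
#' centers is not separately resolved, so `w` must be chosen large enough
#' that a species' band spans several bins: e.g. at `fs = 80` kHz and
#' `w = 4096`, `df = 19.53` Hz and the 80-400 Hz black drum band covers
#' only 16 bins.
#'
#' @param sampleRate Hz.
#' @param windowW frame window size in samples.
#' @return resolution in Hz.
#' @export
freqResolution <- function(sampleRate, windowW) {
  if (windowW < 1) stop("'windowW' must be >= 1")
  sampleRate / windowW
}

#' Indices of frequency bins inside a band
#'
#' Bin centers are `n*df`, `n >= 1` (DC excluded); a bin belongs to the
#' band when `bandLo <= n*df <= bandHi`, judged with a small relative
#' tolerance so that bands specified exactly at bin centers are inclusive.
#'
#' @param bandLo,bandHi band limits in Hz, `0 <= bandLo < bandHi <=
#'   sampleRate/2`.
#' @param sampleRate Hz.
#' @param windowW frame window size in samples.
#' @return `bandBinIndices`: integer vector of bin indices `n`;
#'   `binsInBand`: their count.
#' @examples
#' binsInBand(80, 400, 80000, 4096)  # 16
#' @export
bandBinIndices <- function(bandLo, bandHi, sampleRate, windowW) {
  if (bandLo < 0 || bandLo >= bandHi || bandHi > sampleRate / 2 + 1e-9)
    stop("invalid band: need 0 <= bandLo < bandHi <= sampleRate/2")
  df <- sampleRate / windowW
  nLo <- max(1L, as.integer(ceiling(bandLo / df - 1e-9)))
  nHi <- as.integer(floor(bandHi / df + 1e-9))
  if (nHi < nLo) return(integer(0))
  seq.int(nLo, nHi)
}

#' @rdname bandBinIndices
#' @export
binsInBand <- function(bandLo, bandHi, sampleRate, windowW) {
  length(bandBinIndices(bandLo, bandHi, sampleRate, windowW))
}

#' Calibrated SPL spectrogram from a frame matrix
#'
#' Each data frame (column) is transformed with a `w`-point discrete
#' Fourier transform under a rectangular taper (the framing construction
#' implies no taper), converted to a single-sided amplitude spectrum, and
#' expressed in dB; the calibration correction `S` is subtracted to give
#' per-bin SPL in dB re 1 uPa. Zero-magnitude bins are clamped at
#' `dbFloor` (before calibration) so the matrix stays finite — digital
#' silence therefore yields a constant matrix, which the detector scores
#' as 0, never as a match.
#'
#' @param fm a [FrameMatrix-class].
#' @param cal a [CalibrationSpec-class].
#' @param dbFloor clamp for `20*log10(magnitude)`, dB. Default -200.
#' @return an [SPLSpectrogram-class]: rows = frames, columns = bins
#'   `0..floor(w/2)`.
#' @seealso [spectrogram()] for the one-call wrapper.
#' @export
splSpectrogram <- function(fm, cal, dbFloor = -200) {
  stopifnot(is(fm, "FrameMatrix"), is(cal, "CalibrationSpec"))
  w <- fm@windowW
  nb <- floor(w / 2) + 1L
  Z <- stats::mvfft(fm@frames)
  amp <- Mod(Z[seq_len(nb), , drop = FALSE]) / w
  if (nb > 2L) {
    interior <- 2:(nb - 1L)
    if (w %% 2L == 1L) interior <- 2:nb
    amp[interior, ] <- 2 * amp[interior, , drop = FALSE]
  }
  lev <- 20 * log10(amp)
  lev[!is.finite(lev) | lev < dbFloor] <- dbFloor
  lev <- lev - correctionFactor(cal)
  new("SPLSpectrogram", levels = t(lev), sampleRate = fm@sampleRate,
      windowW = w, repetitionP = fm@repetitionP,
      correction = correctionFactor(cal), dbFloor = dbFloor)
}

#' Frame and transform a clip in one call
#'
#' Convenience wrapper: `splSpectrogram(frameSignal(clip, w, p), cal)`.
#'
#' @inheritParams frameSignal
#' @inheritParams splSpectrogram
#' @param clip an [AudioClip-class].
#' @return an [SPLSpectrogram-class].
#' @export
spectrogram <- function(clip, windowW, repetitionP, cal = CalibrationSpec(),
                        dbFloor = -200) {
  splSpectrogram(frameSignal(clip, windowW, repetitionP), cal,
                 dbFloor = dbFloor)
}
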