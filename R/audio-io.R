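#' Calibration correction factor
#'
#' `S = h + g + 20*log10(1/Vadc)`: the constant offset between the
#' uncalibrated dB level of the digitized signal and sound pressure level
#' in dB re 1 uPa. With the default chain (`h = -186`, `g = 20`,
#' `Vadc = 1`) the factor is `-166` dB.
#'
#' @param cal a [CalibrationSpec-class].
#' @return correction factor `S` in dB.
#' @examples
#' correctionFactor(CalibrationSpec())  # -166
#' @export
correctionFactor <- function(cal) {
  stopifnot(is(cal, "CalibrationSpec"))
  cal@sensitivity + cal@gain + 20 * log10(1 / cal@adcFullScale)
}

#' Broadband sound pressure level of a signal segment
#'
#' Calibrated broadband level `a = b - S`, where `b` is the uncalibrated
#' level of the segment and `S = correctionFactor(cal)`. The default mode
#' is the standard RMS level `b = 10*log10(mean(y^2)) = 20*log10(rms(y))`.
#' `mode = "printed"` instead uses `b = 20*log10(mean(y^2))`, a doubled-dB
#' variant occasionally seen in calibration write-ups; because template
#' matching is invariant to any constant dB offset, the choice does not
#' affect detection, only absolute reported levels.
#'
#' @param segment numeric vector of amplitudes (non-empty).
#' @param cal a [CalibrationSpec-class].
#' @param mode `"rms"` (default) or `"printed"`, see Details.
#' @param zeroAction what to do for an all-zero segment: `"error"`
#'   (default) or `"sentinel"`, which returns `-Inf` with a warning.
#'   Silence never produces a silent `NaN`.
#' @return level in dB re 1 uPa.
#' @examples
#' broadbandSPL(rep(1, 100), CalibrationSpec())  # 166
#' @export
broadbandSPL <- function(segment, cal, mode = c("rms", "printed"),
                         zeroAction = c("error", "sentinel")) {
  mode <- match.arg(mode)
  zeroAction <- match.arg(zeroAction)
  stopifnot(is(cal, "CalibrationSpec"))
  if (length(segment) == 0L) stop("empty segment")
  if (!all(is.finite(segment))) stop("segment must be finite")
  ms <- mean(segment^2)
  if (ms == 0) {
    if (zeroAction == "error")
      stop("all-zero segment: broadband level is undefined")
    warning("all-zero segment: returning -Inf")
    return(-Inf)
  }
  b <- if (mode == "rms") 10 * log10(ms) else 20 * log10(ms)
  b - correctionFactor(cal)
}

## ---- WAV I/O ---------------------------------------------------------------
## Minimal RIFF/WAVE codec: PCM integer (8/16/24/32 bit) and IEEE float 32,
## including WAVE_FORMAT_EXTENSIBLE wrappers. No installed R package reads
## WAV, so the container is parsed here directly.

#' Read a PCM WAV file as a mono [AudioClip-class]
#'
#' Supports integer PCM (8, 16, 24, 32 bit) and 32-bit IEEE float, mono or
#' multichannel (channel 0 is kept; study hardware is single-hydrophone).
#' Integer samples are scaled to `[-1, 1]` by the PCM full-scale value
#' `2^(bits-1)`; 8-bit WAV is unsigned per the format.
#'
#' @param path path to a `.wav` file.
#' @param station optional station label stored on the clip.
#' @param startTime optional `POSIXct` recording start stored on the clip.
#' @return an [AudioClip-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path, station = NA_character_, startTime = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L || rawToChar(hdr[1:4]) != "RIFF" ||
      rawToChar(hdr[9:12]) != "WAVE")
    stop("unsupported format: not a RIFF/WAVE file: ", path)
  fmt <- NULL
  dataRaw <- NULL
  repeat {
    idRaw <- readBin(con, "raw", 4L)
    if (length(idRaw) < 4L) break
    id <- rawToChar(idRaw)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    if (id == "fmt ") {
      fmt <- .parseFmtChunk(readBin(con, "raw", sz))
    } else if (id == "data") {
      dataRaw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # pad byte
  }
  if (is.null(fmt)) stop("unsupported format: no fmt chunk in ", path)
  if (is.null(dataRaw)) stop("unsupported format: no data chunk in ", path)
  x <- .decodePcm(dataRaw, fmt)
  if (fmt$nChannels > 1L)
    x <- x[seq(1L, length(x), by = fmt$nChannels)]
  AudioClip(x, fmt$sampleRate, startTime = startTime, station = station)
}

.parseFmtChunk <- function(raw) {
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  fmt <- list(audioFormat = u16(0L), nChannels = as.integer(u16(2L)),
              sampleRate = u32(4L), bitsPerSample = as.integer(u16(14L)))
  if (fmt$audioFormat == 65534L) {         # WAVE_FORMAT_EXTENSIBLE
    if (length(raw) < 26L)
      stop("unsupported format: truncated extensible fmt chunk")
    fmt$audioFormat <- u16(24L)            # first 2 bytes of the sub-format GUID
  }
  if (!fmt$audioFormat %in% c(1L, 3L))
    stop("unsupported format: compressed or non-PCM WAV (format code ",
         fmt$audioFormat, ")")
  if (fmt$audioFormat == 1L && !fmt$bitsPerSample %in% c(8L, 16L, 24L, 32L))
    stop("unsupported format: ", fmt$bitsPerSample, "-bit integer PCM")
  if (fmt$audioFormat == 3L && fmt$bitsPerSample != 32L)
    stop("unsupported format: ", fmt$bitsPerSample, "-bit float PCM")
  fmt
}

.decodePcm <- function(dataRaw, fmt) {
  bits <- fmt$bitsPerSample
  n <- length(dataRaw) %/% (bits %/% 8L)
  if (fmt$audioFormat == 3L)
    return(readBin(dataRaw, "numeric", n, size = 4L, endian = "little"))
  switch(as.character(bits),
    "8" = (readBin(dataRaw, "integer", n, size = 1L, signed = FALSE) - 128) / 128,
    "16" = readBin(dataRaw, "integer", n, size = 2L, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      b <- matrix(as.integer(dataRaw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "32" = readBin(dataRaw, "integer", n, size = 4L, signed = TRUE,
                   endian = "little") / 2147483648)
}

#' Write an [AudioClip-class] as a WAV file
#'
#' Samples are clamped to `[-1, 1 - 1/2^(bits-1)]` and quantized to the
#' requested integer depth, or written untouched as 32-bit IEEE float.
#'
#' @param clip an [AudioClip-class].
#' @param path output path.
#' @param bitDepth one of 8, 16 (default), 24, 32, or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path, bitDepth = 16) {
  stopifnot(is(clip, "AudioClip"))
  isFloat <- identical(bitDepth, "float32")
  bits <- if (isFloat) 32L else as.integer(bitDepth)
  if (!isFloat && !bits %in% c(8L, 16L, 24L, 32L))
    stop("unsupported bit depth: ", bitDepth)
  x <- clip@samples
  n <- length(x)
  bytesPerSample <- bits %/% 8L
  dataSize <- n * bytesPerSample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(if (isFloat) 3L else 1L, 1L), con, size = 2L, endian = "little")
  writeBin(as.integer(clip@sampleRate), con, size = 4L, endian = "little")
  writeBin(as.integer(clip@sampleRate * bytesPerSample), con, size = 4L,
           endian = "little")
  writeBin(c(bytesPerSample, bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (isFloat) {
    writeBin(x, con, size = 4L, endian = "little")
  } else {
    full <- 2^(bits - 1)
    q <- round(pmin(pmax(x, -1), 1 - 1 / full) * full)
    if (bits == 8L) {
      writeBin(as.raw(q + 128), con)
    } else if (bits == 24L) {
      v <- ifelse(q < 0, q + 16777216, q)
      b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
      writeBin(as.raw(b), con)
    } else {
      writeBin(as.integer(q), con, size = bytesPerSample, endian = "little")
    }
  }
  invisible(path)
}
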