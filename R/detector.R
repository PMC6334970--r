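#' Matching score between a template and a candidate window
#'
#' The normalized centered correlation of two equally-shaped SPL matrices:
#' \deqn{s = \frac{\sum_{m,n}(A_{mn}-\bar A)(B_{mn}-\bar B)}
#'   {\sqrt{\sum_{m,n}(A_{mn}-\bar A)^2 \sum_{m,n}(B_{mn}-\bar B)^2}}}
#' equivalently the product-moment correlation of the flattened matrices.
#' Bounded in `[-1, 1]` by Cauchy-Schwarz; invariant under affine
#' rescaling `B -> alpha*B + beta` (`alpha > 0`), which is why constant
#' calibration offsets never affect detection. A zero-variance input
#' (digital silence) scores 0 with a warning rather than dividing by
#' zero.
#'
#' @param A,B numeric matrices of identical shape.
#' @return score `s` in `[-1, 1]`.
#' @examples
#' A <- matrix(rnorm(20), 5)
#' matchScore(A, 2 * A + 3)  # 1
#' @export
matchScore <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("'A' and 'B' must have the same shape")
  a <- A - mean(A)
  b <- B - mean(B)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) {
    warning("zero-variance input: score defined as 0")
    return(0)
  }
  sum(a * b) / den
}

## Matching scores of one template at every time offset of a spectrogram,
## restricted to the template's frequency rows. Numerator via direct
## column-wise cross-correlation (stats::filter, convolution method);
## denominator via moving window sums. Returns the full score vector.
.scanScores <- function(B, A) {
  m <- nrow(A); n <- ncol(A); Tn <- nrow(B)
  nOff <- Tn - m + 1L
  A0 <- A - mean(A)
  sumA2 <- sum(A0 * A0)
  num <- numeric(nOff)
  for (j in seq_len(n)) {
    y <- stats::filter(B[, j], rev(A0[, j]), method = "convolution",
                       sides = 1)
    num <- num + y[m:Tn]
  }
  ones <- rep(1, m)
  s1 <- stats::filter(rowSums(B), ones, method = "convolution",
                      sides = 1)[m:Tn]
  s2 <- stats::filter(rowSums(B * B), ones, method = "convolution",
                      sides = 1)[m:Tn]
  varB <- s2 - s1 * s1 / (m * n)
  varB[varB < 0] <- 0
  den <- sqrt(sumA2 * varB)
  tiny <- (m * n) * 1e-8
  score <- ifelse(varB <= tiny | sumA2 <= tiny, 0, num / den)
  pmin(1, pmax(-1, score))
}

## Greedy non-maximum suppression: keep candidates in decreasing score
## (ties to the earlier offset); drop any candidate within 'win' frames of
## an already-kept one.
.nonMaxSuppress <- function(offsets, scores, win) {
  keep <- logical(length(offsets))
  for (i in order(-scores, offsets)) {
    if (!any(keep & abs(offsets - offsets[i]) < win)) keep[i] <- TRUE
  }
  which(keep)
}

#' Scan a spectrogram with one call template
#'
#' Computes the matching score at every time offset (the template's
#' frequency rows are fixed to its band; only time is scanned), keeps
#' offsets scoring at least `threshold`, and suppresses candidates lying
#' within one suppression window of a higher-scoring candidate so a
#' single call yields a single detection. Ties in score are broken toward
#' the earlier offset.
#'
#' @param spec an [SPLSpectrogram-class] built with the template's
#'   framing `(w, p)` and sampling rate.
#' @param feature a [CallFeature-class].
#' @param threshold detection threshold `theta` on the score.
#' @param nmsWindowS suppression window in seconds; `NULL` (default) uses
#'   the feature duration.
#' @param sourceFile label recorded on each detection.
#' @return data.frame with columns `species`, `featureId`, `timeOffset`
#'   (s, start of matched window), `score`, `bandLo`, `bandHi`,
#'   `sourceFile`, sorted by time.
#' @export
scanFeature <- function(spec, feature, threshold = NULL, nmsWindowS = NULL,
                        sourceFile = NA_character_) {
  stopifnot(is(spec, "SPLSpectrogram"), is(feature, "CallFeature"))
  if (spec@windowW != feature@framingW ||
      spec@repetitionP != feature@framingP ||
      spec@sampleRate != feature@sampleRate)
    stop("framing mismatch: spectrogram (w=", spec@windowW, ", p=",
         spec@repetitionP, ", fs=", spec@sampleRate,
         ") vs feature (w=", feature@framingW, ", p=", feature@framingP,
         ", fs=", feature@sampleRate, ")")
  if (is.null(threshold)) threshold <- 0.6
  cols <- bandBinIndices(feature@bandLo, feature@bandHi, spec@sampleRate,
                         spec@windowW) + 1L
  if (max(cols) > ncol(spec@levels))
    stop("feature band lies outside the spectrogram's frequency range")
  if (ncol(feature@surface) != length(cols))
    stop("feature band/bin mismatch against this spectrogram")
  B <- spec@levels[, cols, drop = FALSE]
  m <- nrow(feature@surface)
  if (nrow(B) < m) return(.emptyDetections())
  score <- .scanScores(B, feature@surface)
  cand <- which(score >= threshold)
  if (length(cand) == 0L) return(.emptyDetections())
  win <- if (is.null(nmsWindowS) || is.na(nmsWindowS)) m else
    max(1L, as.integer(round(nmsWindowS * spec@sampleRate / spec@repetitionP)))
  keep <- cand[.nonMaxSuppress(cand, score[cand], win)]
  keep <- sort(keep)
  data.frame(species = feature@species, featureId = feature@featureId,
             timeOffset = (keep - 1L) * spec@repetitionP / spec@sampleRate,
             score = score[keep], bandLo = feature@bandLo,
             bandHi = feature@bandHi, sourceFile = sourceFile,
             stringsAsFactors = FALSE)
}

.emptyDetections <- function() {
  data.frame(species = character(0), featureId = character(0),
             timeOffset = numeric(0), score = numeric(0),
             bandLo = numeric(0), bandHi = numeric(0),
             sourceFile = character(0), stringsAsFactors = FALSE)
}

## Merge detections of one species across its templates: keep the
## highest-scoring detection among any that overlap within the suppression
## window (seconds).
.mergeSpeciesDetections <- function(det, winS) {
  if (nrow(det) <= 1L) return(det)
  idx <- .nonMaxSuppress(det$timeOffset, det$score, winS)
  det[sort(idx), , drop = FALSE]
}

#' Detect and count calls of every library species in one clip
#'
#' For each distinct framing `(w, p)` in the library configuration the
#' clip is framed and transformed once; every template of the species
#' sharing that framing then scans the spectrogram. Detections of one
#' species coming from different templates are merged by time-window
#' non-maximum suppression (multiple templates represent one call type),
#' and the survivors are counted.
#'
#' @param clip an [AudioClip-class].
#' @param lib a [FeatureLibrary-class] (non-empty).
#' @param cal a [CalibrationSpec-class].
#' @param sourceFile label for the clip (defaults to its station or
#'   `"clip"`).
#' @return a [FileDetectionSummary-class].
#' @export
detectFile <- function(clip, lib, cal = CalibrationSpec(),
                       sourceFile = NULL) {
  stopifnot(is(clip, "AudioClip"), is(lib, "FeatureLibrary"))
  if (length(lib@features) == 0L) stop("empty feature library")
  if (is.null(sourceFile))
    sourceFile <- if (!is.na(clip@station)) clip@station else "clip"
  cfg <- lib@config
  featSpecies <- vapply(lib@features, function(f) f@species, character(1))
  speciesHere <- unique(featSpecies)
  cfg <- cfg[cfg$species %in% speciesHere, , drop = FALSE]
  shortest <- cfg$species[length(clip@samples) < cfg$windowW]
  if (length(shortest))
    stop("clip shorter than the frame window of species: ",
         paste(shortest, collapse = ", "))
  det <- .emptyDetections()
  for (key in unique(paste(cfg$windowW, cfg$repetitionP))) {
    sub <- cfg[paste(cfg$windowW, cfg$repetitionP) == key, , drop = FALSE]
    spec <- spectrogram(clip, sub$windowW[1], sub$repetitionP[1], cal)
    for (i in seq_len(nrow(sub))) {
      sp <- sub$species[i]
      for (f in lib@features[featSpecies == sp]) {
        det <- rbind(det, scanFeature(spec, f, threshold = sub$threshold[i],
                                      nmsWindowS = sub$nmsWindowS[i],
                                      sourceFile = sourceFile))
      }
    }
  }
  merged <- .emptyDetections()
  counts <- integer(length(speciesHere)); names(counts) <- speciesHere
  best <- rep(NA_real_, length(speciesHere)); names(best) <- speciesHere
  for (sp in speciesHere) {
    spDet <- det[det$species == sp, , drop = FALSE]
    row <- cfg[cfg$species == sp, , drop = FALSE]
    winS <- row$nmsWindowS[1]
    if (is.na(winS)) {
      durs <- vapply(lib@features[featSpecies == sp], featureDuration,
                     numeric(1))
      winS <- max(durs)
    }
    spDet <- .mergeSpeciesDetections(spDet, winS)
    counts[sp] <- nrow(spDet)
    if (nrow(spDet)) best[sp] <- max(spDet$score)
    merged <- rbind(merged, spDet)
  }
  merged <- merged[order(merged$timeOffset), , drop = FALSE]
  rownames(merged) <- NULL
  new("FileDetectionSummary", sourceFile = sourceFile, counts = counts,
      bestScores = best, detections = merged)
}

#' Batch detection over many WAV files
#'
#' Runs [detectFile()] over each path; a file that fails to read or
#' process is recorded in the failure table and skipped, never fatal.
#'
#' @param paths character vector of WAV paths.
#' @param lib a [FeatureLibrary-class].
#' @param cal a [CalibrationSpec-class].
#' @param verbose log one line per file via `message()`.
#' @return list with elements `summaries` (data.frame: one row per
#'   successful file, per-species count columns), `detections`
#'   (data.frame of all merged detections), `failures` (data.frame:
#'   `sourceFile`, `error`), and `status` (0 = clean, 1 = partial
#'   failures).
#' @export
batchDetect <- function(paths, lib, cal = CalibrationSpec(),
                        verbose = FALSE) {
  stopifnot(is(lib, "FeatureLibrary"))
  speciesHere <- unique(vapply(lib@features, function(f) f@species,
                               character(1)))
  sumRows <- list(); detRows <- list(); failRows <- list()
  for (pathI in paths) {
    res <- tryCatch({
      clip <- readWav(pathI)
      detectFile(clip, lib, cal, sourceFile = basename(pathI))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message("FAIL ", pathI, ": ", conditionMessage(res))
      failRows[[length(failRows) + 1L]] <-
        data.frame(sourceFile = basename(pathI),
                   error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      if (verbose)
        message("ok   ", pathI, ": ",
                paste(names(res@counts), res@counts, sep = "=",
                      collapse = " "))
      row <- data.frame(sourceFile = res@sourceFile,
                        stringsAsFactors = FALSE)
      for (sp in speciesHere) row[[sp]] <- res@counts[[sp]]
      sumRows[[length(sumRows) + 1L]] <- row
      if (nrow(res@detections))
        detRows[[length(detRows) + 1L]] <- res@detections
    }
  }
  list(
    summaries = if (length(sumRows)) do.call(rbind, sumRows) else
      data.frame(sourceFile = character(0)),
    detections = if (length(detRows)) do.call(rbind, detRows) else
      .emptyDetections(),
    failures = if (length(failRows)) do.call(rbind, failRows) else
      data.frame(sourceFile = character(0), error = character(0)),
    status = if (length(failRows)) 1L else 0L)
}
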