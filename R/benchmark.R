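## The synthetic benchmark: a seeded suite of clips with ground-truth
## manifests used to calibrate the detector and to measure recovery
## (precision/recall) without field data.

## Template variants per species; the same variants are drawn from when
## injecting benchmark calls (with small onset-grid and frequency jitter),
## mirroring how a field library contains the repertoire it later detects.
.templateVariants <- function() {
  list(
    black_drum = list(
      list(callType = "drum", params = list(f0 = 100, nHarmonics = 3)),
      list(callType = "drum", params = list(f0 = 130, nHarmonics = 3))),
    silver_perch = list(
      list(callType = "pulse_train", params = list(nPulses = 5)),
      list(callType = "pulse_train", params = list(nPulses = 13))),
    spotted_seatrout = list(
      list(callType = "grunt", params = list(nPulses = 8)),
      list(callType = "staccato", params = list(nPulses = 21)),
      list(callType = "drum", params = list(nPulses = 5, pulseRate = 10))),
    red_drum = list(
      list(callType = "pulse_train", params = list(nPulses = 3)),
      list(callType = "pulse_train", params = list(nPulses = 5))))
}

#' Build the default synthetic feature library
#'
#' Synthesizes one representative call per template variant (two black
#' drum harmonic calls, 5- and 13-pulse silver perch trains, seatrout
#' grunt/staccato/drum, 3- and 5-pulse red drum calls) over the reference
#' Gaussian background at high SNR, computes each species' spectrogram
#' with its configured framing, and extracts the call surface as a
#' template. Deterministic given `seed`.
#'
#' @param seed integer RNG seed.
#' @param cal a [CalibrationSpec-class].
#' @param config per-species configuration (default
#'   [defaultSpeciesConfig()]).
#' @param templateSnrDb SNR at which templates are synthesized; high so
#'   the template is dominated by call structure, over a noise floor
#'   comparable to the scanning background.
#' @param noiseRms background RMS for template synthesis.
#' @return a [FeatureLibrary-class].
#' @export
buildDefaultLibrary <- function(seed = 1, cal = CalibrationSpec(),
                                config = defaultSpeciesConfig(),
                                templateSnrDb = 25, noiseRms = 0.01) {
  variants <- .templateVariants()
  features <- list()
  k <- 0L
  for (sp in names(variants)) {
    cfg <- config[config$species == sp, , drop = FALSE]
    if (nrow(cfg) == 0L) next
    for (v in variants[[sp]]) {
      k <- k + 1L
      wave <- .speciesCall(sp, v$callType, v$params)
      callDur <- length(wave) / 80000
      res <- assembleSoundscape(
        events = list(list(species = sp, callType = v$callType,
                           onsetS = 0.5, snrDb = templateSnrDb,
                           params = v$params)),
        background = list(noiseRms = noiseRms, shrimpRate = 0),
        durationS = callDur + 1.0, sampleRate = 80000,
        seed = seed * 1000 + k, clipId = sprintf("template_%02d", k))
      spec <- spectrogram(res$clip, cfg$windowW, cfg$repetitionP, cal)
      feat <- extractFeature(
        spec, 0.5, 0.5 + callDur, cfg$bandLo, cfg$bandHi, sp,
        featureId = sprintf("%s_%s_%02d", sp, v$callType, k),
        callType = v$callType,
        pulseCount = if (is.null(v$params$nPulses)) NA_real_ else
          v$params$nPulses)
      features[[length(features) + 1L]] <- feat
      # black drum upper harmonics vary call to call; a partition-planed
      # copy restricted below 280 Hz generalizes across that variation
      if (sp == "black_drum" && cfg$bandHi > 280) {
        cut <- applyPartitionPlane(feat, 280)
        cut@featureId <- paste0(feat@featureId, "_cut280")
        features[[length(features) + 1L]] <- cut
      }
    }
  }
  FeatureLibrary(features, config)
}

.callDuration <- function(species, callType, params)
  length(.speciesCall(species, callType, params)) / 80000

## Jitter a variant's synthesis parameters slightly so injected calls are
## not bit-identical to the templates.
.jitterParams <- function(species, callType, params) {
  if (species == "black_drum") {
    params$f0 <- (if (is.null(params$f0)) 100 else params$f0) +
      stats::runif(1, -3, 3)
  } else {
    base <- if (!is.null(params$pulseRate)) params$pulseRate
      else if (species == "silver_perch") 12
      else if (species == "red_drum") 7
      else if (identical(callType, "staccato")) 16
      else 22
    params$pulseRate <- base * stats::runif(1, 0.96, 1.04)
  }
  params
}

#' Generate the seeded synthetic benchmark suite
#'
#' Writes, per species, a fixed set of clips with ground-truth JSON
#' manifests: isolated single calls, multi-call clips with well-separated
#' calls, chorus clips with overlapping calls, shrimp-heavy clips, clips
#' masked by low-frequency boat-like noise bursts, and background-only
#' clips. An `index.json` lists every clip with its species, condition
#' and sub-seed. Regenerating with the same seed reproduces the suite
#' exactly.
#'
#' @param dir output directory (created).
#' @param seed integer master seed.
#' @param durationS clip length in seconds.
#' @param snrDb in-band SNR of injected calls.
#' @param nIsolated,nMulti,nChorus,nShrimp,nNoise,nSilent clips per
#'   condition per species.
#' @param species species to include.
#' @param writeWavFiles write WAV files (`TRUE`, the default) or keep
#'   clips only in memory (the returned index then carries the clips).
#' @return invisibly, a list: `index` (data.frame of clips) and
#'   `manifests` (named list), plus `clips` when
#'   `writeWavFiles = FALSE`.
#' @export
makeBenchmark <- function(dir, seed = 1, durationS = 8, snrDb = 20,
                          nIsolated = 10, nMulti = 10, nChorus = 2,
                          nShrimp = 2, nNoise = 2, nSilent = 1,
                          species = sciaenidSpecies,
                          writeWavFiles = TRUE) {
  if (writeWavFiles) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  variants <- .templateVariants()
  conditions <- c(rep("isolated", nIsolated), rep("multi", nMulti),
                  rep("chorus", nChorus), rep("shrimp_heavy", nShrimp),
                  rep("noise_masked", nNoise), rep("silent", nSilent))
  idxRows <- list(); manifests <- list(); clips <- list()
  clipNo <- 0L
  for (sp in species) {
    condCount <- table(factor(conditions, levels = unique(conditions)))
    seen <- integer(length(condCount)); names(seen) <- names(condCount)
    for (cond in conditions) {
      clipNo <- clipNo + 1L
      seen[cond] <- seen[cond] + 1L
      clipId <- sprintf("%s_%s_%02d", sp, cond, seen[cond])
      subSeed <- (seed * 7919L + clipNo * 104729L) %% 2000000000L
      res <- withr::with_seed(subSeed, .benchmarkClip(
        sp, cond, variants[[sp]], durationS, snrDb, clipId))
      res$manifest$rngSeed <- subSeed
      if (writeWavFiles) {
        writeWav(res$clip, file.path(dir, paste0(clipId, ".wav")))
        writeManifest(res$manifest, file.path(dir, paste0(clipId, ".json")))
      } else {
        clips[[clipId]] <- res$clip
      }
      manifests[[clipId]] <- res$manifest
      idxRows[[length(idxRows) + 1L]] <- data.frame(
        clipId = clipId, species = sp, condition = cond, seed = subSeed,
        nEvents = nrow(res$manifest$events), stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, idxRows)
  if (writeWavFiles)
    jsonlite::write_json(list(seed = seed, durationS = durationS,
                              snrDb = snrDb, clips = index),
                         file.path(dir, "index.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  out <- list(index = index, manifests = manifests)
  if (!writeWavFiles) out$clips <- clips
  invisible(out)
}

## Low-frequency, burst-modulated colored noise standing in for boat
## passage; first-order autoregressive noise concentrates energy at the
## bottom of the band where it masks drum calls.
.synthBoatNoise <- function(durationS, sampleRate) {
  n <- round(durationS * sampleRate)
  x <- as.numeric(stats::filter(stats::rnorm(n), 0.995,
                                method = "recursive"))
  burst <- round(stats::runif(1, 0.3, 0.6) * n)
  at <- round(stats::runif(1, 0, n - burst))
  env <- numeric(n)
  env[(at + 1):(at + burst)] <- sin(pi * seq_len(burst) / burst)^2
  x * env / stats::sd(x)
}

## One benchmark clip; assumes the caller scoped the RNG.
.benchmarkClip <- function(sp, cond, spVariants, durationS, snrDb, clipId) {
  pickVariant <- function() spVariants[[sample.int(length(spVariants), 1)]]
  mkEvent <- function(onset, snr = snrDb) {
    v <- pickVariant()
    list(species = sp, callType = v$callType, onsetS = onset, snrDb = snr,
         params = .jitterParams(sp, v$callType, v$params))
  }
  maxDur <- max(vapply(spVariants, function(v)
    .callDuration(sp, v$callType, v$params), numeric(1)))
  margin <- 0.6
  bg <- list(noiseRms = 0.01, shrimpRate = 2, shrimpLevel = 0.05)
  events <- list(); chorus <- FALSE; extra <- NULL
  if (cond == "isolated") {
    events <- list(mkEvent(stats::runif(1, margin,
                                        durationS - maxDur - margin)))
  } else if (cond == "multi") {
    nCalls <- 3L
    slot <- (durationS - 2 * margin) / nCalls
    onsets <- margin + (seq_len(nCalls) - 1L) * slot +
      stats::runif(nCalls, 0, slot - maxDur - 0.8)
    events <- lapply(onsets, mkEvent)
  } else if (cond == "chorus") {
    chorus <- TRUE
    onset <- margin
    while (onset + maxDur < durationS - margin && length(events) < 20L) {
      ev <- mkEvent(onset)
      events[[length(events) + 1L]] <- ev
      # advance by a fraction of this call's own duration: the next call
      # starts before this one ends, so consecutive calls always overlap
      dur <- .callDuration(sp, ev$callType, ev$params)
      onset <- onset + stats::runif(1, 0.5, 0.8) * dur
    }
  } else if (cond == "shrimp_heavy") {
    bg$shrimpRate <- 25
    onsets <- margin + c(0.15, 0.6) * (durationS - 2 * margin - maxDur)
    events <- lapply(onsets, mkEvent)
  } else if (cond == "noise_masked") {
    extra <- 0.05 * .synthBoatNoise(durationS, 80000)
    onsets <- margin + c(0.2, 0.65) * (durationS - 2 * margin - maxDur)
    events <- lapply(onsets, mkEvent)
  }
  res <- assembleSoundscape(events, background = bg, durationS = durationS,
                            sampleRate = 80000, seed = NULL,
                            chorus = chorus, clipId = clipId)
  if (!is.null(extra)) {
    x <- samples(res$clip) + extra
    peak <- max(abs(x))
    if (peak > 0.99) x <- x * 0.99 / peak
    res$clip <- AudioClip(x, 80000)
  }
  res
}

#' Score detector output against ground-truth manifests
#'
#' Matches detections to injected events per clip and species: a
#' detection within the matching tolerance of an event onset is a true
#' positive (greedy, highest score first; one detection per event);
#' leftover detections are false positives and unmatched events false
#' negatives. The default tolerance is one feature duration per species
#' (frame-hop quantization makes tighter matching meaningless).
#'
#' @param detections data.frame of detections (from [batchDetect()]
#'   `$detections` or [detectFile()]); `sourceFile` must hold the clip id
#'   (WAV basename).
#' @param manifests named list of manifests (names = clip ids, with or
#'   without `.wav`).
#' @param lib the [FeatureLibrary-class] used for detection (sets default
#'   tolerances).
#' @param toleranceS optional named numeric vector of per-species
#'   matching tolerances in seconds.
#' @return data.frame: `species`, `nEvents`, `nDetections`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`.
#' @export
evaluateRecovery <- function(detections, manifests, lib = NULL,
                             toleranceS = NULL) {
  stripWav <- function(x) sub("\\.wav$", "", x)
  detections$clipId <- stripWav(detections$sourceFile)
  names(manifests) <- stripWav(names(manifests))
  allSpecies <- unique(c(
    detections$species,
    unlist(lapply(manifests, function(m) m$events$species))))
  tolFor <- function(sp) {
    if (!is.null(toleranceS) && sp %in% names(toleranceS))
      return(toleranceS[[sp]])
    if (!is.null(lib)) {
      durs <- vapply(lib@features, function(f)
        if (f@species == sp) featureDuration(f) else NA_real_, numeric(1))
      if (any(!is.na(durs))) return(max(durs, na.rm = TRUE))
    }
    1
  }
  rows <- list()
  for (sp in allSpecies) {
    tol <- tolFor(sp)
    tp <- 0L; fp <- 0L; fn <- 0L; nEv <- 0L; nDet <- 0L
    for (clipId in names(manifests)) {
      ev <- manifests[[clipId]]$events
      onsets <- ev$onsetS[ev$species == sp]
      det <- detections[detections$clipId == clipId &
                          detections$species == sp, , drop = FALSE]
      nEv <- nEv + length(onsets); nDet <- nDet + nrow(det)
      matched <- rep(FALSE, length(onsets))
      for (i in order(-det$score)) {
        d <- abs(onsets - det$timeOffset[i])
        d[matched] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= tol) {
          matched[j] <- TRUE
          tp <- tp + 1L
        } else {
          fp <- fp + 1L
        }
      }
      fn <- fn + sum(!matched)
    }
    rows[[sp]] <- data.frame(
      species = sp, nEvents = nEv, nDetections = nDet, tp = tp, fp = fp,
      fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Automatic counts by ground-truth calling-intensity category
#'
#' Assigns each benchmark clip its calling-intensity category from the
#' manifest (0 none, 1 one call, 2 multiple calls, 3 overlapping calls /
#' chorus) and pairs it with the automatic call count for the clip's
#' species. Used to check that counts rise with intensity, the
#' box-plot-ordering property of manual-versus-automatic comparison.
#'
#' @param summaries data.frame from [batchDetect()] `$summaries` (one row
#'   per file, per-species count columns).
#' @param manifests named list of manifests.
#' @return data.frame: `clipId`, `species`, `intensity`, `count`.
#' @export
intensityCountTable <- function(summaries, manifests) {
  stripWav <- function(x) sub("\\.wav$", "", x)
  summaries$clipId <- stripWav(summaries$sourceFile)
  names(manifests) <- stripWav(names(manifests))
  rows <- list()
  for (clipId in names(manifests)) {
    ev <- manifests[[clipId]]$events
    if (nrow(ev) == 0L) next
    sp <- ev$species[1]
    srow <- summaries[summaries$clipId == clipId, , drop = FALSE]
    if (nrow(srow) == 0L || !sp %in% names(srow)) next
    rows[[length(rows) + 1L]] <- data.frame(
      clipId = clipId, species = sp,
      intensity = intensityFromManifest(ev), count = srow[[sp]][1],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
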