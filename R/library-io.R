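## Library container: a directory holding a versioned JSON manifest plus one
## full-precision CSV per template surface. Text-based so libraries are
## portable and diff-able; surfaces are written with %.17g, which round-trips
## IEEE doubles exactly.

.LIBRARY_FORMAT_VERSION <- "1.0"

.writeSurface <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
}

.readSurface <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
}

#' Save / load a feature library
#'
#' `saveLibrary()` writes a directory with `manifest.json` (format
#' version, per-species configuration, per-feature metadata) and a
#' `surfaces/` folder holding one CSV per template. `loadLibrary()`
#' reverses it losslessly; it refuses manifests with an incompatible
#' format version and reports missing surface files explicitly.
#'
#' @param lib a [FeatureLibrary-class].
#' @param path directory to write / read.
#' @return `saveLibrary()`: `path` invisibly; `loadLibrary()`: a
#'   [FeatureLibrary-class].
#' @export
saveLibrary <- function(lib, path) {
  stopifnot(is(lib, "FeatureLibrary"))
  dir.create(file.path(path, "surfaces"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- featureMetadata(lib)
  meta$surfaceFile <- file.path("surfaces", paste0(meta$featureId, ".csv"))
  manifest <- list(
    format = "drumcall-feature-library",
    version = .LIBRARY_FORMAT_VERSION,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = lib@config,
    features = meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(nrow(meta)))
    .writeSurface(lib@features[[meta$featureId[i]]]@surface,
                  file.path(path, meta$surfaceFile[i]))
  invisible(path)
}

#' @rdname saveLibrary
#' @export
loadLibrary <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "drumcall-feature-library"))
    stop("not a drumcall feature library: ", path)
  if (!identical(manifest$version, .LIBRARY_FORMAT_VERSION))
    stop("library format version mismatch: file has '", manifest$version,
         "', this package reads '", .LIBRARY_FORMAT_VERSION, "'")
  meta <- manifest$features
  features <- lapply(seq_len(nrow(meta)), function(i) {
    sf <- file.path(path, meta$surfaceFile[i])
    if (!file.exists(sf))
      stop("manifest references missing surface file: ", meta$surfaceFile[i])
    new("CallFeature",
        species = meta$species[i], featureId = meta$featureId[i],
        surface = .readSurface(sf),
        bandLo = meta$bandLo[i], bandHi = meta$bandHi[i],
        framingW = as.integer(meta$framingW[i]),
        framingP = as.integer(meta$framingP[i]),
        sampleRate = meta$sampleRate[i],
        callType = if (is.null(meta$callType) || is.na(meta$callType[i]))
          "" else meta$callType[i],
        pulseCount = if (is.null(meta$pulseCount)) NA_real_ else
          as.numeric(meta$pulseCount[i]))
  })
  config <- as.data.frame(manifest$config, stringsAsFactors = FALSE)
  config$windowW <- as.integer(config$windowW)
  config$repetitionP <- as.integer(config$repetitionP)
  # an all-NA column serializes as JSON nulls and may come back absent
  config$nmsWindowS <- if (is.null(manifest$config$nmsWindowS))
    rep(NA_real_, nrow(config))
  else vapply(as.list(config$nmsWindowS), function(v)
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else
      as.numeric(v), numeric(1))
  FeatureLibrary(features, config)
}

#' Build a feature library from an annotation table
#'
#' Reads a CSV of template annotations — columns `clip` (WAV path),
#' `tStart`, `tEnd` (seconds), `bandLo`, `bandHi` (Hz), `species`,
#' `featureId`, and optionally `callType` and `pulseCount` — extracts each
#' template from the clip's spectrogram using the species' configured
#' framing, and returns the assembled library. Malformed rows are reported
#' with their line numbers.
#'
#' @param annotationCsv path to the annotation CSV.
#' @param cal a [CalibrationSpec-class].
#' @param config per-species configuration (default
#'   [defaultSpeciesConfig()]).
#' @return a [FeatureLibrary-class].
#' @export
buildLibraryFromAnnotations <- function(annotationCsv,
                                        cal = CalibrationSpec(),
                                        config = defaultSpeciesConfig()) {
  ann <- utils::read.csv(annotationCsv, stringsAsFactors = FALSE)
  need <- c("clip", "tStart", "tEnd", "bandLo", "bandHi", "species",
            "featureId")
  if (!all(need %in% names(ann)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  specCache <- new.env(parent = emptyenv())
  features <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    row <- ann[i, ]
    line <- i + 1L  # header is line 1
    cfg <- config[config$species == row$species, , drop = FALSE]
    if (nrow(cfg) == 0L)
      stop(sprintf("line %d: species '%s' has no configuration", line,
                   row$species))
    if (!is.finite(row$bandLo) || !is.finite(row$bandHi) ||
        row$bandLo >= row$bandHi)
      stop(sprintf("line %d: invalid band [%s, %s]", line, row$bandLo,
                   row$bandHi))
    key <- paste(row$clip, cfg$windowW, cfg$repetitionP, sep = "|")
    if (is.null(specCache[[key]])) {
      if (!file.exists(row$clip))
        stop(sprintf("line %d: clip not found: %s", line, row$clip))
      clip <- readWav(row$clip)
      if (row$bandHi > sampleRate(clip) / 2)
        stop(sprintf("line %d: bandHi %s exceeds Nyquist %s", line,
                     row$bandHi, sampleRate(clip) / 2))
      specCache[[key]] <- spectrogram(clip, cfg$windowW, cfg$repetitionP, cal)
    }
    features[[i]] <- tryCatch(
      extractFeature(specCache[[key]], row$tStart, row$tEnd, row$bandLo,
                     row$bandHi, row$species, row$featureId,
                     callType = if ("callType" %in% names(ann))
                       row$callType else "",
                     pulseCount = if ("pulseCount" %in% names(ann))
                       row$pulseCount else NA_real_),
      error = function(e) stop(sprintf("line %d: %s", line,
                                       conditionMessage(e)), call. = FALSE))
  }
  FeatureLibrary(features, config)
}
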