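#' Run configuration
#'
#' The pipeline's tunables as one list, YAML-serializable: calibration
#' constants, per-species detector settings, paths, seed, and logging
#' level. `defaultRunConfig()` prints the shipped defaults;
#' `readRunConfig()` loads a YAML file over those defaults and validates
#' it; `validateRunConfig()` checks completeness (every species in the
#' library must have a full configuration row) and that referenced paths
#' resolve.
#'
#' @param path YAML file path.
#' @param checkPaths verify that `paths` entries exist.
#' @return a config list with elements `calibration` (sensitivity, gain,
#'   adcFullScale), `species` (per-species list of windowW, repetitionP,
#'   threshold, nmsWindowS, bandLo, bandHi), `paths` (library, inputDir,
#'   outputDir), `seed`, `logLevel`.
#' @export
defaultRunConfig <- function() {
  cfg <- defaultSpeciesConfig()
  speciesList <- lapply(seq_len(nrow(cfg)), function(i) as.list(cfg[i, -1]))
  names(speciesList) <- cfg$species
  list(calibration = list(sensitivity = -186, gain = 20, adcFullScale = 1),
       species = speciesList,
       paths = list(library = NULL, inputDir = NULL, outputDir = NULL),
       seed = 1L, logLevel = "info")
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path, checkPaths = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(defaultRunConfig(), user)
  validateRunConfig(config, checkPaths = checkPaths)
  config
}

#' @rdname defaultRunConfig
#' @param config a config list.
#' @export
validateRunConfig <- function(config, checkPaths = FALSE) {
  for (f in c("sensitivity", "gain", "adcFullScale"))
    if (!is.numeric(config$calibration[[f]]))
      stop("calibration$", f, " must be numeric")
  if (config$calibration$adcFullScale <= 0)
    stop("calibration$adcFullScale must be > 0")
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    for (f in c("windowW", "repetitionP", "threshold", "bandLo", "bandHi"))
      if (is.null(s[[f]]) || !is.numeric(s[[f]]))
        stop("species '", sp, "' config incomplete: missing ", f)
    if (s$repetitionP < 1 || s$repetitionP > s$windowW)
      stop("species '", sp, "': need 1 <= repetitionP <= windowW")
  }
  if (checkPaths)
    for (p in names(config$paths))
      if (!is.null(config$paths[[p]]) && !file.exists(config$paths[[p]]))
        stop("configured path does not resolve: paths$", p, " = ",
             config$paths[[p]])
  invisible(config)
}

#' @rdname defaultRunConfig
#' @export
configCalibration <- function(config) {
  CalibrationSpec(config$calibration$sensitivity, config$calibration$gain,
                  config$calibration$adcFullScale)
}

#' @rdname defaultRunConfig
#' @export
configSpeciesTable <- function(config) {
  rows <- lapply(names(config$species), function(sp) {
    s <- config$species[[sp]]
    data.frame(species = sp, windowW = as.integer(s$windowW),
               repetitionP = as.integer(s$repetitionP),
               threshold = s$threshold,
               nmsWindowS = if (is.null(s$nmsWindowS)) NA_real_ else
                 as.numeric(s$nmsWindowS),
               bandLo = s$bandLo, bandHi = s$bandHi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
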