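#' Identification rate
#'
#' Per-file agreement between automatic and manual (or ground-truth)
#' presence labels: `IR = (a - b - c)/a * 100`, with `a` the total number
#' of files, `b` the number of files with false negatives, and `c` the
#' number with false positives. 100% iff every file is labeled correctly.
#'
#' @param counts a list or data.frame row with elements `total`,
#'   `falseNegatives`, `falsePositives` (as returned by
#'   [filePresenceConfusion()]); alternatively supply the three numbers
#'   via `total`, `falseNegatives`, `falsePositives` directly.
#' @param total,falseNegatives,falsePositives scalar counts (used when
#'   `counts` is missing).
#' @return IR in percent.
#' @examples
#' identificationRate(total = 100, falseNegatives = 10,
#'                    falsePositives = 5)  # 85
#' @export
identificationRate <- function(counts = NULL, total = NULL,
                               falseNegatives = NULL,
                               falsePositives = NULL) {
  if (!is.null(counts)) {
    total <- counts$total
    falseNegatives <- counts$falseNegatives
    falsePositives <- counts$falsePositives
  }
  if (is.null(total) || total <= 0) stop("'total' must be > 0")
  if (falseNegatives < 0 || falsePositives < 0 ||
      falseNegatives + falsePositives > total)
    stop("need 0 <= falseNegatives + falsePositives <= total")
  (total - falseNegatives - falsePositives) / total * 100
}

#' File-level presence confusion counts
#'
#' Compares automatic and reference per-file presence of one species:
#' a file is automatically "present" when its call count is >= 1, and
#' reference-present when its manual intensity is >= 1 (or its manifest
#' lists >= 1 event). Both tables must cover exactly the same files;
#' a mismatch is an error that lists the difference.
#'
#' @param auto data.frame with columns `sourceFile` and either a column
#'   named after `species` (count, as from [batchDetect()] `$summaries`)
#'   or columns `species` + `count`.
#' @param truth data.frame with columns `sourceFile`, `species`,
#'   `intensity` (manual scores), or a named list of manifests.
#' @param species species label to compare.
#' @return list with `total`, `falseNegatives`, `falsePositives`.
#' @export
filePresenceConfusion <- function(auto, truth, species) {
  stripWav <- function(x) sub("\\.wav$", "", x)
  autoFiles <- stripWav(auto$sourceFile)
  if (species %in% names(auto)) {
    autoPresent <- auto[[species]] >= 1
  } else if (all(c("species", "count") %in% names(auto))) {
    sel <- auto$species == species
    autoFiles <- autoFiles[sel]
    autoPresent <- auto$count[sel] >= 1
  } else {
    stop("'auto' must carry a '", species, "' count column or ",
         "'species'+'count' columns")
  }
  if (is.data.frame(truth)) {
    sel <- truth$species == species
    truthFiles <- stripWav(truth$sourceFile[sel])
    truthPresent <- truth$intensity[sel] >= 1
  } else {
    truthFiles <- stripWav(names(truth))
    truthPresent <- vapply(truth, function(m)
      sum(m$events$species == species) >= 1, logical(1))
  }
  missing1 <- setdiff(truthFiles, autoFiles)
  missing2 <- setdiff(autoFiles, truthFiles)
  if (length(missing1) || length(missing2))
    stop("file universes differ; only in truth: [",
         paste(utils::head(missing1, 5), collapse = ", "),
         "], only in auto: [",
         paste(utils::head(missing2, 5), collapse = ", "), "]")
  ord <- match(autoFiles, truthFiles)
  truthPresent <- truthPresent[ord]
  list(total = length(autoFiles),
       falseNegatives = sum(truthPresent & !autoPresent),
       falsePositives = sum(!truthPresent & autoPresent))
}

#' Calling-intensity category of a set of events
#'
#' The manual-annotation scale applied to a ground-truth manifest:
#' 0 = no calls, 1 = one call, 2 = multiple calls, 3 = overlapping calls
#' or chorus. Two events overlap when one starts before the other ends.
#'
#' @param events data.frame with columns `onsetS` and `durationS` (a
#'   manifest's `events`), or a manifest list.
#' @return integer 0-3.
#' @export
intensityFromManifest <- function(events) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events))
    events <- events$events
  n <- nrow(events)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  ev <- events[order(events$onsetS), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (ev$onsetS[j] < ev$onsetS[i] + ev$durationS[i] &&
          ev$onsetS[i] < ev$onsetS[j] + ev$durationS[j])
        return(3L)
    }
  }
  2L
}

#' Nightly sums of per-file values
#'
#' Sums per-file values (manual intensity scores or automatic call
#' counts) over calling nights. A night runs from 12:00 on day `d` to
#' 12:00 on day `d + 1` (half-open), matching a noon-to-noon aggregation
#' of evening calling; on a 20-minute file grid this is the familiar
#' "12:00 to 11:40 the next day" window. Nights inside the covered range
#' with no files are reported as missing (`NA`), not zero.
#'
#' @param values numeric per-file values.
#' @param timestamps `POSIXct` per-file timestamps (duplicates are an
#'   error).
#' @return data.frame: `nightStart` (Date of the noon opening the
#'   window), `value` (sum or `NA`), `nFiles`.
#' @export
nightlySums <- function(values, timestamps) {
  if (length(values) != length(timestamps))
    stop("'values' and 'timestamps' must have equal length")
  if (anyDuplicated(timestamps)) stop("duplicate timestamps")
  ## format() renders in the timestamps' own timezone, so the noon
  ## boundary is local noon regardless of session timezone
  night <- as.Date(format(timestamps - 12 * 3600, "%Y-%m-%d"))
  allNights <- seq(min(night), max(night), by = "day")
  sums <- tapply(values, night, sum)
  nFiles <- tapply(values, night, length)
  idx <- match(as.character(allNights), names(sums))
  data.frame(nightStart = allNights,
             value = as.numeric(sums)[idx],
             nFiles = ifelse(is.na(idx), 0L, as.integer(nFiles)[idx]))
}

#' Pearson correlation of aligned nightly series
#'
#' Product-moment correlation and two-sided p-value (the standard t
#' transform of r) between paired nightly sums, e.g. manual intensity
#' sums against automatic call counts. Nights missing in either series
#' are dropped pairwise; at least 3 complete pairs are required. A
#' zero-variance series has no defined correlation and returns `NA` with
#' a warning.
#'
#' @param manual,auto numeric vectors, or data.frames from
#'   [nightlySums()] (aligned on `nightStart`).
#' @return list with `r`, `p`, `n`.
#' @export
correlateNightly <- function(manual, auto) {
  if (is.data.frame(manual) && is.data.frame(auto)) {
    merged <- merge(manual, auto, by = "nightStart",
                    suffixes = c(".manual", ".auto"))
    x <- merged$value.manual
    y <- merged$value.auto
  } else {
    if (length(manual) != length(auto))
      stop("series must have equal length")
    x <- as.numeric(manual)
    y <- as.numeric(auto)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired nightly values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance series: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
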