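#' Water temperature anomaly
#'
#' Observed temperature minus its 30-day moving average. The default
#' alignment is a centered, symmetric window spanning the moving-average
#' period (`windowDays * samplesPerDay + 1` points, i.e. +/- 15 days for
#' hourly data); a trailing window is available by configuration. Points
#' whose window is incomplete, or contains more missing values than
#' `maxGapFrac` allows, are reported as `NA` (flagged missing, never
#' silently filled).
#'
#' A centered window makes the anomaly of any linear trend exactly zero
#' in the interior, so the anomaly isolates departures from the seasonal
#' trajectory rather than the trajectory itself.
#'
#' @param values numeric temperature series on a regular grid, degrees C
#'   (`NA` = gap).
#' @param samplesPerDay samples per day (24 for hourly loggers).
#' @param windowDays moving-average span in days (default 30).
#' @param align `"centered"` (default) or `"trailing"`.
#' @param maxGapFrac largest tolerated fraction of missing values inside
#'   a window (default 0: any gap flags the window).
#' @return numeric anomaly series, same length as `values`.
#' @export
temperatureAnomaly <- function(values, samplesPerDay = 24, windowDays = 30,
                               align = c("centered", "trailing"),
                               maxGapFrac = 0) {
  align <- match.arg(align)
  k <- as.integer(windowDays * samplesPerDay)
  if (align == "centered") k <- k + 1L  # symmetric: +/- windowDays/2
  if (length(values) < k)
    return(rep(NA_real_, length(values)))
  winMean <- function(z) {
    bad <- mean(is.na(z))
    if (bad > maxGapFrac) NA_real_ else mean(z, na.rm = TRUE)
  }
  ma <- zoo::rollapply(values, width = k, FUN = winMean,
                       align = if (align == "centered") "center" else "right",
                       fill = NA_real_)
  values - ma
}

#' Lunar phase category of a lunar day
#'
#' Maps lunar day (1-30, day 1 = new moon epoch) to the four-phase
#' categorization used for calling-rate covariates: new moon spans days
#' 27-4 (wrapping across the cycle), first quarter 5-11, full moon 12-19,
#' third quarter 20-26. The four bins partition the 30-day cycle.
#'
#' @param lunarDay integer vector in 1-30.
#' @return factor with levels `new_moon`, `first_quarter`, `full_moon`,
#'   `third_quarter`.
#' @examples
#' lunarCategory(c(1, 15, 28))  # new_moon, full_moon, new_moon
#' @export
lunarCategory <- function(lunarDay) {
  if (any(!is.finite(lunarDay)) || any(lunarDay < 1) || any(lunarDay > 30) ||
      any(lunarDay != round(lunarDay)))
    stop("'lunarDay' must be integers in 1..30")
  out <- character(length(lunarDay))
  out[lunarDay >= 27 | lunarDay <= 4] <- "new_moon"
  out[lunarDay >= 5 & lunarDay <= 11] <- "first_quarter"
  out[lunarDay >= 12 & lunarDay <= 19] <- "full_moon"
  out[lunarDay >= 20 & lunarDay <= 26] <- "third_quarter"
  factor(out, levels = c("new_moon", "first_quarter", "full_moon",
                         "third_quarter"))
}

#' Expected file count of a duty-cycled recording schedule
#'
#' A recorder capturing one 2-minute file every 20 minutes produces
#' `24 * 3 = 72` files per day; the expected total is
#' `72 * days * stations`. Useful for completeness checks against
#' deployment logs (e.g. 86 days at 4 stations = 24768 files; a 242-day
#' campaign at 4 stations = 69696).
#'
#' @param days days sampled.
#' @param stations number of stations.
#' @param filesPerHour files per hour (default 3, the 20-minute cycle).
#' @return expected file count.
#' @export
expectedFileCount <- function(days, stations, filesPerHour = 3) {
  if (days <= 0 || stations <= 0 || filesPerHour <= 0)
    stop("all inputs must be positive")
  24 * filesPerHour * days * stations
}

#' Daily tidal range from a water-level series
#'
#' Daily maximum minus minimum water level; a covariate column for
#' calling-rate models.
#'
#' @param timestamps `POSIXct`.
#' @param level water level, m.
#' @return data.frame: `date`, `tidalRange`.
#' @export
tidalRange <- function(timestamps, level) {
  day <- as.Date(format(timestamps, "%Y-%m-%d"))
  rng <- tapply(level, day, function(z) max(z, na.rm = TRUE) -
                  min(z, na.rm = TRUE))
  data.frame(date = as.Date(names(rng)), tidalRange = as.numeric(rng),
             row.names = NULL)
}

#' Day length at a site
#'
#' Civil day length (sunrise to sunset, hours) for the site latitude;
#' thin wrapper over `geosphere::daylength()` provided as a covariate
#' column for calling-rate models.
#'
#' @param dates `Date` vector.
#' @param latitude degrees north.
#' @return numeric hours.
#' @export
dayLength <- function(dates, latitude) {
  geosphere::daylength(latitude, as.numeric(format(dates, "%j")))
}
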