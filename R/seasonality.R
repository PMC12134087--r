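#' Standardize an NDVI series over its whole period
#'
#' `z = (v - mean) / sd` using the sample standard deviation, computed over
#' the entire series, so the zero line is the period mean greenness.
#'
#' @param time record times (`POSIXct`).
#' @param value NDVI values.
#' @return data frame `time, z` with `mean(z) == 0` and `sd(z) == 1` (to
#'   1e-9).
#' @export
standardizeNdvi <- function(time, value) {
  stopifnot(length(time) == length(value))
  if (length(unique(value[!is.na(value)])) < 2L)
    stop("constant NDVI series cannot be standardized")
  data.frame(time = asUTC(time), z = (value - mean(value)) / sd(value))
}

# season-years run July 1 -- June 30 so a southern-hemisphere Nov--Apr wet
# season is never split across the search window
seasonYearStart <- function(year) {
  as.POSIXct(sprintf("%d-07-01", year), tz = "UTC")
}

#' Wet/dry season cut points from a standardized NDVI series
#'
#' Within each July--June season-year the series is smoothed with a centred
#' moving mean and thresholded at z = 0 (the period mean). The wet season is
#' the longest contiguous above-threshold run; its first and last zero
#' crossings (linear interpolation between records) are the two cut points
#' of that year. The remainder of the year is dry. Years without a usable
#' crossing structure -- no crossing at all, a longest run shorter than
#' `minWetDays` (a single-wet-season climate has months-long wet seasons),
#' or a sign pattern that flips more than `maxCrossings` times (noise, not
#' seasonality) -- fall back, with a warning, to the calendar default (wet
#' November through April).
#'
#' @param z standardized series, a data frame `time, z` from
#'   [standardizeNdvi()].
#' @param smoothWindow centred moving-mean window, in records (odd; default
#'   3).
#' @param minWetDays shortest credible wet season (days).
#' @param maxCrossings most zero crossings a year may show and still count
#'   as seasonal.
#' @return A [SeasonTable-class] covering whole season-years within the
#'   series span.
#' @export
seasonCutpoints <- function(z, smoothWindow = 3, minWetDays = 100,
                            maxCrossings = 4) {
  stopifnot(is.data.frame(z), all(c("time", "z") %in% names(z)),
            smoothWindow >= 1)
  tt <- as.numeric(z$time)
  v <- z$z
  if (smoothWindow > 1) {
    h <- floor(smoothWindow / 2)
    v <- vapply(seq_along(v), function(i)
      mean(z$z[max(1, i - h):min(length(z$z), i + h)]), numeric(1))
  }
  y0 <- as.integer(format(min(z$time), "%Y")) - 1L
  y1 <- as.integer(format(max(z$time), "%Y"))
  years <- integer(0); ws <- numeric(0); we <- numeric(0); fb <- logical(0)
  for (yr in y0:y1) {
    a <- as.numeric(seasonYearStart(yr)); b <- as.numeric(seasonYearStart(yr + 1L))
    sel <- which(tt >= a & tt < b)
    if (length(sel) < 2L) next
    if (tt[sel[1]] - a > 40 * DAY || b - tt[sel[length(sel)]] > 40 * DAY)
      next # incomplete season-year
    vi <- v[sel]; ti <- tt[sel]
    pos <- vi > 0
    runs0 <- rle(pos)
    longestDays <- if (any(runs0$values)) {
      ends0 <- cumsum(runs0$lengths)
      starts0 <- ends0 - runs0$lengths + 1L
      iR <- which(runs0$values)
      max(ti[ends0[iR]] - ti[starts0[iR]]) / DAY
    } else 0
    degenerate <- !any(pos) || all(pos) ||
      sum(diff(pos) != 0) > maxCrossings || longestDays < minWetDays
    if (degenerate) {
      warning("no seasonal signal in season-year ", yr,
              "; falling back to calendar seasons (Nov-Apr wet)")
      years <- c(years, yr)
      ws <- c(ws, as.numeric(as.POSIXct(sprintf("%d-11-01", yr), tz = "UTC")))
      we <- c(we, as.numeric(as.POSIXct(sprintf("%d-05-01", yr + 1L),
                                        tz = "UTC")))
      fb <- c(fb, TRUE)
      next
    }
    runs <- rle(pos)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    iRun <- which(runs$values)
    best <- iRun[which.max(ti[ends[iRun]] - ti[starts[iRun]])]
    i0 <- starts[best]; i1 <- ends[best]
    tIn <- if (i0 == 1L) ti[1] else
      ti[i0 - 1] + (0 - vi[i0 - 1]) / (vi[i0] - vi[i0 - 1]) *
        (ti[i0] - ti[i0 - 1])
    tOut <- if (i1 == length(vi)) ti[length(vi)] else
      ti[i1] + (0 - vi[i1]) / (vi[i1 + 1] - vi[i1]) * (ti[i1 + 1] - ti[i1])
    years <- c(years, yr); ws <- c(ws, tIn); we <- c(we, tOut)
    fb <- c(fb, FALSE)
  }
  if (!length(years)) stop("no complete season-year in the series")
  new("SeasonTable", year = years,
      wetStart = as.POSIXct(ws, origin = "1970-01-01", tz = "UTC"),
      wetEnd = as.POSIXct(we, origin = "1970-01-01", tz = "UTC"),
      coverageStart = seasonYearStart(years[1]),
      coverageEnd = seasonYearStart(years[length(years)] + 1L),
      fallback = fb)
}

setMethod("show", "SeasonTable", function(object) {
  cat(sprintf("SeasonTable: %d season-year(s), coverage %s .. %s\n",
              length(object@year), format(object@coverageStart),
              format(object@coverageEnd)))
  for (i in seq_along(object@year))
    cat(sprintf("  %d/%d: wet %s .. %s%s\n", object@year[i],
                object@year[i] + 1L, format(object@wetStart[i]),
                format(object@wetEnd[i]),
                if (object@fallback[i]) " (calendar fallback)" else ""))
})

#' Assign wet/dry season labels
#'
#' Wet intervals are closed: a timestamp exactly at a cut point is wet.
#'
#' @param t timestamps (`POSIXct`) within the table's coverage.
#' @param st a [SeasonTable-class].
#' @return character vector of `"wet"` / `"dry"`.
#' @export
assignSeason <- function(t, st) {
  stopifnot(is(st, "SeasonTable"))
  tt <- as.numeric(asUTC(t))
  if (any(tt < as.numeric(st@coverageStart) |
          tt > as.numeric(st@coverageEnd)))
    stop("timestamp outside season-table coverage")
  out <- rep("dry", length(tt))
  for (i in seq_along(st@year))
    out[tt >= as.numeric(st@wetStart[i]) & tt <= as.numeric(st@wetEnd[i])] <-
      "wet"
  out
}

#' Seasonal periods of one type as explicit intervals
#'
#' Used by the revisitation-rate denominator. Wet periods are the wet
#' intervals themselves. A dry season runs from one wet season's end to the
#' next wet season's start, so dry periods straddle the July--June
#' season-year boundary; the dry seasons truncated at the edges of coverage
#' are extended to full length by extrapolating the neighbouring wet cut
#' points one year out, so a partial overlap counts as the right fraction
#' of a whole dry season.
#'
#' @param st a [SeasonTable-class].
#' @param season `"wet"` or `"dry"`.
#' @return data frame `start, end` (`POSIXct`), one row per period (dry
#'   periods may extend beyond coverage; overlaps should be clipped by the
#'   caller).
#' @export
seasonPeriods <- function(st, season = c("wet", "dry")) {
  season <- match.arg(season)
  if (season == "wet")
    return(data.frame(start = st@wetStart, end = st@wetEnd))
  n <- length(st@year)
  shiftYear <- function(t, by) {
    lt <- as.POSIXlt(t, tz = "UTC")
    lt$year <- lt$year + by
    as.POSIXct(lt)
  }
  wetEnd0 <- c(shiftYear(st@wetEnd[1], -1L), st@wetEnd)
  wetStart1 <- c(st@wetStart, shiftYear(st@wetStart[n], 1L))
  data.frame(start = wetEnd0, end = wetStart1)
}
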