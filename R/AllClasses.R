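#' @import methods
#' @importFrom stats var sd cor complete.cases lm coef logLik AIC predict rgeom
#'   rnorm runif rgamma rpois setNames quantile median approx aggregate
#'   dist dnorm
#' @importFrom utils read.csv write.csv head tail
NULL

setOldClass(c("POSIXct", "POSIXt"))

#' Trajectory of one tracked individual
#'
#' Time-ordered GPS fixes for a single individual in a projected (metre)
#' coordinate system.
#'
#' @slot individualId single id string.
#' @slot sex `"bull"`, `"cow"` or `NA_character_`.
#' @slot t fix timestamps (`POSIXct`, UTC), strictly increasing.
#' @slot x,y projected easting / northing in metres.
#' @exportClass Trajectory
setClass("Trajectory",
  slots = c(individualId = "character", sex = "character",
            t = "POSIXct", x = "numeric", y = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@t)
  if (length(object@individualId) != 1L) return("individualId must be length 1")
  if (length(object@x) != n || length(object@y) != n)
    return("t, x, y must have equal length")
  if (n == 0L) return("trajectory has no fixes")
  if (anyNA(object@t) || any(!is.finite(object@x)) || any(!is.finite(object@y)))
    return("fix times and coordinates must be finite")
  if (n > 1L && any(diff(as.numeric(object@t)) <= 0))
    return("fix times must be strictly increasing")
  TRUE
})

#' Set of trajectories sharing one projected CRS
#'
#' @slot trajectories named list of [Trajectory-class] objects, keyed by
#'   individual id.
#' @slot crs free-text descriptor of the shared projected CRS (metre units).
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  slots = c(trajectories = "list", crs = "character"))

setValidity("TrajectorySet", function(object) {
  trs <- object@trajectories
  if (length(trs) == 0L) return("empty trajectory set")
  if (!all(vapply(trs, is, logical(1), "Trajectory")))
    return("all elements must be Trajectory objects")
  ids <- vapply(trs, function(tr) tr@individualId, character(1))
  if (anyDuplicated(ids)) return("duplicate individual ids")
  if (!identical(unname(ids), unname(names(trs))))
    return("list names must equal individual ids")
  TRUE
})

#' Recursion (revisitation) configuration
#'
#' @slot radius circle radius in metres.
#' @slot minTimeAway minimum time away, in hours, before a return counts as a
#'   separate visit.
#' @slot candidateRadii sorted candidate radii (m) for variance-peak selection.
#' @exportClass RecursionConfig
setClass("RecursionConfig",
  slots = c(radius = "numeric", minTimeAway = "numeric",
            candidateRadii = "numeric"))

setValidity("RecursionConfig", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0) return("radius must be a single positive number")
  if (object@minTimeAway < 0) return("minTimeAway must be >= 0")
  cr <- object@candidateRadii
  if (length(cr) && (any(cr <= 0) || is.unsorted(cr, strictly = TRUE)))
    return("candidateRadii must be positive and strictly increasing")
  TRUE
})

#' Planar water features (points, lines, polygons)
#'
#' @slot features list; each element is `list(type =, coords =)` with `type`
#'   one of `"point"`, `"line"`, `"polygon"` and `coords` a 2-column matrix
#'   of metre coordinates (polygon rings implicitly closed).
#' @exportClass WaterFeatures
setClass("WaterFeatures", slots = c(features = "list"))

setValidity("WaterFeatures", function(object) {
  for (f in object@features) {
    if (!is.list(f) || !all(c("type", "coords") %in% names(f)))
      return("each feature needs 'type' and 'coords'")
    if (!f$type %in% c("point", "line", "polygon"))
      return("feature type must be point/line/polygon")
    if (!is.matrix(f$coords) || ncol(f$coords) != 2L)
      return("coords must be a 2-column matrix")
  }
  TRUE
})

#' Single-band raster layer on a regular metre grid
#'
#' Row 1 of `values` is the top (northernmost) row, matching the on-disk
#' ASCII-grid layout.
#'
#' @slot name layer name.
#' @slot values numeric matrix.
#' @slot xmin,ymin lower-left corner of the grid (m).
#' @slot cellsize cell edge (m).
#' @slot nodata value marking missing cells (converted to `NA` on read).
#' @slot units free-text units.
#' @exportClass RasterLayer
setClass("RasterLayer",
  slots = c(name = "character", values = "matrix", xmin = "numeric",
            ymin = "numeric", cellsize = "numeric", nodata = "numeric",
            units = "character"))

setValidity("RasterLayer", function(object) {
  if (length(dim(object@values)) != 2L || !length(object@values))
    return("values must be a non-empty matrix")
  if (object@cellsize <= 0) return("cellsize must be > 0")
  TRUE
})

#' Time-stamped series of raster layers
#'
#' @slot name series name.
#' @slot times strictly increasing record times (`POSIXct`).
#' @slot layers list of [RasterLayer-class], one per record.
#' @slot cadenceDays nominal record cadence in days (16 EVI, 8 LST,
#'   5 precipitation).
#' @exportClass RasterSeries
setClass("RasterSeries",
  slots = c(name = "character", times = "POSIXct", layers = "list",
            cadenceDays = "numeric"))

setValidity("RasterSeries", function(object) {
  if (length(object@times) != length(object@layers))
    return("times and layers differ in length")
  if (length(object@times) == 0L) return("empty series")
  if (length(object@times) > 1L && any(diff(as.numeric(object@times)) <= 0))
    return("record times must be strictly increasing")
  TRUE
})

#' a-LoCoH home range
#'
#' The union of local convex hulls retained at the requested isopleth. The
#' union is kept as the list of member hulls; when one hull contains all
#' others (always the case at `a = defaultA`), `polygon` holds that hull and
#' `areaExact` is `TRUE`.
#'
#' @slot hulls list of 2-column vertex matrices (counter-clockwise convex).
#' @slot polygon the collapsed union hull, or a 0-row matrix.
#' @slot aValue the `a` parameter (m).
#' @slot isopleth fraction of points the union must contain.
#' @slot area union area (m^2); exact if `areaExact`, else grid estimate.
#' @slot areaExact logical.
#' @exportClass HomeRange
setClass("HomeRange",
  slots = c(hulls = "list", polygon = "matrix", aValue = "numeric",
            isopleth = "numeric", area = "numeric", areaExact = "logical"))

#' Wet/dry season table
#'
#' One wet interval per season-year (seasons are sought within July--June
#' years so a southern-hemisphere Nov--Apr wet season is never split); the
#' rest of each year is dry. Wet intervals are closed.
#'
#' @slot year starting calendar year of each July--June season-year.
#' @slot wetStart,wetEnd wet-season cut points (`POSIXct`).
#' @slot coverageStart,coverageEnd span the table is valid for.
#' @slot fallback per year, `TRUE` when no NDVI crossing was found and the
#'   calendar default (Nov--Apr wet) was used.
#' @exportClass SeasonTable
setClass("SeasonTable",
  slots = c(year = "integer", wetStart = "POSIXct", wetEnd = "POSIXct",
            coverageStart = "POSIXct", coverageEnd = "POSIXct",
            fallback = "logical"))

setValidity("SeasonTable", function(object) {
  n <- length(object@year)
  if (length(object@wetStart) != n || length(object@wetEnd) != n ||
      length(object@fallback) != n) return("ragged season table")
  if (any(as.numeric(object@wetEnd) < as.numeric(object@wetStart)))
    return("wetEnd before wetStart")
  TRUE
})
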