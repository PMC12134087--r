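#' Construct a Trajectory
#'
#' Fixes are sorted by time; the coordinate system must already be projected
#' (metres).
#'
#' @param individualId id string.
#' @param t fix times (`POSIXct`), unique within the individual.
#' @param x,y projected coordinates in metres.
#' @param sex `"bull"`, `"cow"` or `NA`.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(individualId, t, x, y, sex = NA_character_) {
  t <- asUTC(t)
  o <- order(t)
  new("Trajectory", individualId = as.character(individualId),
      sex = as.character(sex), t = t[o], x = as.numeric(x)[o],
      y = as.numeric(y)[o])
}

#' Construct a TrajectorySet
#'
#' @param trajectories list of [Trajectory-class] objects.
#' @param crs text descriptor of the shared projected CRS.
#' @return A [TrajectorySet-class].
#' @export
TrajectorySet <- function(trajectories, crs = "local-metric") {
  ids <- vapply(trajectories, function(tr) tr@individualId, character(1))
  names(trajectories) <- ids
  new("TrajectorySet", trajectories = trajectories, crs = crs)
}

#' @describeIn Trajectory number of fixes
#' @param object,x a `Trajectory`
#' @export
nFixes <- function(object) length(object@t)

#' Individual id of a trajectory
#' @param object a [Trajectory-class].
#' @export
individualId <- function(object) object@individualId

#' Fixes of a trajectory as a data frame
#' @param object a [Trajectory-class].
#' @return data frame with columns `id, timestamp, x, y, sex`.
#' @export
fixes <- function(object) {
  data.frame(id = object@individualId, timestamp = object@t,
             x = object@x, y = object@y, sex = object@sex,
             stringsAsFactors = FALSE)
}

#' Trajectories in a set
#' @param object a [TrajectorySet-class].
#' @export
trajectories <- function(object) object@trajectories

setMethod("length", "TrajectorySet", function(x) length(x@trajectories))

setMethod("show", "Trajectory", function(object) {
  sp <- trackingSpan(object)
  cat(sprintf("Trajectory '%s' (%s): %d fixes, %s .. %s\n",
              object@individualId,
              ifelse(is.na(object@sex), "sex unknown", object@sex),
              nFixes(object), format(sp[1]), format(sp[2])))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d individuals, crs '%s'\n",
              length(object@trajectories), object@crs))
  for (tr in object@trajectories) show(tr)
})

looksGeographic <- function(x, y) {
  all(abs(x) <= 360) && all(abs(y) <= 90)
}

#' Read trajectories from delimited text
#'
#' Expects a header `id,timestamp,x,y` with an optional `sex` column;
#' timestamps ISO-8601 (UTC). Coordinates must be projected metres:
#' coordinate ranges consistent with geographic lon/lat are rejected rather
#' than silently reprojected, since all radii and distances downstream are
#' metric. Rows whose timestamp cannot be parsed are rejected and reported;
#' duplicate `(id, timestamp)` pairs are an error.
#'
#' @param path CSV/TSV file path.
#' @param crs text descriptor of the projected CRS the coordinates are in.
#' @param sep field separator (default `","`).
#' @return A [TrajectorySet-class]; rejected rows (if any) are attached as
#'   attribute `"rejected"` and reported via [message()].
#' @export
readTrajectories <- function(path, crs = "local-metric", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- parseTimestamps(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    message("rejected ", length(bad), " row(s) with unparseable timestamps ",
            "(line ", paste(bad + 1L, collapse = ", "), ")")
  keep <- !is.na(ts)
  df <- df[keep, , drop = FALSE]
  ts <- ts[keep]
  if (!nrow(df)) stop("no valid rows in ", path)
  dup <- duplicated(paste(df$id, as.numeric(ts)))
  if (any(dup))
    stop("duplicate (id, timestamp) pair(s), first at id=", df$id[dup][1],
         " t=", formatTimestamps(ts[dup][1]))
  if (looksGeographic(df$x, df$y))
    stop("coordinates look geographic (lon/lat); supply projected metres")
  sexcol <- if ("sex" %in% names(df)) df$sex else rep(NA_character_, nrow(df))
  trs <- lapply(split(seq_len(nrow(df)), df$id), function(ix) {
    sx <- sexcol[ix]
    sx <- if (all(is.na(sx))) NA_character_ else unique(sx[!is.na(sx)])[1]
    Trajectory(df$id[ix][1], ts[ix], df$x[ix], df$y[ix], sex = sx)
  })
  ts_out <- TrajectorySet(trs[order(names(trs))], crs = crs)
  attr(ts_out, "rejected") <- bad + 1L # file line numbers (header = line 1)
  ts_out
}

#' Write trajectories to CSV
#'
#' Deterministic column order `id,timestamp,x,y,sex`; full-precision
#' coordinates so that a write/read round trip is lossless.
#'
#' @param trajset a [TrajectorySet-class].
#' @param path output file.
#' @export
writeTrajectories <- function(trajset, path) {
  df <- do.call(rbind, lapply(trajset@trajectories, fixes))
  frac <- any(as.numeric(df$timestamp) %% 1 != 0)
  df$timestamp <- if (frac)
    format(asUTC(df$timestamp), "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  else formatTimestamps(df$timestamp)
  df$x <- formatC(df$x, format = "g", digits = 17)
  df$y <- formatC(df$y, format = "g", digits = 17)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tracking span of a trajectory
#'
#' First and last fix time; the denominator bookkeeping for rescaling visit
#' counts of individuals tracked for different lengths of time.
#'
#' @param traj a [Trajectory-class].
#' @return `POSIXct` vector `c(first, last)`.
#' @export
trackingSpan <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (!nFixes(traj)) stop("empty trajectory")
  traj@t[c(1L, nFixes(traj))]
}
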