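#' Construct a RasterLayer
#'
#' @param name layer name.
#' @param values numeric matrix; row 1 is the top (northernmost) row.
#' @param xmin,ymin lower-left corner (m).
#' @param cellsize cell edge (m).
#' @param nodata missing-value marker used on disk (in memory, `NA`).
#' @param units free-text units.
#' @return A [RasterLayer-class].
#' @export
rasterLayer <- function(name, values, xmin = 0, ymin = 0, cellsize = 1,
                        nodata = -9999, units = "") {
  new("RasterLayer", name = name, values = values, xmin = xmin, ymin = ymin,
      cellsize = cellsize, nodata = nodata, units = units)
}

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat(sprintf(
    "RasterLayer '%s': %d x %d cells of %g m, origin (%g, %g)%s\n",
    object@name, nrow(v), ncol(v), object@cellsize, object@xmin, object@ymin,
    if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

#' Construct a RasterSeries
#'
#' @param name series name.
#' @param times record times (`POSIXct`), strictly increasing.
#' @param layers list of [RasterLayer-class].
#' @param cadenceDays nominal cadence in days.
#' @return A [RasterSeries-class].
#' @export
rasterSeries <- function(name, times, layers, cadenceDays = NA_real_) {
  new("RasterSeries", name = name, times = asUTC(times), layers = layers,
      cadenceDays = cadenceDays)
}

setMethod("show", "RasterSeries", function(object) {
  cat(sprintf("RasterSeries '%s': %d records, %s .. %s (cadence %g d)\n",
              object@name, length(object@times), format(min(object@times)),
              format(max(object@times)), object@cadenceDays))
})

#' Read a raster from ESRI ASCII grid text
#'
#' @param path `.asc` file.
#' @param name layer name (default: file stem).
#' @param units units string.
#' @return A [RasterLayer-class] with on-disk nodata cells set to `NA`.
#' @export
readAsc <- function(path, name = sub("\\.asc$", "", basename(path)),
                    units = "") {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  m[m == nodata] <- NA_real_
  rasterLayer(name, m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              cellsize = vals[["cellsize"]], nodata = nodata, units = units)
}

#' Write a raster to ESRI ASCII grid text
#'
#' @param layer a [RasterLayer-class].
#' @param path output `.asc` file.
#' @export
writeAsc <- function(layer, path) {
  v <- layer@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(layer@xmin, digits = 15)),
    paste("yllcorner", format(layer@ymin, digits = 15)),
    paste("cellsize", format(layer@cellsize, digits = 15)),
    paste("NODATA_value", format(layer@nodata, digits = 15))), con)
  vv <- v
  vv[is.na(vv)] <- layer@nodata
  writeLines(apply(vv, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

# row/col of the cell containing each point; NA outside the extent.
cellIndex <- function(layer, x, y) {
  v <- layer@values
  cs <- layer@cellsize
  col <- floor((x - layer@xmin) / cs) + 1
  rowFromBottom <- floor((y - layer@ymin) / cs) + 1
  # points exactly on the top/right edge belong to the last cell
  col[x == layer@xmin + ncol(v) * cs] <- ncol(v)
  rowFromBottom[y == layer@ymin + nrow(v) * cs] <- nrow(v)
  row <- nrow(v) - rowFromBottom + 1
  bad <- col < 1 | col > ncol(v) | row < 1 | row > nrow(v) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# x/y centre coordinates of every cell, as vectors aligned with as.vector(m).
cellCentres <- function(layer) {
  v <- layer@values
  cs <- layer@cellsize
  xs <- layer@xmin + (seq_len(ncol(v)) - 0.5) * cs
  ys <- layer@ymin + (nrow(v) - seq_len(nrow(v)) + 0.5) * cs
  list(x = rep(xs, each = nrow(v)), y = rep(ys, times = ncol(v)))
}

#' Extract static raster values at points
#'
#' Nearest-cell lookup (the value of the cell containing the point, no
#' interpolation). Points outside the extent or hitting nodata cells yield
#' `NA` and a warning, never a silent drop.
#'
#' @param layer a [RasterLayer-class].
#' @param x,y point coordinates (m).
#' @return numeric vector of values (`NA` = missing).
#' @export
extractStatic <- function(layer, x, y) {
  stopifnot(is(layer, "RasterLayer"))
  idx <- cellIndex(layer, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx[, "row"])
  if (any(!ok)) warning(sum(!ok), " point(s) outside raster extent of '",
                        layer@name, "'")
  out[ok] <- layer@values[idx[ok, , drop = FALSE]]
  out
}

#' Extract dynamic raster values at points and times
#'
#' For each query the record with the largest timestamp at or before the
#' query time is used (the last record before entry; a record exactly at the
#' entry time counts). Queries before the first record are missing -- the
#' extraction never looks into the future.
#'
#' @param series a [RasterSeries-class].
#' @param x,y point coordinates (m).
#' @param t query times (`POSIXct`), recycled against points.
#' @return numeric vector of values (`NA` = missing).
#' @export
extractDynamic <- function(series, x, y, t) {
  stopifnot(is(series, "RasterSeries"))
  n <- max(length(x), length(t))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  tt <- rep_len(as.numeric(asUTC(t)), n)
  idx <- findInterval(tt, as.numeric(series@times))
  out <- rep(NA_real_, n)
  for (k in unique(idx[idx >= 1L])) {
    sel <- which(idx == k)
    out[sel] <- extractStatic(series@layers[[k]], x[sel], y[sel])
  }
  out
}

#' Terrain slope (degrees) from an elevation raster
#'
#' Horn's 3x3 finite-difference gradient; border cells use edge replication
#' and are flagged in the attribute `"border"`. The modelling transform for
#' slope is `log1p` (not plain `log`): flat terrain (0 degrees) occurs, and
#' `log1p` keeps it finite while preserving the log-scale compression of the
#' skewed slope distribution.
#'
#' @param elev elevation [RasterLayer-class] (m), at least 3x3.
#' @return A [RasterLayer-class] of slope in degrees, with a logical matrix
#'   attribute `"border"` marking edge-replicated cells.
#' @export
slopeFromElevation <- function(elev) {
  z <- elev@values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("elevation grid must be >= 3x3")
  cs <- elev@cellsize
  pad <- z[c(1, seq_len(nrow(z)), nrow(z)), c(1, seq_len(ncol(z)), ncol(z))]
  i <- seq_len(nrow(z)) + 1L; j <- seq_len(ncol(z)) + 1L
  zNW <- pad[i - 1L, j - 1L]; zN <- pad[i - 1L, j]; zNE <- pad[i - 1L, j + 1L]
  zW <- pad[i, j - 1L]; zE <- pad[i, j + 1L]
  zSW <- pad[i + 1L, j - 1L]; zS <- pad[i + 1L, j]; zSE <- pad[i + 1L, j + 1L]
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  dzdy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out <- rasterLayer(paste0(elev@name, "_slope"), slope, xmin = elev@xmin,
                     ymin = elev@ymin, cellsize = cs, nodata = elev@nodata,
                     units = "degrees")
  border <- matrix(FALSE, nrow(z), ncol(z))
  border[c(1L, nrow(z)), ] <- TRUE; border[, c(1L, ncol(z))] <- TRUE
  attr(out, "border") <- border
  out
}

#' Read a raster series from an index CSV
#'
#' The index has columns `timestamp,path` (paths relative to the index file);
#' each referenced file is an ESRI ASCII grid.
#'
#' @param indexPath index CSV.
#' @param name series name.
#' @param cadenceDays nominal cadence in days.
#' @return A [RasterSeries-class].
#' @export
readSeriesIndex <- function(indexPath, name = basename(indexPath),
                            cadenceDays = NA_real_) {
  idx <- read.csv(indexPath, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "path") %in% names(idx)))
  tt <- parseTimestamps(idx$timestamp)
  o <- order(tt)
  layers <- lapply(idx$path[o], function(p)
    readAsc(file.path(dirname(indexPath), p)))
  rasterSeries(name, tt[o], layers, cadenceDays)
}

#' Write a raster series plus its index CSV
#'
#' @param series a [RasterSeries-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return path of the written index CSV.
#' @export
writeSeriesIndex <- function(series, dir, prefix = series@name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.asc", prefix, seq_along(series@layers))
  for (k in seq_along(series@layers))
    writeAsc(series@layers[[k]], file.path(dir, files[k]))
  idx <- data.frame(timestamp = formatTimestamps(series@times), path = files)
  out <- file.path(dir, paste0(prefix, "_index.csv"))
  write.csv(idx, out, row.names = FALSE, quote = FALSE)
  out
}
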