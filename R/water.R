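#' Construct WaterFeatures
#'
#' @param features list of `list(type =, coords =)` elements; `type` one of
#'   `"point"`, `"line"`, `"polygon"`, `coords` a 2-column metre matrix.
#' @return A [WaterFeatures-class].
#' @export
waterFeatures <- function(features = list()) {
  features <- lapply(features, function(f) {
    f$coords <- matrix(as.numeric(f$coords), ncol = 2)
    f
  })
  new("WaterFeatures", features = features)
}

setMethod("show", "WaterFeatures", function(object) {
  tp <- vapply(object@features, `[[`, character(1), "type")
  cat(sprintf("WaterFeatures: %d point, %d line, %d polygon feature(s)\n",
              sum(tp == "point"), sum(tp == "line"), sum(tp == "polygon")))
})

coordMatrix <- function(cc) {
  do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
}

#' Read water features from GeoJSON
#'
#' Supports FeatureCollection / Feature / bare geometries with Point,
#' MultiPoint, LineString, MultiLineString, Polygon and MultiPolygon types.
#' Coordinates are taken as already projected (metres); polygon holes are
#' kept as separate rings.
#'
#' @param path GeoJSON file.
#' @return A [WaterFeatures-class].
#' @export
readWaterGeoJSON <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- list()
  addGeom <- function(geom) {
    ty <- geom$type
    cc <- geom$coordinates
    if (ty == "Point") {
      feats[[length(feats) + 1L]] <<- list(type = "point",
        coords = matrix(as.numeric(unlist(cc)), ncol = 2))
    } else if (ty == "MultiPoint") {
      for (p in cc) feats[[length(feats) + 1L]] <<- list(type = "point",
        coords = matrix(as.numeric(unlist(p)), ncol = 2))
    } else if (ty == "LineString") {
      feats[[length(feats) + 1L]] <<- list(type = "line",
                                           coords = coordMatrix(cc))
    } else if (ty == "MultiLineString") {
      for (l in cc) feats[[length(feats) + 1L]] <<- list(type = "line",
                                                         coords = coordMatrix(l))
    } else if (ty == "Polygon") {
      for (ring in cc) feats[[length(feats) + 1L]] <<-
        list(type = "polygon", coords = coordMatrix(ring))
    } else if (ty == "MultiPolygon") {
      for (poly in cc) for (ring in poly) feats[[length(feats) + 1L]] <<-
        list(type = "polygon", coords = coordMatrix(ring))
    } else if (ty == "GeometryCollection") {
      for (gg in geom$geometries) addGeom(gg)
    } else stop("unsupported GeoJSON geometry: ", ty)
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) addGeom(f$geometry)
  } else if (identical(g$type, "Feature")) {
    addGeom(g$geometry)
  } else addGeom(g)
  waterFeatures(feats)
}

#' Write water features to GeoJSON
#'
#' @param water a [WaterFeatures-class].
#' @param path output file.
#' @export
writeWaterGeoJSON <- function(water, path) {
  featJson <- lapply(water@features, function(f) {
    cc <- f$coords
    geom <- switch(f$type,
      point = list(type = "Point", coordinates = c(cc[1, 1], cc[1, 2])),
      line = list(type = "LineString",
                  coordinates = lapply(seq_len(nrow(cc)),
                                       function(i) c(cc[i, 1], cc[i, 2]))),
      polygon = list(type = "Polygon",
                     coordinates = list(lapply(seq_len(nrow(cc)),
                                        function(i) c(cc[i, 1], cc[i, 2])))))
    list(type = "Feature", properties = list(class = "water"),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = featJson),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Planar distance to the nearest water feature
#'
#' Euclidean distance to the nearest point/segment of any feature; points
#' inside a polygon feature are at distance 0. The square root of the
#' distance is returned alongside the raw metres: available area grows
#' quadratically with distance from water, and the square-root transform is
#' the modelling column that corrects for it.
#'
#' @param x,y query coordinates (m).
#' @param water a [WaterFeatures-class].
#' @return data frame with columns `dist` (m) and `distSqrt` (sqrt m).
#' @export
distanceToWater <- function(x, y, water) {
  stopifnot(is(water, "WaterFeatures"))
  if (!length(water@features)) stop("no water features")
  segs <- list(); pts <- list()
  polys <- list()
  for (f in water@features) {
    cc <- f$coords
    if (f$type == "point") {
      pts[[length(pts) + 1L]] <- cc
    } else {
      ring <- cc
      if (f$type == "polygon") {
        if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
        polys[[length(polys) + 1L]] <- f$coords
      }
      if (nrow(ring) >= 2)
        segs[[length(segs) + 1L]] <- cbind(ring[-nrow(ring), , drop = FALSE],
                                           ring[-1, , drop = FALSE])
    }
  }
  S <- if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(0), ncol = 4)
  P <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), ncol = 2)
  d <- cpp_dist_to_segments(as.numeric(x), as.numeric(y),
                            S[, 1], S[, 2], S[, 3], S[, 4], P[, 1], P[, 2])
  for (ring in polys) {
    inside <- cpp_points_in_poly(as.numeric(x), as.numeric(y),
                                 ring[, 1], ring[, 2])
    d[inside] <- 0
  }
  data.frame(dist = d, distSqrt = sqrt(d))
}
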