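# Shoelace area of a polygon given as a vertex matrix (implicitly closed).
polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Robust containment in a convex CCW polygon: inside (or on boundary, to
# tolerance) iff every edge's cross product is non-negative.
inConvexHull <- function(px, py, v, eps = 1e-9) {
  ok <- rep(TRUE, length(px))
  n <- nrow(v)
  scale <- max(abs(v)) + 1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (px - v[i, 1])
    ok <- ok & cr >= -eps * scale * scale
  }
  ok
}

# chull() returns clockwise order; reorient counter-clockwise.
ccwHull <- function(x, y) {
  h <- grDevices::chull(x, y)
  v <- cbind(x[h], y[h])
  j <- c(seq_len(nrow(v))[-1], 1L)
  if (sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

#' Default a-LoCoH radius: maximum pairwise distance
#'
#' With `a` set to the maximum observed distance between points, every local
#' hull can draw on all points, which collapses the isopleth-1 a-LoCoH
#' polygon to the global convex hull. The maximum pairwise distance is
#' always attained between convex-hull vertices, so it is computed exactly
#' from the hull for any number of points.
#'
#' @param x,y point coordinates (m).
#' @return maximum pairwise distance (m).
#' @export
defaultA <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(paste(x, y))) < 2L) stop("need at least 2 distinct points")
  if (length(x) > 3) {
    h <- grDevices::chull(x, y)
    if (length(h) >= 2) { x <- x[h]; y <- y[h] }
  }
  max(dist(cbind(x, y)))
}

#' Adaptive local convex hull (a-LoCoH) home range
#'
#' For each root point, neighbours are added in order of increasing distance
#' while they remain within the adaptive radius `a` of the root; the convex
#' hull of each local set is formed; hulls are sorted by ascending area and
#' unioned until the union contains at least the isopleth fraction of the
#' input points. Setting `a` to the maximum observed distance between
#' points therefore lets every local hull draw on all points, which is the
#' parameterisation that encompasses the full data.
#' The union is represented by its member hulls (membership = inside any
#' hull); when one hull contains all others -- always the case at
#' `a = defaultA(x, y)` -- the union is that hull and its area is exact,
#' otherwise the area is a fine-grid estimate.
#'
#' @param x,y point coordinates (m), at least 3 non-collinear points.
#' @param a adaptive radius (m); default the maximum pairwise distance.
#' @param isopleth fraction of points the union must contain, in (0, 1].
#' @return A [HomeRange-class].
#' @export
aLoCoH <- function(x, y, a = defaultA(x, y), isopleth = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (isopleth <= 0 || isopleth > 1) stop("isopleth must be in (0, 1]")
  if (a <= 0) stop("a must be > 0")
  if (n < 3L) stop("need at least 3 points")
  if (length(grDevices::chull(x, y)) < 3L)
    stop("degenerate geometry: all points collinear")
  D <- as.matrix(dist(cbind(x, y)))
  hulls <- list(); areas <- numeric(0); seen <- character(0)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    keep <- o[D[i, o] <= a]
    if (length(keep) < 3L) next
    key <- paste(sort(keep), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(grDevices::chull(x[keep], y[keep])) < 3L) next
    v <- ccwHull(x[keep], y[keep])
    hulls[[length(hulls) + 1L]] <- v
    areas <- c(areas, polygonArea(v))
  }
  if (!length(hulls)) stop("no non-degenerate local hull; increase a")
  o <- order(areas)
  hulls <- hulls[o]; areas <- areas[o]
  covered <- rep(FALSE, n)
  used <- integer(0)
  for (k in seq_along(hulls)) {
    todo <- !covered
    if (any(todo))
      covered[todo] <- inConvexHull(x[todo], y[todo], hulls[[k]])
    used <- c(used, k)
    if (mean(covered) >= isopleth) break
  }
  hulls <- hulls[used]; areas <- areas[used]
  big <- which.max(areas)
  collapsed <- all(vapply(seq_along(hulls), function(k) {
    k == big || all(inConvexHull(hulls[[k]][, 1], hulls[[k]][, 2],
                                 hulls[[big]]))
  }, logical(1)))
  if (collapsed) {
    area <- areas[big]
    poly <- hulls[[big]]
  } else {
    bb <- apply(do.call(rbind, hulls), 2, range)
    gx <- seq(bb[1, 1], bb[2, 1], length.out = 201)
    gy <- seq(bb[1, 2], bb[2, 2], length.out = 201)
    gpts <- expand.grid(gx = gx, gy = gy)
    inAny <- rep(FALSE, nrow(gpts))
    for (h in hulls) {
      todo <- !inAny
      if (any(todo)) inAny[todo] <- inConvexHull(gpts$gx[todo], gpts$gy[todo], h)
    }
    area <- mean(inAny) * diff(bb[, 1]) * diff(bb[, 2])
    poly <- matrix(numeric(0), ncol = 2)
  }
  new("HomeRange", hulls = hulls, polygon = poly, aValue = a,
      isopleth = isopleth, area = area, areaExact = collapsed)
}

setMethod("show", "HomeRange", function(object) {
  cat(sprintf(
    "HomeRange (a-LoCoH): a = %.1f m, isopleth %g, %d hull(s), area %s km^2%s\n",
    object@aValue, object@isopleth, length(object@hulls),
    format(object@area / 1e6, digits = 4),
    if (object@areaExact) "" else " (grid estimate)"))
})

#' Test whether points lie inside a home range
#'
#' @param hr a [HomeRange-class].
#' @param x,y point coordinates (m).
#' @return logical vector (inside any member hull, boundary inclusive).
#' @export
containsPoints <- function(hr, x, y) {
  inAny <- rep(FALSE, length(x))
  for (h in hr@hulls) {
    todo <- !inAny
    if (!any(todo)) break
    inAny[todo] <- inConvexHull(x[todo], y[todo], h)
  }
  inAny
}

#' Sample availability points by complete spatial randomness
#'
#' Rejection-samples points uniformly over the home range with the buffered
#' water area excluded, and stamps each accepted point with an entry time
#' drawn uniformly with replacement from the observed visit entry times (a
#' stamped time is needed to extract dynamic covariates for random points).
#'
#' @param hr a [HomeRange-class].
#' @param water a [WaterFeatures-class] (may be empty).
#' @param buffer water exclusion distance (m); accepted points are strictly
#'   farther than this from any water feature.
#' @param n number of points.
#' @param entryTimes pool of visit entry times (`POSIXct`).
#' @param seed RNG seed (reproducible draws for a fixed seed).
#' @return data frame `x, y, stampedTime`.
#' @export
sampleAvailable <- function(hr, water, buffer, n, entryTimes, seed = NULL) {
  stopifnot(is(hr, "HomeRange"), n >= 1, length(entryTimes) >= 1)
  bb <- apply(do.call(rbind, hr@hulls), 2, range)
  withSeed(seed, {
    accX <- numeric(0); accY <- numeric(0)
    tried <- 0
    while (length(accX) < n) {
      m <- max(10000L, 2L * (n - length(accX)))
      px <- runif(m, bb[1, 1], bb[2, 1])
      py <- runif(m, bb[1, 2], bb[2, 2])
      ok <- containsPoints(hr, px, py)
      if (length(water@features) && buffer >= 0)
        ok[ok] <- distanceToWater(px[ok], py[ok], water)$dist > buffer
      tried <- tried + m
      accX <- c(accX, px[ok]); accY <- c(accY, py[ok])
      if (tried >= 50000L && (length(accX) / tried) < 1e-4)
        stop("region nearly empty: acceptance rate < 1e-4")
    }
    data.frame(x = accX[seq_len(n)], y = accY[seq_len(n)],
               stampedTime = sample(asUTC(entryTimes), n, replace = TRUE))
  })
}
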