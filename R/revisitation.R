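#' Recursion configuration constructor
#'
#' Defaults follow the analysis the package implements: a 250 m circle,
#' a 12 h minimum time away before a return counts as a new visit, and the
#' candidate radii 100--500 m screened by the variance-peak rule.
#'
#' @param radius circle radius in metres.
#' @param minTimeAway minimum time away, hours.
#' @param candidateRadii candidate radii (m), strictly increasing.
#' @return A [RecursionConfig-class].
#' @export
recursionConfig <- function(radius = 250, minTimeAway = 12,
                            candidateRadii = c(100, 200, 250, 300, 400, 500)) {
  new("RecursionConfig", radius = radius, minTimeAway = minTimeAway,
      candidateRadii = candidateRadii)
}

#' Crossing times of a moving segment with a circle
#'
#' Solves \eqn{|p_0 + s (p_1 - p_0) - c|^2 = r^2} for \eqn{s \in (0, 1)}
#' under constant-velocity interpolation between the two fixes, so each
#' crossing time is \eqn{t_0 + s (t_1 - t_0)}. Tangency (zero discriminant)
#' is not a crossing: grazing contact never changes in/out state under the
#' closed-disc convention.
#'
#' @param p0,p1 numeric `c(x, y, t)` with `t` in seconds (or `POSIXct`
#'   convertible); `p0[3] < p1[3]`.
#' @param centre numeric `c(x, y)`.
#' @param radius circle radius (m).
#' @return data frame with columns `s` and `t`, 0--2 rows, increasing `s`.
#' @export
circleCrossings <- function(p0, p1, centre, radius) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (any(!is.finite(c(p0, p1, centre, radius))))
    stop("non-finite input")
  if (p0[3] >= p1[3]) stop("p0 must precede p1 in time")
  d <- p1[1:2] - p0[1:2]
  a <- sum(d^2)
  empty <- data.frame(s = numeric(0), t = numeric(0))
  if (a <= 0) return(empty)
  f <- p0[1:2] - centre
  b <- 2 * sum(f * d)
  cc <- sum(f^2) - radius^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(empty)
  s <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  s <- s[s > 0 & s < 1]
  data.frame(s = s, t = p0[3] + s * (p1[3] - p0[3]))
}

#' Detect visits of a trajectory to a circle
#'
#' Computes maximal in-circle intervals from the fixes plus interpolated
#' boundary-crossing times, then merges consecutive intervals whose outside
#' gap is strictly shorter than `minTimeAway` -- brief excursions do not
#' start a new visit; an absence of at least the threshold does. A track
#' that starts (ends) inside the circle opens (closes) its interval at the
#' first (last) fix time. Fixes exactly on the boundary count as inside.
#'
#' @param traj a [Trajectory-class].
#' @param centre numeric `c(x, y)` circle centre (m).
#' @param cfg a [RecursionConfig-class].
#' @return data frame with `POSIXct` columns `tEnter`, `tExit`, one row per
#'   visit, time-ordered.
#' @export
detectVisits <- function(traj, centre, cfg = recursionConfig()) {
  stopifnot(is(traj, "Trajectory"), is(cfg, "RecursionConfig"))
  if (!nFixes(traj)) stop("empty trajectory")
  res <- cpp_detect_visits(as.numeric(traj@t), traj@x, traj@y,
                           centre[1], centre[2], cfg@radius,
                           cfg@minTimeAway * HOUR)
  data.frame(
    tEnter = as.POSIXct(res$tEnter, origin = "1970-01-01", tz = "UTC"),
    tExit = as.POSIXct(res$tExit, origin = "1970-01-01", tz = "UTC"))
}

#' Moving-circle revisitation table
#'
#' The circle is moved along the tracking data points of each individual:
#' every fix becomes a candidate site centred at that fix, and visits of that
#' individual's own track to the circle are counted. `nVisits` counts all
#' maximal visit intervals including the first, so every site has
#' `nVisits >= 1`. Sites are deliberately not deduplicated across
#' overlapping circles; downstream stages consume the table as produced.
#'
#' @param trajset a [TrajectorySet-class].
#' @param cfg a [RecursionConfig-class].
#' @param radius optional override of `cfg@radius` (m).
#' @param storeVisits keep per-visit entry/exit times (needed downstream;
#'   switch off when only counts are wanted, e.g. radius screening).
#' @return list of class `"revisitTable"`: `$sites` (`siteId, individualId,
#'   sex, cx, cy, nVisits`) and `$visits` (`siteId, tEnter, tExit`), ordered
#'   by individual then fix time.
#' @export
revisitationTable <- function(trajset, cfg = recursionConfig(), radius = NULL,
                              storeVisits = TRUE) {
  stopifnot(is(trajset, "TrajectorySet"))
  r <- if (is.null(radius)) cfg@radius else radius
  sites <- list(); visits <- list()
  for (id in names(trajset@trajectories)) {
    tr <- trajset@trajectories[[id]]
    res <- cpp_revisit_table(as.numeric(tr@t), tr@x, tr@y, r,
                             cfg@minTimeAway * HOUR, storeVisits)
    sid <- sprintf("%s:%06d", id, seq_len(nFixes(tr)))
    sites[[id]] <- data.frame(
      siteId = sid, individualId = id, sex = tr@sex,
      cx = tr@x, cy = tr@y, tFix = tr@t, nVisits = res$nVisits,
      stringsAsFactors = FALSE)
    if (storeVisits)
      visits[[id]] <- data.frame(
        siteId = sid[res$site],
        tEnter = as.POSIXct(res$tEnter, origin = "1970-01-01", tz = "UTC"),
        tExit = as.POSIXct(res$tExit, origin = "1970-01-01", tz = "UTC"),
        stringsAsFactors = FALSE)
  }
  out <- list(sites = do.call(rbind, c(sites, make.row.names = FALSE)),
              visits = if (storeVisits)
                do.call(rbind, c(visits, make.row.names = FALSE)),
              radius = r, minTimeAway = cfg@minTimeAway)
  class(out) <- "revisitTable"
  out
}

#' @export
print.revisitTable <- function(x, ...) {
  cat(sprintf(
    "revisitTable: %d sites, %d individuals, radius %g m, min away %g h\n",
    nrow(x$sites), length(unique(x$sites$individualId)), x$radius,
    x$minTimeAway))
  cat(sprintf("  visit counts: median %g, max %g\n",
              median(x$sites$nVisits), max(x$sites$nVisits)))
  invisible(x)
}

#' Variance-peak selection of the recursion radius
#'
#' A circle that is too small yields uniformly low visit counts; one that is
#' too large homogenises counts across sites. The most informative radius is
#' where the across-site variance of visit counts peaks. The variance is
#' computed per individual and summarised across individuals by the median
#' (a per-individual criterion aggregated robustly); ties break to the
#' smaller radius.
#'
#' @param trajset a [TrajectorySet-class].
#' @param cfg a [RecursionConfig-class] providing `candidateRadii` and
#'   `minTimeAway`.
#' @return selected radius (m), with the per-radius summarised variances as
#'   attribute `"variances"`.
#' @export
selectRadius <- function(trajset, cfg = recursionConfig()) {
  radii <- cfg@candidateRadii
  if (length(radii) < 2L) stop("need at least 2 candidate radii")
  vsum <- vapply(radii, function(r) {
    pv <- vapply(trajset@trajectories, function(tr) {
      res <- cpp_revisit_table(as.numeric(tr@t), tr@x, tr@y, r,
                               cfg@minTimeAway * HOUR, FALSE)
      var(as.numeric(res$nVisits))
    }, numeric(1))
    median(pv, na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(vsum) | vsum == 0)) stop("no revisitation structure")
  sel <- radii[which.max(vsum)] # which.max takes the first (smaller) on ties
  attr(sel, "variances") <- setNames(vsum, radii)
  sel
}

#' Remove revisitation sites near water
#'
#' Water-bound sites reflect drinking rather than foraging; every site whose
#' centre lies within `buffer` metres of any water feature is dropped.
#'
#' @param rt a `"revisitTable"` (see [revisitationTable()]).
#' @param water a [WaterFeatures-class].
#' @param buffer exclusion distance (m); a site at distance `<= buffer` is
#'   removed, so `buffer = 0` removes only sites exactly on water.
#' @return the filtered `"revisitTable"`; number removed is reported and
#'   stored as attribute `"nRemoved"`.
#' @export
filterWaterSites <- function(rt, water, buffer = 500) {
  stopifnot(inherits(rt, "revisitTable"), buffer >= 0)
  if (!length(water@features)) {
    warning("empty water set: all sites kept")
    attr(rt, "nRemoved") <- 0L
    return(rt)
  }
  d <- distanceToWater(rt$sites$cx, rt$sites$cy, water)$dist
  drop <- d <= buffer
  message(sum(drop), " site(s) removed within ", buffer, " m of water")
  rt$sites <- rt$sites[!drop, , drop = FALSE]
  if (!is.null(rt$visits))
    rt$visits <- rt$visits[rt$visits$siteId %in% rt$sites$siteId, ,
                           drop = FALSE]
  attr(rt, "nRemoved") <- sum(drop)
  rt
}
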