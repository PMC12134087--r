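#' Collinearity screen for covariate columns
#'
#' Pairwise Pearson correlations on complete rows; for every pair with
#' `|r|` strictly greater than the threshold the lower-priority column is
#' dropped (the canonical case: nitrogen dropped in favour of the
#' ecologically prioritised phosphorus when the two soil nutrients are
#' correlated above 0.5). A pair at exactly the threshold is kept. Constant
#' columns have undefined correlations; they are flagged, never dropped
#' silently.
#'
#' @param df data frame of numeric covariate columns.
#' @param threshold drop threshold on `|r|` (strictly greater).
#' @param priority column names in decreasing priority; defaults to the
#'   column order of `df`.
#' @return list with `retained`, `dropped`, `flagged` (constant columns) and
#'   the full correlation matrix `cor`.
#' @export
correlationScreen <- function(df, threshold = 0.5, priority = names(df)) {
  stopifnot(is.data.frame(df), ncol(df) >= 2L)
  df <- df[, priority, drop = FALSE]
  cc <- df[complete.cases(df), , drop = FALSE]
  if (nrow(cc) < 3L) stop("need at least 3 complete rows")
  sds <- vapply(cc, sd, numeric(1))
  flagged <- names(cc)[sds == 0]
  cm <- suppressWarnings(cor(cc))
  active <- setdiff(priority, flagged)
  retained <- character(0); dropped <- character(0)
  for (v in active) {
    hit <- retained[abs(cm[retained, v]) > threshold]
    if (length(hit)) dropped <- c(dropped, v) else retained <- c(retained, v)
  }
  list(retained = retained, dropped = dropped, flagged = flagged, cor = cm)
}

#' Join environmental covariates to sites or points
#'
#' Builds one covariate row per input point: static layers are extracted
#' once at the point (nearest cell); dynamic series use the last record at
#' or before the point's timestamp; distance to water is stored raw and
#' square-root transformed; slope is derived from elevation (Horn gradient)
#' and `log1p`-transformed. Covariates are taken at the site centre (the
#' fix that defines the circle), not averaged over the circle.
#'
#' @param x,y point coordinates (m).
#' @param t per-point timestamps (`POSIXct`): visit entry times for
#'   revisitation sites, stamped times for availability points.
#' @param layers named list of static [RasterLayer-class] objects; must
#'   contain `phosphorus`, `nitrogen` and `elevation`.
#' @param series named list of [RasterSeries-class] objects; expected names
#'   `evi`, `temperature`, `precipitation`.
#' @param water a [WaterFeatures-class].
#' @return data frame with raw and transformed covariate columns plus a
#'   logical `complete` flag (rows with any missing extraction are flagged,
#'   not dropped).
#' @export
buildCovariates <- function(x, y, t, layers, series, water) {
  stopifnot(all(c("phosphorus", "nitrogen", "elevation") %in% names(layers)))
  slope <- slopeFromElevation(layers$elevation)
  dw <- distanceToWater(x, y, water)
  out <- data.frame(
    x = x, y = y, t = asUTC(t),
    distWater = dw$dist, dw = dw$distSqrt,
    phos = extractStatic(layers$phosphorus, x, y),
    nitrogen = extractStatic(layers$nitrogen, x, y),
    slopeDeg = extractStatic(slope, x, y))
  out$slope <- log1p(out$slopeDeg)
  for (nm in intersect(c("evi", "temperature", "precipitation"),
                       names(series)))
    out[[nm]] <- extractDynamic(series[[nm]], x, y, t)
  out$complete <- stats::complete.cases(
    out[, setdiff(names(out), c("x", "y", "t")), drop = FALSE])
  out
}
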