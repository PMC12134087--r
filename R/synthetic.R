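#' Synthetic-study configuration
#'
#' Defaults mirror the field conditions the pipeline is built for: 41
#' individuals (29 bulls, 12 cows) on hourly fixes over multiple years, a
#' planted hotspot structure at the 250 m scale, a phosphorus--nitrogen
#' field correlation of 0.8, and concave (hump-shaped) planted effects of
#' standardized phosphorus and square-root distance-to-water on hotspot
#' attractiveness. Effects are planted on the transformed covariates so the
#' generator truth and the pipeline's modelling columns share one scale.
#'
#' @param domain domain size `c(x, y)` in metres.
#' @param cellsize raster cell size (m).
#' @param nIndividuals,nBulls number of individuals and how many are bulls.
#' @param durationYears tracking duration per individual (years).
#' @param fixIntervalHours fix cadence (h); must divide 24.
#' @param startDate first fix date (UTC); default July 1 so season-years are
#'   complete.
#' @param K number of hotspots.
#' @param hotspotScale spatial scale of revisited sites (m).
#' @param minHotspotSep minimum distance between hotspot centres (m).
#' @param beta planted attraction coefficients, named
#'   `phos, phos2, dw, dw2` (linear and quadratic on standardized
#'   phosphorus and standardized sqrt distance-to-water).
#' @param rhoPN target phosphorus--nitrogen field correlation.
#' @param smoothingLength Gaussian smoothing length of covariate fields (m).
#' @param stepMean,stepShape travel step-length gamma parameters (m per fix
#'   interval).
#' @param persistence directional persistence weight in `[0, 1)`.
#' @param headingSd wrapped-normal heading noise (radians).
#' @param dwellMeanH,dwellShape hotspot dwell-time gamma parameters (h).
#' @param dwellWander dwell wander radius around the hotspot centre (m).
#' @param excursionMeanLoops mean number of local excursion loops per
#'   hotspot visit (geometric).
#' @param excursionDist excursion distance range `c(lo, hi)` (m).
#' @param excursionDwellMeanH,excursionDwellShape excursion dwell gamma
#'   parameters (h); excursions last longer than the minimum time-away, so
#'   mid-sized circles resolve each loop as a separate revisit while large
#'   circles, which the wandering animal never fully leaves, absorb them.
#' @param excursionWander wander radius at the excursion point (m).
#' @param redwellMeanH mean re-dwell at the hotspot between loops (h).
#' @param waterholeIntensity expected number of waterholes over the domain.
#' @param seed master seed; the whole study is a pure function of the
#'   configuration and this seed.
#' @return object of class `"studyConfig"`.
#' @export
studyConfig <- function(domain = c(10000, 10000), cellsize = 100,
                        nIndividuals = 41, nBulls = 29, durationYears = 2,
                        fixIntervalHours = 1, startDate = "2015-07-01",
                        K = 15, hotspotScale = 250, minHotspotSep = 1500,
                        beta = c(phos = 1.0, phos2 = -1.0,
                                 dw = 0.8, dw2 = -0.8),
                        rhoPN = 0.8, smoothingLength = 500,
                        stepMean = 800, stepShape = 3, persistence = 0.5,
                        headingSd = 0.3, dwellMeanH = 10, dwellShape = 2,
                        dwellWander = 300, excursionMeanLoops = 1,
                        excursionDist = c(400, 800),
                        excursionDwellMeanH = 16, excursionDwellShape = 6,
                        excursionWander = 100, redwellMeanH = 4,
                        waterholeIntensity = 15, seed = 1) {
  stopifnot(all(domain > 0), cellsize > 0, nIndividuals >= 1,
            nBulls <= nIndividuals, durationYears > 0,
            24 %% fixIntervalHours == 0, K >= 2, hotspotScale > 0,
            rhoPN >= 0 && rhoPN < 1)
  if (smoothingLength < cellsize)
    stop("smoothingLength must be >= cellsize")
  cfg <- as.list(environment())
  cfg$startDate <- as.POSIXct(startDate, tz = "UTC")
  class(cfg) <- "studyConfig"
  cfg
}

# Gaussian smoothing of a matrix by separable convolution with
# edge-renormalisation (kernel mass outside the grid is discarded).
gaussSmooth <- function(m, sigmaCells) {
  n <- nrow(m); p <- ncol(m)
  half <- max(1L, ceiling(3 * sigmaCells))
  k <- dnorm(seq(-half, half), sd = sigmaCells)
  bandMat <- function(size) {
    B <- matrix(0, size, size)
    for (d in seq(-half, half)) {
      i <- seq_len(size) + d
      ok <- i >= 1 & i <= size
      B[cbind(i[ok], seq_len(size)[ok])] <- B[cbind(i[ok], seq_len(size)[ok])] +
        k[d + half + 1]
    }
    B
  }
  Br <- bandMat(n); Bc <- bandMat(p)
  (Br %*% m %*% Bc) / (Br %*% matrix(1, n, p) %*% Bc)
}

zstd <- function(v) (v - mean(v)) / sd(v)

seasonSignal <- function(t, peakDoy = 15) {
  doy <- as.numeric(format(asUTC(t), "%j"))
  # default peak mid-January (southern wet season); temperature peaks in
  # October, offset from greenness so the two are not collinear
  cos(2 * pi * (doy - peakDoy) / 365.25)
}

#' Generate synthetic covariate fields and dynamic series
#'
#' Static fields (phosphorus, nitrogen, elevation) are Gaussian-smoothed
#' white noise; nitrogen is built as
#' `rho * z(P) + sqrt(1 - rho^2) * independent field` so the P--N
#' correlation is controlled. EVI, NDVI and day land-surface temperature
#' series combine a spatial field with a seasonal sinusoid peaking
#' mid-January plus noise (16-, 16- and 8-day cadence); precipitation is a
#' seasonal sinusoid with multiplicative noise on a 5-day cadence.
#'
#' @param cfg a `"studyConfig"`.
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `layers` (named [RasterLayer-class] list) and `series`
#'   (named [RasterSeries-class] list including `ndvi`).
#' @export
genFields <- function(cfg, seed = cfg$seed) {
  nr <- ceiling(cfg$domain[2] / cfg$cellsize)
  nc <- ceiling(cfg$domain[1] / cfg$cellsize)
  sig <- cfg$smoothingLength / cfg$cellsize
  withSeed(seed, {
    field <- function() zstd(gaussSmooth(matrix(rnorm(nr * nc), nr, nc), sig))
    zP <- field(); zI <- field(); zE <- field(); zT <- field()
    zV <- field(); zV2 <- field()
    zN <- cfg$rhoPN * zP + sqrt(1 - cfg$rhoPN^2) * zI
    mk <- function(name, v, units) rasterLayer(name, v, xmin = 0, ymin = 0,
                                               cellsize = cfg$cellsize,
                                               units = units)
    layers <- list(
      phosphorus = mk("phosphorus", 15 + 5 * zP, "ppm"),
      nitrogen = mk("nitrogen", 2 + 0.5 * zN, "g/kg"),
      elevation = mk("elevation", 300 + 50 * zE, "m"))
    t0 <- cfg$startDate
    nDays <- ceiling(cfg$durationYears * 365) + 32
    mkSeries <- function(name, cadence, f) {
      times <- seq(t0 - 32 * DAY, t0 + nDays * DAY, by = cadence * DAY)
      rasterSeries(name, times, lapply(times, f), cadence)
    }
    series <- list(
      evi = mkSeries("evi", 16, function(t) mk("evi",
        0.30 + 0.05 * zV + 0.15 * seasonSignal(t) +
          matrix(rnorm(nr * nc, sd = 0.02), nr, nc), "")),
      temperature = mkSeries("temperature", 8, function(t) mk("temperature",
        300 + 3 * zT + 6 * seasonSignal(t, peakDoy = 288) +
          matrix(rnorm(nr * nc, sd = 0.5), nr, nc), "K")),
      precipitation = mkSeries("precipitation", 5, function(t) mk(
        "precipitation",
        pmax(15 * (1 + seasonSignal(t)) / 2 *
               exp(matrix(rnorm(nr * nc, sd = 0.2), nr, nc)), 0), "mm/5d")),
      ndvi = mkSeries("ndvi", 16, function(t) mk("ndvi",
        0.40 + 0.05 * zV2 + 0.20 * seasonSignal(t) +
          matrix(rnorm(nr * nc, sd = 0.02), nr, nc), "")))
    list(layers = layers, series = series)
  })
}

#' Generate synthetic water features
#'
#' One polyline river crossing the domain west to east plus
#' Poisson-scattered waterhole points.
#'
#' @param cfg a `"studyConfig"`.
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return A [WaterFeatures-class].
#' @export
genWater <- function(cfg, seed = cfg$seed + 1) {
  withSeed(seed, {
    X <- cfg$domain[1]; Y <- cfg$domain[2]
    xs <- seq(0, X, by = 250)
    wander <- cumsum(rnorm(length(xs), sd = 120))
    wander <- stats::filter(wander, rep(1 / 5, 5), circular = TRUE)
    ys <- pmin(Y * 0.9, pmax(Y * 0.1, Y * 0.5 + as.numeric(wander)))
    feats <- list(list(type = "line", coords = cbind(xs, ys)))
    nWh <- rpois(1, cfg$waterholeIntensity)
    if (nWh > 0) {
      wx <- runif(nWh, 0, X); wy <- runif(nWh, 0, Y)
      for (i in seq_len(nWh))
        feats[[length(feats) + 1L]] <- list(type = "point",
                                            coords = cbind(wx[i], wy[i]))
    }
    waterFeatures(feats)
  })
}

#' Generate attraction-weighted hotspots
#'
#' Candidate cells are scored by the planted log-linear attraction
#' `eta = b1 z(P) + b2 z(P)^2 + b3 z(sqrt dw) + b4 z(sqrt dw)^2`
#' (standardization over candidate cells); `K` hotspots are sampled with
#' probability proportional to `exp(eta)` subject to a minimum separation,
#' and each hotspot's visit weight is proportional to `exp(eta)`. Cells
#' close to water or to the domain edge are not candidates, so planted
#' sites survive the water-buffer filter and excursions stay in-domain.
#'
#' @param fields output of [genFields()].
#' @param water a [WaterFeatures-class].
#' @param cfg a `"studyConfig"`.
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return data frame `x, y, phosZ, dwZ, eta, w` (weights sum to 1).
#' @export
genHotspots <- function(fields, water, cfg, seed = cfg$seed + 2) {
  P <- fields$layers$phosphorus
  cc <- cellCentres(P)
  dw <- distanceToWater(cc$x, cc$y, water)$dist
  margin <- max(cfg$excursionDist) + 100
  cand <- which(dw > 800 & cc$x > margin & cc$x < cfg$domain[1] - margin &
                  cc$y > margin & cc$y < cfg$domain[2] - margin)
  if (length(cand) < cfg$K) stop("K exceeds candidate cells")
  zP <- zstd(as.vector(P@values)[cand])
  zD <- zstd(sqrt(dw[cand]))
  b <- cfg$beta
  eta <- b[["phos"]] * zP + b[["phos2"]] * zP^2 +
    b[["dw"]] * zD + b[["dw2"]] * zD^2
  withSeed(seed, {
    pick <- integer(0)
    prob <- exp(eta - max(eta))
    avail <- rep(TRUE, length(cand))
    while (length(pick) < cfg$K) {
      if (!any(avail)) stop("cannot place ", cfg$K,
                            " hotspots at separation ", cfg$minHotspotSep)
      i <- sample(seq_along(cand)[avail], 1L, prob = prob[avail])
      pick <- c(pick, i)
      avail <- avail & (sqrt((cc$x[cand] - cc$x[cand[i]])^2 +
                               (cc$y[cand] - cc$y[cand[i]])^2) >=
                          cfg$minHotspotSep)
    }
    w <- exp(eta[pick] - max(eta[pick]))
    data.frame(x = cc$x[cand[pick]], y = cc$y[cand[pick]],
               phosZ = zP[pick], dwZ = zD[pick], eta = eta[pick],
               w = w / sum(w))
  })
}

# positions of an n-hour dwell wandering uniformly in a disc
dwellFixes <- function(n, cx, cy, wander) {
  r <- wander * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  cbind(cx + r * cos(a), cy + r * sin(a))
}

#' Simulate one hotspot-attraction trajectory
#'
#' Alternating trip/dwell process: a target hotspot is chosen with
#' probability proportional to its weight, approached by a biased
#' correlated random walk (gamma step lengths, heading a persistence-
#' weighted mix of the previous heading and the bearing to the target plus
#' wrapped-normal noise); on arrival the animal dwells for a
#' gamma-distributed time, wandering within the hotspot scale, and
#' occasionally makes a long (> 12 h) local excursion a few hundred metres
#' out before returning. Positions are emitted at the fix interval.
#'
#' @param hotspots data frame from [genHotspots()].
#' @param cfg a `"studyConfig"`.
#' @param individualId id string.
#' @param sex `"bull"` or `"cow"`.
#' @param seed RNG seed.
#' @return A [Trajectory-class].
#' @export
genTrajectory <- function(hotspots, cfg, individualId = "ele01",
                          sex = "bull", seed = cfg$seed + 10) {
  K <- nrow(hotspots)
  stopifnot(K >= 2)
  N <- ceiling(cfg$durationYears * 365 * 24 / cfg$fixIntervalHours)
  dtH <- cfg$fixIntervalHours
  X <- cfg$domain[1]; Y <- cfg$domain[2]
  withSeed(seed, {
    px <- numeric(N); py <- numeric(N)
    cur <- sample.int(K, 1L, prob = hotspots$w)
    pos <- c(hotspots$x[cur], hotspots$y[cur])
    heading <- runif(1, 0, 2 * pi)
    k <- 0L
    emit <- function(xy) {
      n <- min(nrow(xy), N - k)
      if (n > 0) {
        px[k + seq_len(n)] <<- xy[seq_len(n), 1]
        py[k + seq_len(n)] <<- xy[seq_len(n), 2]
        k <<- k + n
      }
    }
    travelTo <- function(tx, ty) {
      while (k < N) {
        d <- sqrt((tx - pos[1])^2 + (ty - pos[2])^2)
        if (d <= cfg$hotspotScale) break
        step <- rgamma(1, shape = cfg$stepShape,
                       scale = cfg$stepMean * dtH / cfg$stepShape)
        if (step >= d) {
          pos <<- c(tx, ty) + rnorm(2, sd = 50)
        } else {
          bear <- atan2(ty - pos[2], tx - pos[1])
          mx <- cfg$persistence * cos(heading) + (1 - cfg$persistence) * cos(bear)
          my <- cfg$persistence * sin(heading) + (1 - cfg$persistence) * sin(bear)
          heading <<- atan2(my, mx) + rnorm(1, sd = cfg$headingSd)
          pos <<- pos + step * c(cos(heading), sin(heading))
        }
        pos <<- pmin(c(X, Y), pmax(c(0, 0), pos))
        emit(matrix(pos, 1))
      }
    }
    dwellAt <- function(cx, cy, meanH, wander, shape = cfg$dwellShape) {
      n <- max(1L, ceiling(rgamma(1, shape = shape,
                                  scale = meanH / shape) / dtH))
      xy <- dwellFixes(min(n, N - k), cx, cy, wander)
      if (nrow(xy)) { pos <<- xy[nrow(xy), ]; emit(xy) }
    }
    lineTo <- function(tx, ty) {
      hrs <- max(1L, ceiling(sqrt((tx - pos[1])^2 + (ty - pos[2])^2) /
                               (cfg$stepMean * dtH)))
      path <- cbind(seq(pos[1], tx, length.out = hrs + 1L)[-1],
                    seq(pos[2], ty, length.out = hrs + 1L)[-1]) +
        matrix(rnorm(2 * hrs, sd = 30), ncol = 2)
      emit(path)
      pos <<- c(tx, ty)
    }
    while (k < N) {
      dwellAt(hotspots$x[cur], hotspots$y[cur], cfg$dwellMeanH,
              cfg$dwellWander)
      if (k >= N) break
      nLoop <- rgeom(1, 1 / (1 + cfg$excursionMeanLoops))
      for (lp in seq_len(nLoop)) {
        # local excursion loop: out beyond the hotspot scale, a stay longer
        # than the time-away threshold, then back for a short re-dwell
        dEx <- runif(1, cfg$excursionDist[1], cfg$excursionDist[2])
        aEx <- runif(1, 0, 2 * pi)
        ex <- pmin(c(X, Y), pmax(c(0, 0),
                                 c(hotspots$x[cur] + dEx * cos(aEx),
                                   hotspots$y[cur] + dEx * sin(aEx))))
        lineTo(ex[1], ex[2])
        dwellAt(ex[1], ex[2], cfg$excursionDwellMeanH, cfg$excursionWander,
                shape = cfg$excursionDwellShape)
        if (k >= N) break
        lineTo(hotspots$x[cur], hotspots$y[cur])
        dwellAt(hotspots$x[cur], hotspots$y[cur], cfg$redwellMeanH,
                cfg$dwellWander)
        if (k >= N) break
      }
      if (k >= N) break
      # targets are drawn independently in proportion to hotspot weight;
      # re-drawing the current hotspot extends the stay (split into
      # separate visits only when an excursion loop intervenes)
      nxt <- sample(seq_len(K), 1L, prob = hotspots$w)
      if (nxt != cur) travelTo(hotspots$x[nxt], hotspots$y[nxt])
      cur <- nxt
    }
    tt <- cfg$startDate + (seq_len(N) - 1L) * dtH * HOUR
    Trajectory(individualId, tt, px, py, sex = sex)
  })
}

#' Generate a complete synthetic study
#'
#' Covariate rasters, dynamic series, water features, hotspots with planted
#' attraction, and one trajectory per individual -- everything a pipeline
#' run needs, plus the ground-truth record. The whole bundle is a pure
#' function of the configuration (including its seed).
#'
#' @param cfg a `"studyConfig"`.
#' @return object of class `"studyBundle"`: `trajectories`
#'   ([TrajectorySet-class]), `layers`, `series`, `water`, `truth`
#'   (hotspots, beta, seed), `config`.
#' @export
genStudy <- function(cfg = studyConfig()) {
  fields <- genFields(cfg)
  water <- genWater(cfg)
  hotspots <- genHotspots(fields, water, cfg)
  ids <- sprintf("ele%02d", seq_len(cfg$nIndividuals))
  sexes <- c(rep("bull", cfg$nBulls), rep("cow", cfg$nIndividuals - cfg$nBulls))
  trs <- lapply(seq_len(cfg$nIndividuals), function(i)
    genTrajectory(hotspots, cfg, ids[i], sexes[i],
                  seed = deriveSeed(cfg$seed, 1000L + i)))
  out <- list(trajectories = TrajectorySet(trs),
              layers = fields$layers, series = fields$series, water = water,
              truth = list(hotspots = hotspots, beta = cfg$beta,
                           seed = cfg$seed),
              config = cfg)
  class(out) <- "studyBundle"
  out
}

#' @export
print.studyBundle <- function(x, ...) {
  cat(sprintf(
    "studyBundle: %d individuals x %g y, %d hotspots, seed %d\n",
    x$config$nIndividuals, x$config$durationYears,
    nrow(x$truth$hotspots), x$config$seed))
  invisible(x)
}

#' Write a study bundle to disk in the pipeline's input formats
#'
#' Fixes CSV, ESRI ASCII rasters with per-series index CSVs, water GeoJSON,
#' a domain-averaged NDVI CSV and a truth JSON.
#'
#' @param bundle a `"studyBundle"`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTrajectories(bundle$trajectories, file.path(dir, "fixes.csv"))
  for (nm in names(bundle$layers))
    writeAsc(bundle$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (nm in setdiff(names(bundle$series), "ndvi"))
    writeSeriesIndex(bundle$series[[nm]], file.path(dir, nm), nm)
  ndvi <- ndviSeriesMean(bundle$series$ndvi)
  write.csv(data.frame(timestamp = formatTimestamps(ndvi$time),
                       value = ndvi$value),
            file.path(dir, "ndvi.csv"), row.names = FALSE, quote = FALSE)
  writeWaterGeoJSON(bundle$water, file.path(dir, "water.geojson"))
  jsonlite::write_json(
    list(hotspots = bundle$truth$hotspots, beta = as.list(bundle$truth$beta),
         seed = bundle$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}

#' Domain-averaged series from a raster series
#'
#' @param series a [RasterSeries-class].
#' @return data frame `time, value` (spatial mean per record).
#' @export
ndviSeriesMean <- function(series) {
  data.frame(time = series@times,
             value = vapply(series@layers,
                            function(l) mean(l@values, na.rm = TRUE),
                            numeric(1)))
}
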