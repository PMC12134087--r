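#' Pipeline configuration
#'
#' Defaults follow the analysis design: 250 m recursion circle with a 12 h
#' minimum time away, 500 m water buffer, 100,000 availability points,
#' 10,000 subsampled Kolmogorov iterations of 100 vs 100, quadratic
#' candidate terms for distance-to-water, EVI, phosphorus, temperature and
#' slope (precipitation only in the exploratory binned regressions), and
#' the four ecologically motivated interactions.
#'
#' @param radius recursion radius (m).
#' @param minTimeAway minimum time away (h).
#' @param candidateRadii radii for [selectRadius()] when `chooseRadius`.
#' @param chooseRadius run variance-peak radius selection first.
#' @param buffer water exclusion buffer (m).
#' @param availabilityN number of CSR availability points.
#' @param ksIter,ksM subsampled-KS iterations and per-group subsample size.
#' @param modelVars covariates entering the mixed models (linear +
#'   quadratic each).
#' @param screenPriority priority order for the collinearity screen.
#' @param interactions allow-listed interaction pairs.
#' @param nStrata,perStratum stratified-resampling geometry.
#' @param nRep resamples for the R2 mean +/- SD.
#' @param nBins bins for the exploratory per-variable regressions.
#' @param homeRangeMaxPoints pooled fixes are thinned (every k-th fix) to at
#'   most this many points before the a-LoCoH construction.
#' @param isopleth home-range isopleth.
#' @param seed master seed propagated to every stochastic stage.
#' @return object of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(radius = 250, minTimeAway = 12,
                           candidateRadii = c(100, 200, 250, 300, 400, 500),
                           chooseRadius = FALSE, buffer = 500,
                           availabilityN = 100000, ksIter = 10000, ksM = 100,
                           modelVars = c("dw", "evi", "phos", "temperature",
                                         "slope"),
                           screenPriority = c("dw", "evi", "phos",
                                              "nitrogen", "temperature",
                                              "slope"),
                           interactions = list(c("evi", "slope"),
                                               c("dw", "slope"),
                                               c("evi", "phos"),
                                               c("dw", "phos")),
                           nStrata = 10, perStratum = 50, nRep = 200,
                           nBins = 1000, homeRangeMaxPoints = 1500,
                           isopleth = 1, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

# Deterministic thinning: every k-th pooled fix, capped at maxPoints.
thinPooledFixes <- function(trajset, maxPoints) {
  xy <- do.call(rbind, lapply(trajset@trajectories,
                              function(tr) cbind(tr@x, tr@y)))
  if (nrow(xy) > maxPoints)
    xy <- xy[seq(1L, nrow(xy), length.out = maxPoints), , drop = FALSE]
  xy
}

#' Per-site, per-season modelling records
#'
#' One row per revisitation site and season type with at least one visit:
#' the seasonal revisitation rate (visits per seasonal period, fractional
#' periods in the denominator), its log, the static covariates at the site
#' centre and the per-season mean of the dynamic covariates extracted at
#' the entry time of each visit.
#'
#' @param rt a (water-filtered) `"revisitTable"`.
#' @param trajset the [TrajectorySet-class] the table came from.
#' @param st a [SeasonTable-class].
#' @param layers,series,water environmental inputs (see
#'   [buildCovariates()]).
#' @return data frame of site-season records.
#' @export
siteRecords <- function(rt, trajset, st, layers, series, water) {
  v <- rt$visits
  stopifnot(!is.null(v))
  sites <- rt$sites
  cov0 <- as.numeric(st@coverageStart); cov1 <- as.numeric(st@coverageEnd)
  inCov <- as.numeric(v$tEnter) >= cov0 & as.numeric(v$tEnter) <= cov1
  if (any(!inCov))
    message(sum(!inCov), " visit(s) outside season coverage dropped")
  v <- v[inCov, , drop = FALSE]
  v$season <- assignSeason(v$tEnter, st)
  ix <- match(v$siteId, sites$siteId)
  vc <- buildCovariates(sites$cx[ix], sites$cy[ix], v$tEnter, layers,
                        series, water)
  v <- cbind(v, vc[, c("dw", "phos", "nitrogen", "slope", "evi",
                       "temperature", "precipitation")])
  v$individualId <- sites$individualId[ix]
  v$sex <- sites$sex[ix]
  # seasonal period denominators, one per individual
  nPer <- list()
  for (id in names(trajset@trajectories)) {
    sp <- as.numeric(trackingSpan(trajset@trajectories[[id]]))
    nPer[[id]] <- vapply(c(wet = "wet", dry = "dry"), function(se) {
      per <- seasonPeriods(st, se)
      sum(pmax(0, pmin(sp[2], as.numeric(per$end)) -
                 pmax(sp[1], as.numeric(per$start))) /
            (as.numeric(per$end) - as.numeric(per$start)))
    }, numeric(1))
  }
  covCols <- c("dw", "phos", "nitrogen", "slope", "evi", "temperature",
               "precipitation")
  kf <- factor(paste(v$siteId, v$season))
  cnt <- tabulate(kf, nbins = nlevels(kf))
  means <- rowsum(as.matrix(v[, covCols]), kf) / cnt
  firstIx <- which(!duplicated(kf))
  firstIx <- firstIx[match(levels(kf), kf[firstIx])]
  out <- data.frame(siteId = v$siteId[firstIx], season = v$season[firstIx],
                    individualId = v$individualId[firstIx],
                    sex = v$sex[firstIx], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  denom <- unname(unlist(nPer)[paste(out$individualId, out$season,
                                     sep = ".")])
  keep <- denom > 0
  out <- out[keep, , drop = FALSE]
  out$nVisitsSeason <- cnt[keep]
  out$rate <- out$nVisitsSeason / denom[keep]
  out$logRate <- log(out$rate)
  rownames(out) <- NULL
  out
}

scaleCols <- function(df, vars) {
  for (v in vars) df[[v]] <- as.numeric(scale(df[[v]]))
  df
}

quadTerms <- function(vars) c(vars, sprintf("I(%s^2)", vars))

#' Run the full revisitation analysis pipeline
#'
#' Stages: visit detection (moving-circle recursion) -> water-buffer
#' filtering -> NDVI season segmentation -> a-LoCoH home range ->
#' availability sampling -> covariate joins -> collinearity screen ->
#' used-vs-available subsampled Kolmogorov tests per variable and stratum
#' -> per-variable binned quadratic regressions -> per-stratum mixed-model
#' backward-AIC selection with interactions. Reruns with the same bundle,
#' configuration and seed reproduce the report.
#'
#' @param bundle a `"studyBundle"` from [genStudy()], or an equivalent list
#'   with `trajectories`, `layers`, `series` (including `ndvi`), `water`.
#' @param cfg a `"pipelineConfig"`.
#' @return object of class `"runReport"`.
#' @export
runPipeline <- function(bundle, cfg = pipelineConfig()) {
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
    message("[", stage, "] ", paste(names(list(...)), unlist(list(...)),
                                    sep = "=", collapse = " "))
  }
  stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  trajset <- bundle$trajectories
  rcfg <- recursionConfig(cfg$radius, cfg$minTimeAway, cfg$candidateRadii)
  radius <- cfg$radius
  if (isTRUE(cfg$chooseRadius)) {
    radius <- stageTry("select_radius", selectRadius(trajset, rcfg))
    note("select_radius", radius = as.numeric(radius))
  }
  rt <- stageTry("detect", revisitationTable(trajset, rcfg, radius = radius))
  note("detect", sites = nrow(rt$sites), visits = nrow(rt$visits))
  rt <- stageTry("water_filter",
                 suppressMessages(filterWaterSites(rt, bundle$water,
                                                   cfg$buffer)))
  note("water_filter", kept = nrow(rt$sites),
       removed = attr(rt, "nRemoved"))
  st <- stageTry("seasons", {
    nd <- ndviSeriesMean(bundle$series$ndvi)
    seasonCutpoints(standardizeNdvi(nd$time, nd$value))
  })
  note("seasons", years = length(st@year), fallback = sum(st@fallback))
  hr <- stageTry("home_range", {
    xy <- thinPooledFixes(trajset, cfg$homeRangeMaxPoints)
    aLoCoH(xy[, 1], xy[, 2], isopleth = cfg$isopleth)
  })
  note("home_range", hulls = length(hr@hulls), areaKm2 = hr@area / 1e6)
  avail <- stageTry("availability",
    sampleAvailable(hr, bundle$water, cfg$buffer, cfg$availabilityN,
                    rt$visits$tEnter, seed = deriveSeed(cfg$seed, 2L)))
  note("availability", n = nrow(avail))
  availCov <- stageTry("covariates_available",
    suppressWarnings(buildCovariates(avail$x, avail$y, avail$stampedTime,
                                     bundle$layers, bundle$series,
                                     bundle$water)))
  availCov$season <- assignSeason(
    pmin(pmax(availCov$t, st@coverageStart), st@coverageEnd), st)
  rec <- stageTry("site_records",
    suppressMessages(siteRecords(rt, trajset, st, bundle$layers,
                                 bundle$series, bundle$water)))
  note("site_records", rows = nrow(rec))
  screen <- stageTry("correlation_screen",
    correlationScreen(rec[, cfg$screenPriority], threshold = 0.5,
                      priority = cfg$screenPriority))
  note("correlation_screen", dropped = paste(screen$dropped, collapse = ","))
  modelVars <- intersect(cfg$modelVars, screen$retained)
  ksVars <- c("dw", "evi", "phos", "precipitation", "slope", "temperature")
  ks <- list()
  usedFirst <- rec[!duplicated(rec$siteId), , drop = FALSE]
  k <- 0L
  for (sx in unique(usedFirst$sex)) for (se in c("wet", "dry")) {
    sub <- usedFirst[usedFirst$sex == sx & usedFirst$season == se, ]
    av <- availCov[availCov$season == se, ]
    for (v in ksVars) {
      u <- sub[[v]][is.finite(sub[[v]])]
      a <- av[[v]][is.finite(av[[v]])]
      if (length(u) < cfg$ksM || length(a) < cfg$ksM) next
      k <- k + 1L
      ks[[paste(sx, se, v, sep = ".")]] <-
        subsampledKS(u, a, nIter = cfg$ksIter, m = cfg$ksM,
                     seed = deriveSeed(cfg$seed, 10L + k))
    }
  }
  note("ks_tests", n = length(ks))
  binned <- list()
  for (sx in unique(rec$sex)) for (se in c("wet", "dry")) {
    sub <- rec[rec$sex == sx & rec$season == se, ]
    for (v in ksVars) {
      ok <- is.finite(sub[[v]]) & is.finite(sub$logRate)
      if (sum(ok) < 10 || max(sub[[v]][ok]) <= min(sub[[v]][ok])) next
      bt <- binMeans(sub[[v]][ok], sub$logRate[ok], nBins = cfg$nBins)
      if (nrow(bt) < 3) next
      binned[[paste(sx, se, v, sep = ".")]] <-
        c(quadRegression(bt)[c("coef", "r2")], nBins = nrow(bt))
    }
  }
  note("binned_regressions", n = length(binned))
  models <- list()
  m <- 0L
  for (sx in unique(rec$sex)) for (se in c("wet", "dry")) {
    sub <- rec[rec$sex == sx & rec$season == se, , drop = FALSE]
    sub <- sub[complete.cases(sub[, modelVars]), , drop = FALSE]
    if (nrow(sub) < 10 || length(unique(sub$individualId)) < 2) {
      message("stratum ", sx, "/", se, " too small for a mixed model")
      next
    }
    sub <- scaleCols(sub, modelVars)
    m <- m + 1L
    resCfg <- list(focalVars = modelVars, nStrata = cfg$nStrata,
                   perStratum = cfg$perStratum)
    base <- backwardAIC(quadTerms(modelVars), sub, resample = resCfg,
                        nRep = cfg$nRep, seed = deriveSeed(cfg$seed, 50L + m))
    withInt <- suppressWarnings(
      addInteractions(base, sub, allowList = cfg$interactions,
                      resample = resCfg, nRep = cfg$nRep,
                      seed = deriveSeed(cfg$seed, 80L + m)))
    models[[paste(sx, se, sep = ".")]] <- list(base = base, final = withInt)
  }
  note("models", n = length(models))
  out <- list(config = cfg, radius = as.numeric(radius), log = log,
              seasonTable = st, homeRange = hr, screen = screen,
              ks = ks, binned = binned, models = models,
              siteRecords = rec, nAvailable = nrow(avail))
  class(out) <- "runReport"
  out
}

#' @export
print.runReport <- function(x, ...) {
  cat("runReport\n")
  cat(sprintf("  radius %g m; %d site-season records; %d availability points\n",
              x$radius, nrow(x$siteRecords), x$nAvailable))
  cat(sprintf("  %d KS tests, %d binned regressions, %d model strata\n",
              length(x$ks), length(x$binned), length(x$models)))
  for (nm in names(x$models)) {
    sr <- x$models[[nm]]$final
    cat(sprintf("  [%s] %s | Rm2 %.3f Rc2 %.3f\n", nm,
                if (length(sr$chosenTerms))
                  paste(sr$chosenTerms, collapse = " + ")
                else "(intercept)", sr$Rm2Mean, sr$Rc2Mean))
  }
  invisible(x)
}

#' Serialise a run report to JSON (plus the site-record CSV)
#'
#' @param report a `"runReport"`.
#' @param dir output directory.
#' @return path of the JSON file.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ksJ <- lapply(report$ks, function(r)
    r[c("DMean", "DSd", "pMean", "pSd", "rejectRate", "nIter", "m")])
  binJ <- lapply(report$binned, function(b)
    list(x = b$coef[["x"]], x2 = b$coef[["x2"]], r2 = b$r2,
         nBins = b$nBins))
  modJ <- lapply(report$models, function(mm) {
    sr <- mm$final
    list(chosenTerms = sr$chosenTerms, aic = sr$chosenFit$aic,
         coef = as.list(sr$chosenFit$coef), Rm2 = sr$Rm2Mean,
         Rm2Sd = sr$Rm2Sd, Rc2 = sr$Rc2Mean, Rc2Sd = sr$Rc2Sd,
         visited = sr$visited)
  })
  obj <- list(radius = report$radius, log = report$log,
              screen = list(retained = report$screen$retained,
                            dropped = report$screen$dropped),
              ks = ksJ, binned = binJ, models = modJ)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns")
  write.csv(report$siteRecords, file.path(dir, "site_records.csv"),
            row.names = FALSE)
  path
}
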