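# Shared fixtures and independent oracles, built in code at test time.

t0utc <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

# Random-walk trajectory with irregular (non-hourly) time steps, scaled so
# segments repeatedly cross circles of a few hundred metres.
randomTrajectory <- function(n = 300, id = "rw", seed = NULL) {
  revisit:::withSeed(seed, {
    dt <- runif(n - 1, 30, 90) # seconds
    tt <- t0utc + c(0, cumsum(dt))
    step <- rgamma(n - 1, shape = 2, scale = 40)
    ang <- cumsum(rnorm(n - 1, sd = 0.6))
    Trajectory(id, tt, c(0, cumsum(step * cos(ang))),
               c(0, cumsum(step * sin(ang))))
  })
}

# Brute-force visit oracle: densely resample each segment (linear motion) at
# `stepS`-second ticks, scan in/out runs, merge gaps < minAwayH.
oracleVisits <- function(traj, centre, radius, minAwayH = 12, stepS = 1) {
  tn <- as.numeric(traj@t)
  grid <- seq(tn[1], tn[length(tn)], by = stepS)
  x <- approx(tn, traj@x, xout = grid)$y
  y <- approx(tn, traj@y, xout = grid)$y
  inside <- (x - centre[1])^2 + (y - centre[2])^2 <= radius^2
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(enter = grid[starts[r$values]], exit = grid[ends[r$values]])
  if (nrow(iv) < 2L) return(iv)
  out <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$enter[i] - out$exit[nrow(out)] < minAwayH * 3600)
      out$exit[nrow(out)] <- iv$exit[i]
    else out <- rbind(out, iv[i, ])
  }
  out
}

# Brute-force two-sample ECDF oracle for the Kolmogorov statistic.
oracleD <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Reduced-scale synthetic study: 5 individuals x 1 year.
reducedStudyConfig <- function(seed, ...) {
  studyConfig(nIndividuals = 5, nBulls = 3, durationYears = 1, seed = seed,
              ...)
}

# Small constant raster helpers
flatLayer <- function(value = 7, n = 5, cellsize = 10, name = "flat") {
  rasterLayer(name, matrix(value, n, n), cellsize = cellsize)
}

# Season table with one wet interval per year, for rate tests.
simpleSeasonTable <- function(years = 2015L,
                              wetStart = "-11-01", wetEnd = "-05-01") {
  new("SeasonTable", year = years,
      wetStart = as.POSIXct(paste0(years, wetStart), tz = "UTC"),
      wetEnd = as.POSIXct(paste0(years + 1L, wetEnd), tz = "UTC"),
      coverageStart = as.POSIXct(paste0(years[1], "-07-01"), tz = "UTC"),
      coverageEnd = as.POSIXct(paste0(years[length(years)] + 1L, "-07-01"),
                               tz = "UTC"),
      fallback = rep(FALSE, length(years)))
}

# Pooled per-site-season modelling records for a reduced study, via the
# package's own pipeline pieces (used by recovery checks).
reducedRecords <- function(bundle, radius = 250) {
  rt <- revisitationTable(bundle$trajectories,
                          recursionConfig(radius = radius))
  rt <- suppressMessages(filterWaterSites(rt, bundle$water, 500))
  nd <- ndviSeriesMean(bundle$series$ndvi)
  st <- seasonCutpoints(standardizeNdvi(nd$time, nd$value))
  suppressMessages(siteRecords(rt, bundle$trajectories, st, bundle$layers,
                               bundle$series, bundle$water))
}
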