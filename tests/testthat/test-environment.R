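test_that("static extraction is nearest-cell with explicit missingness", {
  lay <- flatLayer(7, n = 5, cellsize = 10)
  expect_equal(extractStatic(lay, c(5, 25, 49), c(5, 25, 49)), c(7, 7, 7))
  # 2x2 grid, distinct values, points at the four cell centres
  m <- matrix(c(1, 3, 2, 4), 2, 2) # row 1 = top
  lay2 <- rasterLayer("q", m, cellsize = 1)
  expect_equal(extractStatic(lay2, c(0.5, 1.5, 0.5, 1.5),
                             c(1.5, 1.5, 0.5, 0.5)), c(1, 2, 3, 4))
  # nodata cell -> NA; outside extent -> NA with warning
  m[2, 2] <- NA
  lay3 <- rasterLayer("q", m, cellsize = 1)
  expect_true(is.na(extractStatic(lay3, 1.5, 0.5)))
  expect_warning(v <- extractStatic(lay3, 5, 5), "outside")
  expect_true(is.na(v))
})

test_that("extraction twice yields identical values", {
  set.seed(3)
  lay <- rasterLayer("r", matrix(rnorm(100), 10, 10), cellsize = 10)
  px <- runif(50, 0, 100); py <- runif(50, 0, 100)
  expect_identical(extractStatic(lay, px, py), extractStatic(lay, px, py))
})

test_that("dynamic extraction uses the last record at or before t", {
  mk <- function(v) flatLayer(v, n = 2)
  times <- t0utc + c(1, 17, 33) * 86400
  ser <- rasterSeries("s", times, list(mk(10), mk(17), mk(33)), 16)
  at <- function(d) extractDynamic(ser, 1, 1, t0utc + d * 86400)
  expect_equal(at(20), 17)          # day 20 -> day-17 record
  expect_equal(at(17), 17)          # exactly at a record -> that record
  expect_equal(at(33.5), 33)
  expect_true(is.na(at(0.5)))       # before the first record -> missing
})

test_that("dynamic extraction never looks into the future", {
  set.seed(4)
  times <- t0utc + sort(sample(1:300, 12)) * 86400
  ser <- rasterSeries("s", times,
                      lapply(as.numeric(times), flatLayer, n = 2), 16)
  tq <- t0utc + runif(40, 0, 320) * 86400
  v <- extractDynamic(ser, rep(1, 40), rep(1, 40), tq)
  ok <- !is.na(v)
  expect_true(all(v[ok] <= as.numeric(tq)[ok]))
})

test_that("distance to water handles feature types and the sqrt transform", {
  w <- waterFeatures(list(
    list(type = "line", coords = cbind(c(0, 0), c(-1e4, 1e4))),
    list(type = "point", coords = cbind(1700, 0))))
  d <- distanceToWater(900, 0, w)
  expect_equal(d$dist, 800)  # nearest of river (900) and point (800)
  expect_equal(d$distSqrt, sqrt(800))
  expect_equal(distanceToWater(300, 5, w)$dist, 300)
  # a point inside a polygon feature is at distance zero
  poly <- waterFeatures(list(list(type = "polygon",
                                  coords = cbind(c(0, 10, 10, 0),
                                                 c(0, 0, 10, 10)))))
  expect_equal(distanceToWater(c(5, 10, 25), c(5, 5, 5), poly)$dist,
               c(0, 0, 15))
})

test_that("slope from an inclined plane matches the analytic gradient", {
  n <- 8; cs <- 30
  east <- matrix(rep(seq_len(n) * 1, each = n), n, n) # +1 m per cell east
  lay <- rasterLayer("elev", east, cellsize = cs)
  sl <- slopeFromElevation(lay)
  inner <- sl@values[2:(n - 1), 2:(n - 1)]
  expect_equal(max(abs(inner - atan(1 / 30) * 180 / pi)), 0,
               tolerance = 1e-10)
  brd <- attr(sl, "border")
  expect_true(all(brd[1, ]) && all(brd[, 1]))
  expect_false(any(brd[2:(n - 1), 2:(n - 1)]))
  # flat terrain: slope 0, log1p 0
  flat <- slopeFromElevation(flatLayer(100, n = 4))
  expect_true(all(flat@values == 0))
  expect_true(all(log1p(flat@values) == 0))
  expect_error(slopeFromElevation(flatLayer(1, n = 2)), "3x3")
})

test_that("sqrt and log1p transforms preserve ordering", {
  set.seed(6)
  d <- sort(runif(50, 0, 5000))
  expect_true(!is.unsorted(sqrt(d)))
  expect_true(!is.unsorted(log1p(d)))
})

test_that("ASCII grid raster round trip is lossless", {
  set.seed(7)
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  lay <- rasterLayer("rt", m, xmin = 100, ymin = -50, cellsize = 25)
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsc(lay, f)
  back <- readAsc(f)
  expect_equal(back@values, m)
  expect_equal(back@xmin, 100)
  expect_equal(back@cellsize, 25)
})

test_that("correlation screen drops the lower-priority collinear column", {
  set.seed(9)
  P <- rnorm(200)
  N <- 0.8 * P + rnorm(200, sd = 0.3) # r ~ 0.9
  z <- rnorm(200)
  out <- correlationScreen(data.frame(phos = P, nitrogen = N, z = z),
                           threshold = 0.5,
                           priority = c("phos", "nitrogen", "z"))
  expect_identical(out$dropped, "nitrogen")
  expect_setequal(out$retained, c("phos", "z"))
  expect_gt(abs(out$cor["phos", "nitrogen"]), 0.8)
})

test_that("correlation screen boundary and degenerate columns", {
  # cor(c(1,2,3), c(1,3,2)) is exactly 0.5: not strictly greater -> retained
  df <- data.frame(a = c(1, 2, 3), b = c(1, 3, 2))
  out <- correlationScreen(df, threshold = 0.5)
  expect_setequal(out$retained, c("a", "b"))
  # constant column flagged, not silently dropped
  df2 <- data.frame(a = rnorm(10), k = rep(1, 10), b = rnorm(10))
  out2 <- correlationScreen(df2)
  expect_identical(out2$flagged, "k")
  expect_false("k" %in% out2$dropped)
  expect_error(correlationScreen(data.frame(a = 1:2, b = 2:1)),
               "3 complete rows")
})

test_that("covariate rows are flagged, not dropped, when extraction fails", {
  lay <- flatLayer(5, n = 10, cellsize = 1000) # 10 km extent
  layers <- list(phosphorus = lay, nitrogen = lay,
                 elevation = flatLayer(100, n = 10, cellsize = 1000))
  ser <- list(evi = rasterSeries("evi", t0utc,
                                 list(flatLayer(0.3, 10, 1000)), 16))
  w <- waterFeatures(list(list(type = "point", coords = cbind(0, 0))))
  cov <- suppressWarnings(
    buildCovariates(c(500, 500), c(500, 500), c(t0utc + 86400, t0utc - 86400),
                    layers, ser, w))
  expect_true(cov$complete[1])
  expect_false(cov$complete[2]) # dynamic query before first record
  expect_equal(cov$dw, sqrt(cov$distWater))
})
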