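hourTrack <- function(x, y, id = "tr") {
  Trajectory(id, t0utc + (seq_along(x) - 1) * 3600, x, y)
}

test_that("circleCrossings solves the segment-circle intersection", {
  # head-on approach: enters the unit circle halfway through the hour
  cc <- circleCrossings(c(2, 0, 0), c(0, 0, 3600), c(0, 0), 1)
  expect_equal(cc$s, 0.5)
  expect_equal(cc$t, 1800)
  # segment entirely inside: no crossings
  expect_identical(nrow(circleCrossings(c(0.2, 0, 0), c(-0.3, 0.1, 10),
                                        c(0, 0), 1)), 0L)
  # tangent segment (discriminant zero): grazing is not a crossing
  expect_identical(nrow(circleCrossings(c(-2, 1, 0), c(2, 1, 10),
                                        c(0, 0), 1)), 0L)
  # pass-through: two crossings in increasing s
  cc2 <- circleCrossings(c(-2, 0, 0), c(2, 0, 4), c(0, 0), 1)
  expect_equal(cc2$s, c(0.25, 0.75))
  expect_error(circleCrossings(c(0, 0, 5), c(1, 1, 1), c(0, 0), 1),
               "precede")
  expect_error(circleCrossings(c(NA, 0, 0), c(1, 1, 1), c(0, 0), 1),
               "non-finite")
})

test_that("detectVisits merges short gaps and splits long ones", {
  cfg <- recursionConfig(radius = 250, minTimeAway = 12)
  # all fixes inside -> one visit spanning the whole track
  trIn <- hourTrack(rnorm(24, sd = 50), rnorm(24, sd = 50))
  v <- detectVisits(trIn, c(0, 0), cfg)
  expect_identical(nrow(v), 1L)
  expect_equal(v$tEnter, trIn@t[1])
  expect_equal(v$tExit, trIn@t[24])
  # 6 h away -> still one (merged) visit; 13 h away -> two visits
  mk <- function(gapH) hourTrack(c(rep(0, 5), rep(5000, gapH), rep(0, 5)),
                                 rep(0, 10 + gapH))
  expect_identical(nrow(detectVisits(mk(6), c(0, 0), cfg)), 1L)
  expect_identical(nrow(detectVisits(mk(13), c(0, 0), cfg)), 2L)
})

test_that("visit structure matches the dense-resampling oracle", {
  set.seed(21)
  for (i in 1:25) {
    tr <- randomTrajectory(120, seed = 400 + i)
    centre <- c(tr@x[sample(120, 1)], tr@y[sample(120, 1)]) + rnorm(2, sd = 80)
    r <- runif(1, 60, 300)
    got <- detectVisits(tr, centre, recursionConfig(r, minTimeAway = 1))
    want <- oracleVisits(tr, centre, r, minAwayH = 1)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_lt(max(abs(as.numeric(got$tEnter) - want$enter)), 1.5)
      expect_lt(max(abs(as.numeric(got$tExit) - want$exit)), 1.5)
    }
  }
})

test_that("moving-circle table yields one site per fix with own-track visits", {
  tr <- hourTrack(c(0, 1000, 2000, 3000, 4000), rep(0, 5))
  rt <- revisitationTable(TrajectorySet(list(tr)), recursionConfig(250, 12))
  expect_identical(nrow(rt$sites), 5L)
  # a one-way track never re-enters any circle
  expect_true(all(rt$sites$nVisits == 1L))
  expect_identical(rt$sites$cx, tr@x)
})

test_that("table counts agree with single-centre detection and the oracle", {
  set.seed(31)
  tr <- randomTrajectory(150, seed = 77)
  ts <- TrajectorySet(list(tr))
  cfg <- recursionConfig(radius = 120, minTimeAway = 2)
  rt <- revisitationTable(ts, cfg)
  for (j in sample(150, 12)) {
    centre <- c(tr@x[j], tr@y[j])
    expect_identical(rt$sites$nVisits[j],
                     nrow(detectVisits(tr, centre, cfg)))
    expect_identical(rt$sites$nVisits[j],
                     nrow(oracleVisits(tr, centre, 120, minAwayH = 2)))
  }
  vj <- rt$visits[rt$visits$siteId == rt$sites$siteId[1], ]
  expect_identical(nrow(vj), rt$sites$nVisits[1])
  expect_true(all(diff(as.numeric(vj$tEnter)) > 0))
})

test_that("raising the time-away threshold never increases visit count", {
  set.seed(41)
  for (i in 1:10) {
    tr <- randomTrajectory(150, seed = 500 + i)
    centre <- c(tr@x[75], tr@y[75])
    n <- vapply(c(0, 1, 4, 12, 24), function(h)
      nrow(detectVisits(tr, centre, recursionConfig(150, h))), integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("a larger radius never loses in-circle fixes", {
  set.seed(42)
  tr <- randomTrajectory(200, seed = 55)
  centre <- c(tr@x[100], tr@y[100])
  nIn <- vapply(c(100, 200, 300, 400), function(r)
    sum((tr@x - centre[1])^2 + (tr@y - centre[2])^2 <= r^2), integer(1))
  expect_true(all(diff(nIn) >= 0))
})

test_that("per-individual results are independent of set ordering", {
  t1 <- randomTrajectory(80, id = "a", seed = 1)
  t2 <- randomTrajectory(80, id = "b", seed = 2)
  cfg <- recursionConfig(150, 2)
  r12 <- revisitationTable(TrajectorySet(list(t1, t2)), cfg)
  r21 <- revisitationTable(TrajectorySet(list(t2, t1)), cfg)
  a12 <- r12$sites[r12$sites$individualId == "a", ]
  a21 <- r21$sites[r21$sites$individualId == "a", ]
  expect_identical(a12$nVisits, a21$nVisits)
})

test_that("radius selection picks the variance peak, ties to the smaller", {
  # revisitation structure much smaller than every candidate radius: counts
  # (and hence positive variances) identical across radii -> smallest wins
  set.seed(5)
  xs <- c(rep(c(0, 5000), 20), 10000) + rnorm(41, sd = 5)
  tr <- Trajectory("t", t0utc + (0:40) * 13 * 3600, xs, rnorm(41, sd = 5))
  sel <- selectRadius(TrajectorySet(list(tr)),
                      recursionConfig(candidateRadii = c(100, 200, 300)))
  vs <- attr(sel, "variances")
  expect_equal(as.numeric(sel), 100)
  expect_true(max(vs) - min(vs) < 1e-12)
  # selection is the argmax of the reported variance summary
  b <- genStudy(studyConfig(nIndividuals = 2, nBulls = 1, durationYears = 1,
                            seed = 3))
  sel2 <- selectRadius(b$trajectories,
                       recursionConfig(candidateRadii = c(100, 250, 500)))
  vs2 <- attr(sel2, "variances")
  expect_equal(as.numeric(sel2), as.numeric(names(vs2))[which.max(vs2)])
})

test_that("radius selection needs revisitation structure", {
  tr <- hourTrack(seq(0, 50000, by = 1000), rep(0, 51))
  expect_error(selectRadius(TrajectorySet(list(tr)),
                            recursionConfig(candidateRadii = c(100, 200))),
               "no revisitation structure")
  expect_error(selectRadius(TrajectorySet(list(tr)),
                            recursionConfig(candidateRadii = 100)),
               "at least 2")
})

test_that("water-buffer filtering removes sites by distance", {
  tr <- hourTrack(c(0, 400, 600, 2000), rep(0, 4))
  rt <- revisitationTable(TrajectorySet(list(tr)), recursionConfig(50, 12))
  river <- waterFeatures(list(list(type = "line",
                                   coords = cbind(c(0, 0), c(-1e4, 1e4)))))
  kept <- suppressMessages(filterWaterSites(rt, river, buffer = 500))
  expect_identical(attr(kept, "nRemoved"), 2L) # sites at x = 0 and 400
  expect_setequal(kept$sites$cx, c(600, 2000))
  expect_true(all(kept$visits$siteId %in% kept$sites$siteId))
  # buffer 0 removes only sites exactly on water
  kept0 <- suppressMessages(filterWaterSites(rt, river, buffer = 0))
  expect_identical(attr(kept0, "nRemoved"), 1L)
  # empty water set: warning, everything kept
  expect_warning(keptAll <- filterWaterSites(rt, waterFeatures(), 500),
                 "empty water")
  expect_identical(nrow(keptAll$sites), 4L)
})
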