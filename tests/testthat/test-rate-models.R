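test_that("seasonal rates divide visits by overlapped periods", {
  st <- simpleSeasonTable(2015:2016) # wet Nov-Apr, dry otherwise
  span <- as.POSIXct(c("2015-07-01", "2017-07-01"), tz = "UTC") # 2 full years
  # six dry-season visits over exactly two dry "years"
  ve <- as.POSIXct(c("2015-08-01", "2015-09-01", "2015-10-01",
                     "2016-05-15", "2016-06-15", "2016-09-01"), tz = "UTC")
  r <- revisitationRate(ve, st, span)
  expect_equal(r$rate[r$season == "dry"], 3)
  expect_false("wet" %in% r$season) # no wet visits -> no wet record
  # one visit in one fully covered wet season
  span1 <- as.POSIXct(c("2015-07-01", "2016-07-01"), tz = "UTC")
  r1 <- revisitationRate(as.POSIXct("2016-01-10", tz = "UTC"), st, span1)
  expect_equal(r1$rate[r1$season == "wet"], 1)
  # fractional coverage: spanning half of one dry stretch scales the rate
  spanH <- as.POSIXct(c("2015-07-01", "2015-09-01"), tz = "UTC")
  rH <- revisitationRate(as.POSIXct("2015-08-01", tz = "UTC"), st, spanH)
  expect_gt(rH$rate[rH$season == "dry"], 1) # denominator < 1 period
})

test_that("rates are invariant to halving span and visits proportionally", {
  st <- simpleSeasonTable(2015:2016)
  # stationary monthly visiting over two years vs the first year only
  ve2 <- seq(as.POSIXct("2015-07-15", tz = "UTC"), by = "month",
             length.out = 24)
  ve1 <- ve2[1:12]
  span2 <- as.POSIXct(c("2015-07-01", "2017-07-01"), tz = "UTC")
  span1 <- as.POSIXct(c("2015-07-01", "2016-07-01"), tz = "UTC")
  r2 <- revisitationRate(ve2, st, span2)
  r1 <- revisitationRate(ve1, st, span1)
  for (se in c("wet", "dry"))
    expect_equal(r1$rate[r1$season == se], r2$rate[r2$season == se],
                 tolerance = 0.25)
})

test_that("bin means aggregate into equal-interval bins", {
  bt <- binMeans(c(0.1, 0.4, 0.6, 0.9), c(1, 3, 5, 7), nBins = 2)
  expect_equal(bt$meanY, c(2, 6))
  expect_equal(bt$count, c(2L, 2L))
  expect_error(binMeans(rep(2, 5), 1:5), "constant")
  # conservation: grand mean equals the count-weighted mean of bin means
  set.seed(27)
  x <- runif(500); y <- rnorm(500)
  bt2 <- binMeans(x, y, nBins = 40)
  expect_equal(sum(bt2$meanY * bt2$count) / sum(bt2$count), mean(y),
               tolerance = 1e-12)
  # every row lands in exactly one bin
  expect_equal(sum(bt2$count), 500L)
})

test_that("quadratic regression recovers noiseless coefficients", {
  x <- seq(-1, 1, length.out = 50)
  bt <- structure(data.frame(centre = x, meanY = 2 * x - 3 * x^2,
                             count = 1L),
                  class = c("binnedTable", "data.frame"))
  qr <- quadRegression(bt)
  expect_equal(unname(qr$coef["x"]), 2, tolerance = 1e-8)
  expect_equal(unname(qr$coef["x2"]), -3, tolerance = 1e-8)
  expect_equal(qr$r2, 1, tolerance = 1e-8)
  expect_error(quadRegression(binMeans(c(1, 2), c(1, 2), nBins = 2)),
               "3 non-empty")
})

test_that("pure noise yields near-zero R2; concave signals a negative x2", {
  set.seed(28)
  r2s <- replicate(5, {
    bt <- binMeans(runif(2000), rnorm(2000), nBins = 500)
    quadRegression(bt)$r2
  })
  expect_true(all(r2s < 0.1))
  hits <- replicate(20, {
    x <- runif(400)
    bt <- binMeans(x, 1.5 * x - 2 * x^2 + rnorm(400, sd = 0.3), nBins = 100)
    quadRegression(bt)$coef["x2"] < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Nakagawa R2 follows the closed form and its ordering", {
  r2 <- nakagawaR2(c(2, 1, 1))
  expect_equal(unname(r2), c(0.5, 0.75))
  r2b <- nakagawaR2(c(2, 0, 1))
  expect_equal(r2b[["Rm2"]], r2b[["Rc2"]]) # no random variance
  expect_error(nakagawaR2(c(0, 0, 0)), "undefined")
  set.seed(29)
  for (i in 1:20) {
    v <- runif(3)
    r <- nakagawaR2(v)
    expect_lte(r[["Rm2"]], r[["Rc2"]])
  }
})

test_that("mixed-model variance components are recovered", {
  set.seed(30)
  # zero between-individual variance
  n <- 2000
  d0 <- data.frame(individualId = rep(sprintf("i%02d", 1:20), each = 100),
                   x = rnorm(n))
  d0$logRate <- 1 + 0.5 * d0$x + rnorm(n)
  f0 <- fitLmm("x", d0)
  expect_lt(f0$sigmaAlpha2, 0.05)
  # planted variances sigma_alpha^2 = 1, sigma_eps^2 = 1
  nInd <- 40; per <- 200
  d1 <- data.frame(individualId = rep(sprintf("i%02d", 1:nInd), each = per),
                   x = rnorm(nInd * per))
  u <- rep(rnorm(nInd, sd = 1), each = per)
  d1$logRate <- 2 + 0.8 * d1$x + u + rnorm(nInd * per, sd = 1)
  f1 <- fitLmm("x", d1)
  expect_lt(abs(f1$sigmaAlpha2 - 1), 0.2 * 1 + 0.15) # within ~20%
  expect_lt(abs(f1$sigmaEps2 - 1), 0.2)
  expect_equal(f1$aic, 2 * 4 - 2 * f1$loglik, tolerance = 1e-8)
})

test_that("a pure-noise predictor barely moves the log-likelihood", {
  set.seed(32)
  dll <- replicate(9, {
    n <- 600
    d <- data.frame(individualId = rep(sprintf("i%d", 1:6), each = 100),
                    x = rnorm(n), junk = rnorm(n))
    d$logRate <- 1 + 0.5 * d$x +
      rep(rnorm(6, sd = 0.5), each = 100) + rnorm(n)
    fitLmm(c("x", "junk"), d)$loglik - fitLmm("x", d)$loglik
  })
  expect_lt(median(dll), 2)
  expect_true(all(dll >= 0)) # nesting: likelihood never decreases
})

test_that("marginality governs which terms are removable", {
  rem <- revisit:::removableTerms(c("phos", "I(phos^2)", "evi", "dw",
                                    "dw:evi"))
  expect_true("I(phos^2)" %in% rem)   # quadratic before linear
  expect_true("dw:evi" %in% rem)      # interaction before mains
  expect_false("phos" %in% rem)       # blocked by its quadratic
  expect_false("evi" %in% rem)        # blocked by the interaction
  expect_false("dw" %in% rem)
  expect_true("phos" %in% revisit:::removableTerms(c("phos", "evi")))
})

test_that("backward selection recovers a planted quadratic signal", {
  set.seed(33)
  hits <- 0L
  for (i in 1:5) {
    n <- 900
    d <- data.frame(individualId = rep(sprintf("i%d", 1:6), each = 150),
                    x = rnorm(n), z = rnorm(n))
    d$logRate <- 1 + 1.0 * d$x - 0.8 * d$x^2 +
      rep(rnorm(6, sd = 0.5), each = 150) + rnorm(n)
    sel <- backwardAIC(c("x", "I(x^2)", "z", "I(z^2)"), d)
    hits <- hits + (all(c("x", "I(x^2)") %in% sel$chosenTerms) &&
                      !any(c("z", "I(z^2)") %in% sel$chosenTerms))
  }
  expect_gte(hits, 4L)
})

test_that("the parsimony rule prefers fewer terms within 2 AIC", {
  set.seed(34)
  n <- 400
  d <- data.frame(individualId = rep(sprintf("i%d", 1:4), each = 100),
                  x = rnorm(n), z = rnorm(n))
  d$logRate <- 1 + 0.6 * d$x + rep(rnorm(4, sd = 0.5), each = 100) + rnorm(n)
  sel <- backwardAIC(c("x", "z"), d)
  expect_true(sel$chosenAic <= min(sel$visited$aic) + 2)
  nTermsElig <- sel$visited$k[sel$visited$dAIC <= 2]
  expect_equal(length(sel$chosenTerms), min(nTermsElig))
})

test_that("stratified resampling flattens a centre-peaked gradient", {
  set.seed(35)
  d <- data.frame(x = rnorm(5000), y = rnorm(5000))
  rs <- stratifiedResample(d, "x", nStrata = 10, perStratum = 40, seed = 2)
  edges <- seq(min(d$x), max(d$x), length.out = 11)
  counts <- table(findInterval(rs$x, edges, rightmost.closed = TRUE))
  inner <- counts[as.character(3:8)] # strata populated enough to draw from
  expect_lte(max(inner) / min(inner), 1.5)
  # determinism
  rs2 <- stratifiedResample(d, "x", nStrata = 10, perStratum = 40, seed = 2)
  expect_identical(rs, rs2)
  # uniform data: all strata contribute equally
  du <- data.frame(x = runif(4000))
  ru <- stratifiedResample(du, "x", nStrata = 8, perStratum = 30, seed = 3)
  cu <- table(findInterval(ru$x, seq(0, 1, length.out = 9),
                           rightmost.closed = TRUE))
  expect_true(max(cu) / min(cu) <= 1.5)
})

test_that("interaction augmentation respects the allow-list and marginality", {
  set.seed(36)
  n <- 1200
  d <- data.frame(individualId = rep(sprintf("i%d", 1:6), each = 200),
                  evi = rnorm(n), slope = rnorm(n), phos = rnorm(n))
  d$logRate <- 1 + 0.5 * d$evi + 0.5 * d$slope + 0.9 * d$evi * d$slope +
    rep(rnorm(6, sd = 0.4), each = 200) + rnorm(n)
  base <- backwardAIC(c("evi", "slope", "phos"), d)
  # empty allow-list: identical object back
  expect_identical(addInteractions(base, d, allowList = list()), base)
  withInt <- addInteractions(base, d,
                             allowList = list(c("evi", "slope")))
  expect_true("evi:slope" %in% withInt$chosenTerms)
  # interaction whose main effect was never selected is skipped
  expect_warning(
    same <- addInteractions(base, d, allowList = list(c("evi", "absent"))),
    "not in the base model")
  expect_identical(same$chosenTerms, base$chosenTerms)
})

test_that("standardized fits are invariant to raw covariate rescaling", {
  set.seed(37)
  n <- 600
  raw <- data.frame(individualId = rep(sprintf("i%d", 1:6), each = 100),
                    p = rlnorm(n), w = runif(n, 0, 4000))
  raw$logRate <- 0.5 + 0.4 * scale(raw$p) - 0.3 * scale(raw$p)^2 +
    0.2 * scale(raw$w) + rep(rnorm(6, sd = 0.3), each = 100) + rnorm(n)
  fitOn <- function(mult) {
    d <- raw
    d$p <- d$p * mult
    d$p <- as.numeric(scale(d$p)); d$w <- as.numeric(scale(d$w))
    fitLmm(c("p", "I(p^2)", "w"), d)
  }
  f1 <- fitOn(1); f2 <- fitOn(137.5)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  expect_equal(nakagawaR2(f1), nakagawaR2(f2), tolerance = 1e-6)
})
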