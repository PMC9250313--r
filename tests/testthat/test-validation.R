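test_that("the temporal split holds out the last four observed years", {
  rec <- data.frame(species = "a", lon = 0, lat = 0, year = 2000:2015)
  sp <- temporalSplit(rec)
  expect_equal(range(sp$train$year), c(2000, 2011))
  expect_equal(sort(unique(sp$test$year)), 2012:2015)

  rec5 <- data.frame(species = "a", lon = 0, lat = 0, year = c(1:5, 5, 5))
  sp5 <- temporalSplit(rec5)
  expect_equal(unique(sp5$train$year), 1)
  expect_equal(sort(unique(sp5$test$year)), 2:5)
  ## the cut is by calendar year, not record count
  expect_equal(nrow(sp5$test), 6)

  expect_error(temporalSplit(data.frame(year = c(1, 2, 3, 4))), "5 distinct")
})

test_that("observed trends use only each pixel's sampled years", {
  g <- gridSpec(1, 3)
  mk <- function(v) rasterLayer(matrix(v, 1, 3), g)
  maps <- list("2012" = mk(c(5, NA, 1)), "2013" = mk(c(NA, 2, NA)),
               "2014" = mk(c(3, 4, NA)))
  tm <- observedTrend(maps, minYears = 2)
  s <- as.vector(rasterValues(trendSlopeLayer(tm)))
  expect_equal(s[1], -1)       # 5 -> 3 over 2 years
  expect_equal(s[2], 2)        # 2 -> 4 over 1 year
  expect_true(is.na(s[3]))     # a single year is not a trend

  set.seed(29)
  g2 <- gridSpec(5, 5)
  years <- 2010:2016
  panel <- lapply(years, function(y) {
    v <- rnorm(25, mean = y - 2010)
    v[runif(25) < 0.4] <- NA
    rasterLayer(matrix(v, 5, 5, byrow = TRUE), g2)
  })
  names(panel) <- years
  tm2 <- observedTrend(panel, minYears = 2)
  Y <- sapply(panel, cellValues)
  for (px in 1:25) {
    ok <- !is.na(Y[px, ])
    want <- if (sum(ok) < 2) NA_real_ else slopeOracle(years[ok], Y[px, ok])
    expect_equal(cellValues(trendSlopeLayer(tm2))[px], want,
                 tolerance = 1e-10)
  }
})

test_that("direction agreement counts matching signs, excluding flat pixels", {
  g <- gridSpec(4, 4)
  mkTrend <- function(v) {
    st <- rasterStack(list(rasterLayer(matrix(0, 4, 4), g),
                           rasterLayer(matrix(v, 4, 4, byrow = TRUE), g)),
                      labels = 1:2)
    trendSlope(st, 1:2)
  }
  set.seed(37)
  v <- rnorm(16)
  same <- directionAgreement(mkTrend(v), mkTrend(v))
  expect_equal(same$k, same$n)
  opp <- directionAgreement(mkTrend(v), mkTrend(-v))
  expect_equal(opp$k, 0)

  ## brute-force comparison on random signs, with zeros excluded
  p <- rnorm(16); o <- rnorm(16); o[c(3, 8)] <- 0
  da <- directionAgreement(mkTrend(p), mkTrend(o))
  cmp <- o != 0
  expect_equal(da$n, sum(cmp))
  expect_equal(da$k, sum(sign(p[cmp]) == sign(o[cmp])))
  expect_equal(da$nGain, sum(o > 0))
  agreement <- cellValues(da$agreement)
  expect_true(all(is.na(agreement[!cmp])))
})

test_that("the permutation null is calibrated against the binomial tail", {
  ## all-correct at n = 10: exact tail is 2^-10
  p <- permutationPvalue(10, 10, nPerm = 10000, seed = 1)
  exact <- 2^-10
  mcSe <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(p - exact), 3 * mcSe + 2 / 10001)

  expect_gt(permutationPvalue(50, 0, nPerm = 2000, seed = 2), 0.99)

  ## fair-coin symmetry: k = n/2 sits near p = 0.5
  p44 <- permutationPvalue(88, 44, nPerm = 10000, seed = 3)
  expect_lt(abs(p44 - pbinom(43, 88, 0.5, lower.tail = FALSE)), 0.02)

  ## monotone non-increasing in k
  ps <- sapply(0:10, function(k) permutationPvalue(10, k, nPerm = 5000,
                                                   seed = 4))
  expect_true(all(diff(ps) <= 0))

  ## bounds and argument checks
  expect_gte(permutationPvalue(5, 5, nPerm = 100, seed = 5), 1 / 101)
  expect_error(permutationPvalue(10, 5, pGain = 0), "pGain")
  expect_error(permutationPvalue(10, 5, pGain = 0.3), "nGain")
  ## asymmetric null with known composition: all-gain observed, pGain = 0.9
  pAsym <- permutationPvalue(20, 20, nPerm = 20000, pGain = 0.9, seed = 6,
                             nGain = 20)
  expect_lt(abs(pAsym - 0.9^20), 3 * sqrt(0.9^20 * (1 - 0.9^20) / 20000) +
              2 / 20001)
})

test_that("validateDirections assembles counts, p-value and agreement map", {
  g <- gridSpec(5, 5)
  set.seed(41)
  v <- rnorm(25)
  mkTrend <- function(x) trendSlope(rasterStack(
    list(rasterLayer(matrix(0, 5, 5), g), rasterLayer(matrix(x, 5, 5, byrow = TRUE), g)),
    labels = 1:2), 1:2)
  ## flip 5 of 25 signs
  w <- v; w[1:5] <- -w[1:5]
  rep <- validateDirections(mkTrend(v), mkTrend(w), nPerm = 2000, seed = 7)
  expect_s4_class(rep, "ValidationReport")
  expect_equal(rep@nCompared, 25L)
  expect_equal(rep@nCorrect, 20L)
  expect_equal(rep@fractionCorrect, 0.8)
  expect_lt(rep@pValue, 0.05)
  freq <- validateDirections(mkTrend(v), mkTrend(w), nPerm = 2000,
                             matchPredictedFrequency = TRUE, seed = 8)
  expect_true(freq@pValue > 0 && freq@pValue <= 1)
})
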