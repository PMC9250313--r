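test_that("per-pixel slopes follow the OLS closed form", {
  g <- gridSpec(1, 1)
  exact <- rasterStack(lapply(1:5, function(v)
    rasterLayer(matrix(v, 1, 1), g)), labels = 2015:2019)
  tm <- trendSlope(exact, 2015:2019)
  expect_equal(rasterValues(trendSlopeLayer(tm))[1, 1], 1)
  expect_equal(rasterValues(trendDirection(tm))[1, 1], 1)

  const <- rasterStack(lapply(1:5, function(v)
    rasterLayer(matrix(7, 1, 1), g)), labels = 2015:2019)
  tmc <- trendSlope(const, 2015:2019)
  expect_equal(rasterValues(trendSlopeLayer(tmc))[1, 1], 0)
  expect_equal(rasterValues(trendDirection(tmc))[1, 1], 0)

  set.seed(17)
  g2 <- gridSpec(6, 6)
  years <- 2015:2019
  mats <- lapply(years, function(y) matrix(rnorm(36), 6, 6))
  st <- rasterStack(lapply(mats, rasterLayer, grid = g2), labels = years)
  tm2 <- trendSlope(st, years)
  Y <- sapply(st@layers, cellValues)
  want <- apply(Y, 1, function(y) slopeOracle(years, y))
  expect_equal(cellValues(trendSlopeLayer(tm2)), want, tolerance = 1e-10)

  ## reversing the year order negates every slope
  stRev <- rasterStack(rev(st@layers), labels = years)
  tmRev <- trendSlope(stRev, years)
  expect_equal(cellValues(trendSlopeLayer(tmRev)),
               -cellValues(trendSlopeLayer(tm2)), tolerance = 1e-10)

  ## adding a constant to all years leaves slopes unchanged
  stShift <- rasterStack(lapply(st@layers, function(l)
    rasterLayer(rasterValues(l) + 100, g2)), labels = years)
  expect_equal(cellValues(trendSlopeLayer(trendSlope(stShift, years))),
               want, tolerance = 1e-10)
})

test_that("pixels with missing years are masked; short stacks are rejected", {
  g <- gridSpec(2, 2)
  m1 <- matrix(c(1, 2, 3, NA), 2, 2)
  m2 <- matrix(c(2, 3, 4, 5), 2, 2)
  st <- rasterStack(list(rasterLayer(m1, g), rasterLayer(m2, g)),
                    labels = 2015:2016)
  tm <- trendSlope(st, 2015:2016)
  expect_true(is.na(rasterValues(trendSlopeLayer(tm))[2, 2]))
  expect_equal(rasterValues(trendSlopeLayer(tm))[1, 1], 1)
  expect_error(trendSlope(rasterStack(list(rasterLayer(m1, g))), 2015),
               "at least 2")
})

test_that("an eps band reclassifies small slopes as no change", {
  g <- gridSpec(1, 2)
  st <- rasterStack(list(rasterLayer(matrix(c(0, 0), 1, 2), g),
                         rasterLayer(matrix(c(0.05, 2), 1, 2), g)),
                    labels = 2015:2016)
  tm <- trendSlope(st, 2015:2016, eps = 0.1)
  expect_equal(as.vector(rasterValues(trendDirection(tm))), c(0, 1))
})

test_that("yearly projections apply the model to each year's predictors", {
  set.seed(55)
  g <- gridSpec(8, 8)
  lon <- cellCenters(g)$lon; lat <- cellCenters(g)$lat
  X <- cbind(a = runif(64), b = runif(64))
  y <- 3 * X[, "a"] + rnorm(64, sd = 0.05)
  folds <- assignBlocks(lon, lat)
  m <- fitEnsemble(X, y, folds, specs = list(glm = learnerSpec("glm")),
                   seed = 5)

  mkSet <- function(av, bv) new("BioclimSet", grid = g,
    layers = list(layerOf(av, g), layerOf(bv, g)), labels = c("a", "b"),
    period = "x")
  layerOf <- function(v, g) rasterLayer(matrix(v, g@nrow, g@ncol, byrow = TRUE), g)
  sets <- list("2015" = mkSet(X[, "a"], X[, "b"]),
               "2016" = mkSet(X[, "a"], X[, "b"]),
               "2017" = mkSet(X[, "a"] + 1, X[, "b"]))
  st <- projectYearly(m, sets)
  expect_identical(stackLabels(st), c("2015", "2016", "2017"))
  ## identical predictors give identical projections
  expect_equal(rasterValues(getLayer(st, "2015")),
               rasterValues(getLayer(st, "2016")))
  ## each layer equals predictEnsemble on that year's table
  pt <- predictorTable(sets[["2017"]], vars = m@retainedVars)
  expect_equal(cellValues(getLayer(st, "2017"))[pt$cells],
               predictEnsemble(m, pt$matrix))

  ## single year: a stack of one
  expect_equal(nLayers(projectYearly(m, sets["2015"])), 1L)
  ## inconsistent grids across years error
  g2 <- gridSpec(4, 4)
  bad <- new("BioclimSet", grid = g2,
             layers = list(rasterLayer(matrix(1, 4, 4), g2),
                           rasterLayer(matrix(1, 4, 4), g2)),
             labels = c("a", "b"), period = "x")
  expect_error(projectYearly(m, c(sets["2015"], list("2018" = bad))), "2018")
})
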