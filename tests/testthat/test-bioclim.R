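test_that("climatology averages calendar months across years", {
  g <- gridSpec(2, 2)
  y1 <- constClimate(g, prec = 10)
  y2 <- constClimate(g, prec = 30)
  series <- list("2002" = y1, "2003" = y2)

  one <- monthlyClimatology(series, 2002)
  expect_equal(rasterValues(one@prec@layers[[1]]), matrix(10, 2, 2))

  both <- monthlyClimatology(series, 2002:2003)
  expect_equal(rasterValues(both@prec@layers[[1]]), matrix(20, 2, 2))

  expect_error(monthlyClimatology(series, 2002:2005), "2004")
})

test_that("climatology equals the brute-force per-cell mean on a drift series", {
  set.seed(11)
  g <- gridSpec(3, 3)
  years <- 2001:2005
  series <- lapply(years, function(y) {
    tmin <- matrix(rnorm(9 * 12, 10 + 0.1 * (y - 2001)), 9, 12)
    climateFromMatrices(g, tmin, tmin + 10, abs(tmin) * 10)
  })
  names(series) <- years
  clim <- monthlyClimatology(series, years)
  for (m in c(1, 6, 12)) {
    expected <- Reduce(`+`, lapply(series, function(s)
      rasterValues(s@tmin@layers[[m]]))) / length(years)
    expect_equal(rasterValues(clim@tmin@layers[[m]]), expected)
  }
})

test_that("constant climate yields the closed-form bioclim identities", {
  g <- gridSpec(2, 3)
  bc <- deriveBioclim(constClimate(g, tmin = 20, tmax = 30, prec = 100))
  want <- c(bio01 = 25, bio02 = 10, bio03 = 100, bio04 = 0, bio05 = 30,
            bio06 = 20, bio07 = 10, bio08 = 25, bio09 = 25, bio10 = 25,
            bio11 = 25, bio12 = 1200, bio13 = 100, bio14 = 100, bio15 = 0,
            bio16 = 300, bio17 = 300, bio18 = 300, bio19 = 300)
  for (nm in names(want))
    expect_equal(unique(as.vector(rasterValues(getLayer(bc, nm)))),
                 unname(want[nm]), info = nm)
})

test_that("random monthly profiles match the exhaustive-window oracle", {
  set.seed(7)
  g <- gridSpec(5, 4)   # 20 cells, each an independent profile
  n <- 20
  tminM <- matrix(rnorm(n * 12, 10, 5), n, 12)
  tmaxM <- tminM + matrix(runif(n * 12, 0.5, 12), n, 12)
  precM <- matrix(rexp(n * 12, 1 / 80), n, 12)
  bc <- deriveBioclim(climateFromMatrices(g, tminM, tmaxM, precM))
  for (cell in seq_len(n)) {
    want <- bioclimOracle(tminM[cell, ], tmaxM[cell, ], precM[cell, ])
    got <- sapply(sprintf("bio%02d", 1:19), function(v)
      cellValues(getLayer(bc, v))[cell])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("bioclim obeys its ordering and shift invariances", {
  set.seed(42)
  g <- gridSpec(6, 6)
  n <- 36
  tminM <- matrix(rnorm(n * 12, 12, 6), n, 12)
  tmaxM <- tminM + matrix(runif(n * 12, 0.1, 15), n, 12)
  precM <- matrix(rexp(n * 12, 1 / 60), n, 12)
  mc <- climateFromMatrices(g, tminM, tmaxM, precM)
  bc <- deriveBioclim(mc)
  v <- function(nm) cellValues(getLayer(bc, nm))
  expect_true(all(v("bio05") >= v("bio01") & v("bio01") >= v("bio06")))
  expect_true(all(v("bio13") >= v("bio14") & v("bio14") >= 0))
  expect_true(all(v("bio16") >= v("bio17")))
  expect_true(all(v("bio10") >= v("bio11")))

  ## cyclic month permutation leaves every quarter-based variable unchanged
  rot <- c(4:12, 1:3)
  bcRot <- deriveBioclim(climateFromMatrices(g, tminM[, rot], tmaxM[, rot],
                                             precM[, rot]))
  for (nm in c("bio08", "bio09", "bio10", "bio11",
               "bio16", "bio17", "bio18", "bio19"))
    expect_equal(cellValues(getLayer(bcRot, nm)), v(nm), info = nm)

  ## +c on all temperatures shifts the temperature levels, not the ranges
  bcShift <- deriveBioclim(climateFromMatrices(g, tminM + 3, tmaxM + 3, precM))
  for (nm in c("bio01", "bio05", "bio06", "bio08", "bio09", "bio10", "bio11"))
    expect_equal(cellValues(getLayer(bcShift, nm)), v(nm) + 3, info = nm)
  for (nm in c("bio02", "bio04", "bio07"))
    expect_equal(cellValues(getLayer(bcShift, nm)), v(nm), info = nm)
})

test_that("annual NDVI median reduces dated layers cell-wise", {
  g <- gridSpec(2, 2)
  single <- annualNdviMedian(list(constLayer(0.4, g)), 2017, 2017)
  expect_equal(rasterValues(single), matrix(0.4, 2, 2))

  three <- annualNdviMedian(list(constLayer(0.2, g), constLayer(0.5, g),
                                 constLayer(0.9, g)), 2017, 2017)
  expect_equal(rasterValues(three), matrix(0.5, 2, 2))

  set.seed(3)
  layers <- lapply(1:24, function(i)
    rasterLayer(matrix(runif(4, -1, 1), 2, 2), g))
  med <- annualNdviMedian(layers, rep(c(2016, 2017), each = 12), 2017)
  m <- sapply(layers[13:24], cellValues)
  expect_equal(cellValues(med), apply(m, 1, median))

  expect_error(annualNdviMedian(layers, rep(2016, 24), 2019), "2019")
})
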