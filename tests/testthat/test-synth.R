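# a small, fast landscape for generator tests
smallConfig <- function(years = 2002:2006, ...) {
  synthConfig(grid = gridSpec(12, 12, xmin = -52, ymin = -25, res = 0.2),
              years = years, nSpecies = 8, ...)
}

test_that("zero trend and zero noise give identical years; seeds reproduce", {
  cfg <- smallConfig(climateTrend = c(0, 0), noiseSd = 0, seed = 5)
  sim <- simulateClimate(cfg)
  for (m in c(1, 7)) {
    expect_equal(rasterValues(sim$climate[["2002"]]@tmin@layers[[m]]),
                 rasterValues(sim$climate[["2006"]]@tmin@layers[[m]]))
  }
  sim2 <- simulateClimate(cfg)
  expect_identical(rasterValues(sim$climate[["2004"]]@prec@layers[[3]]),
                   rasterValues(sim2$climate[["2004"]]@prec@layers[[3]]))
})

test_that("the imposed warming trend is recoverable from the fields", {
  cfg <- smallConfig(years = 2002:2011, climateTrend = c(0.1, 0),
                     noiseSd = 0.05, seed = 6)
  sim <- simulateClimate(cfg)
  years <- 2002:2011
  tmean <- sapply(as.character(years), function(k)
    cellValues(climateAxis(sim$climate[[k]])))
  slopes <- apply(tmean, 1, function(y) slopeOracle(years, y))
  expect_true(all(abs(slopes - 0.1) < 0.05))
  expect_lt(abs(mean(slopes) - 0.1), 0.01)
})

test_that("climate fields respect their physical constraints", {
  cfg <- smallConfig(noiseSd = 1, seed = 7)
  sim <- simulateClimate(cfg)
  for (k in names(sim$climate)) {
    mc <- sim$climate[[k]]
    for (m in 1:12) {
      expect_true(all(rasterValues(mc@tmax@layers[[m]]) >=
                        rasterValues(mc@tmin@layers[[m]])))
      expect_true(all(rasterValues(mc@prec@layers[[m]]) >= 0))
      nv <- rasterValues(sim$ndvi[[k]][[m]])
      expect_true(all(nv >= -1 & nv <= 1))
    }
  }
})

test_that("simulated trees are binary, labelled and reproducible", {
  t2 <- simulateTree(2, seed = 40)
  expect_equal(ape::Ntip(t2), 2)
  t50 <- simulateTree(50, seed = 41)
  expect_equal(t50$Nnode, 49)   # binary-tree identity
  expect_identical(t50$tip.label, sprintf("sp%03d", 1:50))
  expect_true(all(t50$edge.length >= 0))
  expect_identical(simulateTree(50, seed = 41)$edge.length, t50$edge.length)
})

test_that("ranges are climate-determined with calibrated total coverage", {
  cfg <- synthConfig(years = 2002:2006, seed = 43, rangeScale = 0.5)
  sim <- simulateClimate(cfg)
  axis <- climateAxis(monthlyClimatology(sim$climate, cfg@years))
  tree <- simulateTree(cfg@nSpecies, seed = 43)
  sp <- simulateSpeciesRanges(tree, axis, cfg)

  ## total clade range is rangeScale x grid area
  union <- rowSums(presenceMatrix(sp$community)) > 0
  expect_equal(mean(union), 0.5, tolerance = 0.05)

  ## richness correlates with suitability of the mean optimum
  rich <- cellValues(richnessFromCommunity(sp$community))
  meanOpt <- mean(sp$optima)
  suit <- exp(-(cellValues(axis) - meanOpt)^2 / (2 * cfg@nicheBreadth^2))
  expect_gt(cor(rich, suit, method = "spearman"), 0.5)

  ## two species with identical optima get identical ranges
  sp$optima[2] <- sp$optima[1]
  cm <- communityForClimate(sp, axis)
  expect_identical(presenceMatrix(cm)[, 1], presenceMatrix(cm)[, 2])
})

test_that("infinitely broad niches put every species everywhere", {
  cfg <- smallConfig(seed = 44, nicheBreadth = 1e9, rangeScale = 0.5)
  sim <- simulateClimate(cfg)
  axis <- climateAxis(monthlyClimatology(sim$climate, cfg@years))
  sp <- simulateSpeciesRanges(simulateTree(8, seed = 44), axis, cfg)
  expect_true(all(presenceMatrix(sp$community)))
  expect_true(all(cellValues(richnessFromCommunity(sp$community)) == 8))
})

test_that("inventories thin the truth binomially and are lossless at the limit", {
  cfg <- smallConfig(seed = 47)
  sim <- simulateClimate(cfg)
  axis <- climateAxis(monthlyClimatology(sim$climate, cfg@years))
  sp <- simulateSpeciesRanges(simulateTree(8, seed = 47), axis, cfg)
  comms <- list("2002" = sp$community)

  ## lossless limit: full effort, perfect detection
  rec <- simulateInventory(comms, detectionProb = 1, effort = 1, seed = 1)
  cm <- gridOccurrences(rec, cfg@grid)
  expect_identical(unname(presenceMatrix(cm)),
                   unname(presenceMatrix(sp$community)[, speciesNames(cm),
                                                       drop = FALSE]))
  expect_equal(rasterValues(richnessFromCommunity(cm)),
               rasterValues(richnessFromCommunity(sp$community)))

  ## no detection, no records
  expect_equal(nrow(simulateInventory(comms, detectionProb = 1e-12,
                                      effort = 1, seed = 2)), 0)

  ## binomial thinning: recorded richness in visited pixels matches the
  ## detection rate in expectation (3 SE band)
  rec5 <- simulateInventory(comms, detectionProb = 0.5, effort = 1, seed = 3)
  cm5 <- gridOccurrences(rec5, cfg@grid)
  trueN <- sum(presenceMatrix(sp$community))
  gotN <- sum(presenceMatrix(cm5))
  se <- sqrt(trueN * 0.5 * 0.5)
  expect_lt(abs(gotN - 0.5 * trueN), 3 * se)
})
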