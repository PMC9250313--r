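test_that("stacked ranges reproduce per-cell richness sums", {
  g <- gridSpec(4, 4)
  full <- constLayer(1, g)
  cm <- stackRanges(list(full, full, full), c("a", "b", "c"))
  expect_true(all(rasterValues(richnessFromCommunity(cm)) == 3))

  left <- rasterLayer(cbind(matrix(1, 4, 2), matrix(0, 4, 2)), g)
  right <- rasterLayer(cbind(matrix(0, 4, 2), matrix(1, 4, 2)), g)
  cm2 <- stackRanges(list(left, right), c("a", "b"))
  expect_true(all(rasterValues(richnessFromCommunity(cm2)) == 1))

  set.seed(2)
  ranges <- lapply(1:20, function(i)
    rasterLayer(matrix(rbinom(16, 1, 0.4), 4, 4), g))
  cm3 <- stackRanges(ranges, sprintf("sp%02d", 1:20))
  expected <- Reduce(`+`, lapply(ranges, rasterValues))
  expect_equal(rasterValues(richnessFromCommunity(cm3)), expected)

  bad <- rasterLayer(matrix(2, 4, 4), g)
  expect_error(stackRanges(list(full, bad), c("a", "weird")), "weird")
})

test_that("occurrence gridding bins by half-open cell membership", {
  g <- gridSpec(4, 4, xmin = 0, ymin = 0, res = 1)
  one <- gridOccurrences(data.frame(species = "a", lon = 0.5, lat = 3.5), g)
  r <- rasterValues(richnessFromCommunity(one))
  expect_equal(sum(r), 1)
  expect_equal(r[1, 1], 1)   # north-west cell

  two <- gridOccurrences(data.frame(species = c("a", "b"),
                                    lon = c(1.2, 1.9), lat = c(1.5, 1.2)), g)
  r2 <- rasterValues(richnessFromCommunity(two))
  expect_equal(sum(r2), 2)
  expect_equal(r2[3, 2], 2)

  set.seed(9)
  n <- 1000
  rec <- data.frame(species = sample(letters[1:12], n, replace = TRUE),
                    lon = runif(n, -1, 5), lat = runif(n, -1, 5))
  cm <- gridOccurrences(rec, g)
  ## brute-force point-in-cell oracle
  oracle <- matrix(FALSE, 16, 12,
                   dimnames = list(NULL, sort(unique(rec$species))))
  for (i in seq_len(n)) {
    col <- floor(rec$lon[i]) + 1
    row <- floor(4 - rec$lat[i]) + 1
    if (col >= 1 && col <= 4 && row >= 1 && row <= 4)
      oracle[(row - 1) * 4 + col, rec$species[i]] <- TRUE
  }
  expect_equal(unname(presenceMatrix(cm)), unname(oracle))
  expect_equal(attr(cm, "nOutside"),
               sum(rec$lon < 0 | rec$lon >= 4 | rec$lat <= 0 | rec$lat > 4))

  expect_warning(gridOccurrences(rec[0, ], g), "no occurrence")
})

test_that("Faith's PD equals the path-union oracle on every subset", {
  tree <- simulateTree(6, seed = 13)
  g <- gridSpec(7, 9)   # 63 cells: one per non-empty subset
  subsets <- lapply(1:63, function(k) which(intToBits(k)[1:6] == 1))
  pres <- matrix(FALSE, 63, 6, dimnames = list(NULL, tree$tip.label))
  for (k in 1:63) pres[k, subsets[[k]]] <- TRUE
  cm <- new("CommunityMatrix", grid = g, species = tree$tip.label,
            presence = pres, mask = rep(TRUE, 63))
  pd <- cellValues(faithPD(cm, tree))
  want <- sapply(subsets, function(s) pdOracle(tree, tree$tip.label[s]))
  expect_equal(pd, want, tolerance = 1e-12)
  ## full set: the whole tree
  expect_equal(pd[63], sum(tree$edge.length))
  ## cross-check against an independent implementation
  pic <- picante::pd(pres * 1, tree, include.root = TRUE)$PD
  expect_equal(pd, pic, tolerance = 1e-9)
})

test_that("PD is zero exactly on empty pixels and monotone in composition", {
  tree <- simulateTree(10, seed = 17)
  g <- gridSpec(5, 8)
  set.seed(18)
  pres <- matrix(runif(40 * 10) < 0.3, 40, 10,
                 dimnames = list(NULL, tree$tip.label))
  cm <- new("CommunityMatrix", grid = g, species = tree$tip.label,
            presence = pres, mask = rep(TRUE, 40))
  pd <- cellValues(faithPD(cm, tree))
  rich <- cellValues(richnessFromCommunity(cm))
  expect_identical(pd == 0, rich == 0)
  expect_true(all(pd >= 0))

  ## adding one species never decreases PD
  for (i in 1:10) {
    pres2 <- pres
    cell <- sample(40, 1); sp <- sample(10, 1)
    pres2[cell, sp] <- TRUE
    cm2 <- new("CommunityMatrix", grid = g, species = tree$tip.label,
               presence = pres2, mask = rep(TRUE, 40))
    expect_true(all(cellValues(faithPD(cm2, tree)) >= pd - 1e-12))
  }

  ## subadditivity over shared paths
  pdA <- pdOracle(tree, tree$tip.label[1])
  pdB <- pdOracle(tree, tree$tip.label[2])
  pdAB <- pdOracle(tree, tree$tip.label[1:2])
  expect_true(pdAB <= pdA + pdB + 1e-12)
  expect_true(pdAB >= max(pdA, pdB) - 1e-12)

  ## unknown species are reported by name
  cmBad <- new("CommunityMatrix", grid = g,
               species = c(tree$tip.label[-1], "ghost"),
               presence = pres, mask = rep(TRUE, 40))
  expect_error(faithPD(cmBad, tree), "ghost")
})
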