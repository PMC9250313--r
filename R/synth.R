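## Synthetic landscape generator: monthly climate fields with spatial
## autocorrelation and an inter-annual drift, a clade whose occupancy is
## climate-determined through Gaussian niches evolved along a simulated
## phylogeny, and noisy, spatially sparse inventory records across years.
## Every stage of the framework is exercisable on these inputs with known
## ground truth.

#' Configure the synthetic landscape
#'
#' Defaults emulate a subtropical study region: a 50 x 50 grid of 0.2
#' degree cells, a 7 degree C north-south gradient in mean temperature with
#' a 4 degree C seasonal cycle, years 2002-2019 with a warming drift, and a
#' clade of 30 species with temperature-determined Gaussian niches.
#'
#' @param grid a [GridSpec-class] (default 50 x 50, 0.2 degree cells).
#' @param years simulated calendar years (default 2002:2019).
#' @param nSpecies clade size (default 30).
#' @param nicheBreadth Gaussian niche SD on the temperature axis, degrees C
#'   (default 1.5).
#' @param climateTrend length-2 numeric `c(tmean, prec)`: linear
#'   inter-annual drift in degrees C/year and mm/month/year (default
#'   `c(0.1, 0)`, a strong-warming monitoring scenario).
#' @param noiseSd SD of the spatially autocorrelated inter-annual
#'   temperature noise, degrees C (precipitation noise scales as 8x this,
#'   in mm; default 0.5).
#' @param detectionProb probability a present species is recorded on a
#'   visit (default 0.7).
#' @param rangeScale target clade total range as a fraction of the grid
#'   area (default 0.5).
#' @param effort probability a pixel is visited in a given year
#'   (default 0.3).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(grid = gridSpec(50, 50, xmin = -52, ymin = -25,
                                        res = 0.2),
                        years = 2002:2019, nSpecies = 30,
                        nicheBreadth = 1.5, climateTrend = c(0.1, 0),
                        noiseSd = 0.5, detectionProb = 0.7,
                        rangeScale = 0.5, effort = 0.3, seed = 1L) {
  if (length(climateTrend) == 1) climateTrend <- c(climateTrend, 0)
  new("SynthConfig", grid = grid, years = as.numeric(years),
      nSpecies = as.integer(nSpecies), nicheBreadth = nicheBreadth,
      climateTrend = as.numeric(climateTrend), noiseSd = noiseSd,
      detectionProb = detectionProb, rangeScale = rangeScale,
      effort = effort, seed = as.integer(seed))
}

## spatially autocorrelated standard field: white noise circularly
## convolved with a Gaussian kernel (sigma in cells), rescaled to unit SD
.smoothField <- function(nr, nc, sigma = 2) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  k1 <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = sigma)
  k2 <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = sigma)
  kern <- outer(k1, k2)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(f)
  (f - mean(f)) / s
}

#' Simulate monthly climate and NDVI series
#'
#' Mean temperature is a smooth latitudinal gradient (warmer toward the
#' equator) plus a fixed spatially autocorrelated heterogeneity field, a
#' seasonal cosine peaking in January (austral summer), a per-(year, month)
#' autocorrelated noise field of SD `noiseSd`, and a linear inter-annual
#' drift of `climateTrend[1]` degrees C/year. Daily range is a constant 10
#' degrees C (`tmin = tmean - 5`, `tmax = tmean + 5`). Precipitation has a
#' longitudinal gradient (wetter east), the same seasonal phase, optional
#' drift and nonnegative truncation. Monthly NDVI tracks precipitation and
#' temperature with small noise, clipped to `[-1, 1]`.
#'
#' @param cfg a [SynthConfig-class].
#' @return list with `years`, `climate` (named list year ->
#'   [MonthlyClimate-class]) and `ndvi` (named list year -> list of 12
#'   monthly [RasterLayer-class]).
#' @export
simulateClimate <- function(cfg) {
  g <- cfg@grid
  nr <- g@nrow; nc <- g@ncol
  cc <- cellCenters(g)
  lat <- vecToMatrix(cc$lat, g)
  lon <- vecToMatrix(cc$lon, g)
  y0 <- min(cfg@years)

  set.seed(cfg@seed)
  hetero <- .smoothField(nr, nc, sigma = 3)          # fixed "topography"
  tBase <- 26 + 0.7 * (lat - max(lat)) + 1.0 * hetero
  pBase <- 80 + 6 * (lon - min(lon)) + 8 * .smoothField(nr, nc, sigma = 3)

  climate <- list(); ndvi <- list()
  for (year in cfg@years) {
    tl <- list(); xl <- list(); pl <- list(); nl <- list()
    for (m in 1:12) {
      seas <- cos(2 * pi * (m - 1) / 12)
      tNoise <- cfg@noiseSd * .smoothField(nr, nc, sigma = 2)
      tmean <- tBase + 4 * seas + cfg@climateTrend[1] * (year - y0) + tNoise
      tl[[m]] <- rasterLayer(tmean - 5, g)
      xl[[m]] <- rasterLayer(tmean + 5, g)
      pNoise <- 8 * cfg@noiseSd * .smoothField(nr, nc, sigma = 2)
      prec <- pBase * (1 + 0.5 * seas) + cfg@climateTrend[2] * (year - y0) +
        pNoise
      prec[prec < 0] <- 0
      pl[[m]] <- rasterLayer(prec, g)
      nv <- 0.3 + 0.0025 * prec - 0.015 * abs(tmean - 23) +
        0.03 * .smoothField(nr, nc, sigma = 2)
      nv[nv > 1] <- 1; nv[nv < -1] <- -1
      nl[[m]] <- rasterLayer(nv, g)
    }
    climate[[as.character(year)]] <- monthlyClimate(tl, xl, pl)
    ndvi[[as.character(year)]] <- nl
  }
  list(years = cfg@years, climate = climate, ndvi = ndvi)
}

#' Annual mean temperature axis of a MonthlyClimate
#'
#' The one-dimensional climate axis on which the synthetic niches live:
#' the cell-wise mean over 12 months of `(tmin + tmax)/2`.
#'
#' @param mc a [MonthlyClimate-class].
#' @return A [RasterLayer-class].
#' @export
climateAxis <- function(mc) {
  tavg <- (.monthMatrix(mc@tmin) + .monthMatrix(mc@tmax)) / 2
  layerFromVec(rowMeans(tavg), mc@tmin@grid)
}

#' Simulate a clade phylogeny
#'
#' Pure-birth (Yule) topology conditioned on the number of tips, with
#' independent exponential branch lengths (mean 0.5) and tips labelled
#' `sp001..spNNN`.
#'
#' @param nSpecies number of tips (>= 2).
#' @param seed RNG seed.
#' @return An `ape` `phylo` tree, rooted and binary.
#' @export
simulateTree <- function(nSpecies, seed = 1L) {
  set.seed(seed)
  tree <- ape::rphylo(nSpecies, birth = 1, death = 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 2)
  tree$tip.label <- sprintf("sp%03d", seq_len(nSpecies))
  tree
}

#' Simulate climate-determined species ranges
#'
#' Each species receives a thermal niche optimum evolved along the tree by
#' a Brownian walk (so niches carry phylogenetic signal and the richness/PD
#' mismatch is non-trivial), rescaled so the optima span the central part
#' of the observed temperature range. A species occupies a pixel where its
#' Gaussian suitability reaches a threshold; the threshold is the
#' `(1 - rangeScale)` quantile of per-pixel maximum suitability, which
#' calibrates the clade's total range (union of ranges) to `rangeScale x`
#' the grid area.
#'
#' @param tree clade phylogeny ([simulateTree()]).
#' @param axis baseline climate axis [RasterLayer-class]
#'   (see [climateAxis()]).
#' @param cfg a [SynthConfig-class].
#' @return list of class `synth_species`: `community`
#'   ([CommunityMatrix-class] at baseline), `ranges` ([RasterStack-class]
#'   of binary layers), `tree`, `optima`, `threshold`, `nicheBreadth`.
#' @export
simulateSpeciesRanges <- function(tree, axis, cfg) {
  clim <- cellValues(axis)
  ok <- !is.na(clim)
  set.seed(cfg@seed + 7L)
  raw <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  ## optima SD at 10% of the climate range: the clade is a coherent band of
  ## thermal specialists, so richness is a smooth unimodal function of the
  ## climate axis peaking near the mean optimum
  spread <- 0.1 * (max(clim[ok]) - min(clim[ok]))
  opt <- mean(clim[ok]) + (raw - mean(raw)) / max(stats::sd(raw), 1e-12) * spread
  names(opt) <- tree$tip.label

  suit <- exp(-outer(clim, opt, "-")^2 / (2 * cfg@nicheBreadth^2))
  ## exact threshold calibration: the union of ranges covers the pixels
  ## whose best suitability reaches tau, so the (1 - rangeScale) quantile
  ## of per-pixel max suitability puts the clade's total range at
  ## rangeScale x the grid area
  maxSuit <- apply(suit[ok, , drop = FALSE], 1, max)
  tau <- unname(stats::quantile(maxSuit, probs = 1 - cfg@rangeScale))

  occ <- suit >= tau
  occ[!ok, ] <- FALSE
  cm <- new("CommunityMatrix", grid = axis@grid, species = tree$tip.label,
            presence = occ, mask = ok)
  ranges <- rasterStack(lapply(seq_along(tree$tip.label), function(s) {
    v <- as.numeric(occ[, s]); v[!ok] <- NA_real_
    layerFromVec(v, axis@grid)
  }), labels = tree$tip.label)
  structure(list(community = cm, ranges = ranges, tree = tree,
                 optima = opt, threshold = tau,
                 nicheBreadth = cfg@nicheBreadth),
            class = "synth_species")
}

#' Community realised under a different climate
#'
#' Re-evaluates the clade's occupancy (same optima, same calibrated
#' threshold) on a new climate axis, e.g. a single year's mean temperature.
#' This is the ground-truth mechanism by which climate drift moves
#' richness.
#'
#' @param sp a `synth_species` object ([simulateSpeciesRanges()]).
#' @param axis climate axis [RasterLayer-class].
#' @return A [CommunityMatrix-class].
#' @export
communityForClimate <- function(sp, axis) {
  clim <- cellValues(axis)
  ok <- !is.na(clim)
  suit <- exp(-outer(clim, sp$optima, "-")^2 / (2 * sp$nicheBreadth^2))
  occ <- suit >= sp$threshold
  occ[!ok, ] <- FALSE
  new("CommunityMatrix", grid = axis@grid, species = names(sp$optima),
      presence = occ, mask = ok)
}

#' Simulate sparse, noisy inventory records
#'
#' Emulates field inventories: each year a pixel is visited with
#' probability `effort` (or the probability in `effortMap`), and every
#' species truly present in a visited pixel is recorded with probability
#' `detectionProb`. Records are placed at cell centers.
#'
#' @param communities named list (names = years) of
#'   [CommunityMatrix-class] (the true per-year communities).
#' @param detectionProb per-species detection probability on a visit.
#' @param effort scalar visit probability per pixel-year.
#' @param effortMap optional [RasterLayer-class] of per-pixel visit
#'   probabilities (overrides `effort`).
#' @param seed RNG seed.
#' @return data.frame with columns `species`, `lon`, `lat`, `year`.
#' @export
simulateInventory <- function(communities, detectionProb = 0.7,
                              effort = 0.3, effortMap = NULL, seed = 1L) {
  set.seed(seed)
  out <- vector("list", length(communities))
  for (i in seq_along(communities)) {
    cm <- communities[[i]]
    year <- as.numeric(names(communities)[i])
    cc <- cellCenters(cm@grid)
    pVisit <- if (is.null(effortMap)) rep(effort, length(cm@mask))
              else cellValues(effortMap)
    visited <- cm@mask & stats::runif(length(cm@mask)) < pVisit
    rec <- which(cm@presence[visited, , drop = FALSE] &
                   matrix(stats::runif(sum(visited) * length(cm@species)) <
                            detectionProb,
                          sum(visited), length(cm@species)),
                 arr.ind = TRUE)
    vIdx <- which(visited)
    out[[i]] <- if (nrow(rec) == 0) {
      data.frame(species = character(), lon = numeric(), lat = numeric(),
                 year = numeric())
    } else {
      data.frame(species = cm@species[rec[, 2]],
                 lon = cc$lon[vIdx[rec[, 1]]],
                 lat = cc$lat[vIdx[rec[, 1]]],
                 year = year)
    }
  }
  do.call(rbind, out)
}
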