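#' @import methods
NULL

#' Grid geometry of a raster
#'
#' Describes a regular lon/lat (or projected) grid: dimensions, extent,
#' resolution and a CRS identifier. Row 0 of any layer on this grid is the
#' northernmost row; extents are half-open `[min, max)` so a point exactly on
#' the eastern/southern edge falls outside the grid.
#'
#' @slot nrow,ncol grid dimensions.
#' @slot xmin,ymin,xmax,ymax extent in map units (cell edges, not centers).
#' @slot res cell size in map units (square cells).
#' @slot crs text CRS identifier, e.g. `"EPSG:4326"`.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    nrow = "integer", ncol = "integer",
    xmin = "numeric", ymin = "numeric",
    xmax = "numeric", ymax = "numeric",
    res  = "numeric", crs = "character"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@res <= 0) msg <- c(msg, "res must be > 0")
  if (object@nrow < 1L || object@ncol < 1L) msg <- c(msg, "nrow/ncol must be >= 1")
  if (abs((object@xmax - object@xmin) / object@res - object@ncol) > 1e-6)
    msg <- c(msg, "(xmax - xmin)/res must equal ncol")
  if (abs((object@ymax - object@ymin) / object@res - object@nrow) > 1e-6)
    msg <- c(msg, "(ymax - ymin)/res must equal nrow")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin,ymin lower-left corner (cell edge) in map units.
#' @param res cell size in map units.
#' @param crs CRS identifier string.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(10, 10, xmin = -50, ymin = -25, res = 0.5)
#' @export
gridSpec <- function(nrow, ncol, xmin = 0, ymin = 0, res = 1, crs = "EPSG:4326") {
  new("GridSpec",
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmin) + as.numeric(ncol) * res,
    ymax = as.numeric(ymin) + as.numeric(nrow) * res,
    res = as.numeric(res), crs = crs
  )
}

#' Single-band georeferenced raster
#'
#' A single gridded field. Values are stored as a numeric matrix with one row
#' per grid row (row 1 = northernmost); `NA` marks masked (nodata) cells,
#' which never enter any statistic downstream.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix, `NA` = masked.
#' @exportClass RasterLayer
setClass("RasterLayer",
  representation(grid = "GridSpec", values = "matrix")
)

setValidity("RasterLayer", function(object) {
  d <- dim(object@values)
  if (d[1] != object@grid@nrow || d[2] != object@grid@ncol)
    return("values matrix does not match grid dimensions")
  TRUE
})

#' Construct a RasterLayer
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` = masked.
#' @param grid a [GridSpec-class]; defaults to a unit grid matching `values`.
#' @return A [RasterLayer-class].
#' @examples
#' rasterLayer(matrix(1:6, 2, 3))
#' @export
rasterLayer <- function(values, grid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- gridSpec(nrow(values), ncol(values))
  new("RasterLayer", grid = grid, values = values)
}

#' Ordered, labelled collection of co-registered rasters
#'
#' All layers share one [GridSpec-class]; labels are unique.
#'
#' @slot grid shared [GridSpec-class].
#' @slot layers list of [RasterLayer-class].
#' @slot labels character, one per layer, unique.
#' @exportClass RasterStack
setClass("RasterStack",
  representation(grid = "GridSpec", layers = "list", labels = "character")
)

setValidity("RasterStack", function(object) {
  if (length(object@layers) != length(object@labels))
    return("labels and layers differ in length")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  for (l in object@layers) {
    if (!is(l, "RasterLayer")) return("all layers must be RasterLayer")
    if (!sameGrid(l@grid, object@grid)) return("all layers must share one GridSpec")
  }
  TRUE
})

#' Construct a RasterStack
#'
#' @param layers list of [RasterLayer-class] on one shared grid.
#' @param labels unique layer labels; defaults to names of `layers`.
#' @return A [RasterStack-class].
#' @export
rasterStack <- function(layers, labels = names(layers)) {
  if (is(layers, "RasterLayer")) layers <- list(layers)
  if (is.null(labels)) labels <- paste0("layer", seq_along(layers))
  new("RasterStack", grid = layers[[1]]@grid, layers = unname(layers),
      labels = as.character(labels))
}

#' Monthly climate normals or single-year monthlies
#'
#' Twelve layers each of minimum temperature, maximum temperature (degrees C)
#' and precipitation (mm/month), January first, on one shared grid.
#'
#' @slot tmin,tmax,prec [RasterStack-class] of 12 layers each.
#' @exportClass MonthlyClimate
setClass("MonthlyClimate",
  representation(tmin = "RasterStack", tmax = "RasterStack", prec = "RasterStack")
)

setValidity("MonthlyClimate", function(object) {
  for (s in list(object@tmin, object@tmax, object@prec))
    if (length(s@layers) != 12L) return("tmin/tmax/prec must each have 12 monthly layers")
  if (!sameGrid(object@tmin@grid, object@tmax@grid) ||
      !sameGrid(object@tmin@grid, object@prec@grid))
    return("all 36 layers must share one GridSpec")
  TRUE
})

#' The 19 bioclimatic summaries (+ optional NDVI) for one period
#'
#' A [RasterStack-class] labelled `bio01`..`bio19` (and `ndvi` when set) with
#' the period it summarises.
#'
#' @slot period text label of the period, e.g. `"2002-2014"` or `"2017"`.
#' @exportClass BioclimSet
setClass("BioclimSet", contains = "RasterStack",
  representation(period = "character"))

#' Pixels-by-species presence/absence on a grid
#'
#' Rows index grid cells in row-major order (row 1 west-to-east first);
#' `mask` flags the valid cells. Presence is FALSE everywhere on masked cells.
#'
#' @slot grid a [GridSpec-class].
#' @slot species unique species names (match phylogeny tips for PD).
#' @slot presence logical matrix, `ncell x nspecies`.
#' @slot mask logical vector of length `ncell`; TRUE = valid cell.
#' @exportClass CommunityMatrix
setClass("CommunityMatrix",
  representation(grid = "GridSpec", species = "character",
                 presence = "matrix", mask = "logical")
)

setValidity("CommunityMatrix", function(object) {
  ncell <- object@grid@nrow * object@grid@ncol
  if (nrow(object@presence) != ncell) return("presence must have one row per grid cell")
  if (ncol(object@presence) != length(object@species))
    return("presence must have one column per species")
  if (anyDuplicated(object@species)) return("species names must be unique")
  if (length(object@mask) != ncell) return("mask must have one entry per grid cell")
  if (any(object@presence[!object@mask, , drop = FALSE]))
    return("presence recorded on masked cells")
  TRUE
})

#' Spatial block fold assignment
#'
#' Quadrant labels 1-4 (NW, NE, SW, SE) from a latitude-first median split.
#'
#' @slot fold integer fold per point.
#' @slot lon,lat point coordinates.
#' @slot splitLat latitude of the N/S split.
#' @slot splitLons longitudes of the W/E splits in the northern and southern
#'   halves, in that order.
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(fold = "integer", lon = "numeric", lat = "numeric",
                 splitLat = "numeric", splitLons = "numeric")
)

#' RMSE-weighted ensemble of four regression learners
#'
#' Full-data fits of the tuned members, their spatial-CV RMSEs, the
#' inverse-RMSE (or stacking) weights, and cross-validated fit diagnostics.
#'
#' @slot members named list of fitted member objects (internal wrappers).
#' @slot cvRmse named numeric, pooled out-of-fold RMSE per member.
#' @slot weights named numeric, nonnegative, summing to 1.
#' @slot retainedVars predictor names the members were trained on.
#' @slot response `"richness"` or `"pd"` (or another response label).
#' @slot fitR2 squared Pearson correlation of pooled out-of-fold ensemble
#'   predictions with the response.
#' @slot trainR2 same on full-data (training) predictions.
#' @slot oofPred pooled out-of-fold ensemble predictions (training order).
#' @slot dropped members that failed to fit and were excluded.
#' @slot seed master seed used for the stochastic members.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(members = "list", cvRmse = "numeric", weights = "numeric",
                 retainedVars = "character", response = "character",
                 fitR2 = "numeric", trainR2 = "numeric", oofPred = "numeric",
                 dropped = "character", seed = "integer")
)

setValidity("EnsembleModel", function(object) {
  if (length(object@members) == 0L) return("ensemble has no members")
  w <- object@weights
  if (any(w < 0)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
  TRUE
})

#' Per-pixel linear trend of a diversity surface
#'
#' @slot slope,intercept [RasterLayer-class]; slope in response units/year.
#' @slot direction [RasterLayer-class] coded -1 (loss), 0 (none), +1 (gain).
#' @slot years the years regressed over (strictly increasing).
#' @slot eps half-width of the "no change" slope band (default 0).
#' @exportClass TrendMap
setClass("TrendMap",
  representation(slope = "RasterLayer", intercept = "RasterLayer",
                 direction = "RasterLayer", years = "numeric", eps = "numeric")
)

setValidity("TrendMap", function(object) {
  if (length(object@years) < 2L) return("need at least 2 years")
  if (any(diff(object@years) <= 0)) return("years must be strictly increasing")
  TRUE
})

#' Residuals of the per-year PD-on-richness regression
#'
#' @slot residuals [RasterLayer-class] of OLS residuals (positive = more
#'   phylogenetic diversity than expected for the species count).
#' @slot slope,intercept,r2 scalars of the cross-pixel OLS fit.
#' @slot year period label.
#' @exportClass MismatchMap
setClass("MismatchMap",
  representation(residuals = "RasterLayer", slope = "numeric",
                 intercept = "numeric", r2 = "numeric", year = "character")
)

#' Direction-of-change validation report
#'
#' @slot nCompared pixels with a jointly valid, nonzero-observed-slope sign.
#' @slot nCorrect pixels where predicted and observed signs agree.
#' @slot fractionCorrect `nCorrect / nCompared`.
#' @slot pValue permutation p-value against random gain/loss predictions.
#' @slot nPermutations number of null draws.
#' @slot agreement [RasterLayer-class]: 1 = correct, 0 = incorrect, NA =
#'   not compared.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(nCompared = "integer", nCorrect = "integer",
                 fractionCorrect = "numeric", pValue = "numeric",
                 nPermutations = "integer", agreement = "RasterLayer")
)

#' Configuration of the synthetic landscape generator
#'
#' Defines the study conditions emulated by the generator: grid, years,
#' clade size, niche geometry, climate drift and observation process.
#' See [synthConfig()] for field semantics and defaults.
#'
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(grid = "GridSpec", years = "numeric", nSpecies = "integer",
                 nicheBreadth = "numeric", climateTrend = "numeric",
                 noiseSd = "numeric", detectionProb = "numeric",
                 rangeScale = "numeric", effort = "numeric", seed = "integer")
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nSpecies < 2L) msg <- c(msg, "nSpecies must be >= 2")
  if (object@nicheBreadth <= 0) msg <- c(msg, "nicheBreadth must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@detectionProb <= 0 || object@detectionProb > 1)
    msg <- c(msg, "detectionProb must be in (0, 1]")
  if (object@rangeScale <= 0 || object@rangeScale > 1)
    msg <- c(msg, "rangeScale must be in (0, 1]")
  if (length(msg)) msg else TRUE
})
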