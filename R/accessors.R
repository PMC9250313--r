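#' @include AllClasses.R
NULL

#' Accessors for the spatial containers
#'
#' `gridOf()` returns the [GridSpec-class] of an object; `rasterValues()`
#' the value matrix of a [RasterLayer-class] (NA = masked); `rasterMask()`
#' its validity mask; `stackLabels()` and `nLayers()` describe a
#' [RasterStack-class]; `getLayer()` extracts a layer by label or position.
#'
#' @param x the object.
#' @param label layer label (character) or position (numeric).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setMethod("gridOf", "RasterLayer", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "RasterStack", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "CommunityMatrix", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "SynthConfig", function(x) x@grid)

#' @rdname accessors
#' @export
rasterValues <- function(x) x@values

#' @rdname accessors
#' @export
rasterMask <- function(x) !is.na(x@values)

#' @rdname accessors
#' @export
stackLabels <- function(x) x@labels

#' @rdname accessors
#' @export
nLayers <- function(x) length(x@layers)

#' @rdname accessors
#' @export
getLayer <- function(x, label) {
  if (is.character(label)) {
    i <- match(label, x@labels)
    if (is.na(i)) stop("no layer labelled '", label, "'")
  } else i <- label
  x@layers[[i]]
}

#' Accessors for community matrices
#'
#' @param x a [CommunityMatrix-class].
#' @return `speciesNames()`: character vector; `presenceMatrix()`: logical
#'   cells-by-species matrix in row-major cell order.
#' @name community-accessors
NULL

#' @rdname community-accessors
#' @export
speciesNames <- function(x) x@species

#' @rdname community-accessors
#' @export
presenceMatrix <- function(x) x@presence

#' Accessors for ensemble models
#'
#' @param x an [EnsembleModel-class].
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
memberWeights <- function(x) x@weights

#' @rdname ensemble-accessors
#' @export
cvRMSE <- function(x) x@cvRmse

#' @rdname ensemble-accessors
#' @export
fitR2 <- function(x) x@fitR2

#' Accessors for trend maps
#'
#' @param x a [TrendMap-class].
#' @name trend-accessors
NULL

#' @rdname trend-accessors
#' @export
trendSlopeLayer <- function(x) x@slope

#' @rdname trend-accessors
#' @export
trendDirection <- function(x) x@direction

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, res %g, extent [%g, %g) x [%g, %g), %s\n",
              object@nrow, object@ncol, object@res,
              object@xmin, object@xmax, object@ymin, object@ymax, object@crs))
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  ok <- !is.na(v)
  cat(sprintf("RasterLayer: %d x %d cells (%d valid)\n",
              nrow(v), ncol(v), sum(ok)))
  if (any(ok))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v[ok]), mean(v[ok]), max(v[ok])))
})

setMethod("show", "RasterStack", function(object) {
  cat(sprintf("RasterStack: %d layers on a %d x %d grid\n",
              length(object@layers), object@grid@nrow, object@grid@ncol))
  cat("  labels:", paste(utils::head(object@labels, 8), collapse = ", "),
      if (length(object@labels) > 8) "...", "\n")
})

setMethod("show", "BioclimSet", function(object) {
  cat(sprintf("BioclimSet (%s): %d layers on a %d x %d grid\n",
              object@period, length(object@layers),
              object@grid@nrow, object@grid@ncol))
})

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d species on a %d x %d grid (%d valid cells)\n",
              length(object@species), object@grid@nrow, object@grid@ncol,
              sum(object@mask)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel (%s): %d members\n",
              object@response, length(object@members)))
  df <- data.frame(cv_rmse = round(object@cvRmse, 4),
                   weight = round(object@weights, 4))
  print(df)
  cat(sprintf("  out-of-fold R2: %.3f (training R2: %.3f)\n",
              object@fitR2, object@trainR2))
  if (length(object@dropped))
    cat("  dropped members:", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "TrendMap", function(object) {
  s <- cellValues(object@slope)
  d <- cellValues(object@direction)
  cat(sprintf("TrendMap over %s\n", paste(range(object@years), collapse = "-")))
  cat(sprintf("  slope: min %.4g, max %.4g (units/year); gain %d, loss %d, none %d pixels\n",
              min(s, na.rm = TRUE), max(s, na.rm = TRUE),
              sum(d == 1, na.rm = TRUE), sum(d == -1, na.rm = TRUE),
              sum(d == 0, na.rm = TRUE)))
})

setMethod("show", "MismatchMap", function(object) {
  cat(sprintf("MismatchMap (%s): pd = %.4g + %.4g * sr, R2 = %.3f\n",
              object@year, object@intercept, object@slope, object@r2))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d/%d directions correct (%.1f%%), p = %.4g (%d permutations)\n",
              object@nCorrect, object@nCompared,
              100 * object@fractionCorrect, object@pValue,
              object@nPermutations))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %d x %d grid, years %s, %d species, seed %d\n",
              object@grid@nrow, object@grid@ncol,
              paste(range(object@years), collapse = "-"),
              object@nSpecies, object@seed))
})
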