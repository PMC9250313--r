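## Four spatial blocks along latitude/longitude lines, for cross-validation
## that tests transferability across space rather than interpolation.

## most balanced threshold: pick t from candidate values so that the count
## of elements on the "lower-index" side (>= t for latitude, <= t for
## longitude) is as close to half as possible; deterministic on ties.
.balancedSplit <- function(v, lowerIsGE) {
  cand <- sort(unique(v))
  nIn <- vapply(cand, function(t) if (lowerIsGE) sum(v >= t) else sum(v <= t),
                numeric(1))
  imb <- abs(2 * nIn - length(v))
  cand[which.min(imb)]   # ties -> smallest candidate value
}

#' Assign pixels to four spatial blocks
#'
#' Latitude-first median split: pixels are first divided into north/south
#' halves at the latitude giving the most even split, then each half is
#' divided east/west at its own most even longitude. Quadrants are labelled
#' 1 (NW), 2 (NE), 3 (SW), 4 (SE). Points exactly on a split line go to the
#' lower-index side (north for the latitude split, west for the longitude
#' splits). If all points are collinear along one axis, falls back to a 1-D
#' quartile split along the varying axis with a warning.
#'
#' @param lon,lat point (pixel-center) coordinates.
#' @param nFolds number of folds; only 4 is supported.
#' @return A [FoldAssignment-class].
#' @examples
#' fa <- assignBlocks(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' fa@fold  # one corner per fold
#' @export
assignBlocks <- function(lon, lat, nFolds = 4) {
  stopifnot(length(lon) == length(lat))
  if (nFolds != 4) stop("only 4 spatial blocks are supported")
  n <- length(lon)
  if (n < 4) stop("need at least 4 pixels to form 4 blocks")

  if (length(unique(lat)) == 1L || length(unique(lon)) == 1L) {
    warning("pixels are collinear; falling back to a 1-D quartile split")
    v <- if (length(unique(lat)) == 1L) lon else lat
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 1)
    fold <- as.integer(cut(v, c(-Inf, q, Inf), labels = FALSE))
    return(new("FoldAssignment", fold = fold, lon = lon, lat = lat,
               splitLat = NA_real_, splitLons = c(NA_real_, NA_real_)))
  }

  splitLat <- .balancedSplit(lat, lowerIsGE = TRUE)
  north <- lat >= splitLat
  splitLonN <- .balancedSplit(lon[north], lowerIsGE = FALSE)
  splitLonS <- .balancedSplit(lon[!north], lowerIsGE = FALSE)
  fold <- integer(n)
  fold[north] <- ifelse(lon[north] <= splitLonN, 1L, 2L)
  fold[!north] <- ifelse(lon[!north] <= splitLonS, 3L, 4L)
  new("FoldAssignment", fold = fold, lon = as.numeric(lon),
      lat = as.numeric(lat), splitLat = splitLat,
      splitLons = c(splitLonN, splitLonS))
}

#' Spatial blocks for the valid cells of a grid
#'
#' Convenience wrapper: blocks computed on the cell centers of the unmasked
#' cells (the modelling response lives on pixels, not occurrence points).
#'
#' @param grid a [GridSpec-class].
#' @param cells row-major indices of the cells to assign (e.g. the `cells`
#'   of a [predictorTable()]).
#' @return A [FoldAssignment-class] aligned with `cells`.
#' @export
blocksForCells <- function(grid, cells) {
  cc <- cellCenters(grid)
  assignBlocks(cc$lon[cells], cc$lat[cells])
}

#' Export a fold assignment as an integer raster
#'
#' @param fa a [FoldAssignment-class] built from grid cells.
#' @param grid the [GridSpec-class] the folds live on.
#' @param cells the row-major cell indices matching `fa@fold`.
#' @return A [RasterLayer-class] with fold labels 1-4 (NA elsewhere).
#' @export
foldRaster <- function(fa, grid, cells) {
  v <- rep(NA_real_, grid@nrow * grid@ncol)
  v[cells] <- fa@fold
  layerFromVec(v, grid)
}
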