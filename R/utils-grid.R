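## Grid geometry helpers. Cells are indexed row-major with row 1 the
## northernmost row; extents are half-open [min, max).

#' Test whether two GridSpecs describe the same grid
#'
#' @param a,b [GridSpec-class] objects.
#' @param tol numeric tolerance on extents/resolution.
#' @return logical.
#' @export
sameGrid <- function(a, b, tol = 1e-9) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    abs(a@xmin - b@xmin) < tol && abs(a@ymin - b@ymin) < tol &&
    abs(a@res - b@res) < tol
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid a [GridSpec-class].
#' @return data.frame with `lon`, `lat` in row-major cell order (row 1 =
#'   northernmost row, west to east).
#' @export
cellCenters <- function(grid) {
  lons <- grid@xmin + (seq_len(grid@ncol) - 0.5) * grid@res
  lats <- grid@ymax - (seq_len(grid@nrow) - 0.5) * grid@res
  data.frame(lon = rep(lons, times = grid@nrow),
             lat = rep(lats, each = grid@ncol))
}

#' Row-major cell index of point coordinates
#'
#' Half-open binning: a point exactly on a cell's southern or eastern edge
#' belongs to the neighbouring cell; points outside the extent get NA.
#'
#' @param grid a [GridSpec-class].
#' @param lon,lat point coordinates.
#' @return integer vector of row-major cell indices (NA = outside).
#' @export
cellFromXY <- function(grid, lon, lat) {
  col <- floor((lon - grid@xmin) / grid@res) + 1
  row <- floor((grid@ymax - lat) / grid@res) + 1
  ## points exactly on the northern/western outer edge are inside
  row[lat == grid@ymax] <- 1
  col[lon == grid@xmin] <- 1
  bad <- col < 1 | col > grid@ncol | row < 1 | row > grid@nrow |
    is.na(lon) | is.na(lat)
  idx <- (row - 1) * grid@ncol + col
  idx[bad] <- NA_integer_
  as.integer(idx)
}

## row-major vector <-> matrix (values matrices are nrow x ncol)
vecToMatrix <- function(v, grid) matrix(v, grid@nrow, grid@ncol, byrow = TRUE)
matrixToVec <- function(m) as.vector(t(m))

#' Extract cell values in row-major order
#'
#' @param x a [RasterLayer-class].
#' @return numeric vector, one entry per cell (NA = masked).
#' @export
cellValues <- function(x) matrixToVec(x@values)

## build a layer from a row-major cell vector
layerFromVec <- function(v, grid) rasterLayer(vecToMatrix(v, grid), grid)
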