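## Bioclimatic summaries from monthly climate grids.
##
## All 19 variables are computed cell-wise from 12 monthly tmin/tmax/prec
## layers; mean monthly temperature is (tmin + tmax)/2. Quarters are the 12
## cyclic windows of 3 consecutive months (Dec-Jan-Feb wraps), with ties
## broken by the lowest starting-month index. Standard deviations (bio4,
## bio15) are population SDs (divide by 12).

#' Construct a MonthlyClimate object
#'
#' @param tmin,tmax,prec lists of 12 [RasterLayer-class] (January first) or
#'   [RasterStack-class]s of 12 layers; temperatures in degrees C,
#'   precipitation in mm/month.
#' @return A [MonthlyClimate-class].
#' @export
monthlyClimate <- function(tmin, tmax, prec) {
  asStack <- function(x, pre) {
    if (is(x, "RasterStack")) return(x)
    rasterStack(x, labels = sprintf("%s_m%02d", pre, seq_along(x)))
  }
  new("MonthlyClimate", tmin = asStack(tmin, "tmin"),
      tmax = asStack(tmax, "tmax"), prec = asStack(prec, "prec"))
}

#' Cross-year monthly climatology
#'
#' Averages each calendar month's tmin/tmax/prec cell-wise across a window
#' of years, producing the climate normals used to train the diversity
#' models (the projection years use single-year monthlies instead).
#'
#' @param series named list (names = years) of [MonthlyClimate-class].
#' @param window years to average over; must all be present in `series`.
#' @return A [MonthlyClimate-class] of cross-year means.
#' @export
monthlyClimatology <- function(series, window) {
  keys <- as.character(window)
  missing <- setdiff(keys, names(series))
  if (length(missing))
    stop("missing climate years: ", paste(missing, collapse = ", "))
  grid <- series[[keys[1]]]@tmin@grid
  avg <- function(slot) {
    lapply(1:12, function(m) {
      mats <- lapply(keys, function(k) slot(series[[k]])@layers[[m]]@values)
      arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
      rasterLayer(rowMeans(arr, dims = 2, na.rm = FALSE), grid)
    })
  }
  monthlyClimate(avg(function(x) x@tmin), avg(function(x) x@tmax),
                 avg(function(x) x@prec))
}

## cells x 12 matrix from a 12-layer stack
.monthMatrix <- function(stack) {
  do.call(cbind, lapply(stack@layers, cellValues))
}

#' Derive the 19 bioclimatic variables
#'
#' Computes bio1-bio19 cell-wise from a [MonthlyClimate-class]:
#' annual means and extremes (bio1, bio5, bio6, bio12-bio14), diurnal range
#' and isothermality (bio2, bio3, bio7), seasonality (bio4 = population SD
#' of monthly mean temperature x 100; bio15 = 100 x SD(prec)/(1 + bio12/12)),
#' and the eight quarter summaries (bio8-bio11, bio16-bio19) over cyclic
#' 3-month windows: wettest/driest by summed precipitation, warmest/coldest
#' by mean temperature.
#'
#' @param mc a [MonthlyClimate-class].
#' @param ndvi optional annual NDVI [RasterLayer-class] appended as layer
#'   `"ndvi"` (see [annualNdviMedian()]).
#' @param period period label carried on the result.
#' @return A [BioclimSet-class] with layers `bio01`..`bio19` (+ `ndvi`).
#' @examples
#' g <- gridSpec(2, 2)
#' const <- function(x) rasterLayer(matrix(x, 2, 2), g)
#' mc <- monthlyClimate(replicate(12, const(20)), replicate(12, const(30)),
#'                      replicate(12, const(100)))
#' bc <- deriveBioclim(mc)
#' rasterValues(getLayer(bc, "bio02"))  # diurnal range: all 10
#' @export
deriveBioclim <- function(mc, ndvi = NULL, period = "") {
  grid <- mc@tmin@grid
  tmin <- .monthMatrix(mc@tmin)
  tmax <- .monthMatrix(mc@tmax)
  prec <- .monthMatrix(mc@prec)
  tavg <- (tmin + tmax) / 2
  n <- nrow(tavg)

  popSd <- function(m) sqrt(rowMeans((m - rowMeans(m))^2))

  b <- list()
  b$bio01 <- rowMeans(tavg)
  b$bio02 <- rowMeans(tmax - tmin)
  b$bio04 <- popSd(tavg) * 100
  b$bio05 <- do.call(pmax, as.data.frame(tmax))
  b$bio06 <- do.call(pmin, as.data.frame(tmin))
  b$bio07 <- b$bio05 - b$bio06
  b$bio03 <- ifelse(b$bio07 != 0, 100 * b$bio02 / b$bio07, NA_real_)
  b$bio12 <- rowSums(prec)
  b$bio13 <- do.call(pmax, as.data.frame(prec))
  b$bio14 <- do.call(pmin, as.data.frame(prec))
  b$bio15 <- 100 * popSd(prec) / (1 + b$bio12 / 12)

  ## cyclic 3-month windows starting at month w
  qsum <- matrix(0, n, 12); qmean <- matrix(0, n, 12)
  for (w in 1:12) {
    idx <- ((w - 1):(w + 1)) %% 12 + 1
    qsum[, w] <- rowSums(prec[, idx, drop = FALSE])
    qmean[, w] <- rowMeans(tavg[, idx, drop = FALSE])
  }
  pick <- function(m, q) q[cbind(seq_len(n), m)]
  wet <- max.col(qsum, ties.method = "first")
  dry <- max.col(-qsum, ties.method = "first")
  warm <- max.col(qmean, ties.method = "first")
  cold <- max.col(-qmean, ties.method = "first")

  b$bio08 <- pick(wet, qmean)
  b$bio09 <- pick(dry, qmean)
  b$bio10 <- pick(warm, qmean)
  b$bio11 <- pick(cold, qmean)
  b$bio16 <- pick(wet, qsum)
  b$bio17 <- pick(dry, qsum)
  b$bio18 <- pick(warm, qsum)
  b$bio19 <- pick(cold, qsum)

  ord <- sprintf("bio%02d", 1:19)
  layers <- lapply(ord, function(k) layerFromVec(b[[k]], grid))
  labels <- ord
  if (!is.null(ndvi)) {
    stopifnot(sameGrid(ndvi@grid, grid))
    layers <- c(layers, list(ndvi))
    labels <- c(labels, "ndvi")
  }
  new("BioclimSet", grid = grid, layers = layers, labels = labels,
      period = as.character(period))
}

#' Cell-wise annual NDVI median
#'
#' Reduces a dated series of NDVI layers to the cell-wise median over the
#' observations falling in one year.
#'
#' @param layers list of NDVI [RasterLayer-class].
#' @param years year of each layer (recycled vector or scalar).
#' @param year the year to summarise.
#' @return A [RasterLayer-class] of medians.
#' @export
annualNdviMedian <- function(layers, years, year) {
  years <- rep_len(years, length(layers))
  sel <- which(years == year)
  if (!length(sel)) stop("no NDVI layers dated within ", year)
  grid <- layers[[sel[1]]]@grid
  m <- do.call(cbind, lapply(layers[sel], cellValues))
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  layerFromVec(med, grid)
}

#' Predictor table from a BioclimSet
#'
#' Flattens a [BioclimSet-class] (or any [RasterStack-class]) into the
#' pixels-by-variables matrix the variable selection and ensemble stages
#' consume. Only pixels valid in every layer are kept.
#'
#' @param x a [RasterStack-class].
#' @param vars optional subset of layer labels.
#' @return list with `matrix` (pixels x vars), `cells` (row-major cell
#'   indices of the retained pixels) and `grid`.
#' @export
predictorTable <- function(x, vars = NULL) {
  if (is.null(vars)) vars <- x@labels
  m <- do.call(cbind, lapply(vars, function(v) cellValues(getLayer(x, v))))
  colnames(m) <- vars
  ok <- stats::complete.cases(m)
  list(matrix = m[ok, , drop = FALSE], cells = which(ok), grid = x@grid)
}
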