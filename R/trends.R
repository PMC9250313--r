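## Yearly projections of a fitted ensemble and their reduction to a
## per-pixel linear trend (slope of diversity on calendar year).

#' Project an ensemble onto yearly predictor sets
#'
#' Applies the fitted model to each year's bioclim (+NDVI) layers, yielding
#' one predicted diversity surface per year.
#'
#' @param model an [EnsembleModel-class].
#' @param yearlyPredictors named list (names = years) of
#'   [BioclimSet-class] / [RasterStack-class], all on one grid, each
#'   containing every `model@retainedVars` layer.
#' @return A [RasterStack-class] with one layer per year, labelled by year.
#' @export
projectYearly <- function(model, yearlyPredictors) {
  yrs <- names(yearlyPredictors)
  grid <- yearlyPredictors[[1]]@grid
  layers <- vector("list", length(yrs))
  for (i in seq_along(yrs)) {
    bs <- yearlyPredictors[[i]]
    if (!sameGrid(bs@grid, grid))
      stop("predictor grids differ across years (year ", yrs[i], ")")
    pt <- predictorTable(bs, vars = model@retainedVars)
    v <- rep(NA_real_, grid@nrow * grid@ncol)
    if (nrow(pt$matrix)) v[pt$cells] <- predictEnsemble(model, pt$matrix)
    layers[[i]] <- layerFromVec(v, grid)
  }
  new("RasterStack", grid = grid, layers = layers, labels = yrs)
}

## per-pixel OLS slope/intercept of Y (cells x years) on centered years;
## rows with fewer than minYears valid entries come back NA
.pixelOLS <- function(Y, years, minYears = length(years)) {
  ok <- !is.na(Y)
  nOk <- rowSums(ok)
  W <- ok * 1
  Yz <- Y; Yz[!ok] <- 0
  tY <- Yz %*% years          # sum of t*y over valid
  sY <- rowSums(Yz)           # sum of y
  sT <- W %*% years           # sum of t over valid
  sT2 <- W %*% years^2
  denom <- as.vector(sT2 - sT^2 / nOk)
  slope <- as.vector(tY - sT * sY / nOk) / denom
  intercept <- sY / nOk - slope * as.vector(sT) / nOk
  bad <- nOk < max(2, minYears) | !is.finite(slope)
  slope[bad] <- NA_real_; intercept[bad] <- NA_real_
  list(slope = slope, intercept = intercept)
}

#' Per-pixel linear trend of a yearly stack
#'
#' Ordinary least squares of the stacked values on calendar year, per pixel
#' (years are centered internally; the slope is unaffected). A pixel enters
#' only if it is valid in every layer; otherwise it is masked. Direction is
#' the sign of the slope, with `"none"` where `|slope| <= eps`.
#'
#' @param stack a [RasterStack-class], one layer per year.
#' @param years numeric years matching the layers, strictly increasing.
#' @param eps half-width of the no-change band (default 0: any nonzero
#'   slope counts as gain or loss, matching a sign-based validation).
#' @return A [TrendMap-class]; slope in response units per year.
#' @examples
#' g <- gridSpec(1, 1)
#' st <- rasterStack(lapply(1:5, function(v) rasterLayer(matrix(v, 1, 1), g)),
#'                   labels = 2015:2019)
#' tm <- trendSlope(st, 2015:2019)
#' rasterValues(trendSlopeLayer(tm))  # slope 1
#' @export
trendSlope <- function(stack, years, eps = 0) {
  years <- as.numeric(years)
  stopifnot(length(years) == length(stack@layers))
  if (length(years) < 2) stop("need at least 2 years for a trend")
  Y <- do.call(cbind, lapply(stack@layers, cellValues))
  complete <- rowSums(is.na(Y)) == 0
  Y[!complete, ] <- NA_real_
  tc <- years - mean(years)
  fit <- .pixelOLS(Y, tc, minYears = length(years))
  grid <- stack@grid
  dir <- ifelse(is.na(fit$slope), NA_real_,
                ifelse(fit$slope > eps, 1, ifelse(fit$slope < -eps, -1, 0)))
  new("TrendMap", slope = layerFromVec(fit$slope, grid),
      intercept = layerFromVec(fit$intercept, grid),
      direction = layerFromVec(dir, grid),
      years = years, eps = eps)
}
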