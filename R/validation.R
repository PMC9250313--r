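## Ground-truthing: compare modelled direction-of-change with observed
## inventory trends per pixel, scored against a permutation null of random
## gain/loss predictions.

#' Split occurrence records at the last four observed years
#'
#' Test records are those from the last `holdoutYears` distinct observed
#' calendar years; everything earlier is training. The cut is by calendar
#' year, never by record count.
#'
#' @param records data.frame with a `year` column.
#' @param holdoutYears number of most recent observed years held out
#'   (default 4).
#' @return list with `train` and `test` data.frames.
#' @examples
#' rec <- data.frame(species = "a", lon = 0, lat = 0, year = 2000:2015)
#' sp <- temporalSplit(rec)
#' range(sp$train$year)  # 2000 2011
#' @export
temporalSplit <- function(records, holdoutYears = 4) {
  stopifnot("year" %in% names(records))
  yrs <- sort(unique(records$year[!is.na(records$year)]))
  if (length(yrs) < holdoutYears + 1)
    stop("need at least ", holdoutYears + 1, " distinct observed years")
  testYears <- utils::tail(yrs, holdoutYears)
  list(train = records[!is.na(records$year) &
                         records$year < min(testYears), , drop = FALSE],
       test = records[!is.na(records$year) &
                        records$year %in% testYears, , drop = FALSE])
}

#' Observed per-pixel richness trend from sparse inventories
#'
#' Per-pixel OLS slope of observed richness on year, using only the years
#' in which the pixel has data; pixels observed in fewer than `minYears`
#' years are masked (sparse sampling rarely covers every pixel each year).
#'
#' @param perYearRichness named list (names = years) of richness
#'   [RasterLayer-class]; `NA` marks pixels unsampled that year.
#' @param minYears minimum number of sampled years for a pixel to get a
#'   trend (default 2).
#' @return A [TrendMap-class].
#' @export
observedTrend <- function(perYearRichness, minYears = 2) {
  years <- as.numeric(names(perYearRichness))
  stopifnot(length(years) >= minYears)
  grid <- perYearRichness[[1]]@grid
  Y <- do.call(cbind, lapply(perYearRichness, cellValues))
  tc <- years - mean(years)
  fit <- .pixelOLS(Y, tc, minYears = minYears)
  dir <- ifelse(is.na(fit$slope), NA_real_, sign(fit$slope))
  new("TrendMap", slope = layerFromVec(fit$slope, grid),
      intercept = layerFromVec(fit$intercept, grid),
      direction = layerFromVec(dir, grid),
      years = years, eps = 0)
}

#' Direction-of-change agreement between two trend maps
#'
#' Compares the sign of the slope on jointly valid pixels; pixels whose
#' observed slope is exactly zero are excluded (their sign is undefined).
#'
#' @param predicted,observed [TrendMap-class] on one shared grid.
#' @return list with `n` (pixels compared), `k` (signs agreeing),
#'   `nGain` (observed gains among compared pixels), and `agreement`
#'   ([RasterLayer-class]: 1 correct, 0 incorrect, NA not compared).
#' @export
directionAgreement <- function(predicted, observed) {
  if (!sameGrid(predicted@slope@grid, observed@slope@grid))
    stop("trend maps must share one grid")
  ps <- cellValues(predicted@slope)
  os <- cellValues(observed@slope)
  cmp <- !is.na(ps) & !is.na(os) & os != 0
  if (!any(cmp)) stop("no pixels with comparable direction of change")
  agree <- rep(NA_real_, length(ps))
  agree[cmp] <- as.numeric(sign(ps[cmp]) == sign(os[cmp]))
  list(n = sum(cmp), k = sum(agree[cmp]),
       nGain = sum(os[cmp] > 0),
       agreement = layerFromVec(agree, predicted@slope@grid))
}

#' Permutation p-value for direction-of-change accuracy
#'
#' Simulates `nPerm` random gain/loss prediction maps (each pixel predicted
#' "gain" independently with probability `pGain`), counts how many pixels
#' each random map gets right, and reports the add-one permutation p-value
#' `p = (1 + #(correct >= k)) / (nPerm + 1)`.
#'
#' With `pGain = 0.5` the null match count is Binomial(n, 0.5) regardless
#' of the observed gain/loss composition, so `nGain` is not needed. For an
#' asymmetric null (e.g. matching the predicted gain frequency) the
#' composition matters: supply `nGain`, the number of observed-gain pixels
#' among the `n` compared.
#'
#' @param n pixels compared.
#' @param k pixels with correctly predicted direction.
#' @param nPerm number of random predictions (default 10000).
#' @param pGain probability that a random prediction calls "gain"
#'   (default 0.5, a fair coin).
#' @param seed optional RNG seed.
#' @param nGain observed gains among the `n` pixels; required when
#'   `pGain != 0.5`.
#' @return the permutation p-value (in `[1/(nPerm+1), 1]`).
#' @export
permutationPvalue <- function(n, k, nPerm = 10000, pGain = 0.5, seed = NULL,
                              nGain = NULL) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (pGain <= 0 || pGain >= 1) stop("pGain must be in (0, 1)")
  if (is.null(nGain)) {
    if (abs(pGain - 0.5) > 1e-12)
      stop("nGain (observed gains) is required when pGain != 0.5")
    nGain <- 0L   # irrelevant under the symmetric null
  }
  if (!is.null(seed)) set.seed(seed)
  ## a random label matches an observed gain w.p. pGain, a loss w.p. 1-pGain
  correct <- stats::rbinom(nPerm, nGain, pGain) +
    stats::rbinom(nPerm, n - nGain, 1 - pGain)
  (1 + sum(correct >= k)) / (nPerm + 1)
}

#' Validate modelled direction of change against observed trends
#'
#' Convenience wrapper chaining [directionAgreement()] and
#' [permutationPvalue()] into a [ValidationReport-class].
#'
#' @param predicted,observed [TrendMap-class] on one shared grid.
#' @param nPerm number of null draws.
#' @param pGain probability of "gain" in a random prediction; with
#'   `matchPredictedFrequency = TRUE` it is replaced by the predicted gain
#'   fraction over the compared pixels.
#' @param matchPredictedFrequency use the frequency-matched null instead of
#'   the fair coin.
#' @param seed optional RNG seed for the null draws.
#' @return A [ValidationReport-class].
#' @export
validateDirections <- function(predicted, observed, nPerm = 10000,
                               pGain = 0.5, matchPredictedFrequency = FALSE,
                               seed = NULL) {
  da <- directionAgreement(predicted, observed)
  if (matchPredictedFrequency) {
    ps <- cellValues(predicted@slope)
    os <- cellValues(observed@slope)
    cmp <- !is.na(ps) & !is.na(os) & os != 0
    pGain <- mean(ps[cmp] > 0)
    pGain <- min(max(pGain, 1 / (da$n + 1)), 1 - 1 / (da$n + 1))
  }
  p <- permutationPvalue(da$n, da$k, nPerm = nPerm, pGain = pGain,
                         seed = seed, nGain = da$nGain)
  new("ValidationReport", nCompared = as.integer(da$n),
      nCorrect = as.integer(da$k),
      fractionCorrect = da$k / da$n, pValue = p,
      nPermutations = as.integer(nPerm), agreement = da$agreement)
}
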