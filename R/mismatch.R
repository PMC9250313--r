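## Richness/PD mismatch: residuals of the cross-pixel OLS regression of
## phylogenetic diversity on species richness, recomputed independently for
## each year. Positive residuals flag pixels holding more evolutionary
## diversity than expected for their species count.

#' Residuals of PD regressed on species richness
#'
#' Fits `pd = a + b * sr` by OLS across the jointly valid pixels of one
#' year and maps the residuals. Residuals average zero and are orthogonal
#' to richness by construction.
#'
#' @param pd phylogenetic diversity [RasterLayer-class].
#' @param sr species richness [RasterLayer-class] on the same grid.
#' @param year period label carried on the result.
#' @return A [MismatchMap-class].
#' @export
pdSrResiduals <- function(pd, sr, year = "") {
  if (!sameGrid(pd@grid, sr@grid)) stop("pd and sr must share one grid")
  pdv <- cellValues(pd); srv <- cellValues(sr)
  ok <- !is.na(pdv) & !is.na(srv)
  if (sum(ok) < 3) stop("need at least 3 jointly valid pixels")
  if (stats::sd(srv[ok]) == 0)
    stop("richness is constant across pixels; slope undefined")
  fit <- stats::lm.fit(cbind(1, srv[ok]), pdv[ok])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  res <- rep(NA_real_, length(pdv))
  res[ok] <- pdv[ok] - (a + b * srv[ok])
  r2 <- 1 - sum(fit$residuals^2) / sum((pdv[ok] - mean(pdv[ok]))^2)
  new("MismatchMap", residuals = layerFromVec(res, pd@grid),
      slope = unname(b), intercept = unname(a), r2 = unname(r2),
      year = as.character(year))
}
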