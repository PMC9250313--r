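## Multicollinearity pruning by stepwise variance-inflation-factor
## elimination (the usual ecology preprocessing before regression-type
## diversity models). Applied once, on the training-window predictors.

#' Variance inflation factors
#'
#' VIF of column j is 1/(1 - R2_j), with R2_j from the OLS regression of
#' column j on all other columns plus an intercept. Columns are standardized
#' first (VIF is scale-invariant; standardizing improves conditioning).
#' A perfectly collinear column reports `Inf` rather than failing.
#'
#' @param x numeric matrix with column names (pixels x variables).
#' @return named numeric vector of VIFs (all >= 1).
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(200), b = rnorm(200))
#' computeVIF(x)  # both close to 1
#' @export
computeVIF <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance columns: ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  vif <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, xs[, -j, drop = FALSE]), xs[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum(xs[, j]^2)   # standardized, mean 0
    r2 <- 1 - rss / tss
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(vif, colnames(x))
}

#' Stepwise VIF elimination
#'
#' Iteratively drops the single variable with the largest VIF while that
#' VIF exceeds the threshold, recomputing after each drop; stops when all
#' remaining VIFs are at or below the threshold. Deterministic: ties go to
#' the earlier-listed variable.
#'
#' @param x numeric matrix with column names (pixels x variables).
#' @param threshold VIF threshold (default 10, the usual redundancy cut).
#' @return list with `retained` (names), `dropped` (data.frame `var`,
#'   `vif` recorded at the drop, in drop order) and `threshold`.
#' @export
vifStepwise <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  keep <- colnames(x)
  dropped <- data.frame(var = character(), vif = numeric())
  while (length(keep) >= 2) {
    vif <- computeVIF(x[, keep, drop = FALSE])
    worst <- which.max(vif)     # first index on ties
    if (vif[worst] <= threshold) break
    dropped <- rbind(dropped,
                     data.frame(var = keep[worst], vif = unname(vif[worst])))
    keep <- keep[-worst]
  }
  list(retained = keep, dropped = dropped, threshold = threshold)
}

#' Drop constant or numerically degenerate predictor columns
#'
#' A predictor with (near-)zero variance carries no information and makes
#' VIF undefined; such columns arise naturally (e.g. a bioclim variable
#' that is constant over a region). Returns the names of the informative
#' columns.
#'
#' @param x numeric matrix with column names.
#' @param tol relative variance tolerance.
#' @return character vector of retained column names.
#' @export
informativeVars <- function(x, tol = 1e-8) {
  sds <- apply(x, 2, stats::sd)
  mus <- abs(colMeans(x))
  keep <- sds > tol * (1 + mus)
  if (!all(keep))
    message("dropping constant predictors: ",
            paste(colnames(x)[!keep], collapse = ", "))
  colnames(x)[keep]
}
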