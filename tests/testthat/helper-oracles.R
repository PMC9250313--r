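# Independent brute-force oracles used to pin expected values.
# These deliberately share no code with the package internals: scalar
# loops, explicit window enumeration, textbook formulas.

# all 19 bioclimatic values for one cell, enumerating the 12 cyclic
# 3-month windows explicitly
bioclimOracle <- function(tmin, tmax, prec) {
  tavg <- (tmin + tmax) / 2
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  qIdx <- lapply(1:12, function(w) ((w - 1):(w + 1)) %% 12 + 1)
  qPrec <- sapply(qIdx, function(i) sum(prec[i]))
  qTavg <- sapply(qIdx, function(i) mean(tavg[i]))
  wet <- which.max(qPrec); dry <- which.min(qPrec)
  warm <- which.max(qTavg); cold <- which.min(qTavg)
  out <- c(
    bio01 = mean(tavg),
    bio02 = mean(tmax - tmin),
    bio04 = sdp(tavg) * 100,
    bio05 = max(tmax),
    bio06 = min(tmin),
    bio12 = sum(prec),
    bio13 = max(prec),
    bio14 = min(prec),
    bio08 = qTavg[wet], bio09 = qTavg[dry],
    bio10 = qTavg[warm], bio11 = qTavg[cold],
    bio16 = qPrec[wet], bio17 = qPrec[dry],
    bio18 = qPrec[warm], bio19 = qPrec[cold]
  )
  out["bio07"] <- out["bio05"] - out["bio06"]
  out["bio03"] <- 100 * out["bio02"] / out["bio07"]
  out["bio15"] <- 100 * sdp(prec) / (1 + out["bio12"] / 12)
  out[sprintf("bio%02d", 1:19)]
}

# VIF by explicit per-column lm() regressions
vifOracle <- function(x) {
  sapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}

# rooted Faith's PD by explicit root-to-tip path union
pdOracle <- function(tree, tips) {
  if (!length(tips)) return(0)
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  onPath <- logical(nrow(tree$edge))
  for (tp in tips) {
    node <- match(tp, tree$tip.label)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      onPath[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[onPath])
}

# OLS slope of y on t, textbook closed form
slopeOracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# constant-valued layer on a grid
constLayer <- function(x, grid) rasterLayer(matrix(x, grid@nrow, grid@ncol), grid)

# 12-month constant climate on a small grid
constClimate <- function(grid, tmin = 20, tmax = 30, prec = 100) {
  monthlyClimate(replicate(12, constLayer(tmin, grid), simplify = FALSE),
                 replicate(12, constLayer(tmax, grid), simplify = FALSE),
                 replicate(12, constLayer(prec, grid), simplify = FALSE))
}

# climate whose 12 monthly per-cell values are supplied as cells x 12
# matrices (for oracle comparisons)
climateFromMatrices <- function(grid, tminM, tmaxM, precM) {
  toLayers <- function(m) lapply(1:12, function(j)
    rasterLayer(matrix(m[, j], grid@nrow, grid@ncol, byrow = TRUE), grid))
  monthlyClimate(toLayers(tminM), toLayers(tmaxM), toLayers(precM))
}
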