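## End-to-end orchestration on the synthetic landscape: climate ->
## bioclim -> VIF pruning -> spatially cross-validated ensembles ->
## yearly projections -> trend and mismatch maps -> inventory-based
## direction-of-change validation. Deterministic given the master seed;
## every artifact directory carries a provenance log naming the config
## hash.

#' Pipeline run configuration
#'
#' Bundles the constants of a full run. Defaults follow the framework's
#' standard design: a 13-year training window, five projection years, VIF
#' threshold 10, four spatial folds, inverse-RMSE weighting, 10,000
#' permutations.
#'
#' @param synth a [SynthConfig-class] describing the landscape.
#' @param trainYears training window (default 2002:2014).
#' @param projYears projection years (default 2015:2019); must be disjoint
#'   from and later than the training window.
#' @param vifThreshold VIF cut for predictor pruning (default 10).
#' @param weighting ensemble weighting rule (see [fitEnsemble()]).
#' @param nPerm permutations for the validation null (default 10000).
#' @param coarseFactor aggregation factor from the modelling grid to the
#'   inventory-validation grid (default 5, i.e. a 10x-coarser cell area
#'   ratio of 25; mirrors a 10 km -> "large pixel" coarsening).
#' @param holdoutYears most recent observed years held out for validation
#'   (default 4).
#' @param responses which diversity metrics to model.
#' @return list of class `run_config`.
#' @export
runConfig <- function(synth = synthConfig(), trainYears = 2002:2014,
                      projYears = 2015:2019, vifThreshold = 10,
                      weighting = "inverse_rmse", nPerm = 10000,
                      coarseFactor = 5, holdoutYears = 4,
                      responses = c("richness", "pd")) {
  if (length(intersect(trainYears, projYears)))
    stop("projection years must be disjoint from the training window")
  if (min(projYears) <= max(trainYears))
    stop("projection years must be later than the training window")
  structure(list(synth = synth, trainYears = trainYears,
                 projYears = projYears, vifThreshold = vifThreshold,
                 weighting = weighting, nPerm = nPerm,
                 coarseFactor = coarseFactor, holdoutYears = holdoutYears,
                 responses = responses),
            class = "run_config")
}

## small deterministic fingerprint of a config (polynomial rolling hash)
configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

## bioclim set for one simulated year (single-year monthlies + NDVI median)
.yearBioclim <- function(sim, year) {
  key <- as.character(year)
  nd <- annualNdviMedian(sim$ndvi[[key]], year, year)
  deriveBioclim(sim$climate[[key]], ndvi = nd, period = key)
}

## bioclim climatology over a window (cross-year monthly means; NDVI median
## over all monthly layers in the window)
.windowBioclim <- function(sim, window) {
  mc <- monthlyClimatology(sim$climate, window)
  ndviLayers <- unlist(lapply(as.character(window),
                              function(k) sim$ndvi[[k]]), recursive = FALSE)
  nd <- annualNdviMedian(ndviLayers, rep(1, length(ndviLayers)), 1)
  deriveBioclim(mc, ndvi = nd,
                period = paste(range(window), collapse = "-"))
}

#' Run the full monitoring pipeline on a synthetic landscape
#'
#' Simulates climate, clade and inventories from `config$synth`, then runs
#' every stage of the framework and (optionally) writes the artifact
#' directory: bioclim GeoTIFFs, the retained-variable list, model
#' manifests, yearly projections, trend and mismatch maps, the validation
#' report and a provenance log.
#'
#' @param config a [runConfig()].
#' @param outDir artifact directory; `NULL` skips writing files.
#' @param verbose print stage progress.
#' @return (invisibly) a list with elements `bioclimTrain`,
#'   `selection`, `models`, `projections`, `trends`, `mismatch`,
#'   `validation`, `driftRecovery` (agreement of the modelled richness
#'   trend with the generator's true richness trend over the projection
#'   years), `species`, `records`, and `hash`.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cfg <- config$synth
  hash <- configHash(config)
  log <- list()
  stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed (config ", hash, "): ",
           conditionMessage(e), call. = FALSE))
    log[[length(log) + 1]] <<- list(stage = name, config = hash,
                                    seconds = round(as.numeric(
                                      Sys.time() - t0, units = "secs"), 2))
    out
  }

  sim <- stage("simulate-climate", simulateClimate(cfg))
  bioclimTrain <- stage("bioclim-train",
                        .windowBioclim(sim, config$trainYears))
  bioclimYears <- stage("bioclim-projection-years", {
    out <- lapply(config$projYears, function(y) .yearBioclim(sim, y))
    stats::setNames(out, config$projYears)
  })

  species <- stage("simulate-species", {
    tree <- simulateTree(cfg@nSpecies, seed = cfg@seed + 11L)
    simulateSpeciesRanges(tree, climateAxis(
      monthlyClimatology(sim$climate, config$trainYears)), cfg)
  })
  richness <- richnessFromCommunity(species$community)
  pd <- faithPD(species$community, species$tree)

  sel <- stage("vif-selection", {
    pt <- predictorTable(bioclimTrain)
    keep <- suppressMessages(informativeVars(pt$matrix))
    vifStepwise(pt$matrix[, keep, drop = FALSE],
                threshold = config$vifThreshold)
  })
  pt <- predictorTable(bioclimTrain, vars = sel$retained)
  folds <- blocksForCells(pt$grid, pt$cells)

  responses <- list(richness = richness, pd = pd)[config$responses]
  models <- list(); projections <- list(); trends <- list()
  for (resp in names(responses)) {
    y <- cellValues(responses[[resp]])[pt$cells]
    models[[resp]] <- stage(paste0("fit-ensemble-", resp),
      fitEnsemble(pt$matrix, y, folds, response = resp,
                  weighting = config$weighting, seed = cfg@seed + 23L))
    projections[[resp]] <- stage(paste0("project-", resp),
      projectYearly(models[[resp]], bioclimYears))
    trends[[resp]] <- stage(paste0("trend-", resp),
      trendSlope(projections[[resp]], config$projYears))
  }

  mismatch <- NULL
  if (all(c("richness", "pd") %in% names(models))) {
    mismatch <- stage("mismatch", lapply(seq_along(config$projYears),
      function(i) pdSrResiduals(projections$pd@layers[[i]],
                                projections$richness@layers[[i]],
                                year = config$projYears[i])))
    names(mismatch) <- config$projYears
  }

  ## ground truth: the generator's own per-year communities
  allYears <- sort(unique(c(config$trainYears, config$projYears)))
  trueComms <- stage("true-communities", {
    out <- lapply(allYears, function(y)
      communityForClimate(species,
                          climateAxis(sim$climate[[as.character(y)]])))
    stats::setNames(out, allYears)
  })
  ## the imposed drift: richness trajectory under the noise-free climate
  ## (same seed, so the deterministic fields are identical); "drifting"
  ## pixels are those whose imposed richness slope is nonzero
  driftRecovery <- NULL
  if ("richness" %in% names(trends)) {
    driftRecovery <- stage("drift-recovery", {
      cfgDet <- cfg; cfgDet@noiseSd <- 0
      simDet <- simulateClimate(cfgDet)
      detStack <- rasterStack(
        lapply(as.character(config$projYears), function(k)
          richnessFromCommunity(
            communityForClimate(species,
                                climateAxis(simDet$climate[[k]])))),
        labels = config$projYears)
      trueTrend <- trendSlope(detStack, config$projYears)
      directionAgreement(trends$richness, trueTrend)
    })
  }

  records <- stage("simulate-inventory",
    simulateInventory(trueComms, detectionProb = cfg@detectionProb,
                      effort = cfg@effort, seed = cfg@seed + 31L))

  validation <- stage("validate",
    validateInventory(records, sim, config, seed = cfg@seed + 41L))

  result <- list(bioclimTrain = bioclimTrain, bioclimYears = bioclimYears,
                 selection = sel, folds = folds, models = models,
                 projections = projections, trends = trends,
                 mismatch = mismatch, validation = validation,
                 driftRecovery = driftRecovery, species = species,
                 records = records, hash = hash, log = log)
  if (!is.null(outDir)) writeArtifacts(result, config, outDir)
  invisible(result)
}

#' Inventory-based direction-of-change validation
#'
#' The ground-truthing stage: grids the occurrence records per year on a
#' coarse validation grid, holds out the last `holdoutYears` observed
#' years, trains a fresh richness ensemble on the pooled training
#' pixel-years (observed richness vs that year's coarse bioclim), projects
#' it onto the holdout years, reduces both the projections and the held-out
#' observations to per-pixel trends, and scores the direction agreement
#' against the permutation null.
#'
#' @param records occurrence data.frame (`species`, `lon`, `lat`, `year`).
#' @param sim a simulated climate series ([simulateClimate()]).
#' @param config a [runConfig()].
#' @param seed RNG seed for the permutation null.
#' @return A [ValidationReport-class] with attribute `"model"` (the
#'   validation-stage [EnsembleModel-class]) and `"predictedTrend"` /
#'   `"observedTrend"`.
#' @export
validateInventory <- function(records, sim, config, seed = 1L) {
  g <- config$synth@grid
  cg <- gridSpec(g@nrow %/% config$coarseFactor,
                 g@ncol %/% config$coarseFactor,
                 xmin = g@xmin, ymin = g@ymax -
                   (g@nrow %/% config$coarseFactor) *
                   g@res * config$coarseFactor,
                 res = g@res * config$coarseFactor, crs = g@crs)

  sp <- temporalSplit(records, holdoutYears = config$holdoutYears)
  obsRichness <- function(recs) {
    yrs <- sort(unique(recs$year))
    out <- lapply(yrs, function(y) {
      cm <- gridOccurrences(recs[recs$year == y, , drop = FALSE], cg)
      r <- richnessFromCommunity(cm)
      v <- cellValues(r)
      v[v == 0] <- NA_real_    # unsampled pixels are indistinguishable
      layerFromVec(v, cg)
    })
    stats::setNames(out, yrs)
  }
  trainMaps <- obsRichness(sp$train)
  testMaps <- obsRichness(sp$test)

  coarseBioclim <- function(year) {
    bs <- .yearBioclim(sim, year)
    agg <- alignStack(bs, cg, method = "mean")
    new("BioclimSet", grid = cg, layers = agg@layers, labels = agg@labels,
        period = as.character(year))
  }

  ## pooled pixel-year training rows
  trainYears <- as.numeric(names(trainMaps))
  Xrows <- list(); yrows <- list(); cellRows <- list()
  for (k in seq_along(trainYears)) {
    bs <- coarseBioclim(trainYears[k])
    ptk <- predictorTable(bs)
    obs <- cellValues(trainMaps[[k]])[ptk$cells]
    okk <- !is.na(obs)
    Xrows[[k]] <- ptk$matrix[okk, , drop = FALSE]
    yrows[[k]] <- obs[okk]
    cellRows[[k]] <- ptk$cells[okk]
  }
  X <- do.call(rbind, Xrows)
  y <- unlist(yrows)
  cells <- unlist(cellRows)
  if (length(y) < 16)
    stop("too few sampled pixel-years to train the validation model")

  cc <- cellCenters(cg)
  cellFold <- assignBlocks(cc$lon[unique(cells)], cc$lat[unique(cells)])
  foldOfCell <- stats::setNames(cellFold@fold, unique(cells))
  folds <- new("FoldAssignment", fold = unname(foldOfCell[as.character(cells)]),
               lon = cc$lon[cells], lat = cc$lat[cells],
               splitLat = cellFold@splitLat, splitLons = cellFold@splitLons)

  model <- fitEnsemble(X, y, folds, response = "richness",
                       weighting = config$weighting, seed = seed)

  testYears <- as.numeric(names(testMaps))
  predStack <- projectYearly(model,
                             stats::setNames(lapply(testYears, coarseBioclim),
                                             testYears))
  predictedTrend <- trendSlope(predStack, testYears)
  observed <- observedTrend(testMaps, minYears = 2)

  report <- validateDirections(predictedTrend, observed,
                               nPerm = config$nPerm, seed = seed)
  attr(report, "model") <- model
  attr(report, "predictedTrend") <- predictedTrend
  attr(report, "observedTrend") <- observed
  report
}

## write the artifact directory: GeoTIFFs, manifests, provenance log
writeArtifacts <- function(result, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(layer, name) writeRaster(layer, file.path(outDir, name))

  bdir <- file.path(outDir, "bioclim"); dir.create(bdir, showWarnings = FALSE)
  for (lb in result$bioclimTrain@labels)
    writeRaster(getLayer(result$bioclimTrain, lb),
                file.path(bdir, paste0(lb, ".tif")))
  writeLines(result$selection$retained, file.path(outDir, "retained.txt"))

  for (resp in names(result$models)) {
    m <- result$models[[resp]]
    manifest <- list(response = resp, members = names(m@members),
                     cv_rmse = as.list(m@cvRmse),
                     weights = as.list(m@weights),
                     retained_vars = m@retainedVars,
                     fit_r2 = m@fitR2, train_r2 = m@trainR2,
                     dropped = m@dropped, config = result$hash)
    jsonlite::write_json(manifest,
                         file.path(outDir, paste0("model_", resp, ".json")),
                         auto_unbox = TRUE, digits = NA)
    st <- result$projections[[resp]]
    for (i in seq_along(st@layers))
      wr(st@layers[[i]], sprintf("proj_%s_%s.tif", resp, st@labels[i]))
    wr(result$trends[[resp]]@slope, sprintf("trend_%s_slope.tif", resp))
    wr(result$trends[[resp]]@direction,
       sprintf("trend_%s_direction.tif", resp))
  }
  if (!is.null(result$mismatch))
    for (k in names(result$mismatch))
      wr(result$mismatch[[k]]@residuals, sprintf("mismatch_resid_%s.tif", k))

  v <- result$validation
  jsonlite::write_json(
    list(n_pixels_compared = v@nCompared, n_correct = v@nCorrect,
         fraction_correct = v@fractionCorrect, p_value = v@pValue,
         n_permutations = v@nPermutations, config = result$hash),
    file.path(outDir, "validation_report.json"),
    auto_unbox = TRUE, digits = NA)
  wr(v@agreement, "validation_agreement.tif")

  utils::write.csv(result$records, file.path(outDir, "occurrences.csv"),
                   row.names = FALSE)
  con <- file(file.path(outDir, "provenance.jsonl"), "w")
  for (entry in result$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  close(con)
  invisible(outDir)
}
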