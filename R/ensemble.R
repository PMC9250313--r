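## Spatially cross-validated ensemble of four regression families
## (random forest, single-hidden-layer neural network, radial-kernel SVM,
## Gaussian GLM), each tuned by pooled out-of-fold RMSE over the four
## spatial blocks, then refit on all data and combined with weights
## proportional to inverse CV-RMSE.

#' Learner specification
#'
#' @param family one of `"random_forest"`, `"neural_net"`, `"svm_radial"`,
#'   `"glm"`.
#' @param grid data.frame of hyperparameter candidates (one row per grid
#'   point); `NULL` uses the family default ([defaultTuningGrid()]); the GLM
#'   grid is empty.
#' @param seed integer seed for the family's stochastic fit.
#' @return list of class `learner_spec`.
#' @export
learnerSpec <- function(family = c("random_forest", "neural_net",
                                   "svm_radial", "glm"),
                        grid = NULL, seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Default tuning grids
#'
#' Random forest: 500 trees, variables-per-split in `{ceil(p/3), ceil(sqrt(p)),
#' p}`. Neural net: hidden units in `{3, 5, 8}` x weight decay in
#' `{0.01, 0.1}`. Radial SVM: cost in `{1, 10}`, kernel width from the
#' median-distance heuristic. GLM: no tuning.
#'
#' @param family learner family.
#' @param p number of predictors.
#' @return data.frame of candidates (0 rows for `"glm"`).
#' @export
defaultTuningGrid <- function(family, p) {
  switch(family,
    random_forest = data.frame(mtry = unique(pmin(p, c(ceiling(p / 3),
                                                       ceiling(sqrt(p)), p)))),
    neural_net = expand.grid(size = c(3L, 5L, 8L), decay = c(0.01, 0.1)),
    svm_radial = data.frame(cost = c(1, 10)),
    glm = data.frame()
  )
}

#' The paper-default four learner specs
#'
#' @param seed master seed; each member gets a derived seed.
#' @return named list of four [learnerSpec()] objects.
#' @export
defaultLearnerSpecs <- function(seed = 1L) {
  fams <- c("random_forest", "neural_net", "svm_radial", "glm")
  specs <- lapply(seq_along(fams), function(i)
    learnerSpec(fams[i], seed = as.integer(seed) + i * 101L))
  stats::setNames(specs, fams)
}

## median-distance heuristic for the RBF kernel width, on standardized X
.medianGamma <- function(xs, seed) {
  n <- nrow(xs)
  idx <- if (n > 500) {
    set.seed(seed); sample.int(n, 500)
  } else seq_len(n)
  d <- stats::dist(xs[idx, , drop = FALSE])
  sigma <- stats::median(d[d > 0])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  1 / (2 * sigma^2)
}

## fit one member; returns list(predict = function(Xnew), ...)
.fitMember <- function(family, params, X, y, seed) {
  X <- as.matrix(X)
  if (family == "random_forest") {
    dat <- data.frame(X, .y = y, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = 500, mtry = params$mtry, seed = seed, num.threads = 1
    )
    list(family = family, params = params,
         predict = function(Xnew)
           stats::predict(fit, data.frame(as.matrix(Xnew),
                                          check.names = FALSE),
                          num.threads = 1)$predictions)
  } else if (family == "neural_net") {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    yc <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
    xs <- scale(X, ctr, scl)
    set.seed(seed)
    fit <- nnet::nnet(xs, (y - yc) / ys, size = params$size,
                      decay = params$decay, linout = TRUE, maxit = 300,
                      trace = FALSE)
    list(family = family, params = params,
         predict = function(Xnew) {
           xn <- scale(as.matrix(Xnew), ctr, scl)
           as.vector(stats::predict(fit, xn)) * ys + yc
         })
  } else if (family == "svm_radial") {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    xs <- scale(X, ctr, scl)
    gamma <- .medianGamma(xs, seed)
    fit <- e1071::svm(xs, y, kernel = "radial", cost = params$cost,
                      gamma = gamma, scale = FALSE)
    list(family = family, params = c(params, gamma = gamma),
         predict = function(Xnew) {
           xn <- scale(as.matrix(Xnew), ctr, scl)
           as.vector(stats::predict(fit, xn))
         })
  } else if (family == "glm") {
    dat <- data.frame(X, .y = y, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = dat)
    list(family = family, params = params,
         predict = function(Xnew)
           as.vector(stats::predict(fit, data.frame(as.matrix(Xnew),
                                                    check.names = FALSE))))
  } else stop("unknown learner family: ", family)
}

#' Tune one learner by spatial cross-validation
#'
#' For every hyperparameter candidate, fits on three spatial blocks,
#' predicts the held-out block, pools the out-of-fold predictions over all
#' four blocks and computes RMSE; the candidate minimizing pooled RMSE wins
#' (ties: first grid row).
#'
#' @param spec a [learnerSpec()].
#' @param X predictor matrix (pixels x variables, named columns).
#' @param y response vector aligned with `X` rows.
#' @param folds a [FoldAssignment-class] aligned with `X` rows.
#' @return list with `params` (best row), `cvRmse`, and `oof` (pooled
#'   out-of-fold predictions at the best candidate, in training order).
#' @export
tuneLearner <- function(spec, X, y, folds) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(folds@fold) == length(y))
  fsz <- table(folds@fold)
  if (any(fsz < 2))
    stop("a spatial fold has fewer than 2 pixels; use a larger region")
  grid <- spec$grid
  if (is.null(grid)) grid <- defaultTuningGrid(spec$family, ncol(X))
  if (nrow(grid) == 0) grid <- data.frame(.dummy = 1)

  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    oof <- rep(NA_real_, length(y))
    for (k in sort(unique(folds@fold))) {
      hold <- folds@fold == k
      m <- .fitMember(spec$family, params, X[!hold, , drop = FALSE],
                      y[!hold], seed = spec$seed + k)
      oof[hold] <- m$predict(X[hold, , drop = FALSE])
    }
    rmse <- sqrt(mean((oof - y)^2))
    if (is.null(best) || rmse < best$cvRmse)
      best <- list(params = params, cvRmse = rmse, oof = oof)
  }
  best
}

#' Fit the RMSE-weighted four-learner ensemble
#'
#' Tunes each member by spatial CV ([tuneLearner()]), refits each on all
#' data with its tuned settings, and weights members by normalized inverse
#' CV-RMSE: `w_i = (1/rmse_i) / sum_j (1/rmse_j)`. A member that fails to
#' fit is dropped with a warning and the weights renormalized. `fitR2` is
#' the squared Pearson correlation between the pooled out-of-fold ensemble
#' predictions and the response (the transferability-honest fit measure);
#' `trainR2` is the same on full-data predictions.
#'
#' @param X predictor matrix (pixels x variables, named columns).
#' @param y response vector.
#' @param folds a [FoldAssignment-class] aligned with `X` rows.
#' @param specs named list of [learnerSpec()]; default the four families.
#' @param response label stored on the model (`"richness"`, `"pd"`, ...).
#' @param weighting `"inverse_rmse"` (the primary rule) or `"nnls"`
#'   (nonnegative least-squares stacking of the out-of-fold predictions).
#' @param seed master seed used when `specs` is NULL-seeded.
#' @return An [EnsembleModel-class].
#' @export
fitEnsemble <- function(X, y, folds, specs = NULL, response = "richness",
                        weighting = c("inverse_rmse", "nnls"), seed = 1L) {
  weighting <- match.arg(weighting)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  if (is.null(specs)) specs <- defaultLearnerSpecs(seed)

  tuned <- list(); members <- list(); dropped <- character()
  for (nm in names(specs)) {
    t <- tryCatch(tuneLearner(specs[[nm]], X, y, folds),
                  error = function(e) e)
    if (inherits(t, "error")) {
      warning("member '", nm, "' failed to fit and was dropped: ",
              conditionMessage(t))
      dropped <- c(dropped, nm)
      next
    }
    full <- tryCatch(.fitMember(specs[[nm]]$family, t$params, X, y,
                                seed = specs[[nm]]$seed),
                     error = function(e) e)
    if (inherits(full, "error")) {
      warning("member '", nm, "' failed to fit and was dropped: ",
              conditionMessage(full))
      dropped <- c(dropped, nm)
      next
    }
    tuned[[nm]] <- t
    members[[nm]] <- full
  }
  if (!length(members)) stop("all ensemble members failed to fit")

  cvRmse <- vapply(tuned, `[[`, numeric(1), "cvRmse")
  weights <- inverseRmseWeights(cvRmse)
  if (weighting == "nnls") {
    oofMat <- vapply(tuned, `[[`, numeric(length(y)), "oof")
    weights <- .nnlsWeights(oofMat, y)
  }

  oofMat <- vapply(tuned, `[[`, numeric(length(y)), "oof")
  oofEns <- as.vector(oofMat %*% weights)
  trainPred <- as.vector(
    vapply(members, function(m) m$predict(X), numeric(length(y))) %*% weights)
  r2 <- function(p) {
    if (stats::sd(p) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(p, y)^2
  }
  new("EnsembleModel", members = members, cvRmse = cvRmse,
      weights = weights, retainedVars = colnames(X),
      response = response, fitR2 = r2(oofEns), trainR2 = r2(trainPred),
      oofPred = oofEns, dropped = dropped, seed = as.integer(seed))
}

#' Inverse-RMSE ensemble weights
#'
#' `w_i = (1/rmse_i) / sum_j (1/rmse_j)`. A member with zero RMSE takes all
#' the weight (shared equally if several are exactly zero); a member with
#' infinite RMSE gets weight 0.
#'
#' @param rmse named numeric vector of member RMSEs.
#' @return named weights, nonnegative, summing to 1.
#' @examples
#' inverseRmseWeights(c(a = 1, b = 2, c = 4, d = 8))  # (8,4,2,1)/15
#' @export
inverseRmseWeights <- function(rmse) {
  if (any(rmse == 0)) {
    w <- as.numeric(rmse == 0)
  } else {
    w <- 1 / rmse
    w[!is.finite(w)] <- 0
    if (sum(w) == 0) w <- rep(1, length(rmse))
  }
  stats::setNames(w / sum(w), names(rmse))
}

## nonnegative least squares of y on member OOF predictions, normalized
.nnlsWeights <- function(oofMat, y) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("weighting = 'nnls' needs the glmnet package")
  fit <- glmnet::glmnet(oofMat, y, lambda = 0, lower.limits = 0,
                        intercept = FALSE, standardize = FALSE)
  w <- as.numeric(fit$beta)
  if (sum(w) <= 0) w <- rep(1, ncol(oofMat))
  stats::setNames(w / sum(w), colnames(oofMat))
}

#' Predict from an ensemble
#'
#' The ensemble prediction is the weighted sum of the member predictions.
#'
#' @param model an [EnsembleModel-class].
#' @param Xnew predictor matrix containing all `model@retainedVars` columns.
#' @return numeric predictions, one per row of `Xnew`.
#' @export
predictEnsemble <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  miss <- setdiff(model@retainedVars, colnames(Xnew))
  if (length(miss))
    stop("missing predictor columns: ", paste(miss, collapse = ", "))
  Xnew <- Xnew[, model@retainedVars, drop = FALSE]
  preds <- vapply(model@members, function(m) m$predict(Xnew),
                  numeric(nrow(Xnew)))
  if (nrow(Xnew) == 1) preds <- matrix(preds, nrow = 1)
  as.vector(preds %*% model@weights)
}

#' @describeIn predictEnsemble S4 `predict` method.
#' @param object an [EnsembleModel-class].
#' @param newdata predictor matrix.
#' @export
setMethod("predict", "EnsembleModel",
          function(object, newdata) predictEnsemble(object, newdata))
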