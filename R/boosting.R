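#' Construct a boosting configuration
#'
#' @param preset `"moderate"` (learning rate 0.3, depth 6, early stopping
#'   after 3 non-improving rounds), `"underfit"` (rate 0.1, depth 3, early
#'   stopping 3) or `"overfit"` (rate 0.3, depth 6, exactly 50 rounds, no
#'   early stopping). Individual fields can be overridden.
#' @param learningRate,maxDepth,earlyStoppingRounds,maxRounds,basePrediction
#'   optional overrides of the preset values; `basePrediction = NA` means
#'   "use the training-phenotype mean" (many boosting libraries default to
#'   0.5, which distorts SHAP base values for regression).
#' @return a [BoostConfig-class].
#' @examples
#' boostConfig("overfit")   # 50 rounds, no early stopping
#' @export
boostConfig <- function(preset = c("moderate", "underfit", "overfit"),
                        learningRate = NULL, maxDepth = NULL,
                        earlyStoppingRounds = NULL, maxRounds = NULL,
                        basePrediction = NA_real_) {
  preset <- match.arg(preset)
  def <- switch(preset,
    moderate = list(lr = 0.3, depth = 6L, esr = 3L, rounds = 1000L),
    underfit = list(lr = 0.1, depth = 3L, esr = 3L, rounds = 1000L),
    overfit  = list(lr = 0.3, depth = 6L, esr = NA_integer_, rounds = 50L))
  new("BoostConfig", preset = preset,
      learningRate = if (is.null(learningRate)) def$lr else learningRate,
      maxDepth = as.integer(if (is.null(maxDepth)) def$depth else maxDepth),
      earlyStoppingRounds = as.integer(
        if (is.null(earlyStoppingRounds)) def$esr else earlyStoppingRounds),
      maxRounds = as.integer(if (is.null(maxRounds)) def$rounds
                             else maxRounds),
      basePrediction = basePrediction)
}

#' Fit a gradient-boosted tree ensemble
#'
#' Squared-error boosting via xgboost with the remaining (validation) set
#' driving early stopping: training stops once the validation RMSE has not
#' improved for `earlyStoppingRounds` consecutive rounds, and the ensemble
#' is truncated to the best validation iteration. Regularisation is the
#' library default (L2 penalty 1, gamma 0, no row/column subsampling),
#' pinned explicitly so the preset stays reproducible.
#'
#' @param X,y training features (numeric matrix) and response.
#' @param validX,validY held-out set for early stopping; required unless the
#'   configuration disables early stopping.
#' @param config a [BoostConfig-class].
#' @param seed optional integer seed for the fit.
#' @return a [TreeEnsemble-class] with the fitted booster attached.
#' @examples
#' X <- matrix(rep(c(-1, 1), each = 20), ncol = 1)
#' fit <- fitEnsemble(X, X[, 1], config = boostConfig("overfit"),
#'                    seed = 1)
#' nTrees(fit)   # 50
#' @export
fitEnsemble <- function(X, y, validX = NULL, validY = NULL,
                        config = boostConfig(), seed = NULL) {
  stopIf(nrow(X) == 0L, "empty training set")
  stopIf(length(y) != nrow(X), "y must match the rows of X")
  stopIf(!all(is.finite(y)), "non-finite phenotype values")
  esr <- config@earlyStoppingRounds
  stopIf(!is.na(esr) && (is.null(validX) || nrow(validX) == 0L),
         "early stopping requires a non-empty validation set")
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  base <- if (is.na(config@basePrediction)) mean(y) else config@basePrediction
  params <- list(objective = "reg:squarederror",
                 eta = config@learningRate, max_depth = config@maxDepth,
                 lambda = 1, gamma = 0, subsample = 1,
                 colsample_bytree = 1, base_score = base,
                 eval_metric = "rmse", nthread = 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  withSeed(seed, {
    if (!is.na(esr)) {
      if (is.null(colnames(validX))) colnames(validX) <- colnames(X)
      dvalid <- xgboost::xgb.DMatrix(validX, label = validY, nthread = 1)
      bst <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config@maxRounds,
                                evals = list(valid = dvalid),
                                early_stopping_rounds = esr, verbose = 0)
    } else {
      bst <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config@maxRounds, verbose = 0)
    }
    extractStructure(bst, featureNames = colnames(X))
  })
}

# number of trees default predict() uses: the best early-stopping
# iteration (a 0-based index, hence + 1) or all boosted rounds
usedRounds <- function(booster) {
  best <- xgboost::xgb.attributes(booster)$best_iteration
  if (is.null(best)) xgboost::xgb.get.num.boosted.rounds(booster)
  else as.integer(best) + 1L
}

#' Extract the tree structure of a fitted booster
#'
#' Lossless structural dump of a fitted `xgb.Booster` into a
#' [TreeEnsemble-class]: split features, thresholds, children, leaf weights
#' and covers per node, truncated to the trees that the booster itself uses
#' for prediction (the best early-stopping iteration, if any).
#'
#' @param booster a fitted `xgb.Booster`.
#' @param featureNames character vector naming the training columns.
#' @param basePrediction override for the stored intercept; defaults to the
#'   `base_score` the booster was trained with.
#' @return a [TreeEnsemble-class].
#' @export
extractStructure <- function(booster, featureNames = NULL,
                             basePrediction = NULL) {
  stopIf(!inherits(booster, "xgb.Booster"), "booster must be an xgb.Booster")
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(booster))
  if (is.null(featureNames)) {
    featureNames <- setdiff(unique(dt$Feature), "Leaf")
  }
  if (is.null(basePrediction)) {
    cfg <- xgboost::xgb.config(booster)
    if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
    basePrediction <- as.numeric(cfg$learner$learner_model_param$base_score)
  }
  keep <- seq_len(usedRounds(booster)) - 1L
  trees <- lapply(keep, function(k) {
    tt <- dt[dt$Tree == k, , drop = FALSE]
    tt <- tt[order(tt$Node), , drop = FALSE]
    id2row <- seq_len(nrow(tt))
    names(id2row) <- tt$ID
    leaf <- tt$Feature == "Leaf"
    feat <- match(tt$Feature, featureNames)
    data.frame(
      feature = ifelse(leaf, NA_integer_, feat),
      split = ifelse(leaf, NA_real_, tt$Split),
      yes = ifelse(leaf, NA_integer_, unname(id2row[tt$Yes])),
      no = ifelse(leaf, NA_integer_, unname(id2row[tt$No])),
      value = ifelse(leaf, tt$Gain, NA_real_),
      cover = tt$Cover)
  })
  new("TreeEnsemble", trees = trees, basePrediction = basePrediction,
      nFeatures = length(featureNames), featureNames = featureNames,
      booster = booster)
}

# route rows of X through one tree table; returns leaf values
routeTree <- function(tr, X) {
  idx <- rep(1L, nrow(X))
  repeat {
    internal <- !is.na(tr$feature[idx])
    if (!any(internal)) break
    i <- which(internal)
    f <- tr$feature[idx[i]]
    goYes <- X[cbind(i, f)] < tr$split[idx[i]]
    idx[i] <- ifelse(goYes, tr$yes[idx[i]], tr$no[idx[i]])
  }
  tr$value[idx]
}

#' Predict from a tree ensemble
#'
#' Routes every row through every tree (strictly-less-than goes to the
#' `yes` child) and sums the reached leaf weights plus the base prediction.
#'
#' @param object a [TreeEnsemble-class].
#' @param newdata numeric matrix with `nFeatures` columns.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "TreeEnsemble", function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  stopIf(ncol(newdata) != object@nFeatures,
         "newdata has %d columns, ensemble expects %d", ncol(newdata),
         object@nFeatures)
  out <- rep(object@basePrediction, nrow(newdata))
  for (tr in object@trees) out <- out + routeTree(tr, newdata)
  out
})
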