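#' Balanced class weights from label counts
#'
#' Per-class sample weights proportional to inverse class frequency,
#' normalized so the mean sample weight is 1 (the sum of weights over all
#' samples equals the sample count).  Only the ratio matters to the tree
#' loss; the normalization fixes the scale.
#'
#' @param nPos,nNeg positive class counts (each at least 1).
#' @return list with `weight_positive`, `weight_negative`.
#' @export
balancedWeights <- function(nPos, nNeg) {
  if (nPos < 1 || nNeg < 1)
    stop("both classes must be present to compute balanced weights")
  n <- nPos + nNeg
  list(weight_positive = n / (2 * nPos), weight_negative = n / (2 * nNeg))
}

#' Configuration for the stacking classifier
#'
#' Hyperparameters are constrained to the tuning ranges used throughout the
#' package: `nEstimators` in \[50, 2000\], `depth` in \[2, 10\],
#' `learningRate` in \[.05, .5\].
#'
#' @param nFolds folds for out-of-fold meta-training (default 5, minimum 2).
#' @param seed integer seed controlling fold assignment.
#' @param threshold probability cutoff for hard calls (default 0.5; calls
#'   are positive when probability is strictly greater).
#' @param equalParams,balancedParams per-base named lists with
#'   `nEstimators`, `depth`, `learningRate`.
#' @return list of class `"StackConfig"`.
#' @export
stackConfig <- function(nFolds = 5L, seed = 1L, threshold = 0.5,
                        equalParams = list(nEstimators = 300L, depth = 3L,
                                           learningRate = 0.05),
                        balancedParams = equalParams) {
  check_params <- function(p) {
    stopifnot(p$nEstimators >= 50, p$nEstimators <= 2000,
              p$depth >= 2, p$depth <= 10,
              p$learningRate >= 0.05, p$learningRate <= 0.5)
    p
  }
  stopifnot(nFolds >= 2L, threshold >= 0, threshold <= 1)
  structure(list(nFolds = as.integer(nFolds), seed = as.integer(seed),
                 threshold = threshold,
                 equalParams = check_params(equalParams),
                 balancedParams = check_params(balancedParams)),
            class = "StackConfig")
}

# Fit one gradient-boosted base classifier with the given per-class weights.
#' @keywords internal
fit_base <- function(features, labels, params, classWeights, seed) {
  w <- ifelse(labels == 1, classWeights$weight_positive,
              classWeights$weight_negative)
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, weight = w,
                                 nthread = 1)
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = as.integer(round(params$depth)),
                  eta = params$learningRate,
                  nthread = 1),
    data = dtrain,
    nrounds = as.integer(round(params$nEstimators)),
    verbose = 0))
}

#' @keywords internal
predict_base <- function(booster, features) {
  predict(booster, xgboost::xgb.DMatrix(features, nthread = 1))
}

# Stratified fold assignment: shuffle within class, then deal round-robin.
#' @keywords internal
stratified_folds <- function(labels, nFolds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

#' Fit the two-base stacking classifier
#'
#' Trains two gradient-boosted tree base classifiers — one with equal class
#' weights, one with balanced class weights — and a logistic meta-learner on
#' their out-of-fold positive-class probabilities from a stratified
#' `nFolds`-fold cross-validated prediction pass, so the meta-learner never
#' sees probabilities from a base trained on the same rows.  After the
#' meta-pass both bases are refit on the full training set for inference.
#' The meta-learner itself uses balanced class weights.
#'
#' @param features numeric matrix (rows = sites, columns = feature values),
#'   e.g. from [assembleFeatures()].
#' @param labels binary vector (1 = positive) of length `nrow(features)`.
#' @param cfg a [stackConfig()].
#' @return [StackModel-class].
#' @export
fitStack <- function(features, labels, cfg = stackConfig()) {
  stopifnot(inherits(cfg, "StackConfig"), is.matrix(features),
            length(labels) == nrow(features))
  labels <- as.integer(labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to fit the stack")
  if (min(nPos, nNeg) < cfg$nFolds)
    stop("need at least nFolds samples in each class")
  eq_w <- list(weight_positive = 1, weight_negative = 1)
  bal_w <- balancedWeights(nPos, nNeg)

  fold <- stratified_folds(labels, cfg$nFolds, cfg$seed)
  oof <- matrix(NA_real_, length(labels), 2,
                dimnames = list(NULL, c("pEqual", "pBalanced")))
  for (k in seq_len(cfg$nFolds)) {
    tr <- fold != k
    b1 <- fit_base(features[tr, , drop = FALSE], labels[tr],
                   cfg$equalParams, eq_w, cfg$seed + k)
    b2 <- fit_base(features[tr, , drop = FALSE], labels[tr],
                   cfg$balancedParams, bal_w, cfg$seed + k)
    oof[!tr, "pEqual"] <- predict_base(b1, features[!tr, , drop = FALSE])
    oof[!tr, "pBalanced"] <- predict_base(b2, features[!tr, , drop = FALSE])
  }

  # balanced-weight logistic meta-learner on exactly (pEqual, pBalanced);
  # quasibinomial IRLS gives the same point estimates as binomial with
  # non-integer prior weights
  mw <- ifelse(labels == 1, bal_w$weight_positive, bal_w$weight_negative)
  meta_df <- data.frame(y = labels, oof)
  meta <- stats::glm(y ~ pEqual + pBalanced, data = meta_df,
                     family = stats::quasibinomial(), weights = mw)
  coefs <- stats::coef(meta)
  coefs[is.na(coefs)] <- 0

  base_equal <- fit_base(features, labels, cfg$equalParams, eq_w, cfg$seed)
  base_bal <- fit_base(features, labels, cfg$balancedParams, bal_w, cfg$seed)

  new("StackModel", baseEqual = base_equal, baseBalanced = base_bal,
      metaCoef = unname(coefs), config = unclass(cfg),
      featureDim = ncol(features), classCounts = c(nPos, nNeg))
}

#' Predict positive-class probabilities from a fitted stack
#'
#' @param model [StackModel-class].
#' @param features numeric matrix with the training feature width.
#' @param type `"stack"` (default) for the meta-learner output, or
#'   `"equal"` / `"balanced"` for a standalone base classifier.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predictProba <- function(model, features, type = c("stack", "equal",
                                                   "balanced")) {
  type <- match.arg(type)
  stopifnot(is(model, "StackModel"), is.matrix(features))
  if (ncol(features) != model@featureDim)
    stop("feature width mismatch: model expects ", model@featureDim,
         " columns, got ", ncol(features))
  p1 <- predict_base(model@baseEqual, features)
  if (type == "equal") return(p1)
  p2 <- predict_base(model@baseBalanced, features)
  if (type == "balanced") return(p2)
  stats::plogis(model@metaCoef[1] + model@metaCoef[2] * p1 +
                model@metaCoef[3] * p2)
}

#' Hard calls from a fitted stack
#'
#' @param model [StackModel-class].
#' @param features feature matrix.
#' @param threshold cutoff; defaults to the model's configured threshold.
#'   Calls are positive when probability is strictly greater.
#' @return integer vector of 0/1 calls.
#' @export
predictLabel <- function(model, features, threshold = NULL) {
  if (is.null(threshold)) threshold <- model@config$threshold
  as.integer(predictProba(model, features) > threshold)
}

#' Configuration for hyperparameter search
#'
#' @param iterations number of evaluated parameter points (default 100).
#' @param seed RNG seed for the search.
#' @param bounds named list of length-2 ranges for `nEstimators`, `depth`,
#'   `learningRate`; defaults to the full supported ranges.
#' @param method `"random"` (uniform random search; default).  The search
#'   strategy sits behind this interface so alternative optimizers can be
#'   plugged in.
#' @return list of class `"TuneConfig"`.
#' @export
tuneConfig <- function(iterations = 100L, seed = 1L,
                       bounds = list(nEstimators = c(50, 2000),
                                     depth = c(2, 10),
                                     learningRate = c(0.05, 0.5)),
                       method = "random") {
  stopifnot(iterations >= 1L,
            bounds$nEstimators[1] >= 50, bounds$nEstimators[2] <= 2000,
            bounds$depth[1] >= 2, bounds$depth[2] <= 10,
            bounds$learningRate[1] >= 0.05, bounds$learningRate[2] <= 0.5)
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed), bounds = bounds, method = method),
            class = "TuneConfig")
}

#' Tune one base classifier on a validation set
#'
#' Searches the three-dimensional hyperparameter space (`nEstimators`,
#' `depth`, `learningRate`) for the parameters maximizing validation F1 at
#' threshold 0.5, for a single base classifier with the given class-weight
#' mode.  `nEstimators` and `depth` are rounded to the nearest integer.
#' The full search trace (one row per evaluation) is attached as the
#' `"trace"` attribute.
#'
#' @param trainFeatures,trainLabels training data.
#' @param valFeatures,valLabels disjoint validation data.
#' @param weights `"equal"` or `"balanced"` class weighting for the base.
#' @param tcfg a [tuneConfig()].
#' @return named list `nEstimators`, `depth`, `learningRate` (best point),
#'   with attributes `objective` (best validation F1) and `trace`.
#' @export
tuneBase <- function(trainFeatures, trainLabels, valFeatures, valLabels,
                     weights = c("equal", "balanced"), tcfg = tuneConfig()) {
  weights <- match.arg(weights)
  stopifnot(inherits(tcfg, "TuneConfig"))
  nPos <- sum(trainLabels == 1); nNeg <- sum(trainLabels == 0)
  cw <- if (weights == "balanced") balancedWeights(nPos, nNeg)
        else list(weight_positive = 1, weight_negative = 1)
  b <- tcfg$bounds
  pts <- with_seed(tcfg$seed, data.frame(
    nEstimators = round(stats::runif(tcfg$iterations, b$nEstimators[1],
                                     b$nEstimators[2])),
    depth = round(stats::runif(tcfg$iterations, b$depth[1], b$depth[2])),
    learningRate = stats::runif(tcfg$iterations, b$learningRate[1],
                                b$learningRate[2])))
  score <- numeric(tcfg$iterations)
  for (i in seq_len(tcfg$iterations)) {
    p <- as.list(pts[i, ])
    fit <- fit_base(trainFeatures, trainLabels, p, cw, tcfg$seed + i)
    prob <- predict_base(fit, valFeatures)
    cm <- confusionMatrix(prob, valLabels, threshold = 0.5)
    score[i] <- suppressWarnings(prf(cm)["F1"])
  }
  best <- which.max(score)
  out <- list(nEstimators = as.integer(pts$nEstimators[best]),
              depth = as.integer(pts$depth[best]),
              learningRate = pts$learningRate[best])
  attr(out, "objective") <- score[best]
  attr(out, "trace") <- cbind(pts, F1 = score)
  out
}

#' Tune both base classifiers of a stack
#'
#' Runs [tuneBase()] independently for the equal-weight and balanced-weight
#' base classifiers (the intended usage tunes the S/T and Y models
#' separately, each with its own data).
#'
#' @inheritParams tuneBase
#' @param tcfg a [tuneConfig()].
#' @return a [stackConfig()] carrying the tuned per-base parameters.
#' @export
tuneStack <- function(trainFeatures, trainLabels, valFeatures, valLabels,
                      tcfg = tuneConfig()) {
  eq <- tuneBase(trainFeatures, trainLabels, valFeatures, valLabels,
                 "equal", tcfg)
  bal <- tuneBase(trainFeatures, trainLabels, valFeatures, valLabels,
                  "balanced", tcfg)
  cfg <- stackConfig(seed = tcfg$seed,
                     equalParams = eq[c("nEstimators", "depth", "learningRate")],
                     balancedParams = bal[c("nEstimators", "depth",
                                            "learningRate")])
  attr(cfg, "traces") <- list(equal = attr(eq, "trace"),
                              balanced = attr(bal, "trace"))
  cfg
}

MODEL_BUNDLE_VERSION <- "1"

#' Save / load a fitted stack model bundle
#'
#' A versioned directory holding the two base boosters, the meta-learner
#' coefficients, the configuration and the feature-width metadata.
#' `loadStackModel()` refuses bundles written with a different version.
#'
#' @param model [StackModel-class].
#' @param dir bundle directory (created if needed).
#' @return `saveStackModel`: `dir`, invisibly; `loadStackModel`: a
#'   [StackModel-class].
#' @export
saveStackModel <- function(model, dir) {
  stopifnot(is(model, "StackModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model@baseEqual, file.path(dir, "base_equal.ubj"))
  xgboost::xgb.save(model@baseBalanced, file.path(dir, "base_balanced.ubj"))
  meta <- list(version = MODEL_BUNDLE_VERSION,
               metaCoef = model@metaCoef,
               featureDim = model@featureDim,
               classCounts = model@classCounts,
               config = model@config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname saveStackModel
#' @export
loadStackModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$version), MODEL_BUNDLE_VERSION))
    stop("model bundle version mismatch: found ", meta$version,
         ", expected ", MODEL_BUNDLE_VERSION)
  new("StackModel",
      baseEqual = xgboost::xgb.load(file.path(dir, "base_equal.ubj")),
      baseBalanced = xgboost::xgb.load(file.path(dir, "base_balanced.ubj")),
      metaCoef = as.numeric(meta$metaCoef),
      config = meta$config,
      featureDim = as.integer(meta$featureDim),
      classCounts = as.integer(meta$classCounts))
}
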