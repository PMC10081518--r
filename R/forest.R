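#' Weighted random forest configuration
#'
#' Hyper-parameters of the PM2.5 regression forest: 500 trees, `mTry` =
#' square root of the predictor count rounded up (resolved at fit time when
#' `NULL`), minimum node size 5, maximum depth 20.
#'
#' @param nTrees Number of trees.
#' @param mTry Predictors tried per split (`NULL` = `ceiling(sqrt(p))`).
#' @param minNodeSize Minimum node size.
#' @param maxDepth Maximum tree depth (levels).
#' @param seed Integer seed.
#' @param variant `"AQS_ONLY"`, `"AQS_PA_WEIGHTED"` or `"AQS_PA_SMOTE"`.
#' @return A list of class `ForestConfig`.
#' @export
forestConfig <- function(nTrees = 500, mTry = NULL, minNodeSize = 5,
                         maxDepth = 20, seed = 1L,
                         variant = c("AQS_PA_WEIGHTED", "AQS_ONLY",
                                     "AQS_PA_SMOTE")) {
  variant <- match.arg(variant)
  stopifnot(nTrees >= 1, is.null(mTry) || mTry >= 1)
  structure(list(nTrees = as.integer(nTrees), mTry = mTry,
                 minNodeSize = as.integer(minNodeSize),
                 maxDepth = as.integer(maxDepth),
                 seed = as.integer(seed), variant = variant),
            class = "ForestConfig")
}

#' Train a weighted random forest on complete feature rows
#'
#' Each tree is grown on a weight-proportional bootstrap (an observation's
#' selection probability is proportional to its weight, realising the
#' regulatory-vs-low-cost 1.0 / 0.15 weighting), with split search over
#' `mTry` randomly chosen predictors under the variance-reduction
#' criterion. Out-of-bag predictions (mean over trees whose bootstrap
#' excluded the row) and permutation variable importance are returned.
#'
#' @param features Complete feature rows (no missing predictors; see
#'   [completeFeatures()]).
#' @param config A [forestConfig()].
#' @param predictors Predictor column names (default [predictorNames]).
#' @param targetCol,weightCol Target / weight column names.
#' @return List of class `ForestFit`: `fit` (the ranger ensemble),
#'   `oobPredictions`, `importance` (permutation, decreasing), `config`,
#'   `predictors`.
#' @export
trainForest <- function(features, config = forestConfig(),
                        predictors = predictorNames,
                        targetCol = "pm25", weightCol = "weight") {
  stopifnot(inherits(config, "ForestConfig"))
  X <- features[, predictors, drop = FALSE]
  if (anyNA(X))
    stop("feature rows contain missing predictors; filter with completeFeatures()")
  p <- length(predictors)
  mTry <- if (is.null(config$mTry)) ceiling(sqrt(p)) else config$mTry
  if (mTry > p) stop("mTry (", mTry, ") exceeds predictor count (", p, ")")
  w <- features[[weightCol]]
  stopifnot(all(w > 0), all(w <= 1))
  fit <- ranger::ranger(
    x = X, y = features[[targetCol]],
    num.trees = config$nTrees, mtry = mTry,
    min.node.size = config$minNodeSize, max.depth = config$maxDepth,
    case.weights = w, importance = "permutation",
    seed = config$seed, num.threads = 1L)
  structure(list(fit = fit,
                 oobPredictions = fit$predictions,
                 importance = sort(fit$variable.importance,
                                   decreasing = TRUE),
                 config = config, predictors = predictors),
            class = "ForestFit")
}

#' Predict PM2.5 for new feature rows
#'
#' @param forest A `ForestFit` from [trainForest()].
#' @param features Feature rows (complete in the forest's predictors).
#' @return Ensemble-mean predictions (ug/m3).
#' @export
predictForest <- function(forest, features) {
  stopifnot(inherits(forest, "ForestFit"))
  predict(forest$fit, data = features[, forest$predictors, drop = FALSE],
          num.threads = 1L)$predictions
}

#' Build a 10-fold temporal (blocked) cross-validation plan
#'
#' Rows are sorted by hour (ties by station id) and split into `k`
#' contiguous blocks whose sizes differ by at most one (larger blocks
#' first), so training and validation occupy disjoint time segments.
#'
#' @param rows Feature table with `hour` and `stationId`.
#' @param k Number of blocks (default 10).
#' @return A [FoldPlan-class] with one fold id per row of `rows`.
#' @export
makeTemporalFolds <- function(rows, k = 10) {
  n <- nrow(rows)
  k <- as.integer(k)
  stopifnot(k >= 1, n >= k)
  ord <- order(rows$hour, rows$stationId)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  assignments <- integer(n)
  assignments[ord] <- rep(seq_len(k), times = sizes)
  new("FoldPlan", kind = "TEMPORAL_10FOLD", assignments = assignments,
      nFolds = k)
}

#' Build a spatially heterogeneous leave-group-out plan
#'
#' Monitors are ordered along a Hilbert space-filling curve over their
#' coordinates and dealt round-robin into `ceiling(M / groupSize)` groups,
#' so every group spans the whole domain (spatial heterogeneity within
#' groups, following the leave-ten-monitors-out design). Monitors sharing
#' a grid cell are forced into the same group, since their observations
#' are merged during deduplication.
#'
#' @param monitors data.frame: `stationId`, `lon`, `lat`, optionally
#'   `cellId`.
#' @param groupSize Target monitors per group (default 10; the last groups
#'   may be smaller).
#' @return A [FoldPlan-class] with a group id per monitor, named by
#'   station id.
#' @export
makeSpatialFolds <- function(monitors, groupSize = 10) {
  stopifnot(nrow(monitors) >= 1, groupSize >= 1)
  monitors <- monitors[order(monitors$stationId), ]
  unitOf <- if ("cellId" %in% names(monitors))
    match(monitors$cellId, unique(monitors$cellId))
  else seq_len(nrow(monitors))
  uLon <- tapply(monitors$lon, unitOf, mean)
  uLat <- tapply(monitors$lat, unitOf, mean)
  sc <- function(v) {
    if (diff(range(v)) == 0) rep(0L, length(v))
    else as.integer(floor(255 * (v - min(v)) / diff(range(v))))
  }
  h <- hilbertIndex(sc(uLon), sc(uLat), 8L)
  uOrd <- order(h, as.integer(names(uLon)))
  G <- max(1L, as.integer(ceiling(nrow(monitors) / groupSize)))
  groupOfUnit <- integer(length(uOrd))
  groupOfUnit[uOrd] <- (seq_along(uOrd) - 1L) %% G + 1L
  assignments <- groupOfUnit[unitOf]
  names(assignments) <- monitors$stationId
  new("FoldPlan", kind = "SPATIAL_LEAVE_TEN_OUT",
      assignments = setNames(as.integer(assignments), monitors$stationId),
      nFolds = G)
}

#' Measured-vs-predicted evaluation metrics
#'
#' R-squared is the squared Pearson correlation of measured and predicted;
#' slope and intercept come from the OLS regression of predicted on
#' measured (the dotted-line convention of measured-vs-predicted scatter
#' plots). The high-range slope repeats that regression on the subset with
#' measured values at or above the minority cutoff, quantifying
#' underestimation of smoke-impacted concentrations.
#'
#' @param measured,predicted Numeric vectors (ug/m3).
#' @param minorityCutoff High-range threshold (default 100 ug/m3).
#' @return List: `r2`, `rmse`, `slope`, `intercept`, `highSlope`,
#'   `highIntercept`, `n`, `nHigh` (high-range entries are `NA` with fewer
#'   than 3 high-range points).
#' @export
evaluatePredictions <- function(measured, predicted, minorityCutoff = 100) {
  ok <- is.finite(measured) & is.finite(predicted)
  measured <- measured[ok]; predicted <- predicted[ok]
  stopifnot(length(measured) >= 2)
  fit <- coef(lm(predicted ~ measured))
  hi <- measured >= minorityCutoff
  if (sum(hi) >= 3) {
    hfit <- coef(lm(predicted[hi] ~ measured[hi]))
  } else hfit <- c(NA_real_, NA_real_)
  list(r2 = cor(measured, predicted)^2,
       rmse = sqrt(mean((measured - predicted)^2)),
       slope = unname(fit[2]), intercept = unname(fit[1]),
       highSlope = unname(hfit[2]), highIntercept = unname(hfit[1]),
       n = length(measured), nHigh = sum(hi))
}

#' Cross-validate a forest variant under a fold plan
#'
#' For each fold, the forest is trained on all other folds and scored on
#' the held-out rows; predictions are pooled so every original row is
#' predicted exactly once, and metrics are computed on the pooled original
#' rows. When a SMOTE configuration is supplied it is applied to the
#' training portion of each fold only, after the split, so synthetic rows
#' can never leak into, or be scored against, validation data (a fold
#' whose training part has no minority rows skips SMOTE with a warning).
#' Leakage guards are asserted on every fold: no station id may span a
#' spatial train/validation split, temporal blocks must not interleave,
#' and no synthetic row is ever scored.
#'
#' @param features Complete feature rows.
#' @param plan A [FoldPlan-class] covering `features`.
#' @param config A [forestConfig()] (per-fold seeds derive from its seed).
#' @param smote Optional [smoteConfig()] (the SMOTE variant).
#' @return List of class `CvResult`: `predictions` (data.frame with
#'   measured, predicted, fold), `metrics` (from [evaluatePredictions()]),
#'   `kind`, `variant`.
#' @export
crossValidate <- function(features, plan, config = forestConfig(),
                          smote = NULL) {
  stopifnot(is(plan, "FoldPlan"))
  if (plan@nFolds < 2L) stop("degenerate fold plan: need at least 2 folds")
  if (!is.null(features$isSynthetic) && any(features$isSynthetic))
    stop("cross-validation input must contain original rows only")
  foldOf <- if (plan@kind == "TEMPORAL_10FOLD") {
    if (length(plan@assignments) != nrow(features))
      stop("temporal plan was built for a different table")
    plan@assignments
  } else {
    f <- plan@assignments[features$stationId]
    if (anyNA(f)) stop("fold plan does not cover all stations")
    unname(f)
  }
  predicted <- rep(NA_real_, nrow(features))
  for (f in sort(unique(foldOf))) {
    val <- foldOf == f
    train <- features[!val, , drop = FALSE]
    if (plan@kind == "SPATIAL_LEAVE_TEN_OUT" &&
        length(intersect(unique(train$stationId),
                         unique(features$stationId[val]))))
      stop("leakage: station spans train/validation split")
    if (plan@kind == "TEMPORAL_10FOLD") {
      ord <- order(features$hour, features$stationId)
      runs <- rle(foldOf[ord])$values
      if (anyDuplicated(runs))
        stop("leakage: temporal folds interleave in time")
    }
    if (!is.null(smote)) {
      if (!any(labelMinority(train$pm25, smote$minorityCutoff))) {
        warning("fold ", f, ": no minority rows in training; SMOTE skipped")
      } else {
        cfgF <- smote
        cfgF$seed <- smote$seed + f
        train <- smoteAugment(train, cfgF)
      }
    }
    cfgF <- config
    cfgF$seed <- config$seed + f
    forest <- trainForest(train, cfgF)
    stopifnot(!any(val & !is.na(predicted)))   # each row scored once
    predicted[val] <- predictForest(forest, features[val, , drop = FALSE])
  }
  stopifnot(!anyNA(predicted))
  structure(list(
    predictions = data.frame(cellId = features$cellId,
                             hour = features$hour,
                             stationId = features$stationId,
                             measured = features$pm25,
                             predicted = predicted, fold = foldOf),
    metrics = evaluatePredictions(features$pm25, predicted),
    kind = plan@kind, variant = config$variant), class = "CvResult")
}

# per-variant view of the training table: AQS_ONLY keeps regulatory rows
# (weight 1); the other variants keep everything with the stored weights
variantFeatures <- function(features, variant) {
  if (variant == "AQS_ONLY") {
    out <- features[features$network == "AQS", , drop = FALSE]
    out$weight <- 1
    out
  } else features
}

#' Run the full synthetic pipeline up to the feature table
#'
#' Generates a domain and its ground networks, calibrates the low-cost
#' sensors against collocated regulatory monitors by GWR, deduplicates
#' ground values per cell-hour, and assembles the training feature table.
#'
#' @param config A [DomainConfig-class].
#' @param bandwidthKm GWR bandwidth (km) or `"auto"`.
#' @param weightPa Low-cost observation weight (default 0.15).
#' @return List: `domain`, `obs` (raw observations), `pairs`
#'   (collocations), `gwr`, `ground` (deduplicated), `features`
#'   (training table; use [completeFeatures()] before modeling).
#' @export
buildFeaturesFromConfig <- function(config, bandwidthKm = "auto",
                                    weightPa = 0.15) {
  domain <- simulateDomain(config)
  obs <- sampleNetworks(config, domain)
  aqs <- obs[obs$network == "AQS", ]
  pa <- obs[obs$network == "PURPLEAIR", ]
  pairs <- findCollocations(aqs, pa)
  gwr <- fitGWR(pairs, bandwidthKm)
  paCal <- applyCalibration(gwr, pa)
  ground <- dedupGround(rbind(aqs[, c("stationId", "network", "cellId",
                                      "hour", "pm25")],
                              paCal[, c("stationId", "network", "cellId",
                                        "hour", "pm25")]),
                        weightPa = weightPa)
  features <- assembleFeatures(domain, ground, mode = "training")
  list(domain = domain, obs = obs, pairs = pairs, gwr = gwr,
       ground = ground, features = features)
}

#' Compare the three model variants by spatial cross-validation
#'
#' For each seed, the full synthetic pipeline is run and the three forest
#' variants (regulatory-only; plus weighted low-cost sensors; plus
#' fold-safe SMOTE) are evaluated with leave-group-out spatial
#' cross-validation on their own training datasets, mirroring the
#' three-model comparison structure of the analysis. Forest size defaults
#' to 50 trees here to keep the multi-seed study tractable; `ForestConfig`
#' defaults are unchanged elsewhere.
#'
#' @param config Base [DomainConfig-class] (its seed is replaced by each
#'   element of `seeds`).
#' @param seeds Integer vector of generator seeds (one pipeline run each).
#' @param nTrees Trees per forest in this study.
#' @param smote [smoteConfig()] for the SMOTE variant.
#' @param groupSize Monitors per spatial CV group.
#' @param bandwidthKm GWR bandwidth or `"auto"`.
#' @return data.frame: one row per seed and variant with spatial-CV `r2`,
#'   `rmse`, `slope`, `intercept`, `highSlope`, `n`, `nHigh`.
#' @export
modelOrderingStudy <- function(config = domainConfig(), seeds = 1:5,
                               nTrees = 50, smote = smoteConfig(),
                               groupSize = 10, bandwidthKm = "auto") {
  res <- list()
  for (s in seeds) {
    cfg <- config
    cfg@seed <- as.integer(s)
    pipe <- buildFeaturesFromConfig(cfg, bandwidthKm = bandwidthKm)
    ftAll <- completeFeatures(pipe$features)
    for (variant in c("AQS_ONLY", "AQS_PA_WEIGHTED", "AQS_PA_SMOTE")) {
      ft <- variantFeatures(ftAll, variant)
      monitors <- unique(data.frame(
        stationId = ft$stationId,
        cellId = ft$cellId))
      geom <- cellCenters(pipe$domain)
      monitors$lon <- geom$lon[match(monitors$cellId, geom$cellId)]
      monitors$lat <- geom$lat[match(monitors$cellId, geom$cellId)]
      plan <- makeSpatialFolds(monitors, groupSize = groupSize)
      fc <- forestConfig(nTrees = nTrees, seed = as.integer(s),
                         variant = variant)
      cv <- crossValidate(ft, plan, fc,
                          smote = if (variant == "AQS_PA_SMOTE") smote)
      res[[length(res) + 1L]] <- data.frame(
        seed = s, variant = variant, scheme = "spatial_cv",
        r2 = cv$metrics$r2, rmse = cv$metrics$rmse,
        slope = cv$metrics$slope, intercept = cv$metrics$intercept,
        highSlope = cv$metrics$highSlope, n = cv$metrics$n,
        nHigh = cv$metrics$nHigh)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
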