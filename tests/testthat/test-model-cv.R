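test_that("temporal folds are contiguous blocks of near-equal size", {
  rows <- data.frame(hour = sample(0:49, 100, TRUE),
                     stationId = sprintf("S%02d", sample(1:8, 100, TRUE)))
  plan <- makeTemporalFolds(rows, k = 10)
  expect_equal(plan@nFolds, 10L)
  expect_equal(as.integer(table(plan@assignments)), rep(10L, 10))
  # 105 rows: five blocks of 11 then five of 10
  rows2 <- data.frame(hour = sample(0:49, 105, TRUE),
                      stationId = "S01")
  plan2 <- makeTemporalFolds(rows2, k = 10)
  expect_equal(sort(as.integer(table(plan2@assignments)), decreasing = TRUE),
               c(rep(11L, 5), rep(10L, 5)))
  # every row in exactly one block; blocks ordered in time
  ord <- order(rows$hour, rows$stationId)
  runs <- rle(plan@assignments[ord])$values
  expect_equal(runs, 1:10)                      # oracle: direct scan
  expect_equal(sort(unique(plan@assignments)), 1:10)
})

test_that("spatial folds partition monitors into domain-spanning groups", {
  set.seed(3)
  mon <- data.frame(stationId = sprintf("M%03d", 1:960),
                    lon = runif(960, -124, -118),
                    lat = runif(960, 33, 41))
  plan <- makeSpatialFolds(mon, groupSize = 10)
  expect_equal(plan@nFolds, 96L)                # 96 groups of 10 monitors
  expect_equal(as.integer(table(plan@assignments)), rep(10L, 96))
  expect_setequal(names(plan@assignments), mon$stationId)
  # groups span the domain rather than tiling it: each group's latitude
  # spread is comparable to the whole domain's
  sp <- tapply(mon$lat[match(names(plan@assignments), mon$stationId)],
               plan@assignments, function(v) diff(range(v)))
  expect_gt(min(sp), 0.5 * diff(range(mon$lat)) * 0.5)
})

test_that("four corner monitors pair into opposite-corner groups", {
  mon <- data.frame(stationId = c("A", "B", "C", "D"),
                    lon = c(-124, -118, -124, -118),
                    lat = c(33, 33, 41, 41))
  plan <- makeSpatialFolds(mon, groupSize = 2)
  g <- plan@assignments
  # oracle: the only groupings maximising within-group spread put opposite
  # corners together: {A,D}/{B,C}
  expect_equal(g[["A"]], g[["D"]])
  expect_equal(g[["B"]], g[["C"]])
  expect_false(g[["A"]] == g[["B"]])
})

test_that("monitors sharing a grid cell stay in one spatial group", {
  mon <- data.frame(stationId = sprintf("M%02d", 1:8),
                    lon = c(-121, -121, -120, -120, -119, -119, -118, -118),
                    lat = c(38, 38.5, 39, 39.5, 38, 38.5, 39, 39.5),
                    cellId = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L))
  plan <- makeSpatialFolds(mon, groupSize = 2)
  g <- plan@assignments
  expect_equal(g[["M01"]], g[["M02"]])          # same cell, same group
})

test_that("evaluation metrics match hand-computed values", {
  ident <- evaluatePredictions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$r2, 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  off <- evaluatePredictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(off$rmse, sqrt(1 / 3))           # oracle: hand computation
  shift <- evaluatePredictions(c(1, 2, 3), c(6, 7, 8))
  expect_equal(shift$r2, 1)                     # Pearson is shift-invariant
  expect_equal(shift$rmse, 5)
  expect_equal(shift$intercept, 5)
  hi <- evaluatePredictions(c(10, 50, 120, 150, 200), 0.5 * c(10, 50, 120, 150, 200))
  expect_equal(hi$highSlope, 0.5)
  expect_equal(hi$nHigh, 3L)
})

test_that("a learnable identity predictor gives near-perfect OOB skill", {
  set.seed(5)
  n <- 600
  ft <- data.frame(cellId = 0L, hour = 0L, stationId = "S", network = "AQS",
                   weight = 1, pm25 = runif(n, 0, 300))
  ft$x <- ft$pm25
  fit <- trainForest(ft, forestConfig(nTrees = 100, seed = 1),
                     predictors = "x")
  ok <- is.finite(fit$oobPredictions)
  expect_gt(cor(ft$pm25[ok], fit$oobPredictions[ok])^2, 0.95)
  expect_named(fit$importance, "x")
})

test_that("forest configuration contracts are enforced", {
  ft <- data.frame(pm25 = runif(20), weight = 1, x = runif(20),
                   y = runif(20))
  expect_error(trainForest(ft, forestConfig(mTry = 5), predictors = c("x", "y")),
               "mTry")
  ft$x[3] <- NA
  expect_error(trainForest(ft, forestConfig(), predictors = c("x", "y")),
               "missing")
  expect_error(forestConfig(variant = "BOGUS"))
})

test_that("near-zero low-cost weight converges to the regulatory-only model", {
  set.seed(8)
  n <- 800
  ft <- data.frame(cellId = sample(0:99, n, TRUE), hour = 0L,
                   stationId = sprintf("S%02d", sample(1:20, n, TRUE)),
                   network = rep(c("AQS", "PURPLEAIR"), c(200, 600)))
  ft$x1 <- rnorm(n)
  ft$x2 <- rnorm(n)
  ft$pm25 <- 50 + 30 * ft$x1 + rnorm(n, sd = 2)
  # low-cost rows carry a large spurious offset; with vanishing weight the
  # forest should ignore them and match the regulatory-only fit
  ft$pm25[ft$network == "PURPLEAIR"] <- ft$pm25[ft$network == "PURPLEAIR"] + 80
  newX <- data.frame(x1 = seq(-2, 2, length.out = 50), x2 = 0)
  ftEps <- ft
  ftEps$weight <- ifelse(ft$network == "AQS", 1, 1e-6)
  fitEps <- trainForest(ftEps, forestConfig(nTrees = 150, seed = 2),
                        predictors = c("x1", "x2"))
  aqsOnly <- ft[ft$network == "AQS", ]
  aqsOnly$weight <- 1
  fitAqs <- trainForest(aqsOnly, forestConfig(nTrees = 150, seed = 2),
                        predictors = c("x1", "x2"))
  pEps <- predictForest(fitEps, newX)
  pAqs <- predictForest(fitAqs, newX)
  expect_lt(mean(abs(pEps - pAqs)), 6)
  # while an equally-weighted fit is pulled far upward by the offset rows
  ftEq <- ft; ftEq$weight <- 1
  fitEq <- trainForest(ftEq, forestConfig(nTrees = 150, seed = 2),
                       predictors = c("x1", "x2"))
  expect_gt(mean(predictForest(fitEq, newX) - pAqs), 30)
})

test_that("cross-validation pools one honest prediction per row", {
  cfg <- tinyConfig(seed = 10)
  pipe <- buildFeaturesFromConfig(cfg, bandwidthKm = 100)
  ft <- completeFeatures(pipe$features)
  plan <- makeTemporalFolds(ft, k = 5)
  cv <- crossValidate(ft, plan, forestConfig(nTrees = 30, seed = 1))
  expect_equal(nrow(cv$predictions), nrow(ft))
  expect_false(anyNA(cv$predictions$predicted))
  expect_equal(cv$metrics$n, nrow(ft))
  expect_gt(cv$metrics$r2, 0)
  # degenerate single-fold plan is rejected
  plan1 <- makeTemporalFolds(ft, k = 1)
  expect_error(crossValidate(ft, plan1, forestConfig(nTrees = 10)),
               "degenerate")
})

test_that("spatial CV never lets a station span the split and SMOTE stays in training", {
  cfg <- tinyConfig(seed = 15)
  pipe <- buildFeaturesFromConfig(cfg, bandwidthKm = 100)
  ft <- completeFeatures(pipe$features)
  geom <- cellCenters(pipe$domain)
  monitors <- unique(data.frame(stationId = ft$stationId,
                                cellId = ft$cellId))
  monitors$lon <- geom$lon[match(monitors$cellId, geom$cellId)]
  monitors$lat <- geom$lat[match(monitors$cellId, geom$cellId)]
  plan <- makeSpatialFolds(monitors, groupSize = 10)
  # exhaustive guard: group partition of stations
  foldOf <- plan@assignments[ft$stationId]
  for (f in unique(foldOf)) {
    trainSt <- unique(ft$stationId[foldOf != f])
    valSt <- unique(ft$stationId[foldOf == f])
    expect_length(intersect(trainSt, valSt), 0)
  }
  sm <- smoteConfig(seed = 7)
  cv <- crossValidate(ft, plan, forestConfig(nTrees = 30, seed = 2,
                                             variant = "AQS_PA_SMOTE"),
                      smote = sm)
  # pooled predictions cover exactly the original rows: synthetic rows are
  # never scored
  expect_equal(nrow(cv$predictions), nrow(ft))
  expect_equal(cv$predictions$measured, ft$pm25)
  # feeding augmented rows into CV is refused outright
  aug <- smoteAugment(ft, sm)
  expect_error(crossValidate(aug, plan, forestConfig(nTrees = 10)),
               "original rows")
})
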