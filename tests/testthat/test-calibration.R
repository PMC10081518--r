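# synthetic collocation pairs at a handful of sites with a known global
# linear sensor bias: raw = a + b * truth, AQS measures truth
makePairs <- function(a = 2, b = 1.1, nSites = 6, hoursPerSite = 40,
                      seed = 1, noiseSd = 0) {
  set.seed(seed)
  lon <- -121.8 + runif(nSites, 0, 0.5)
  lat <- 38.8 + runif(nSites, 0, 0.5)
  out <- do.call(rbind, lapply(seq_len(nSites), function(i) {
    truth <- runif(hoursPerSite, 2, 120)
    data.frame(paStationId = sprintf("PA_%03d", i),
               aqsStationId = sprintf("AQS_%02d", i),
               distanceM = 100, hour = seq_len(hoursPerSite) - 1L,
               paPm25 = a + b * truth + rnorm(hoursPerSite, sd = noiseSd),
               aqsPm25 = truth,
               temperature = runif(hoursPerSite, 5, 25),
               relativeHumidity = runif(hoursPerSite, 20, 80),
               uptime = runif(hoursPerSite, 0, 400),
               operatingTime = runif(hoursPerSite, 30, 300),
               paLon = lon[i], paLat = lat[i])
  }))
  rownames(out) <- NULL
  out
}

test_that("collocation pairs respect the radius and nearest-monitor rule", {
  base <- c(-121.5, 39.0)
  p400 <- ptNorth(base[1], base[2], 400)
  p600 <- ptNorth(base[1], base[2], 600)
  aqs <- rbind(obsRow("AQS_01", "AQS", base[1], base[2], 0, 10),
               obsRow("AQS_01", "AQS", base[1], base[2], 1, 12))
  paIn <- rbind(obsRow("PA_001", "PURPLEAIR", p400[1], p400[2], 0, 14),
                obsRow("PA_001", "PURPLEAIR", p400[1], p400[2], 5, 15))
  paOut <- obsRow("PA_002", "PURPLEAIR", p600[1], p600[2], 0, 9)
  pairs <- findCollocations(aqs, rbind(paIn, paOut), radiusM = 500)
  # 400 m pair at the shared hour only; 600 m sensor excluded
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$paStationId, "PA_001")
  expect_equal(pairs$hour, 0L)
  expect_equal(pairs$paPm25, 14)
  expect_equal(pairs$aqsPm25, 10)
  expect_lt(abs(pairs$distanceM - 400), 5)
})

test_that("a sensor with several qualifying monitors pairs with the nearest", {
  base <- c(-121.5, 39.0)
  a100 <- ptNorth(base[1], base[2], 100)
  a300 <- ptNorth(base[1], base[2], -300)
  aqs <- rbind(obsRow("AQS_far", "AQS", a300[1], a300[2], 0, 30),
               obsRow("AQS_near", "AQS", a100[1], a100[2], 0, 20))
  pa <- obsRow("PA_001", "PURPLEAIR", base[1], base[2], 0, 25)
  pairs <- findCollocations(aqs, pa, radiusM = 500)
  # oracle: exhaustive pairing then min-distance filter
  expect_equal(pairs$aqsStationId, "AQS_near")
  expect_equal(pairs$aqsPm25, 20)
  expect_equal(findCollocations(aqs[0, ], pa, 500),
               findCollocations(aqs, pa[0, ], 500))
  expect_equal(nrow(findCollocations(aqs[0, ], pa, 500)), 0L)
})

test_that("GWR recovers an inverse global linear bias at every anchor", {
  a <- 2; b <- 1.1
  pairs <- makePairs(a = a, b = b)
  model <- fitGWR(pairs, bandwidthKm = 50)
  expect_equal(unname(model@coefficients[, "paPm25"]),
               rep(1 / b, nrow(model@anchors)), tolerance = 0.05)
  expect_equal(unname(model@coefficients[, "(Intercept)"]),
               rep(-a / b, nrow(model@anchors)), tolerance = 0.05)
  for (cv in c("temperature", "relativeHumidity", "uptime", "operatingTime"))
    expect_equal(unname(model@coefficients[, cv]), rep(0, nrow(model@anchors)),
                 tolerance = 1e-6)
  # oracle: global least squares gives the same inverse relation
  ols <- coef(lm(aqsPm25 ~ paPm25 + temperature + relativeHumidity +
                   uptime + operatingTime, data = pairs))
  expect_equal(unname(ols["paPm25"]), 1 / b, tolerance = 1e-8)
})

test_that("identity sensors calibrate to the identity", {
  pairs <- makePairs(a = 0, b = 1)
  model <- fitGWR(pairs, bandwidthKm = 50)
  expect_equal(unname(model@coefficients[, "paPm25"]),
               rep(1, nrow(model@anchors)), tolerance = 1e-6)
  expect_equal(unname(model@coefficients[, "(Intercept)"]),
               rep(0, nrow(model@anchors)), tolerance = 1e-6)
})

test_that("an effectively infinite bandwidth reproduces global OLS exactly", {
  pairs <- makePairs(a = 3, b = 0.9, noiseSd = 4, seed = 4)
  model <- fitGWR(pairs, bandwidthKm = 1e6)
  ols <- coef(lm(aqsPm25 ~ paPm25 + temperature + relativeHumidity +
                   uptime + operatingTime, data = pairs))
  for (i in seq_len(nrow(model@anchors)))
    expect_equal(unname(model@coefficients[i, ]), unname(ols),
                 tolerance = 1e-6)
})

test_that("identity coefficients pass raw values through; negatives floor at 0", {
  anchors <- data.frame(paStationId = "PA_001", lon = -121.5, lat = 39)
  cf <- matrix(c(0, 1, 0, 0, 0, 0), 1,
               dimnames = list("PA_001",
                               c("(Intercept)", "paPm25", "temperature",
                                 "relativeHumidity", "uptime",
                                 "operatingTime")))
  model <- new("GwrModel", anchors = anchors, coefficients = cf,
               bandwidthKm = 50, kernel = "gaussian")
  pa <- rbind(obsRow("PA_001", "PURPLEAIR", -121.5, 39, 0, 17.5),
              obsRow("PA_001", "PURPLEAIR", -121.5, 39, 1, 3.2))
  cal <- applyCalibration(model, pa)
  expect_equal(cal$pm25, c(17.5, 3.2))
  expect_equal(cal$pm25Raw, c(17.5, 3.2))

  cf2 <- cf; cf2[1, "(Intercept)"] <- -10; cf2[1, "paPm25"] <- 0.5
  model2 <- new("GwrModel", anchors = anchors, coefficients = cf2,
                bandwidthKm = 50, kernel = "gaussian")
  cal2 <- applyCalibration(model2, pa)
  expect_equal(cal2$pm25, pmax(0, -10 + 0.5 * c(17.5, 3.2)))
  expect_equal(cal2$pm25[2], 0)
})

test_that("rows with missing covariates are dropped with a message", {
  anchors <- data.frame(paStationId = "PA_001", lon = -121.5, lat = 39)
  cf <- matrix(c(0, 1, 0, 0, 0, 0), 1,
               dimnames = list("PA_001",
                               c("(Intercept)", "paPm25", "temperature",
                                 "relativeHumidity", "uptime",
                                 "operatingTime")))
  model <- new("GwrModel", anchors = anchors, coefficients = cf,
               bandwidthKm = 50, kernel = "gaussian")
  pa <- rbind(obsRow("PA_001", "PURPLEAIR", -121.5, 39, 0, 17.5),
              obsRow("PA_001", "PURPLEAIR", -121.5, 39, 1, 3.2,
                     relativeHumidity = NA))
  expect_message(cal <- applyCalibration(model, pa), "dropped 1")
  expect_equal(nrow(cal), 1L)
})

test_that("calibration removes synthetic sensor bias and reduces RMSE", {
  cfg <- tinyConfig(seed = 6)
  dom <- simulateDomain(cfg)
  obs <- sampleNetworks(cfg, dom)
  aqs <- obs[obs$network == "AQS", ]
  pa <- obs[obs$network == "PURPLEAIR", ]
  pairs <- findCollocations(aqs, pa)
  expect_gt(nrow(pairs), 20)
  model <- fitGWR(pairs, bandwidthKm = "auto")
  cal <- applyCalibration(model, pa)
  rawBias <- mean(pa$pm25 - pa$truthPm25)
  calBias <- mean(cal$pm25 - cal$truthPm25)
  expect_lt(abs(calBias), abs(rawBias))
  rawRmse <- sqrt(mean((pa$pm25 - pa$truthPm25)^2))
  calRmse <- sqrt(mean((cal$pm25 - cal$truthPm25)^2))
  expect_lt(calRmse, rawRmse)
})
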