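#' SMOTE configuration for the continuous PM2.5 target
#'
#' @param minorityCutoff Target value (ug/m3) at or above which a row
#'   belongs to the minority class (default 100).
#' @param nSynthPerMinority Synthetic rows generated per minority row
#'   (default 2).
#' @param kNeighbors Minority nearest neighbors considered (default 5).
#' @param seed Integer seed governing neighbor and gap draws.
#' @param standardize Z-score continuous predictors (on the minority
#'   subset) before the neighbor search; recommended because the
#'   predictors carry heterogeneous units (Pa, m/s, fractions).
#' @return A list of class `SmoteConfig`.
#' @export
smoteConfig <- function(minorityCutoff = 100, nSynthPerMinority = 2,
                        kNeighbors = 5, seed = 1L, standardize = TRUE) {
  stopifnot(minorityCutoff > 0, nSynthPerMinority >= 0, kNeighbors >= 1)
  structure(list(minorityCutoff = minorityCutoff,
                 nSynthPerMinority = as.integer(nSynthPerMinority),
                 kNeighbors = as.integer(kNeighbors),
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "SmoteConfig")
}

#' Label minority (high-concentration) rows
#'
#' A row is minority when its target is at or above the cutoff (inclusive:
#' a measurement of exactly 100 ug/m3 is minority).
#'
#' @param pm25 Target values (ug/m3).
#' @param cutoff Minority cutoff (ug/m3), default 100.
#' @return Logical vector.
#' @export
labelMinority <- function(pm25, cutoff = 100) {
  pm25 >= cutoff
}

#' Augment a feature table with SMOTE for the continuous target
#'
#' Classical SMOTE adapted to a regression target: for each minority row
#' (target at or above the cutoff), its `kNeighbors` nearest minority rows
#' are found in standardized continuous-predictor space; each synthetic
#' draw picks a neighbor uniformly and a gap `g ~ Uniform(0,1)`, and sets
#' synthetic continuous predictors and target to
#' `seed + g * (neighbor - seed)`. Binary predictors, spatial/temporal
#' bookkeeping (cell, hour, station) and the observation weight are copied
#' from the seed row, so a synthetic low-cost-derived point keeps its
#' down-weighted trust. Majority rows are untouched. The output row count
#' is exactly `nrow(rows) + nSynthPerMinority * (number of minority rows)`.
#'
#' Draw order is fixed: after `set.seed(seed)`, one block of neighbor
#' indices `sample.int(k, m * nSynthPerMinority, replace = TRUE)` (minority
#' rows in input order, draws per row adjacent), then one block of gaps
#' `runif(m * nSynthPerMinority)`. Output is therefore deterministic under
#' a fixed seed and reproducible by an independent implementation of the
#' same contract.
#'
#' @param rows Feature table (must contain `targetCol` and the predictor
#'   columns).
#' @param config A [smoteConfig()].
#' @param continuousCols,binaryCols Predictor column names to interpolate /
#'   copy; defaults cover the standard feature table.
#' @param targetCol Target column name (default `"pm25"`).
#' @return `rows` plus synthetic rows, with a logical `isSynthetic` column.
#' @export
smoteAugment <- function(rows, config = smoteConfig(),
                         continuousCols = setdiff(predictorNames,
                                                  binaryPredictorNames),
                         binaryCols = binaryPredictorNames,
                         targetCol = "pm25") {
  stopifnot(inherits(config, "SmoteConfig"))
  rows$isSynthetic <- FALSE
  minority <- which(labelMinority(rows[[targetCol]], config$minorityCutoff))
  m <- length(minority)
  if (m == 0L) {
    warning("no minority rows at cutoff ", config$minorityCutoff,
            "; input returned unchanged")
    return(rows)
  }
  if (config$nSynthPerMinority == 0L) return(rows)
  k <- config$kNeighbors
  if (m <= k) {
    k <- max(1L, m - 1L)
    message("smoteAugment: only ", m, " minority rows; k shrunk to ", k)
  }
  if (m == 1L) {
    # a single minority row has no neighbor: interpolation degenerates to
    # copies of the seed row
    nn <- matrix(1L, 1, 1)
  } else {
    M <- as.matrix(rows[minority, continuousCols, drop = FALSE])
    if (config$standardize) {
      mu <- colMeans(M)
      sdv <- apply(M, 2, sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      M <- sweep(sweep(M, 2, mu), 2, sdv, "/")
    }
    # squared Euclidean distances among minority rows
    sq <- rowSums(M^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
    diag(D2) <- Inf
    nn <- t(apply(D2, 1, function(d) order(d)[seq_len(k)]))
    if (k == 1L) nn <- matrix(nn, ncol = 1L)
  }
  nS <- config$nSynthPerMinority
  set.seed(config$seed)
  nbPick <- sample.int(ncol(nn), m * nS, replace = TRUE)
  g <- runif(m * nS)
  interpCols <- c(continuousCols, targetCol)

  seedIdx <- rep(seq_len(m), each = nS)                 # minority-local
  nbLocal <- nn[cbind(seedIdx, nbPick)]
  synth <- rows[minority[seedIdx], , drop = FALSE]
  S <- as.matrix(rows[minority[seedIdx], interpCols, drop = FALSE])
  N <- as.matrix(rows[minority[nbLocal], interpCols, drop = FALSE])
  synth[interpCols] <- as.data.frame(S + g * (N - S))
  synth$isSynthetic <- TRUE
  out <- rbind(rows, synth)
  rownames(out) <- NULL
  out
}
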