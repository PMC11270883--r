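DIRECTION_FEATURES <- c(
  "query_protein_count", "target_protein_count",
  "query_residue_count", "target_residue_count",
  "query_mean_len", "target_mean_len",
  "size_fold", "count_fold"
)

#' Build classifier features for a proteome pair
#'
#' The pair is put into canonical orientation: the proteome with fewer
#' residues becomes the query (leftmost); ties are broken by protein
#' count and then by proteome id. Besides the per-proteome summaries, the
#' differences in proteome size and protein count are expressed in folds
#' (always >= 1, larger over smaller), so the features are invariant
#' under argument swap.
#'
#' @param statsA,statsB [ProteomeStats-class] of the two proteomes.
#' @return list with `features` (named numeric vector of the eight
#'   classifier features), `queryId` and `targetId` (the canonical
#'   orientation).
#' @export
buildPairFeatures <- function(statsA, statsB) {
  swap <- statsB@residueCount < statsA@residueCount ||
    (statsB@residueCount == statsA@residueCount &&
       (statsB@proteinCount < statsA@proteinCount ||
          (statsB@proteinCount == statsA@proteinCount &&
             statsB@proteomeId < statsA@proteomeId)))
  q <- if (swap) statsB else statsA
  t <- if (swap) statsA else statsB
  feats <- c(
    query_protein_count = as.numeric(q@proteinCount),
    target_protein_count = as.numeric(t@proteinCount),
    query_residue_count = q@residueCount,
    target_residue_count = t@residueCount,
    query_mean_len = q@meanProteinLength,
    target_mean_len = t@meanProteinLength,
    size_fold = max(q@residueCount, t@residueCount) /
      min(q@residueCount, t@residueCount),
    count_fold = max(q@proteinCount, t@proteinCount) /
      min(q@proteinCount, t@proteinCount)
  )
  list(features = feats, queryId = q@proteomeId, targetId = t@proteomeId)
}

#' Label a training sample from measured alignment times
#'
#' The sample represents the canonical direction A-B; its label is 1
#' (faster) iff the A-B alignment took strictly less time than B-A, else
#' 0. Ties map to 0 so labeling is deterministic.
#'
#' @param timeAB,timeBA execution times in seconds, both > 0.
#' @return integer label, 0 or 1.
#' @export
labelFromTimes <- function(timeAB, timeBA) {
  if (any(timeAB <= 0) || any(timeBA <= 0))
    stop("alignment times must be positive")
  as.integer(timeAB < timeBA)
}

#' Train the faster-alignment-direction classifier
#'
#' Boosted decision stumps (depth-1 gradient-boosted trees) on the eight
#' pair features, with a grid search over ensemble size and learning rate
#' scored by k-fold cross-validation accuracy. Training is single-threaded
#' and fully seeded, so two runs with the same samples and seed give
#' identical predictions.
#'
#' @param samples data.frame with the eight feature columns (see
#'   [buildPairFeatures()]) and a `label` column in \{0, 1\}.
#' @param seed integer training seed.
#' @param nroundsGrid,etaGrid hyper-parameter grid (ensemble sizes and
#'   learning rates).
#' @param nfolds folds for cross-validation (default 10).
#' @return a [DirectionModel-class].
#' @export
trainDirectionModel <- function(samples, seed = 1L,
                                nroundsGrid = c(50L, 100L, 200L, 400L),
                                etaGrid = c(0.1, 0.5, 1.0),
                                nfolds = 10L) {
  stopifnot(all(DIRECTION_FEATURES %in% names(samples)),
            "label" %in% names(samples))
  if (nrow(samples) < 2L) stop("need at least 2 training samples")
  y <- as.integer(samples$label)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; both labels are required")
  X <- as.matrix(samples[, DIRECTION_FEATURES])

  set.seed(deriveSeed(seed, "cv"))
  fold <- sample(rep_len(seq_len(nfolds), nrow(X)))

  fitOne <- function(Xtr, ytr, nrounds, eta) {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 1L,
                    eta = eta, nthread = 1L, seed = deriveSeed(seed, "model")),
      data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L),
      nrounds = nrounds, verbose = 0
    )
  }

  grid <- expand.grid(nrounds = nroundsGrid, eta = etaGrid)
  cvAcc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(nfolds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- fitOne(X[tr, , drop = FALSE], y[tr], grid$nrounds[g], grid$eta[g])
      p <- predict(m, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                           nthread = 1L))
      mean(as.integer(p > 0.5) == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))

  best <- which.max(cvAcc)  # ties: smallest nrounds/eta first in the grid
  booster <- fitOne(X, y, grid$nrounds[best], grid$eta[best])
  new("DirectionModel",
      booster = booster,
      featureNames = DIRECTION_FEATURES,
      cvAccuracy = cvAcc[best],
      params = list(nrounds = grid$nrounds[best], eta = grid$eta[best]),
      nSamples = nrow(X),
      seed = as.integer(seed))
}

#' @describeIn DirectionModel-class cross-validation accuracy of the
#'   selected hyper-parameters
#' @param x a `DirectionModel`.
#' @export
cvAccuracy <- function(x) x@cvAccuracy

#' Predict labels for pair-feature rows
#'
#' @param model a [DirectionModel-class].
#' @param samples data.frame or matrix with the eight feature columns.
#' @return integer vector of labels (1 = the canonical direction is the
#'   faster one).
#' @export
predictDirectionLabel <- function(model, samples) {
  X <- as.matrix(as.data.frame(samples)[, model@featureNames])
  p <- predict(model@booster, xgboost::xgb.DMatrix(X, nthread = 1L))
  as.integer(p > 0.5)
}

setMethod("show", "DirectionModel", function(object) {
  cat("DirectionModel: boosted stumps, nrounds=", object@params$nrounds,
      ", eta=", object@params$eta, ", CV accuracy=",
      round(object@cvAccuracy, 4), " (n=", object@nSamples, ", seed=",
      object@seed, ")\n", sep = "")
})

#' Decide which alignment direction to run in full first
#'
#' With a trained model, the direction the model labels as faster is run
#' first. Without one, the proteome-size heuristic is used: the larger
#' proteome (more residues) becomes the query of the first, full
#' alignment and the smaller the target; the reverse direction is then
#' restricted to the essential subsets. Exact ties fall back to
#' lexicographic proteome-id order.
#'
#' @param feats output of [buildPairFeatures()] for the pair.
#' @param model optional [DirectionModel-class].
#' @return list with `first` and `second` (each c(query, target) proteome
#'   ids; the two orientations of the same pair) and `source` ("model",
#'   "heuristic" or "tie_break").
#' @export
predictDirection <- function(feats, model = NULL) {
  q <- feats$queryId; t <- feats$targetId  # canonical: q is the smaller
  if (!is.null(model)) {
    lab <- predictDirectionLabel(model, as.data.frame(t(feats$features)))
    first <- if (lab == 1L) c(q, t) else c(t, q)
    src <- "model"
  } else if (feats$features[["size_fold"]] == 1 &&
             feats$features[["count_fold"]] == 1) {
    ord <- sort(c(q, t))
    first <- ord
    src <- "tie_break"
  } else {
    first <- c(t, q)  # larger proteome as query
    src <- "heuristic"
  }
  list(first = first, second = rev(first), source = src)
}

#' Write / read direction-model training samples as TSV
#'
#' One row per oriented pair: the eight feature columns plus the label.
#'
#' @param samples data.frame of features + label.
#' @param path TSV path.
#' @return `readDirectionSamples` returns the samples data.frame.
#' @export
writeDirectionSamples <- function(samples, path) {
  write.table(samples[, c(DIRECTION_FEATURES, "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDirectionSamples
#' @export
readDirectionSamples <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Persist / restore a trained direction model
#'
#' The booster is stored as a binary artifact next to a JSON metadata
#' sidecar (feature order, CV accuracy, hyper-parameters, seed, package
#' version).
#'
#' @param model a [DirectionModel-class].
#' @param path file path for the binary artifact; the sidecar is written
#'   to `<path>.json`.
#' @return `loadDirectionModel` returns the restored model.
#' @export
saveDirectionModel <- function(model, path) {
  raw <- xgboost::xgb.save.raw(model@booster)
  writeBin(raw, path)
  meta <- list(format = "orthoduet-direction-model", version = 1L,
               featureNames = model@featureNames,
               cvAccuracy = model@cvAccuracy, params = model@params,
               nSamples = model@nSamples, seed = model@seed,
               package = as.character(utils::packageVersion("OrthoDuet")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveDirectionModel
#' @export
loadDirectionModel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  booster <- xgboost::xgb.load.raw(readBin(path, "raw",
                                           file.info(path)$size))
  new("DirectionModel", booster = booster,
      featureNames = meta$featureNames,
      cvAccuracy = as.numeric(meta$cvAccuracy),
      params = as.list(meta$params),
      nSamples = as.integer(meta$nSamples),
      seed = as.integer(meta$seed))
}
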