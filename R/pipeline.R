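#' @include imaging.R bagging.R training.R heatmap.R synthetic.R
NULL

# Half-resolution reduction of a logical mask: a 2x2 block is lesion iff any
# of its pixels is.
.resizeMaskHalf <- function(mask) {
  resizeHalf(mask * 1) > 0
}

#' Prepare one dataset case for the MIL pipeline
#'
#' Applies the preprocessing chain to one patient case: optional chest-wall
#' edge-band removal per view, optional half-resizing, CC + MLO
#' concatenation (multimodal) or single-view passthrough, then bag
#' construction under the foreground rule. The lesion mask is carried
#' through the same geometry so localisation can be scored later.
#'
#' @param case one element of a [generateDataset()] / [loadDataset()] list.
#' @param patchSize patch edge, px (default 64 at desk scale).
#' @param overlap overlapping factor (default 0.5).
#' @param threshold foreground threshold (default 0.75).
#' @param multimodal concatenate CC + MLO into one bag (default TRUE);
#'   otherwise only the CC view is used.
#' @param artifactBandPx columns to crop at the chest-wall edge (0 = none).
#' @param resize half-resize the views before concatenation.
#' @return list with `bag` ([MammoBag-class]) and `mask` (logical matrix in
#'   the bag's source-image geometry).
#' @export
prepareCase <- function(case, patchSize = 64L, overlap = 0.5,
                        threshold = 0.75, multimodal = TRUE,
                        artifactBandPx = 0L, resize = FALSE) {
  cc <- case$cc
  mlo <- case$mlo
  blank <- function(img) matrix(FALSE, nrow(pixels(img)), ncol(pixels(img)))
  maskCC <- if (is.null(case$maskCC)) blank(cc) else case$maskCC
  maskMLO <- if (is.null(case$maskMLO)) blank(mlo) else case$maskMLO
  if (artifactBandPx > 0L) {
    cc <- removeEdgeArtifact(cc, artifactBandPx)
    mlo <- removeEdgeArtifact(mlo, artifactBandPx)
    maskCC <- maskCC[, -seq_len(artifactBandPx), drop = FALSE]
    maskMLO <- maskMLO[, -seq_len(artifactBandPx), drop = FALSE]
  }
  if (resize) {
    cc <- resizeHalf(cc)
    mlo <- resizeHalf(mlo)
    maskCC <- .resizeMaskHalf(maskCC)
    maskMLO <- .resizeMaskHalf(maskMLO)
  }
  if (multimodal) {
    img <- concatViews(cc, mlo)
    mask <- rbind(maskCC, maskMLO)
  } else {
    img <- cc
    mask <- maskCC
  }
  list(bag = buildBag(img, patchSize, overlap, threshold), mask = mask)
}

#' Prepare a whole dataset: bags, labels, masks, features
#'
#' Maps [prepareCase()] over the dataset and extracts frozen features for
#' every bag.
#'
#' @inheritParams prepareCase
#' @param dataset list of cases.
#' @param extractor an [ExtractorSpec-class].
#' @return list with `bags`, `masks`, `features` (per-case lists),
#'   `labels01` (0/1 vector) and `patientIds`.
#' @export
prepareDataset <- function(dataset, patchSize = 64L, overlap = 0.5,
                           threshold = 0.75, multimodal = TRUE,
                           artifactBandPx = 0L, resize = FALSE,
                           extractor = tinyExtractor()) {
  prep <- lapply(dataset, prepareCase, patchSize = patchSize,
                 overlap = overlap, threshold = threshold,
                 multimodal = multimodal, artifactBandPx = artifactBandPx,
                 resize = resize)
  bags <- lapply(prep, `[[`, "bag")
  list(bags = bags,
       masks = lapply(prep, `[[`, "mask"),
       features = lapply(bags, extractFeatures, spec = extractor),
       labels01 = vapply(dataset,
                         function(cs) as.integer(cs$label == "cancer"), 0L),
       patientIds = vapply(dataset, `[[`, "", "patientId"))
}

# Map patient-id sets of a fold onto case indices.
.foldIdx <- function(fold, patientIds) {
  list(train = which(patientIds %in% fold$train),
       val = which(patientIds %in% fold$val),
       test = which(patientIds %in% fold$test))
}

#' Train on one fold split and evaluate on its test set
#'
#' @param prep output of [prepareDataset()].
#' @param fold one element of [makeFolds()].
#' @param cfg a [trainConfig()].
#' @param initSeed RNG seed for weight initialisation.
#' @param optimizeThreshold `"none"` (0.5) or `"youden"` (optimised on the
#'   validation scores, then applied to the test set).
#' @return list: `model`, `log`, `metrics` (named vector from
#'   [evaluateScores()]), `testScores`, `testLabels`, `testIdx`.
#' @export
trainFold <- function(prep, fold, cfg = trainConfig(), initSeed = NULL,
                      optimizeThreshold = "none") {
  idx <- .foldIdx(fold, prep$patientIds)
  old <- .Random.seed_exists()
  set.seed(if (is.null(initSeed)) cfg$seed else initSeed)
  model <- initModel(extractor = tinyExtractor(), k = cfg$kEvidence,
                     dropout = cfg$dropout)
  .restore_seed(old)
  fit <- trainModel(prep$features, prep$labels01, idx$train, idx$val,
                    model, cfg)
  score <- function(i) predictBag(fit$model, prep$features[[i]])$prob
  thr <- 0.5
  if (identical(optimizeThreshold, "youden")) {
    valScores <- vapply(idx$val, score, 0)
    if (length(unique(prep$labels01[idx$val])) == 2L)
      thr <- youdenThreshold(valScores, prep$labels01[idx$val])$threshold
  }
  testScores <- vapply(idx$test, score, 0)
  testLabels <- prep$labels01[idx$test]
  list(model = fit$model, log = fit$log, bestEpoch = fit$bestEpoch,
       metrics = evaluateScores(testScores, testLabels, thr),
       testScores = testScores, testLabels = testLabels, testIdx = idx$test)
}

#' Patient-wise cross-validated training and evaluation
#'
#' Orchestrates [makeFolds()] over the patients, [trainFold()] per fold and
#' [aggregateCV()] over the per-fold test metrics.
#'
#' @inheritParams trainFold
#' @param prep output of [prepareDataset()].
#' @param nFolds number of folds (default 5).
#' @return list: `folds`, `perFold` (list of [trainFold()] results),
#'   `aggregate` ([aggregateCV()] output), `report`
#'   ([formatCVReport()] data.frame).
#' @export
runCrossvalOnPrep <- function(prep, nFolds = 5L, cfg = trainConfig(),
                              optimizeThreshold = "none") {
  labelsByPatient <- prep$labels01
  folds <- makeFolds(prep$patientIds, labelsByPatient, nFolds = nFolds,
                     seed = cfg$seed)
  perFold <- lapply(folds, function(f)
    trainFold(prep, f, cfg, initSeed = cfg$seed + 1000L * f$foldId,
              optimizeThreshold = optimizeThreshold))
  metrics <- do.call(rbind, lapply(perFold, `[[`, "metrics"))
  agg <- aggregateCV(metrics)
  list(folds = folds, perFold = perFold, aggregate = agg,
       report = formatCVReport(agg))
}
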