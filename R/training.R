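#' @include mil.R
NULL

#' Training configuration
#'
#' Defaults follow the reference regime: SGD with momentum 0.9, learning
#' rate 0.001 decayed by a constant factor 0.9 every 10 epochs, weight decay
#' 0.001, batch size 1 with gradient accumulation over 8 samples, at least
#' 20 and at most 100 epochs with 20-epoch early-stopping patience,
#' loss mix 0.7 (bag BCE) / 0.3 (instance CCE), evidence count k = 8,
#' dropout 0.25, seed 42.
#'
#' @param lr,lrGamma,weightDecay,momentum optimiser parameters.
#' @param accumSteps gradient accumulation group size.
#' @param minEpochs,maxEpochs,patience early-stopping schedule.
#' @param lossWeights bag/instance loss mixing weights (sum to 1).
#' @param kEvidence evidence count per cluster.
#' @param dropout attention-module dropout rate.
#' @param seed RNG seed driving sampling, dropout and initialisation.
#' @param valMetric `"loss"` (default) or `"auc"` for model selection.
#' @return named list of training settings.
#' @export
trainConfig <- function(lr = 0.001, lrGamma = 0.9, weightDecay = 0.001,
                        momentum = 0.9, accumSteps = 8L, minEpochs = 20L,
                        maxEpochs = 100L, patience = 20L,
                        lossWeights = c(0.7, 0.3), kEvidence = 8L,
                        dropout = 0.25, seed = 42L, valMetric = "loss") {
  stopifnot(lr > 0, lrGamma > 0, weightDecay >= 0, momentum >= 0,
            accumSteps >= 1, minEpochs >= 1, maxEpochs >= minEpochs,
            patience >= 0, abs(sum(lossWeights) - 1) < 1e-9,
            kEvidence >= 1, dropout >= 0, dropout < 1,
            valMetric %in% c("loss", "auc"))
  list(lr = lr, lrGamma = lrGamma, weightDecay = weightDecay,
       momentum = momentum, batchSize = 1L,
       accumSteps = as.integer(accumSteps),
       minEpochs = as.integer(minEpochs), maxEpochs = as.integer(maxEpochs),
       patience = as.integer(patience), lossWeights = lossWeights,
       kEvidence = as.integer(kEvidence), dropout = dropout,
       seed = as.integer(seed), valMetric = valMetric)
}

#' Patient-wise stratified cross-validation folds
#'
#' Patients are shuffled once per class with the seed and partitioned into
#' `nFolds` near-equal test folds (stratified by class, so per-fold class
#' counts stay balanced); for each fold the remaining patients are split
#' into training and validation at 7:1, giving approximately 70/10/20
#' proportions. All assignment is at patient level — every image of a
#' patient follows the patient — and the test folds are disjoint and cover
#' all patients.
#'
#' @param patientIds character vector of unique patient ids.
#' @param labels per-patient class labels (same length; any two-level
#'   coding).
#' @param nFolds number of folds (default 5).
#' @param seed shuffle seed.
#' @return list of folds; each is `list(foldId, train, val, test)` of
#'   patient-id character vectors.
#' @export
makeFolds <- function(patientIds, labels, nFolds = 5L, seed = 42L) {
  stopifnot(length(patientIds) == length(labels),
            !anyDuplicated(patientIds), nFolds >= 2L)
  if (length(patientIds) < nFolds)
    stop("fewer patients than folds")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  classes <- split(patientIds, labels)
  shuffled <- lapply(classes, sample)
  # round-robin assignment to test folds, per class
  testSets <- vector("list", nFolds)
  for (cl in shuffled) {
    f <- rep(seq_len(nFolds), length.out = length(cl))
    for (i in seq_len(nFolds))
      testSets[[i]] <- c(testSets[[i]], cl[f == i])
  }
  lapply(seq_len(nFolds), function(i) {
    test <- testSets[[i]]
    val <- character()
    train <- character()
    for (cl in shuffled) {
      rest <- setdiff(cl, test)   # keeps the shuffled order
      nVal <- round(length(rest) / 8)
      if (nVal > 0L) {
        val <- c(val, rest[seq_len(nVal)])
        train <- c(train, rest[-seq_len(nVal)])
      } else {
        train <- c(train, rest)
      }
    }
    list(foldId = i, train = train, val = val, test = test)
  })
}

#' Class-balancing oversampling weights
#'
#' Weighted random oversampling: each training case is drawn with
#' probability inversely proportional to its class frequency, so the
#' expected per-class draw mass is 0.5 each.
#'
#' @param labels training-set class labels (two classes required).
#' @return per-sample probabilities summing to 1.
#' @export
samplingWeights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("training set contains a single class")
  w <- 1 / as.numeric(tab[as.character(labels)])
  w / sum(w)
}

#' Learning rate at a given epoch
#'
#' Step decay by the constant factor `lrGamma` every 10 epochs:
#' `lr * lrGamma^floor((epoch - 1) / 10)`.
#'
#' @param epoch epoch number (1-based).
#' @param cfg a [trainConfig()].
#' @return learning rate.
#' @export
lrAtEpoch <- function(epoch, cfg) {
  stopifnot(epoch >= 1)
  cfg$lr * cfg$lrGamma^((epoch - 1) %/% 10)
}

#' Early-stopping rule
#'
#' Training halts after the current epoch iff
#' `epoch >= max(minEpochs, bestEpoch + patience)` or `epoch >= maxEpochs`;
#' it therefore never halts before `minEpochs` and never runs past
#' `maxEpochs`.
#'
#' @param epoch current epoch (completed).
#' @param bestEpoch epoch of the best validation metric so far.
#' @param cfg a [trainConfig()].
#' @return logical.
#' @export
shouldStopEarly <- function(epoch, bestEpoch, cfg) {
  epoch >= cfg$maxEpochs ||
    (epoch >= cfg$minEpochs && epoch >= bestEpoch + cfg$patience)
}

.decayed <- c("Wr", "V", "U", "w", "W1", "W2", "Wi1", "Wi2")

.zeroLike <- function(params) {
  lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
         else numeric(length(x)))
}

#' Train the MIL head
#'
#' SGD with momentum on the combined 0.7 bag-BCE + 0.3 instance-CCE loss,
#' one case per step, gradients averaged over accumulation groups of
#' `accumSteps` draws (the final partial group of an epoch still updates),
#' weight decay on weights but not biases, class-balanced oversampling of
#' training cases, dropout in the attention module, and early stopping on
#' the validation metric. The extractor and the feature-standardisation
#' statistics stay frozen throughout; the returned model carries the
#' parameters of the best validation epoch.
#'
#' @param features list of K x M raw feature matrices, one per case.
#' @param labels01 per-case 0/1 labels (1 = cancer).
#' @param trainIdx,valIdx integer indices into `features`.
#' @param model a [MILModel-class] from [initModel()] (optionally
#'   [transferInit()]-ialised).
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list: `model` (best checkpoint), `log` (data.frame with epoch,
#'   lr, trainLoss, valLoss, valAuc, nUpdates), `bestEpoch`.
#' @export
trainModel <- function(features, labels01, trainIdx, valIdx, model,
                       cfg = trainConfig(), verbose = FALSE) {
  stopifnot(length(trainIdx) >= 1L, length(valIdx) >= 1L,
            all(labels01 %in% c(0, 1)))
  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(.restore_seed(old), add = TRUE)

  model@dims$k <- cfg$kEvidence
  model@dropout <- cfg$dropout
  if (!length(model@featNorm))
    model <- fitFeatureNorm(model, features[trainIdx])

  w <- samplingWeights(labels01[trainIdx])
  vel <- .zeroLike(model@params)
  best <- list(params = model@params, metric = Inf, epoch = 0L)
  log <- list()

  valLossAuc <- function(mod) {
    losses <- numeric(length(valIdx))
    probs <- numeric(length(valIdx))
    for (j in seq_along(valIdx)) {
      i <- valIdx[j]
      fw <- .milForward(mod, features[[i]], y = labels01[i],
                        training = FALSE, lossWeights = cfg$lossWeights)
      losses[j] <- fw$loss
      probs[j] <- fw$prob
    }
    auc <- if (length(unique(labels01[valIdx])) == 2L)
      rocAuc(probs, labels01[valIdx]) else NA_real_
    list(loss = mean(losses), auc = auc)
  }

  for (epoch in seq_len(cfg$maxEpochs)) {
    lr <- lrAtEpoch(epoch, cfg)
    draws <- sample(trainIdx, length(trainIdx), replace = TRUE, prob = w)
    acc <- .zeroLike(model@params)
    nAcc <- 0L
    nUpdates <- 0L
    epochLoss <- 0
    applyUpdate <- function() {
      for (nm in names(model@params)) {
        gmean <- acc[[nm]] / nAcc
        if (nm %in% .decayed)
          gmean <- gmean + cfg$weightDecay * model@params[[nm]]
        vel[[nm]] <<- cfg$momentum * vel[[nm]] + gmean
        model@params[[nm]] <<- model@params[[nm]] - lr * vel[[nm]]
      }
      acc <<- .zeroLike(model@params)
      nAcc <<- 0L
      nUpdates <<- nUpdates + 1L
    }
    for (i in draws) {
      fw <- .milForward(model, features[[i]], y = labels01[i],
                        training = TRUE, lossWeights = cfg$lossWeights)
      if (!is.finite(fw$loss))
        stop(sprintf("non-finite loss at epoch %d (case %d): divergence",
                     epoch, i))
      gr <- .milGradients(model, features[[i]], fw)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
      nAcc <- nAcc + 1L
      epochLoss <- epochLoss + fw$loss
      if (nAcc == cfg$accumSteps) applyUpdate()
    }
    if (nAcc > 0L) applyUpdate()  # remainder group still updates

    val <- valLossAuc(model)
    metric <- if (cfg$valMetric == "loss") val$loss else -val$auc
    improved <- metric < best$metric
    if (improved)
      best <- list(params = model@params, metric = metric, epoch = epoch)
    log[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      trainLoss = epochLoss / length(draws),
      valLoss = val$loss, valAuc = val$auc, nUpdates = nUpdates)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.5f train %.4f val %.4f auc %s%s",
        epoch, lr, epochLoss / length(draws), val$loss,
        ifelse(is.na(val$auc), "NA", sprintf("%.3f", val$auc)),
        if (improved) " *" else ""))
    if (shouldStopEarly(epoch, best$epoch, cfg)) break
  }
  model@params <- best$params
  list(model = model, log = do.call(rbind, log), bestEpoch = best$epoch)
}

#' Initialise a model from a source checkpoint (transfer learning)
#'
#' Copies every learnable parameter (and the frozen feature-normalisation
#' statistics) from an architecture-compatible source model, so training on
#' the target data starts from the knowledge gained on the source domain.
#' Any shape mismatch aborts with the offending parameter name and nothing
#' is partially loaded.
#'
#' @param model target [MILModel-class].
#' @param source source [MILModel-class] (e.g. from [loadCheckpoint()]).
#' @return the target model with source parameters.
#' @export
transferInit <- function(model, source) {
  for (nm in names(model@params)) {
    a <- model@params[[nm]]
    b <- source@params[[nm]]
    if (is.null(b) || !identical(dim(a), dim(b)) ||
        length(a) != length(b))
      stop("incompatible checkpoint: parameter '", nm, "' has a different shape")
  }
  if (model@extractor@name != source@extractor@name)
    stop("incompatible checkpoint: extractor '", source@extractor@name,
         "' does not match '", model@extractor@name, "'")
  model@params <- source@params
  model@featNorm <- source@featNorm
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the named parameter arrays
#' (bit-exact on round trip) plus a JSON sidecar recording the extractor
#' name, the architecture dimensions, the dropout rate and an optional
#' decision threshold.
#'
#' @param model a [MILModel-class].
#' @param path file path without extension; writes `<path>.rds` and
#'   `<path>.json`.
#' @param threshold optional decision threshold to record.
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: the
#'   restored [MILModel-class].
#' @export
saveCheckpoint <- function(model, path, threshold = 0.5) {
  saveRDS(list(params = model@params, dims = model@dims,
               featNorm = model@featNorm, dropout = model@dropout),
          paste0(path, ".rds"))
  jsonlite::write_json(
    list(extractor = model@extractor@name, featureDim = model@dims$M,
         Mprime = model@dims$Mprime, L = model@dims$L, k = model@dims$k,
         dropout = model@dropout, threshold = threshold),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param extractor the [ExtractorSpec-class] to attach (must match the name
#'   recorded in the sidecar).
#' @export
loadCheckpoint <- function(path, extractor = tinyExtractor()) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (meta$extractor != extractor@name)
    stop("checkpoint was trained with extractor '", meta$extractor, "'")
  obj <- readRDS(paste0(path, ".rds"))
  new("MILModel", params = obj$params, dims = obj$dims,
      extractor = extractor, featNorm = obj$featNorm, dropout = obj$dropout)
}
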