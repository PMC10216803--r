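test_that("learning rate decays by a constant factor every ten epochs", {
  cfg <- trainConfig()
  expect_equal(lrAtEpoch(1, cfg), 0.001)
  expect_equal(lrAtEpoch(10, cfg), 0.001)
  expect_equal(lrAtEpoch(11, cfg), 0.0009)
  expect_equal(lrAtEpoch(25, cfg), 0.00081)
})

test_that("fold splits give stratified ~70/10/20 patient proportions", {
  ids <- sprintf("p%03d", 1:789)
  labs <- rep(c("cancer", "non_cancer"), length.out = 789)
  folds <- makeFolds(ids, labs, nFolds = 5, seed = 1)
  sizes <- t(vapply(folds, function(f)
    c(length(f$train), length(f$val), length(f$test)), numeric(3)))
  expect_true(all(abs(sizes[, 3] - 158) <= 1))
  expect_true(all(abs(sizes[, 2] - 79) <= 1))
  expect_true(all(abs(sizes[, 1] - 552) <= 1))
  # stratification: per-fold test class balance close to the global one
  for (f in folds) {
    frac <- mean(labs[match(f$test, ids)] == "cancer")
    expect_lt(abs(frac - 0.5), 0.05)
  }
})

test_that("fold splits are disjoint, exhaustive and patient-atomic", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(12:120, 1)
    ids <- sprintf("q%04d", sample(1e4, n))
    labs <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labs)) < 2) labs[1:2] <- c("a", "b")
    k <- sample(2:5, 1)
    folds <- makeFolds(ids, labs, nFolds = k, seed = i)
    allTest <- unlist(lapply(folds, `[[`, "test"))
    expect_identical(sort(allTest), sort(ids))   # disjoint + covering
    for (f in folds) {
      expect_length(intersect(f$train, f$val), 0)
      expect_length(intersect(f$train, f$test), 0)
      expect_length(intersect(f$val, f$test), 0)
      expect_identical(sort(c(f$train, f$val, f$test)), sort(ids))
    }
  }
  expect_error(makeFolds(c("a", "b"), c("x", "y"), nFolds = 5), "fewer")
})

test_that("fold splitting is reproducible from the seed", {
  ids <- sprintf("p%02d", 1:40)
  labs <- rep(c("c", "n"), 20)
  expect_identical(makeFolds(ids, labs, seed = 7),
                   makeFolds(ids, labs, seed = 7))
  expect_false(identical(makeFolds(ids, labs, seed = 7),
                         makeFolds(ids, labs, seed = 8)))
})

test_that("oversampling weights rebalance the classes to 0.5 each", {
  w <- samplingWeights(rep(c("a", "b"), each = 100))
  expect_true(all(abs(w - 1 / 200) < 1e-12))
  labs <- c(rep("maj", 150), rep("min", 50))
  w2 <- samplingWeights(labs)
  expect_equal(w2[151] / w2[1], 3)
  expect_equal(sum(w2[labs == "maj"]), 0.5)
  expect_equal(sum(w2), 1)
  expect_error(samplingWeights(rep("a", 10)), "single class")
  # empirical class balance over many draws
  set.seed(123)
  draws <- sample(labs, 10000, replace = TRUE, prob = w2)
  expect_lt(abs(mean(draws == "min") - 0.5), 0.02)
})

test_that("early stopping respects the minimum and maximum epoch bounds", {
  cfg <- trainConfig()
  # validation flat from epoch 1: stop exactly at epoch 21, never before 20
  stops <- vapply(1:30, function(e) shouldStopEarly(e, 1L, cfg), TRUE)
  expect_identical(min(which(stops)), 21L)
  # still improving late: run to maxEpochs and no further
  expect_false(shouldStopEarly(99, 95, cfg))
  expect_true(shouldStopEarly(100, 95, cfg))
  # never halts before minEpochs even with patience exhausted
  expect_false(shouldStopEarly(15, 1, cfg))
})

test_that("gradient accumulation updates once per full or partial group", {
  m <- toyModel()
  cfg <- trainConfig(minEpochs = 1L, maxEpochs = 1L, patience = 0L,
                     seed = 2L)
  s16 <- tinyTrainSetup(n = 18)
  fit16 <- trainModel(s16$features[1:16], s16$labels[1:16], 1:14, 15:16,
                      m, cfg)
  expect_identical(fit16$log$nUpdates, as.integer(ceiling(14 / 8)))
  s20 <- tinyTrainSetup(n = 24)
  fit20 <- trainModel(s20$features, s20$labels, 1:20, 21:24, m, cfg)
  expect_identical(fit20$log$nUpdates, 3L)  # 8 + 8 + 4
})

test_that("training is reproducible from the seed", {
  m <- toyModel()
  s <- tinyTrainSetup(n = 14)
  cfg <- trainConfig(minEpochs = 3L, maxEpochs = 3L, patience = 0L,
                     seed = 31L)
  f1 <- trainModel(s$features, s$labels, 1:10, 11:14, m, cfg)
  f2 <- trainModel(s$features, s$labels, 1:10, 11:14, m, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("transfer initialisation copies parameters atomically", {
  src <- toyModel(seed = 1L)
  src@featNorm <- list(mean = rnorm(32), sd = rep(1, 32))
  tgt <- toyModel(seed = 2L)
  moved <- transferInit(tgt, src)
  expect_identical(moved@params, src@params)
  expect_identical(moved@featNorm, src@featNorm)
  # zero epochs of training leaves the transferred model identical
  H2 <- matrix(rnorm(5 * 32), 5, 32)
  expect_identical(predictBag(moved, H2), predictBag(src, H2))
  bad <- toyModel(Mprime = 9L)
  expect_error(transferInit(bad, src), "Wr")
})

test_that("transfer from one phantom domain helps initial validation loss", {
  # paired comparison over 5 seeds: a model transferred from a first phantom
  # domain starts no worse on a second domain than a fresh initialisation
  sA <- tinyTrainSetup(n = 16, seed = 101)
  sB <- tinyTrainSetup(n = 16, seed = 202)
  cfg <- trainConfig(minEpochs = 2L, maxEpochs = 2L, patience = 0L, seed = 1L)
  valLoss <- function(model, s, idx) {
    mean(vapply(idx, function(i) {
      MammoMIL:::.milForward(model, s$features[[i]], y = s$labels[i],
                             training = FALSE)$loss
    }, 0))
  }
  diffs <- vapply(1:5, function(sd) {
    set.seed(sd)
    fresh <- initModel(toyModel()@extractor, Mprime = 8L, L = 4L, k = 2L,
                       hidden = 6L)
    fresh <- fitFeatureNorm(fresh, sB$features[1:12])
    cfgS <- trainConfig(minEpochs = 2L, maxEpochs = 2L, patience = 0L,
                        seed = sd)
    pre <- trainModel(sA$features, sA$labels, 1:12, 13:16, fresh, cfgS)$model
    moved <- transferInit(fresh, pre)
    valLoss(fresh, sB, 13:16) - valLoss(moved, sB, 13:16)
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("checkpoints round-trip bit-exactly with their JSON sidecar", {
  d <- withr::local_tempdir()
  m <- toyModel(seed = 9L)
  m@featNorm <- list(mean = rnorm(32), sd = runif(32, 0.5, 2))
  saveCheckpoint(m, file.path(d, "ck"), threshold = 0.42)
  meta <- jsonlite::read_json(file.path(d, "ck.json"))
  expect_identical(meta$extractor, "toy")
  expect_equal(meta$threshold, 0.42)
  back <- loadCheckpoint(file.path(d, "ck"),
                         extractor = m@extractor)
  expect_identical(back@params, m@params)
  expect_identical(back@featNorm, m@featNorm)
  expect_error(loadCheckpoint(file.path(d, "ck")), "toy")
})
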