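test_that("gated attention reproduces hand-computed scores and weights", {
  prm <- list(V = matrix(1, 1, 1), U = matrix(10, 1, 1), w = 1)
  ga <- gatedAttention(matrix(c(2, 0), 2, 1), prm)
  expect_equal(ga$raw, c(tanh(2) * plogis(20), 0), tolerance = 1e-12)
  expect_equal(ga$a, c(0.7239, 0.2761), tolerance = 1e-4)
})

test_that("attention weights form a probability vector for any bag size", {
  m <- toyModel()
  prm <- m@params
  for (K in c(1L, 2L, 7L, 10000L)) {
    Hp <- matrix(rnorm(K * 8), K, 8)
    a <- gatedAttention(Hp, prm)$a
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-6)
  }
  expect_equal(gatedAttention(matrix(rnorm(8), 1, 8), prm)$a, 1)
  # identical rows -> uniform weights
  Hp <- matrix(rep(rnorm(8), each = 5), 5, 8)
  expect_equal(gatedAttention(Hp, prm)$a, rep(0.2, 5))
})

test_that("softmax attention is invariant to constant raw-score shifts", {
  set.seed(4)
  Hp <- matrix(rnorm(4 * 3), 4, 3)
  prm <- list(V = matrix(rnorm(6), 2, 3), U = matrix(rnorm(6), 2, 3),
              w = rnorm(2))
  ga <- gatedAttention(Hp, prm)
  shifted <- exp(ga$raw + 5) / sum(exp(ga$raw + 5))
  expect_equal(ga$a, shifted, tolerance = 1e-12)
})

test_that("gated attention matches a scalar-loop oracle on random instances", {
  set.seed(10)
  for (i in 1:60) {
    K <- sample(1:5, 1)
    L <- sample(1:4, 1)
    Mp <- sample(1:4, 1)
    Hp <- matrix(rnorm(K * Mp), K, Mp)
    prm <- list(V = matrix(rnorm(L * Mp), L, Mp),
                U = matrix(rnorm(L * Mp), L, Mp), w = rnorm(L))
    got <- gatedAttention(Hp, prm)
    want <- oracleGatedAttention(Hp, prm$V, prm$U, prm$w)
    expect_equal(got$raw, want$raw, tolerance = 1e-6)
    expect_equal(got$a, want$a, tolerance = 1e-6)
  }
})

test_that("bag pooling is the attention-weighted feature average", {
  Hp <- rbind(c(3, 0, 0), c(0, 3, 0))
  expect_equal(poolBag(c(2 / 3, 1 / 3), Hp), c(2, 1, 0))
  expect_equal(poolBag(c(0, 1), Hp), c(0, 3, 0))       # one-hot selection
  expect_equal(poolBag(c(0.5, 0.5), Hp), colMeans(Hp)) # uniform average
  expect_error(poolBag(c(1, 0, 0), Hp), "mismatch")
  # permutation invariance and convex hull membership
  set.seed(6)
  H5 <- matrix(rnorm(5 * 4), 5, 4)
  a <- MammoMIL:::.softmax(rnorm(5))
  B <- poolBag(a, H5)
  p <- sample(5)
  expect_equal(poolBag(a[p], H5[p, ]), B, tolerance = 1e-12)
  expect_true(all(B >= apply(H5, 2, min) - 1e-12 &
                  B <= apply(H5, 2, max) + 1e-12))
})

test_that("feature reduction is rectified with the declared output width", {
  m <- toyModel()
  H <- matrix(rnorm(3 * 32), 3, 32)
  Hp <- reduceFeatures(H, m)
  expect_identical(dim(Hp), c(3L, 8L))
  expect_true(all(Hp >= 0))
  expect_identical(dim(reduceFeatures(matrix(rnorm(32), 1, 32), m)),
                   c(1L, 8L))
  mz <- m
  mz@params$Wr[] <- 0
  mz@params$br[] <- 0
  expect_true(all(reduceFeatures(H, mz) == 0))
  expect_error(reduceFeatures(matrix(0, 2, 5), m), "dimension")
})

test_that("the bag classifier outputs sigmoid probabilities", {
  m <- toyModel()
  mz <- m
  mz@params$W2[] <- 0
  mz@params$b2 <- 0
  expect_equal(classifyBag(rnorm(8), mz), 0.5)
  p <- classifyBag(rnorm(8), m)
  expect_true(p > 0 && p < 1)
})

test_that("evidence selection partitions top and bottom attention", {
  a16 <- runif(16)
  ev <- selectEvidence(a16, 8)
  expect_identical(ev$kEff, 8L)
  expect_identical(sort(c(ev$positive, ev$negative)), 1:16)
  expect_identical(ev$pseudoLabels, c(rep(1L, 8), rep(0L, 8)))
  ev10 <- selectEvidence(runif(10), 8)
  expect_identical(ev10$kEff, 5L)
  expect_length(intersect(ev10$positive, ev10$negative), 0)
  ev1 <- selectEvidence(c(0.9, 0.8, 0.1, 0.05), 1)
  expect_identical(ev1$positive, 1L)
  expect_identical(ev1$negative, 4L)
  # ties break toward the lower patch index
  evT <- selectEvidence(c(0.5, 0.5, 0.5, 0.5), 1)
  expect_identical(evT$positive, 1L)
  expect_identical(evT$negative, 2L)  # disjoint even under full ties
  expect_error(selectEvidence(0.5, 1), "at least 2")
})

test_that("instance loss is the mean categorical cross-entropy", {
  perfect <- rbind(c(0, 1), c(1, 0))
  expect_equal(instanceLoss(perfect, c(1, 0)), 0, tolerance = 1e-9)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(instanceLoss(uniform, c(1, 1, 0, 0)), log(2))
  two <- rbind(c(0.1, 0.9), c(0.2, 0.8))
  expect_equal(instanceLoss(two, c(1, 1)), -(log(0.9) + log(0.8)) / 2)
  expect_error(instanceLoss(matrix(0, 0, 2), integer()), "empty")
})

test_that("the combined loss mixes bag and instance terms 0.7 / 0.3", {
  expect_equal(totalLoss(1, 0), 0.7)
  expect_equal(totalLoss(0, 1), 0.3)
  expect_equal(totalLoss(0.5, 0.2), 0.41)
  expect_error(totalLoss(-1, 0), "non-negative")
})

test_that("analytic gradients match finite differences", {
  m <- toyModel(Mprime = 6L, L = 3L, k = 2L, hidden = 5L, M = 7L)
  set.seed(21)
  H <- matrix(rnorm(9 * 7), 9, 7)
  for (y in c(0, 1)) {
    fw <- MammoMIL:::.milForward(m, H, y = y, training = FALSE)
    gr <- MammoMIL:::.milGradients(m, H, fw)
    eps <- 1e-6
    for (nm in names(m@params)) {
      picks <- sample(length(m@params[[nm]]),
                      min(6, length(m@params[[nm]])))
      for (j in picks) {
        m2 <- m
        m2@params[[nm]][j] <- m@params[[nm]][j] + eps
        lp <- MammoMIL:::.milForward(m2, H, y = y, training = FALSE)$loss
        m2@params[[nm]][j] <- m@params[[nm]][j] - eps
        lm <- MammoMIL:::.milForward(m2, H, y = y, training = FALSE)$loss
        expect_equal(gr[[nm]][j], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("the inference forward pass is deterministic, dropout is not", {
  m <- toyModel(seed = 3L)
  H <- matrix(rnorm(6 * 32), 6, 32)
  p1 <- predictBag(m, H)
  p2 <- predictBag(m, H)
  expect_identical(p1, p2)
  md <- m
  md@dropout <- 0.5
  set.seed(1)
  f1 <- MammoMIL:::.milForward(md, H, y = 1, training = TRUE)
  set.seed(1)
  f2 <- MammoMIL:::.milForward(md, H, y = 1, training = TRUE)
  expect_identical(f1$loss, f2$loss)
  set.seed(2)
  f3 <- MammoMIL:::.milForward(md, H, y = 1, training = TRUE)
  expect_false(identical(f1$loss, f3$loss))
})

test_that("feature standardisation is fitted once and then frozen", {
  m <- toyModel()
  feats <- replicate(4, matrix(rnorm(5 * 32, mean = 3), 5, 32),
                     simplify = FALSE)
  mf <- fitFeatureNorm(m, feats)
  expect_length(mf@featNorm$mean, 32L)
  X <- do.call(rbind, feats)
  expect_equal(mf@featNorm$mean, colMeans(X))
  # training leaves the statistics untouched
  s <- tinyTrainSetup(n = 8)
  cfg <- trainConfig(minEpochs = 1L, maxEpochs = 1L, patience = 0L,
                     seed = 1L)
  fit <- trainModel(s$features, s$labels, 1:6, 7:8, mf, cfg)
  expect_identical(fit$model@featNorm, mf@featNorm)
})

test_that("identical patch content yields identical feature rows", {
  spec <- tinyExtractor()
  p <- matrix(runif(32 * 32), 32, 32)
  bag <- new("MammoBag", patches = list(p, p),
             coords = cbind(row0 = c(0L, 0L), col0 = c(0L, 32L)),
             patchSize = 32L, overlap = 0, label = "cancer",
             sourceShape = c(32L, 64L), patientId = "p")
  H <- extractFeatures(bag, spec)
  expect_identical(dim(H), c(2L, 32L))
  expect_identical(H[1, ], H[2, ])
  # extraction is stable across calls (frozen weights)
  expect_identical(extractFeatures(bag, spec), H)
})
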