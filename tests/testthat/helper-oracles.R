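# Independent brute-force oracles used by unit and acceptance tests.
# Each re-derives its quantity with plain scalar loops, never through the
# package's vectorised implementations.

oracleGatedAttention <- function(Hp, V, U, w) {
  K <- nrow(Hp)
  L <- length(w)
  raw <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (l in seq_len(L)) {
      va <- 0
      ua <- 0
      for (j in seq_len(ncol(Hp))) {
        va <- va + V[l, j] * Hp[k, j]
        ua <- ua + U[l, j] * Hp[k, j]
      }
      s <- s + w[l] * tanh(va) * (1 / (1 + exp(-ua)))
    }
    raw[k] <- s
  }
  e <- exp(raw)
  list(raw = raw, a = e / sum(e))
}

oraclePool <- function(a, Hp) {
  B <- numeric(ncol(Hp))
  for (j in seq_len(ncol(Hp)))
    for (k in seq_len(nrow(Hp)))
      B[j] <- B[j] + a[k] * Hp[k, j]
  B
}

oracleMetrics <- function(TP, TN, FP, FN) {
  c(accuracy = if (TP + TN + FP + FN == 0) 0 else
      (TP + TN) / (TP + TN + FP + FN),
    precision = if (TP + FP == 0) 0 else TP / (TP + FP),
    recall = if (TP + FN == 0) 0 else TP / (TP + FN),
    f1 = if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN))
}

oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracleYouden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  bestJ <- -Inf
  bestT <- NA
  for (t in cand) {
    sens <- sum(scores > t & labels == 1) / n1
    spec <- sum(scores <= t & labels == 0) / n0
    J <- sens + spec - 1
    if (J > bestJ + 1e-9) {
      bestJ <- J
      bestT <- t
    }
  }
  list(threshold = bestT, J = bestJ)
}

oracleTileGrid <- function(rows, cols, P, overlap) {
  stride <- max(1, floor((1 - overlap) * P + 0.5))
  out <- NULL
  for (r in 0:rows) {
    if (r %% stride != 0 || r + P > rows) next
    for (cl in 0:cols) {
      if (cl %% stride != 0 || cl + P > cols) next
      out <- rbind(out, c(r, cl))
    }
  }
  out
}

oracleHeatmap <- function(coords, P, a, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cov <- matrix(0, shape[1], shape[2])
  for (k in seq_len(nrow(coords))) {
    for (r in (coords[k, 1] + 1):(coords[k, 1] + P)) {
      for (cl in (coords[k, 2] + 1):(coords[k, 2] + P)) {
        acc[r, cl] <- acc[r, cl] + a[k]
        cov[r, cl] <- cov[r, cl] + 1
      }
    }
  }
  for (r in seq_len(shape[1]))
    for (cl in seq_len(shape[2]))
      if (cov[r, cl] > 0) acc[r, cl] <- acc[r, cl] / cov[r, cl]
  v <- acc[cov > 0]
  if (max(v) > min(v)) {
    acc[cov > 0] <- (v - min(v)) / (max(v) - min(v))
  } else {
    acc[cov > 0] <- 1
  }
  list(values = acc, coverage = cov)
}

# Small fixture helpers -------------------------------------------------

makeMammogram <- function(px, patientId = "p1", laterality = "left",
                          view = "CC", label = "non_cancer",
                          bitDepth = 12L, pixelSpacing = 0.085) {
  Mammogram(px, bitDepth = bitDepth, patientId = patientId,
            laterality = laterality, view = view, label = label,
            pixelSpacing = pixelSpacing, scaled = TRUE)
}

makeBag <- function(coords, P, shape, label = "cancer", value = 0.5) {
  patches <- lapply(seq_len(nrow(coords)),
                    function(i) matrix(value, P, P))
  co <- coords
  storage.mode(co) <- "integer"
  colnames(co) <- c("row0", "col0")
  new("MammoBag", patches = patches, coords = co, patchSize = as.integer(P),
      overlap = 0, label = label,
      sourceShape = as.integer(shape), patientId = "p1")
}

tinyTrainSetup <- function(n = 12L, seed = 5L) {
  # small feature-space-only training fixture: class-separated Gaussians
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  features <- lapply(seq_len(n), function(i) {
    K <- sample(4:7, 1)
    matrix(rnorm(K * 32, mean = ifelse(labels[i] == 1, 0.5, 0)), K, 32)
  })
  list(features = features, labels = labels)
}

toyModel <- function(Mprime = 8L, L = 4L, k = 2L, dropout = 0,
                     hidden = 6L, M = 32L, seed = 11L) {
  ex <- new("ExtractorSpec", name = "toy", featureDim = as.integer(M),
            frozenNormStats = TRUE, fun = function(x) numeric(M))
  set.seed(seed)
  initModel(ex, Mprime = Mprime, L = L, k = k, dropout = dropout,
            hidden = hidden)
}
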