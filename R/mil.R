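#' @include AllClasses.R extractor.R
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Initialise the attention MIL model
#'
#' Creates the learnable head on top of a frozen extractor: an M -> Mprime
#' fully connected reduction with ReLU, the gated attention parameters
#' (V, U in R^(L x Mprime), w in R^L), a bag classifier with one 256-neuron
#' hidden layer and sigmoid output, and a two-class instance classifier with
#' one 256-neuron hidden layer. Weights are Glorot-initialised from the
#' current RNG stream; biases start at zero.
#'
#' @param extractor an [ExtractorSpec-class] (default [tinyExtractor()]).
#' @param Mprime reduced feature dimension (default 256).
#' @param L attention hidden dimension (default 256).
#' @param k evidence count per cluster for the clustering constraint
#'   (default 8).
#' @param dropout dropout rate in the attention module during training
#'   (default 0.25).
#' @param hidden hidden width of the bag and instance classifiers (256).
#' @return a [MILModel-class].
#' @export
initModel <- function(extractor = tinyExtractor(), Mprime = 256L, L = 256L,
                      k = 8L, dropout = 0.25, hidden = 256L) {
  M <- extractor@featureDim
  gl <- function(nin, nout) {
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)),
           nin, nout)
  }
  params <- list(
    Wr = gl(M, Mprime), br = numeric(Mprime),
    V = gl(L, Mprime), U = gl(L, Mprime), w = as.numeric(gl(L, 1L)),
    W1 = gl(Mprime, hidden), b1 = numeric(hidden),
    W2 = as.numeric(gl(hidden, 1L)), b2 = 0,
    Wi1 = gl(Mprime, hidden), bi1 = numeric(hidden),
    Wi2 = gl(hidden, 2L), bi2 = numeric(2L)
  )
  new("MILModel", params = params,
      dims = list(M = M, Mprime = as.integer(Mprime), L = as.integer(L),
                  k = as.integer(k), hidden = as.integer(hidden)),
      extractor = extractor, featNorm = list(), dropout = dropout)
}

#' Fit the frozen feature-standardisation statistics
#'
#' Computes per-dimension mean and standard deviation over the rows of the
#' supplied (training) feature matrices and stores them in the model. Like a
#' pretrained backbone's normalisation statistics, they are fitted once and
#' frozen: training never updates them and evaluation reuses them.
#'
#' @param model a [MILModel-class].
#' @param featureList list of K x M feature matrices.
#' @return the model with `featNorm` set.
#' @export
fitFeatureNorm <- function(model, featureList) {
  X <- do.call(rbind, featureList)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  model@featNorm <- list(mean = mu, sd = sd)
  model
}

.normFeatures <- function(model, H) {
  if (!length(model@featNorm)) return(H)
  sweep(sweep(H, 2L, model@featNorm$mean, "-"), 2L, model@featNorm$sd, "/")
}

#' Reduce extractor features to the attention feature space
#'
#' One fully connected layer with ReLU mapping M-dimensional extractor
#' features to Mprime (256) dimensions; all outputs are non-negative.
#'
#' @param H K x M feature matrix.
#' @param model a [MILModel-class].
#' @return K x Mprime matrix.
#' @export
reduceFeatures <- function(H, model) {
  if (ncol(H) != model@dims$M)
    stop(sprintf("feature dimension %d does not match extractor dim %d",
                 ncol(H), model@dims$M))
  Hn <- .normFeatures(model, H)
  pmax(sweep(Hn %*% model@params$Wr, 2L, model@params$br, "+"), 0)
}

#' Gated attention scores over a bag
#'
#' For each patch k with reduced features h_k, the raw score is
#' `w' (tanh(V h_k) * sigmoid(U h_k))` (element-wise product of the tanh and
#' sigmoid branches), and the attention weights are the softmax of the raw
#' scores over all K patches, so they are non-negative and sum to one
#' regardless of bag size.
#'
#' @param Hp K x Mprime reduced feature matrix.
#' @param params list with `V`, `U` (L x Mprime) and `w` (length L), e.g.
#'   `model@params`.
#' @return list with `a` (length-K attention weights) and `raw` (pre-softmax
#'   scores).
#' @export
gatedAttention <- function(Hp, params) {
  stopifnot(nrow(Hp) >= 1L)
  A <- Hp %*% t(params$V)
  Bq <- Hp %*% t(params$U)
  m <- tanh(A) * .sigmoid(Bq)
  raw <- as.numeric(m %*% params$w)
  if (any(!is.finite(raw)))
    stop("non-finite attention score at patch ", which(!is.finite(raw))[1L])
  list(a = .softmax(raw), raw = raw)
}

#' Attention-weighted bag pooling
#'
#' `B = sum_k a_k h_k`: the bag embedding is the attention-weighted average
#' of the reduced patch features, hence lies in their convex hull and is
#' invariant to any joint permutation of patches and weights.
#'
#' @param a length-K attention weights (summing to 1).
#' @param Hp K x Mprime reduced features.
#' @return length-Mprime bag embedding.
#' @export
poolBag <- function(a, Hp) {
  if (length(a) != nrow(Hp)) stop("attention/feature length mismatch")
  as.numeric(crossprod(Hp, a))
}

#' Bag probability from the bag embedding
#'
#' One 256-neuron ReLU hidden layer followed by a single sigmoid output
#' neuron; scores above 0.5 are predicted cancer by default.
#'
#' @param B bag embedding (length Mprime).
#' @param model a [MILModel-class].
#' @return probability in (0, 1).
#' @export
classifyBag <- function(B, model) {
  p <- model@params
  g1 <- pmax(as.numeric(B %*% p$W1) + p$b1, 0)
  .sigmoid(sum(g1 * p$W2) + p$b2)
}

#' Select positive and negative evidence instances
#'
#' Sorts the attention scores and takes the `k_eff = min(k, floor(K/2))`
#' highest-attended patches as the positive-evidence cluster (pseudo label 1)
#' and the `k_eff` lowest as the negative-evidence cluster (pseudo label 0).
#' The two sets are disjoint; ties break toward the lower patch index.
#'
#' @param a length-K attention weights (or raw scores; only order matters).
#' @param k requested evidence count (default 8).
#' @return list with `positive`, `negative` (1-based index vectors),
#'   `pseudoLabels` (1s then 0s) and `kEff`.
#' @export
selectEvidence <- function(a, k = 8L) {
  K <- length(a)
  if (K < 2L) stop("evidence selection needs at least 2 patches")
  kEff <- min(as.integer(k), K %/% 2L)
  ordDesc <- order(-a, seq_len(K))
  ordAsc <- order(a, seq_len(K))
  pos <- ordDesc[seq_len(kEff)]
  # disjointness takes precedence over the low-index tie rule when a tie
  # group spans both ends (possible only with heavily tied scores)
  neg <- setdiff(ordAsc, pos)[seq_len(kEff)]
  list(positive = pos, negative = neg,
       pseudoLabels = c(rep(1L, kEff), rep(0L, kEff)), kEff = kEff)
}

#' Instance-classifier class probabilities
#'
#' @param Hsel n x Mprime reduced features of the selected evidence patches.
#' @param model a [MILModel-class].
#' @return n x 2 matrix of class probabilities (column 2 = positive).
#' @export
instanceProbs <- function(Hsel, model) {
  p <- model@params
  z <- pmax(sweep(Hsel %*% p$Wi1, 2L, p$bi1, "+"), 0)
  logits <- sweep(z %*% p$Wi2, 2L, p$bi2, "+")
  t(apply(logits, 1L, .softmax))
}

#' Mean categorical cross-entropy of evidence instances
#'
#' @param probs n x 2 matrix of predicted class probabilities.
#' @param pseudoLabels length-n 0/1 pseudo-cluster labels.
#' @return non-negative mean cross-entropy.
#' @export
instanceLoss <- function(probs, pseudoLabels) {
  if (length(pseudoLabels) == 0L) stop("empty evidence set")
  stopifnot(nrow(probs) == length(pseudoLabels))
  p <- probs[cbind(seq_len(nrow(probs)), pseudoLabels + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Combined training loss
#'
#' `0.7 * bag binary cross-entropy + 0.3 * instance categorical
#' cross-entropy`.
#'
#' @param bagBce bag-level BCE (non-negative).
#' @param instanceCce instance-level CCE (non-negative).
#' @param weights the two mixing weights (default `c(0.7, 0.3)`).
#' @return weighted loss.
#' @export
totalLoss <- function(bagBce, instanceCce, weights = c(0.7, 0.3)) {
  if (bagBce < 0 || instanceCce < 0) stop("losses must be non-negative")
  weights[1L] * bagBce + weights[2L] * instanceCce
}

# Full forward pass on raw features H for one bag.
# y in {0,1}; training toggles dropout (masks drawn from the current RNG
# stream). Returns every intermediate needed for the backward pass.
.milForward <- function(model, H, y = NULL, training = FALSE,
                        lossWeights = c(0.7, 0.3)) {
  p <- model@params
  K <- nrow(H)
  keep <- 1 - if (training) model@dropout else 0
  Hn <- .normFeatures(model, H)
  Zr <- sweep(Hn %*% p$Wr, 2L, p$br, "+")
  R0 <- pmax(Zr, 0)
  Mr <- if (training && keep < 1)
    matrix(stats::runif(length(R0)) < keep, nrow(R0), ncol(R0)) else NULL
  Hp <- if (is.null(Mr)) R0 else R0 * Mr / keep
  A <- Hp %*% t(p$V)
  Tt <- tanh(A)
  Mt <- if (training && keep < 1)
    matrix(stats::runif(length(Tt)) < keep, nrow(Tt), ncol(Tt)) else NULL
  Td <- if (is.null(Mt)) Tt else Tt * Mt / keep
  Bq <- Hp %*% t(p$U)
  S <- .sigmoid(Bq)
  Ms <- if (training && keep < 1)
    matrix(stats::runif(length(S)) < keep, nrow(S), ncol(S)) else NULL
  Sd <- if (is.null(Ms)) S else S * Ms / keep
  m <- Td * Sd
  raw <- as.numeric(m %*% p$w)
  a <- .softmax(raw)
  B <- as.numeric(crossprod(Hp, a))
  z1 <- as.numeric(B %*% p$W1) + p$b1
  g1 <- pmax(z1, 0)
  logit <- sum(g1 * p$W2) + p$b2
  prob <- .sigmoid(logit)
  out <- list(K = K, keep = keep, Hn = Hn, Zr = Zr, Mr = Mr, Hp = Hp,
              Tt = Tt, Mt = Mt, Td = Td, S = S, Ms = Ms, Sd = Sd,
              raw = raw, a = a, B = B, z1 = z1, g1 = g1, prob = prob,
              lossWeights = lossWeights)
  if (!is.null(y)) {
    pc <- min(max(prob, 1e-12), 1 - 1e-12)
    out$bagLoss <- -(y * log(pc) + (1 - y) * log(1 - pc))
    if (K >= 2L) {
      ev <- selectEvidence(a, model@dims$k)
      sel <- c(ev$positive, ev$negative)
      Hsel <- Hp[sel, , drop = FALSE]
      zi <- sweep(Hsel %*% p$Wi1, 2L, p$bi1, "+")
      gi <- pmax(zi, 0)
      logits <- sweep(gi %*% p$Wi2, 2L, p$bi2, "+")
      shift <- logits - apply(logits, 1L, max)
      lse <- log(rowSums(exp(shift)))
      logq <- shift - lse
      q <- exp(logq)
      lab <- ev$pseudoLabels
      out$ev <- ev
      out$sel <- sel
      out$zi <- zi
      out$gi <- gi
      out$q <- q
      out$instLoss <- mean(-logq[cbind(seq_along(sel), lab + 1L)])
    } else {
      out$instLoss <- 0
    }
    out$loss <- lossWeights[1L] * out$bagLoss + lossWeights[2L] * out$instLoss
    out$y <- y
  }
  out
}

# Analytic gradients of the combined loss for one bag (evidence selection is
# treated as non-differentiable, as in the reference CLAM formulation).
.milGradients <- function(model, H, fw) {
  p <- model@params
  K <- fw$K
  keep <- fw$keep
  lw <- fw$lossWeights
  g <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
              else numeric(length(x)))

  # bag classifier
  dlogit <- lw[1L] * (fw$prob - fw$y)
  g$W2 <- fw$g1 * dlogit
  g$b2 <- dlogit
  dg1 <- dlogit * p$W2
  dz1 <- dg1 * (fw$z1 > 0)
  g$W1 <- outer(fw$B, dz1)
  g$b1 <- dz1
  dB <- as.numeric(p$W1 %*% dz1)

  # pooling: B = Hp' a
  dHp <- outer(fw$a, dB)
  da <- as.numeric(fw$Hp %*% dB)

  # softmax
  draw <- fw$a * (da - sum(fw$a * da))

  # raw = (Td * Sd) w
  m <- fw$Td * fw$Sd
  g$w <- as.numeric(crossprod(m, draw))
  dm <- outer(draw, p$w)
  dTd <- dm * fw$Sd
  dSd <- dm * fw$Td
  dT <- if (is.null(fw$Mt)) dTd else dTd * fw$Mt / keep
  dS <- if (is.null(fw$Ms)) dSd else dSd * fw$Ms / keep
  dA <- dT * (1 - fw$Tt^2)
  dBq <- dS * fw$S * (1 - fw$S)
  g$V <- crossprod(dA, fw$Hp)
  g$U <- crossprod(dBq, fw$Hp)
  dHp <- dHp + dA %*% p$V + dBq %*% p$U

  # instance branch
  if (!is.null(fw$ev)) {
    n <- length(fw$sel)
    onehot <- matrix(0, n, 2L)
    onehot[cbind(seq_len(n), fw$ev$pseudoLabels + 1L)] <- 1
    dlogits <- lw[2L] * (fw$q - onehot) / n
    g$Wi2 <- crossprod(fw$gi, dlogits)
    g$bi2 <- colSums(dlogits)
    dgi <- dlogits %*% t(p$Wi2)
    dzi <- dgi * (fw$zi > 0)
    Hsel <- fw$Hp[fw$sel, , drop = FALSE]
    g$Wi1 <- crossprod(Hsel, dzi)
    g$bi1 <- colSums(dzi)
    dHsel <- dzi %*% t(p$Wi1)
    dHp[fw$sel, ] <- dHp[fw$sel, , drop = FALSE] + dHsel
  }

  # dropout on reduction output, then ReLU, then the reduction layer
  dR0 <- if (is.null(fw$Mr)) dHp else dHp * fw$Mr / keep
  dZr <- dR0 * (fw$Zr > 0)
  g$Wr <- crossprod(fw$Hn, dZr)
  g$br <- colSums(dZr)
  g
}

#' Predict the bag probability from raw features
#'
#' Inference-mode forward pass (dropout disabled, frozen normalisation).
#'
#' @param model a [MILModel-class].
#' @param H K x M raw feature matrix for one bag.
#' @return list with `prob` (bag probability) and `attention` (length-K
#'   weights).
#' @export
predictBag <- function(model, H) {
  fw <- .milForward(model, H, training = FALSE)
  list(prob = fw$prob, attention = fw$a)
}
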