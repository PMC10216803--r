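#' @include AllClasses.R
NULL

# im2col for a single-channel matrix and k x k kernels (valid convolution):
# returns (oh*ow) x (k*k) with output positions in column-major order.
.im2col <- function(x, k) {
  H <- nrow(x)
  W <- ncol(x)
  oh <- H - k + 1L
  ow <- W - k + 1L
  idx0 <- rep(seq_len(oh), times = ow) + (rep(seq_len(ow), each = oh) - 1L) * H
  out <- matrix(0, oh * ow, k * k)
  j <- 0L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      j <- j + 1L
      out[, j] <- x[idx0 + dr + dc * H]
    }
  }
  out
}

# Non-overlapping s x s max pooling of channel maps stored as
# (oh*ow) x C (column-major positions). Returns list(maps, oh, ow).
.maxPool <- function(maps, oh, ow, s) {
  ph <- oh %/% s
  pw <- ow %/% s
  C <- ncol(maps)
  pooled <- matrix(-Inf, ph * pw, C)
  for (dc in 0:(s - 1L)) {
    for (dr in 0:(s - 1L)) {
      ri <- rep(seq.int(1L + dr, s * ph, by = s), times = pw)
      ci <- rep(seq.int(1L + dc, s * pw, by = s), each = ph)
      pooled <- pmax(pooled, maps[ri + (ci - 1L) * oh, , drop = FALSE])
    }
  }
  list(maps = pooled, oh = ph, ow = pw)
}

# Fixed extractor weights, a pure function of an internal constant seed so
# every session sees the same "pretrained" backbone.
.tinyWeights <- function() {
  old <- .Random.seed_exists()
  set.seed(192837L)
  on.exit(.restore_seed(old), add = TRUE)
  W1 <- matrix(stats::rnorm(9 * 8, sd = sqrt(2 / 9)), 9, 8)
  W1[, 1L] <- 1 / 9  # box-mean filter: a plain local-intensity channel
  W2 <- matrix(stats::rnorm((9 * 8) * 16, sd = sqrt(2 / (9 * 8))), 9 * 8, 16)
  list(W1 = W1, W2 = W2)
}

.tinyCache <- new.env(parent = emptyenv())

# Forward pass of the tiny frozen CNN on one grayscale patch matrix.
.tinyForward <- function(px) {
  if (is.null(.tinyCache$w)) .tinyCache$w <- .tinyWeights()
  w <- .tinyCache$w
  # stage 1: 3x3 conv, 8 filters, ReLU, 4x4 max pool
  c1 <- pmax(.im2col(px, 3L) %*% w$W1, 0)
  p1 <- .maxPool(c1, nrow(px) - 2L, ncol(px) - 2L, 4L)
  # stage 2: 3x3 conv over 8 channels, 16 filters, ReLU
  cols <- do.call(cbind, lapply(seq_len(8L), function(ch)
    .im2col(matrix(p1$maps[, ch], p1$oh, p1$ow), 3L)))
  # reorder so kernel taps of one channel are contiguous per W2 layout
  c2 <- pmax(cols %*% w$W2, 0)
  # global mean + max pooling per channel -> 32 features
  c(colMeans(c2), apply(c2, 2L, max))
}

#' The built-in tiny frozen feature extractor (feature_dim 32)
#'
#' A two-stage convolutional extractor with fixed weights: 3 x 3 convolution
#' with 8 filters (the first a box-mean filter, so one channel tracks plain
#' local intensity), ReLU, 4 x 4 max pooling, then a second 3 x 3 convolution
#' with 16 filters and ReLU, followed by global mean and max pooling per
#' channel (16 + 16 = 32 features). Weights are drawn once from an internal
#' fixed seed and never trained, standing in for a pretrained backbone with
#' frozen normalisation statistics; the same patch content always yields the
#' same features. Patches must be at least 23 px so both stages fit.
#'
#' @return an [ExtractorSpec-class] with `featureDim` 32.
#' @export
tinyExtractor <- function() {
  new("ExtractorSpec", name = "tiny32", featureDim = 32L,
      frozenNormStats = TRUE,
      fun = function(patch) {
        px <- if (length(dim(patch)) == 3L) {
          # channels are replicated grayscale; average them back
          (patch[, , 1L] + patch[, , 2L] + patch[, , 3L]) / 3
        } else patch
        if (nrow(px) < 23L || ncol(px) < 23L)
          stop("tiny32 extractor needs patches of at least 23 px")
        .tinyForward(px)
      })
}

#' Extract per-patch features for a bag
#'
#' Runs the (frozen, shared-weight) extractor on every patch after 3-channel
#' expansion and stacks the K feature rows into a K x M matrix. Identical
#' patch content yields identical rows.
#'
#' @param bag a [MammoBag-class].
#' @param spec an [ExtractorSpec-class] (default [tinyExtractor()]).
#' @param augment optional [augmentationPolicy()]; when supplied (training
#'   only) each patch is augmented before extraction using the current RNG
#'   stream.
#' @return K x M numeric feature matrix.
#' @export
extractFeatures <- function(bag, spec = tinyExtractor(), augment = NULL) {
  stopifnot(is(bag, "MammoBag"), is(spec, "ExtractorSpec"))
  K <- nPatches(bag)
  H <- matrix(0, K, spec@featureDim)
  for (k in seq_len(K)) {
    p <- bag@patches[[k]]
    if (!is.null(augment)) p <- augmentInstance(p, augment, training = TRUE)
    f <- spec@fun(expandChannels(p))
    if (length(f) != spec@featureDim)
      stop(sprintf("extractor '%s' returned %d features, declared %d",
                   spec@name, length(f), spec@featureDim))
    H[k, ] <- f
  }
  H
}
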