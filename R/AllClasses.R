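#' @import methods
NULL

.LATERALITIES <- c("left", "right")
.VIEWS <- c("CC", "MLO")
.LABELS <- c("non_cancer", "cancer")

#' Mammogram: a single-view grayscale mammographic image
#'
#' Container for one view (CC or MLO) of one breast, with pixel intensities
#' linearly scaled to \[0, 1\] from the acquisition bit depth, plus the
#' acquisition metadata needed downstream (pixel spacing for physical patch
#' size, laterality/view for pairing, image-level label for weak supervision).
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\] (rows x cols).
#' @slot patientId character scalar, opaque patient identifier.
#' @slot laterality `"left"` or `"right"`.
#' @slot view `"CC"` (craniocaudal) or `"MLO"` (mediolateral oblique).
#' @slot pixelSpacing positive numeric, millimetres per pixel.
#' @slot bitDepth integer, 8 or 12 (full-scale raw value is 2^bitDepth - 1).
#' @slot label `"cancer"` or `"non_cancer"` (image-level label).
#' @export
setClass("Mammogram",
  representation(
    pixels = "matrix",
    patientId = "character",
    laterality = "character",
    view = "character",
    pixelSpacing = "numeric",
    bitDepth = "integer",
    label = "character"
  )
)

setValidity("Mammogram", function(object) {
  p <- object@pixels
  msg <- character()
  if (!is.numeric(p) || length(dim(p)) != 2L)
    msg <- c(msg, "pixels must be a 2-D numeric matrix")
  else if (anyNA(p) || min(p) < 0 || max(p) > 1)
    msg <- c(msg, "all pixels must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 12L))
    msg <- c(msg, "bitDepth must be 8 or 12")
  if (!object@laterality %in% .LATERALITIES)
    msg <- c(msg, "laterality must be 'left' or 'right'")
  if (!object@view %in% .VIEWS)
    msg <- c(msg, "view must be 'CC' or 'MLO'")
  if (!object@label %in% .LABELS)
    msg <- c(msg, "label must be 'cancer' or 'non_cancer'")
  if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' MultimodalImage: vertically concatenated CC + MLO views
#'
#' The multimodal input formed by row-stacking the CC view on top of the MLO
#' view of the same breast, so that a single bag of patches spans both
#' projections.
#'
#' @slot pixels numeric matrix in \[0, 1\].
#' @slot patientId character scalar.
#' @slot laterality `"left"` or `"right"`.
#' @slot pixelSpacing millimetres per pixel.
#' @slot sourceRows integer of length 2: row counts of the CC and MLO sources.
#' @slot resized logical, whether the image has been half-resized.
#' @slot label `"cancer"` or `"non_cancer"`.
#' @export
setClass("MultimodalImage",
  representation(
    pixels = "matrix",
    patientId = "character",
    laterality = "character",
    pixelSpacing = "numeric",
    sourceRows = "integer",
    resized = "logical",
    label = "character"
  )
)

setValidity("MultimodalImage", function(object) {
  p <- object@pixels
  msg <- character()
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    msg <- c(msg, "all pixels must lie in [0, 1]")
  if (length(object@sourceRows) != 2L || any(object@sourceRows < 1L))
    msg <- c(msg, "sourceRows must be two positive integers")
  if (!object@resized && nrow(p) != sum(object@sourceRows))
    msg <- c(msg, "row count must equal the sum of the source row counts")
  if (!object@label %in% .LABELS)
    msg <- c(msg, "label must be 'cancer' or 'non_cancer'")
  if (length(msg)) msg else TRUE
})

#' MammoBag: the multiple-instance-learning unit
#'
#' An ordered set of square patches cut from one prepared image (single view
#' or multimodal), each passing the foreground rule, together with the
#' top-left pixel coordinates needed to render attention back onto the image.
#' Coordinates are row-major, 0-based, half-open: patch k covers rows
#' `[row0, row0 + patchSize)` and columns `[col0, col0 + patchSize)`.
#'
#' @slot patches list of patchSize x patchSize numeric matrices in \[0, 1\].
#' @slot coords integer matrix (K x 2), columns `row0`, `col0`.
#' @slot patchSize integer edge length in pixels.
#' @slot overlap numeric in \[0, 1): per-axis overlapping factor.
#' @slot label `"cancer"` or `"non_cancer"`, inherited from the image.
#' @slot sourceShape integer of length 2: (rows, cols) of the source image.
#' @slot patientId character scalar.
#' @export
setClass("MammoBag",
  representation(
    patches = "list",
    coords = "matrix",
    patchSize = "integer",
    overlap = "numeric",
    label = "character",
    sourceShape = "integer",
    patientId = "character"
  )
)

setValidity("MammoBag", function(object) {
  msg <- character()
  K <- length(object@patches)
  if (K < 1L) msg <- c(msg, "bag must contain at least one patch")
  if (nrow(object@coords) != K)
    msg <- c(msg, "coords must have one row per patch")
  if (K >= 1L) {
    P <- object@patchSize
    if (any(vapply(object@patches, function(x) !all(dim(x) == c(P, P)), TRUE)))
      msg <- c(msg, "every patch must be patchSize x patchSize")
    inb <- object@coords[, 1L] >= 0L & object@coords[, 2L] >= 0L &
      object@coords[, 1L] + P <= object@sourceShape[1L] &
      object@coords[, 2L] + P <= object@sourceShape[2L]
    if (!all(inb))
      msg <- c(msg, "every patch must lie fully inside the source image")
  }
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must be in [0, 1)")
  if (!object@label %in% .LABELS)
    msg <- c(msg, "label must be 'cancer' or 'non_cancer'")
  if (length(msg)) msg else TRUE
})

#' ExtractorSpec: contract for a pluggable patch feature extractor
#'
#' Declares the extractor identity, its output feature dimension M, and the
#' function mapping one patch (P x P x 3 array, values in \[0, 1\]) to a
#' length-M numeric vector. Extractors are frozen: the same patch content
#' always yields the same features, and any normalisation statistics they
#' carry are never updated by training.
#'
#' @slot name character identifier, stored in checkpoints.
#' @slot featureDim integer, output dimension M.
#' @slot frozenNormStats logical; TRUE means downstream feature
#'   standardisation statistics are fitted once and then frozen.
#' @slot fun function(array) -> numeric vector of length featureDim.
#' @export
setClass("ExtractorSpec",
  representation(
    name = "character",
    featureDim = "integer",
    frozenNormStats = "logical",
    fun = "function"
  )
)

setValidity("ExtractorSpec", function(object) {
  if (object@featureDim < 1L) "featureDim must be positive" else TRUE
})

#' MILModel: the attention MIL head
#'
#' Learnable parameters of the clustering-constrained attention MIL network:
#' the M -> 256 feature reduction, the gated attention parameters (V, U, w),
#' the bag classifier (one 256-neuron hidden layer, sigmoid output) and the
#' two-class instance classifier, plus the frozen extractor spec and the
#' frozen feature-standardisation statistics.
#'
#' @slot params named list of numeric matrices/vectors (see [initModel()]).
#' @slot dims named list: M (extractor dim), Mprime (reduced dim, 256),
#'   L (attention hidden dim), k (evidence count per cluster).
#' @slot extractor an [ExtractorSpec-class].
#' @slot featNorm list with `mean` and `sd` (length M) or empty list before
#'   [fitFeatureNorm()] has been applied.
#' @slot dropout numeric dropout rate used in training mode.
#' @export
setClass("MILModel",
  representation(
    params = "list",
    dims = "list",
    extractor = "ExtractorSpec",
    featNorm = "list",
    dropout = "numeric"
  )
)

#' AttentionHeatmap: per-pixel rendered attention
#'
#' Attention weights accumulated over each patch's pixel square, averaged by
#' per-pixel coverage, then min-max scaled over covered pixels. Uncovered
#' pixels (coverage 0) are pinned to 0.
#'
#' @slot values numeric matrix in \[0, 1\], same shape as the source image.
#' @slot coverage integer matrix: number of patches overlaying each pixel.
#' @export
setClass("AttentionHeatmap",
  representation(values = "matrix", coverage = "matrix")
)

setValidity("AttentionHeatmap", function(object) {
  msg <- character()
  if (!all(dim(object@values) == dim(object@coverage)))
    msg <- c(msg, "values and coverage must share a shape")
  v <- object@values
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    msg <- c(msg, "heatmap values must lie in [0, 1]")
  if (any(object@values[object@coverage == 0L] != 0))
    msg <- c(msg, "uncovered pixels must be 0")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic breast-phantom generator
#'
#' Describes a phantom dataset: paired CC/MLO breast-shaped foregrounds on a
#' zero background, optional bright lesion discs (present iff the label is
#' cancer), and an optional high-intensity vertical edge-artifact band at the
#' chest-wall edge whose presence can be correlated with the label.
#'
#' @slot nPatients integer number of patients (one CC + one MLO each).
#' @slot imageShape integer (rows, cols); default 256 x 192 desk scale.
#' @slot cancerFraction numeric in \[0, 1\].
#' @slot lesion list: `radiusRange` (px), `liftRange` (peak intensity lift),
#'   `countRange` (lesions per cancer view).
#' @slot background list: `axisRowFrac`, `axisColFrac` (half-ellipse semi-axis
#'   ranges as fractions of the image shape), `baseIntensity`, `noiseSd`.
#' @slot artifact list: `probCancer`, `probNonCancer`, `bandPx`, `intensity`.
#' @slot seed integer RNG seed; the whole dataset is a pure function of it.
#' @export
setClass("PhantomSpec",
  representation(
    nPatients = "integer",
    imageShape = "integer",
    cancerFraction = "numeric",
    lesion = "list",
    background = "list",
    artifact = "list",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be positive")
  if (any(object@imageShape < 32L))
    msg <- c(msg, "imageShape must be at least 32 x 32")
  if (object@cancerFraction < 0 || object@cancerFraction > 1)
    msg <- c(msg, "cancerFraction must be in [0, 1]")
  pr <- c(object@artifact$probCancer, object@artifact$probNonCancer)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "artifact probabilities must be in [0, 1]")
  if (max(object@lesion$radiusRange) * 2 >=
      min(object@imageShape) * min(object@background$axisRowFrac))
    msg <- c(msg, "lesion radius range too large for the breast axes")
  if (length(msg)) msg else TRUE
})
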