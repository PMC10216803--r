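#' @include AllClasses.R
NULL

#' Accessors for MammoMIL objects
#'
#' `pixels()` returns the intensity matrix; `patientId()`, `laterality()`,
#' `imgLabel()` the corresponding metadata; `pixelSpacing()` the physical
#' spacing in mm/px; `nPatches()` the bag size K; `patchCoords()` the K x 2
#' 0-based top-left coordinate matrix; `heatmapValues()` and `coverage()` the
#' rendered attention map and its per-pixel patch counts.
#'
#' @param object a MammoMIL S4 object.
#' @return the slot value (see details above).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("laterality", function(object) standardGeneric("laterality"))

#' @rdname accessors
#' @export
setGeneric("imgLabel", function(object) standardGeneric("imgLabel"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("nPatches", function(object) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setGeneric("patchCoords", function(object) standardGeneric("patchCoords"))

#' @rdname accessors
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setMethod("pixels", "Mammogram", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "MultimodalImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("patientId", "Mammogram", function(object) object@patientId)

#' @rdname accessors
#' @export
setMethod("patientId", "MultimodalImage", function(object) object@patientId)

#' @rdname accessors
#' @export
setMethod("patientId", "MammoBag", function(object) object@patientId)

#' @rdname accessors
#' @export
setMethod("laterality", "Mammogram", function(object) object@laterality)

#' @rdname accessors
#' @export
setMethod("laterality", "MultimodalImage", function(object) object@laterality)

#' @rdname accessors
#' @export
setMethod("imgLabel", "Mammogram", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("imgLabel", "MultimodalImage", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("imgLabel", "MammoBag", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "Mammogram", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "MultimodalImage",
          function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setMethod("nPatches", "MammoBag", function(object) length(object@patches))

#' @rdname accessors
#' @export
setMethod("patchCoords", "MammoBag", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("heatmapValues", "AttentionHeatmap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("coverage", "AttentionHeatmap", function(object) object@coverage)

#' Extract one patch from a bag
#'
#' @param bag a [MammoBag-class].
#' @param k patch index (1-based).
#' @return list with `pixels` (matrix), `row0`, `col0` (0-based top-left).
#' @export
getPatch <- function(bag, k) {
  stopifnot(is(bag, "MammoBag"), k >= 1L, k <= nPatches(bag))
  list(pixels = bag@patches[[k]],
       row0 = bag@coords[k, 1L], col0 = bag@coords[k, 2L])
}

setMethod("show", "Mammogram", function(object) {
  cat(sprintf(
    "Mammogram %s [%s %s] %d x %d px, %g mm/px, %d-bit, label: %s\n",
    object@patientId, object@laterality, object@view,
    nrow(object@pixels), ncol(object@pixels),
    object@pixelSpacing, object@bitDepth, object@label))
})

setMethod("show", "MultimodalImage", function(object) {
  cat(sprintf(
    "MultimodalImage %s [%s, CC+MLO%s] %d x %d px, label: %s\n",
    object@patientId, object@laterality,
    if (object@resized) ", half-resized" else "",
    nrow(object@pixels), ncol(object@pixels), object@label))
})

setMethod("show", "MammoBag", function(object) {
  cat(sprintf(
    "MammoBag %s: %d patches of %d px (overlap %.2f) from %d x %d image, label: %s\n",
    object@patientId, length(object@patches), object@patchSize,
    object@overlap, object@sourceShape[1L], object@sourceShape[2L],
    object@label))
})

setMethod("show", "ExtractorSpec", function(object) {
  cat(sprintf("ExtractorSpec '%s': feature_dim %d, frozen norm stats: %s\n",
              object@name, object@featureDim, object@frozenNormStats))
})

setMethod("show", "MILModel", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf(
    "MILModel: extractor '%s' (M=%d) -> reduce %d -> gated attention (L=%d) -> bag classifier\n",
    object@extractor@name, object@dims$M, object@dims$Mprime, object@dims$L))
  cat(sprintf("  evidence k=%d, dropout %.2f, %d learnable parameters, feature norm %s\n",
              object@dims$k, object@dropout, np,
              if (length(object@featNorm)) "fitted" else "unfitted"))
})

setMethod("show", "AttentionHeatmap", function(object) {
  cat(sprintf("AttentionHeatmap %d x %d, %d covered pixels, max coverage %d\n",
              nrow(object@values), ncol(object@values),
              sum(object@coverage > 0L), max(object@coverage)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d patients, %d x %d px, cancer fraction %.2f, artifact P(cancer)=%.2f P(non)=%.2f, seed %d\n",
    object@nPatients, object@imageShape[1L], object@imageShape[2L],
    object@cancerFraction, object@artifact$probCancer,
    object@artifact$probNonCancer, object@seed))
})
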