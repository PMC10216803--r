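#' @include AllClasses.R
NULL

#' Construct a Mammogram from raw pixel values
#'
#' Raw detector values are linearly scaled to \[0, 1\] by the bit-depth
#' full-scale value `2^bitDepth - 1` (4095 for 12-bit, 255 for 8-bit) — a
#' fixed scale, not per-image min-max, so that intensity is comparable across
#' images.
#'
#' @param raw numeric matrix of raw values in `[0, 2^bitDepth - 1]`, or
#'   already-scaled values in \[0, 1\] when `scaled = TRUE`.
#' @param bitDepth 8 or 12.
#' @param patientId,laterality,view,label image metadata (copied verbatim).
#' @param pixelSpacing millimetres per pixel.
#' @param scaled set TRUE if `raw` is already in \[0, 1\].
#' @return a [Mammogram-class].
#' @examples
#' m <- Mammogram(matrix(c(0, 4095), 1, 2), bitDepth = 12,
#'                patientId = "p1", laterality = "left", view = "CC",
#'                label = "non_cancer")
#' range(pixels(m))  # 0 1
#' @export
Mammogram <- function(raw, bitDepth, patientId, laterality, view, label,
                      pixelSpacing = 0.085, scaled = FALSE) {
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 12L)) stop("bitDepth must be 8 or 12")
  raw <- as.matrix(raw)
  if (scaled) {
    px <- raw
  } else {
    full <- 2^bitDepth - 1
    bad <- raw > full | raw < 0
    if (any(bad)) {
      stop(sprintf("raw value %g outside [0, %d] for bit depth %d",
                   raw[which(bad)[1L]], full, bitDepth))
    }
    px <- raw / full
  }
  new("Mammogram", pixels = px, patientId = as.character(patientId),
      laterality = laterality, view = view,
      pixelSpacing = pixelSpacing, bitDepth = bitDepth, label = label)
}

#' Load a grayscale mammogram from a PNG file
#'
#' Reads an 8- or 16-bit grayscale PNG and rescales it so that the *declared*
#' acquisition bit depth maps linearly onto \[0, 1\]: a raw value of
#' `2^bitDepth - 1` becomes exactly 1.0 and 0 stays 0.0. Twelve-bit data is
#' expected to be stored in a 16-bit container with values up to 4095; any
#' stored value above the declared full scale is a range error.
#'
#' @param path PNG file path (single-channel grayscale).
#' @param bitDepth declared acquisition depth, 8 or 12.
#' @inheritParams Mammogram
#' @return a [Mammogram-class].
#' @export
loadMammogram <- function(path, bitDepth, patientId, laterality, view, label,
                          pixelSpacing = 0.085) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L &&
        !all(img[, , 1L] == img[, , pmin(2L, dim(img)[3L])]))
      stop("expected a single-channel grayscale image: ", path)
    img <- img[, , 1L]
  }
  # readPNG scales by the *container* depth (255 or 65535); recover raw
  # values and rescale by the declared acquisition full scale. An 8-bit
  # container yields values that are exact multiples of 1/255.
  containerBits <- if (all(abs(img * 255 - round(img * 255)) < 1e-9)) 8L
                   else 16L
  raw <- round(img * (2^containerBits - 1))
  Mammogram(raw, bitDepth = bitDepth, patientId = patientId,
            laterality = laterality, view = view, label = label,
            pixelSpacing = pixelSpacing)
}

#' Read an image label table
#'
#' CSV with columns `patient_id`, `laterality`, `view`, `label`, `path`.
#'
#' @param path CSV file path.
#' @return data.frame with those columns, character-typed.
#' @export
readLabelTable <- function(path) {
  if (!file.exists(path)) stop("label CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "laterality", "view", "label", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Replicate a single-channel image to 3 channels
#'
#' Convolutional feature extractors operate on 3-channel inputs; grayscale
#' mammograms are replicated across the channel axis.
#'
#' @param x numeric matrix (H x W) or a [Mammogram-class].
#' @return H x W x 3 array with identical channels.
#' @export
expandChannels <- function(x) {
  if (is(x, "Mammogram")) x <- x@pixels
  if (length(dim(x)) == 3L) stop("input is already multi-channel")
  array(x, dim = c(nrow(x), ncol(x), 3L))
}

# Mean intensity of the outermost 5% column band on each side.
.edgeBandMeans <- function(px, frac = 0.05) {
  w <- ncol(px)
  b <- max(1L, floor(w * frac))
  c(left = mean(px[, seq_len(b)]), right = mean(px[, (w - b + 1L):w]))
}

#' Normalise chest-wall orientation
#'
#' The chest-wall edge is the vertical image edge whose adjacent 5% column
#' band has the greater mean intensity (the breast is flush with the chest
#' wall). The image is mirrored horizontally iff that edge is not on
#' `targetSide`; all other metadata is preserved. The operation is a
#' normaliser: its output is a fixed point of the operation.
#'
#' @param img a [Mammogram-class] (or plain matrix, returned as matrix).
#' @param targetSide `"left"` (default) or `"right"`.
#' @param tol relative tolerance under which the two edge bands are declared
#'   equally bright (then a warning is issued and no flip happens).
#' @return same type as `img`, chest wall on `targetSide`.
#' @export
orientChestWall <- function(img, targetSide = "left", tol = 1e-8) {
  isM <- is(img, "Mammogram")
  px <- if (isM) img@pixels else img
  m <- .edgeBandMeans(px)
  if (abs(m["left"] - m["right"]) <= tol * max(m, 1e-12)) {
    warning("both vertical edges are equally bright; leaving image unflipped")
    return(img)
  }
  side <- if (m["left"] > m["right"]) "left" else "right"
  if (side != targetSide) px <- px[, ncol(px):1L, drop = FALSE]
  if (isM) { img@pixels <- px; img } else px
}

#' Remove the chest-wall edge-artifact band
#'
#' Deletes the `bandPx` columns adjacent to the chest-wall edge (assumed on
#' `side` after [orientChestWall()]). This removes the high-intensity
#' collimator band that can otherwise act as a label-correlated shortcut
#' feature. Width decreases by `bandPx`; height is unchanged.
#'
#' @param img [Mammogram-class], [MultimodalImage-class] or matrix.
#' @param bandPx number of columns to delete (default 20); 0 is a no-op.
#' @param side chest-wall side, `"left"` (default) or `"right"`.
#' @return same type as `img`, `bandPx` columns narrower.
#' @export
removeEdgeArtifact <- function(img, bandPx = 20L, side = "left") {
  px <- if (is.matrix(img)) img else pixels(img)
  bandPx <- as.integer(bandPx)
  if (bandPx < 0L || bandPx >= ncol(px))
    stop(sprintf("bandPx must be in [0, %d)", ncol(px)))
  if (bandPx == 0L) return(img)
  keep <- if (side == "left") (bandPx + 1L):ncol(px) else
    seq_len(ncol(px) - bandPx)
  out <- px[, keep, drop = FALSE]
  if (is.matrix(img)) return(out)
  img@pixels <- out
  img
}

#' Halve image resolution by 2 x 2 area averaging
#'
#' Each output pixel is the mean of its 2 x 2 input block; output dimensions
#' are `floor(input / 2)` per axis (a trailing odd row/column is dropped).
#' Area averaging preserves constants, keeps intensities in \[0, 1\] and is
#' seed-free. Pixel spacing doubles.
#'
#' @param img [Mammogram-class], [MultimodalImage-class] or matrix.
#' @return same type, half resolution.
#' @export
resizeHalf <- function(img) {
  px <- if (is.matrix(img)) img else pixels(img)
  if (nrow(px) < 2L || ncol(px) < 2L)
    stop("resizeHalf needs at least 2 pixels per axis")
  hr <- nrow(px) %/% 2L
  hc <- ncol(px) %/% 2L
  ri <- seq_len(2L * hr)
  ci <- seq_len(2L * hc)
  px <- px[ri, ci, drop = FALSE]
  out <- (px[seq(1L, 2L * hr, 2L), seq(1L, 2L * hc, 2L), drop = FALSE] +
          px[seq(2L, 2L * hr, 2L), seq(1L, 2L * hc, 2L), drop = FALSE] +
          px[seq(1L, 2L * hr, 2L), seq(2L, 2L * hc, 2L), drop = FALSE] +
          px[seq(2L, 2L * hr, 2L), seq(2L, 2L * hc, 2L), drop = FALSE]) / 4
  if (is.matrix(img)) return(out)
  img@pixels <- out
  img@pixelSpacing <- img@pixelSpacing * 2
  if (is(img, "MultimodalImage")) img@resized <- TRUE
  img
}

#' Concatenate CC and MLO views into a multimodal image
#'
#' Row-stacks the CC view on top of the MLO view of the same patient and
#' breast, so one bag of patches spans both projections. If the two views
#' differ in width (possible after artifact cropping of only one view), the
#' narrower is padded with zero columns on the non-chest-wall side.
#'
#' @param cc,mlo [Mammogram-class] objects for the same patient and breast.
#' @param side chest-wall side of both inputs (pad opposite side).
#' @return a [MultimodalImage-class]; rows = `nrow(cc) + nrow(mlo)`.
#' @export
concatViews <- function(cc, mlo, side = "left") {
  stopifnot(is(cc, "Mammogram"), is(mlo, "Mammogram"))
  if (cc@view != "CC" || mlo@view != "MLO")
    stop("concatViews expects a CC view then an MLO view")
  if (cc@patientId != mlo@patientId || cc@laterality != mlo@laterality)
    stop("views belong to different patients or breasts")
  if (cc@label != mlo@label)
    stop("views carry different image labels")
  a <- cc@pixels
  b <- mlo@pixels
  wid <- max(ncol(a), ncol(b))
  padTo <- function(x, w) {
    if (ncol(x) == w) return(x)
    pad <- matrix(0, nrow(x), w - ncol(x))
    if (side == "left") cbind(x, pad) else cbind(pad, x)
  }
  px <- rbind(padTo(a, wid), padTo(b, wid))
  new("MultimodalImage", pixels = px, patientId = cc@patientId,
      laterality = cc@laterality, pixelSpacing = cc@pixelSpacing,
      sourceRows = c(nrow(a), nrow(b)), resized = FALSE, label = cc@label)
}

#' Physical patch size in millimetres
#'
#' @param patchPx patch edge length in pixels.
#' @param spacingMm pixel spacing in mm/px (0.085 for the reference FFDM
#'   scanner at full resolution).
#' @return edge length in millimetres (e.g. 224 px at 0.085 mm/px = 19.04 mm).
#' @export
patchPhysicalSizeMm <- function(patchPx, spacingMm = 0.085) {
  patchPx * spacingMm
}
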