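#' @include AllClasses.R
NULL

#' Render per-patch attention into a per-pixel heatmap
#'
#' An empty canvas of the source image shape accumulates each patch's
#' attention weight over its pixel square; every pixel is then divided by
#' the number of patches overlaying it (pixels covered by no patch stay 0),
#' and finally min-max scaling over the covered pixels maps the map to
#' \[0, 1\]. A constant covered region maps to 1 (max-side convention), so a
#' single-patch map stays visible.
#'
#' @param bag a [MammoBag-class] (supplies coordinates and patch size).
#' @param a length-K attention weights from [gatedAttention()] /
#'   [predictBag()].
#' @param shape optional (rows, cols); defaults to the bag's source shape.
#' @return an [AttentionHeatmap-class].
#' @export
renderHeatmap <- function(bag, a, shape = NULL) {
  stopifnot(is(bag, "MammoBag"), length(a) == nPatches(bag))
  if (is.null(shape)) shape <- bag@sourceShape
  P <- bag@patchSize
  co <- bag@coords
  if (any(co[, 1L] + P > shape[1L]) || any(co[, 2L] + P > shape[2L]))
    stop("patch coordinates fall outside the requested shape")
  acc <- matrix(0, shape[1L], shape[2L])
  cov <- matrix(0L, shape[1L], shape[2L])
  for (k in seq_len(nrow(co))) {
    ri <- (co[k, 1L] + 1L):(co[k, 1L] + P)
    ci <- (co[k, 2L] + 1L):(co[k, 2L] + P)
    acc[ri, ci] <- acc[ri, ci] + a[k]
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  covered <- cov > 0L
  acc[covered] <- acc[covered] / cov[covered]
  v <- acc[covered]
  lo <- min(v)
  hi <- max(v)
  if (hi > lo) {
    acc[covered] <- (v - lo) / (hi - lo)
  } else {
    acc[covered] <- 1  # constant covered region pinned to the max side
  }
  new("AttentionHeatmap", values = acc, coverage = cov)
}

#' Score lesion localisation against a known mask
#'
#' Mean heatmap value inside the lesion mask versus outside it (covered
#' pixels only), and their ratio. On synthetic phantoms with ground-truth
#' masks this quantifies how much attention concentrates on lesions.
#'
#' @param hm an [AttentionHeatmap-class].
#' @param mask logical matrix, same shape, TRUE on lesion pixels.
#' @return list `meanIn`, `meanOut`, `ratio` (`Inf` when `meanOut` is 0 and
#'   `meanIn` > 0).
#' @export
localizationScore <- function(hm, mask) {
  stopifnot(is(hm, "AttentionHeatmap"), all(dim(mask) == dim(hm@values)))
  covered <- hm@coverage > 0L
  inPx <- covered & mask
  outPx <- covered & !mask
  if (!any(inPx) || !any(outPx))
    stop("lesion and non-lesion covered regions must both be non-empty")
  meanIn <- mean(hm@values[inPx])
  meanOut <- mean(hm@values[outPx])
  list(meanIn = meanIn, meanOut = meanOut,
       ratio = if (meanOut == 0) ifelse(meanIn > 0, Inf, 1)
               else meanIn / meanOut)
}

#' Fraction of attention mass in the chest-wall edge band
#'
#' Sum of heatmap values over the `bandPx` columns at the chest-wall edge
#' divided by the total heatmap sum. Under spatially uniform attention this
#' equals the band's share of the heat-carrying area; values far above that
#' indicate the edge-artifact shortcut.
#'
#' @param hm an [AttentionHeatmap-class].
#' @param bandPx band width in columns (default 20).
#' @param side chest-wall side, `"left"` (default) or `"right"`.
#' @return fraction in \[0, 1\].
#' @export
edgeAttentionMass <- function(hm, bandPx = 20L, side = "left") {
  v <- hm@values
  stopifnot(bandPx >= 1L, bandPx < ncol(v))
  tot <- sum(v)
  if (tot == 0) stop("heatmap has zero total mass")
  cols <- if (side == "left") seq_len(bandPx)
          else (ncol(v) - bandPx + 1L):ncol(v)
  sum(v[, cols]) / tot
}

#' Write a heatmap (optionally blended with its source image) as PNG
#'
#' @param hm an [AttentionHeatmap-class].
#' @param path output PNG path.
#' @param source optional source image matrix for a fixed-alpha 0.5 overlay.
#' @return the path, invisibly.
#' @export
writeHeatmapPNG <- function(hm, path, source = NULL) {
  v <- hm@values
  if (!is.null(source)) {
    stopifnot(all(dim(source) == dim(v)))
    v <- 0.5 * v + 0.5 * source
  }
  png::writePNG(v, path)
  invisible(path)
}
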