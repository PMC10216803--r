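#' @include AllClasses.R
NULL

#' Enumerate the patch grid
#'
#' Square patches of edge `patchSize` are cut starting at the top-left corner
#' with a per-axis stride of `(1 - overlap) * patchSize`, rounded to the
#' nearest integer (half away from zero) with a minimum of 1. Positions run
#' `0, stride, 2*stride, ...` while the patch still fits
#' (`p + patchSize <= axis`); positions beyond the last full fit are dropped
#' so all patches are identically sized. The result is the row-major
#' Cartesian product of the two axis offset sets.
#'
#' @param rows,cols image dimensions in pixels.
#' @param patchSize patch edge length in pixels.
#' @param overlap overlapping factor in \[0, 1).
#' @return integer matrix with columns `row0`, `col0` (0-based top-left
#'   corners), row-major order; zero rows (with a warning) if the patch does
#'   not fit.
#' @examples
#' tileGrid(448, 448, 224, 0.5)   # 9 positions at offsets 0, 112, 224
#' @export
tileGrid <- function(rows, cols, patchSize, overlap) {
  stopifnot(overlap >= 0, overlap < 1, patchSize >= 1)
  if (patchSize > rows || patchSize > cols) {
    warning(sprintf("patch size %d exceeds image axis (%d x %d): empty grid",
                    patchSize, rows, cols))
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("row0", "col0"))))
  }
  stride <- max(1L, as.integer(floor((1 - overlap) * patchSize + 0.5)))
  offs <- function(n) seq.int(0L, n - patchSize, by = stride)
  r0 <- offs(rows)
  c0 <- offs(cols)
  out <- cbind(row0 = rep(r0, each = length(c0)),
               col0 = rep(c0, times = length(r0)))
  storage.mode(out) <- "integer"
  out
}

#' Fraction of non-zero pixels in a patch
#'
#' The background of a prepared mammogram is exactly 0 (scaling maps raw 0 to
#' 0.0), so foreground content is the fraction of pixels strictly greater
#' than zero, with no epsilon.
#'
#' @param patch numeric matrix (or array) of intensities in \[0, 1\].
#' @return real in \[0, 1\].
#' @export
foregroundFraction <- function(patch) {
  sum(patch > 0) / length(patch)
}

#' Build the MIL bag for one image
#'
#' Tiles the image with [tileGrid()], keeps exactly the patches whose
#' [foregroundFraction()] is at least `threshold` (inclusive boundary), in
#' grid order, and attaches the image-level label to the bag. Patch top-left
#' coordinates are retained so attention can later be rendered back onto the
#' image.
#'
#' @param img [Mammogram-class], [MultimodalImage-class], or numeric matrix.
#' @param patchSize patch edge in px.
#' @param overlap overlapping factor in \[0, 1).
#' @param threshold minimum foreground fraction (default 0.75).
#' @param label,patientId required when `img` is a plain matrix.
#' @return a [MammoBag-class].
#' @export
buildBag <- function(img, patchSize, overlap, threshold = 0.75,
                     label = NULL, patientId = NULL) {
  if (is.matrix(img)) {
    px <- img
    if (is.null(label)) label <- "non_cancer"
    if (is.null(patientId)) patientId <- "unknown"
  } else {
    px <- pixels(img)
    label <- imgLabel(img)
    patientId <- patientId(img)
  }
  patchSize <- as.integer(patchSize)
  grid <- tileGrid(nrow(px), ncol(px), patchSize, overlap)
  patches <- vector("list", nrow(grid))
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r0 <- grid[i, 1L]
    c0 <- grid[i, 2L]
    p <- px[(r0 + 1L):(r0 + patchSize), (c0 + 1L):(c0 + patchSize),
            drop = FALSE]
    if (foregroundFraction(p) >= threshold) {
      keep[i] <- TRUE
      patches[[i]] <- p
    }
  }
  if (!any(keep))
    stop(sprintf("no patch of image '%s' passes the %.0f%% foreground rule",
                 patientId, 100 * threshold))
  new("MammoBag", patches = patches[keep],
      coords = grid[keep, , drop = FALSE],
      patchSize = patchSize, overlap = as.numeric(overlap),
      label = label, sourceShape = c(nrow(px), ncol(px)),
      patientId = as.character(patientId))
}

#' Instance augmentation policy
#'
#' Training-time per-patch augmentations, applied sequentially: one
#' uniformly chosen right-angle rotation (probability 1), horizontal flip
#' (probability 0.5), vertical flip (probability 0.5), and a random resized
#' crop with area scale uniform in \[0.8, 1\] (probability 1) resized back to
#' the patch size. Validation and test data are never augmented.
#'
#' @param rotationAngles allowed rotations in degrees.
#' @param hflipProb,vflipProb flip probabilities.
#' @param cropScale area-scale range of the resized crop.
#' @return a list policy for [augmentInstance()].
#' @export
augmentationPolicy <- function(rotationAngles = c(0L, 90L, 180L, 270L),
                               hflipProb = 0.5, vflipProb = 0.5,
                               cropScale = c(0.8, 1.0)) {
  stopifnot(all(rotationAngles %% 90 == 0),
            hflipProb >= 0, hflipProb <= 1, vflipProb >= 0, vflipProb <= 1,
            length(cropScale) == 2L, cropScale[1L] <= cropScale[2L],
            cropScale[1L] > 0, cropScale[2L] <= 1)
  list(rotationAngles = as.integer(rotationAngles),
       hflipProb = hflipProb, vflipProb = vflipProb, cropScale = cropScale)
}

# Clockwise right-angle rotation of a matrix, angle in {0, 90, 180, 270}.
.rot90 <- function(x, angle) {
  switch(as.character(angle %% 360L),
         "0" = x,
         "90" = t(x[nrow(x):1L, , drop = FALSE]),
         "180" = x[nrow(x):1L, ncol(x):1L, drop = FALSE],
         "270" = t(x)[ncol(x):1L, , drop = FALSE],
         stop("rotation must be a multiple of 90 degrees"))
}

# Bilinear resize of a matrix to size out x out.
.resizeBilinear <- function(x, out) {
  n <- nrow(x)
  m <- ncol(x)
  if (n == out && m == out) return(x)
  # map output pixel centres into input pixel-centre coordinates
  rs <- (seq_len(out) - 0.5) * n / out + 0.5 - 1
  cs <- (seq_len(out) - 0.5) * m / out + 0.5 - 1
  r0 <- pmin(pmax(floor(rs), 0), n - 1)
  c0 <- pmin(pmax(floor(cs), 0), m - 1)
  r1 <- pmin(r0 + 1, n - 1)
  c1 <- pmin(c0 + 1, m - 1)
  fr <- pmin(pmax(rs - r0, 0), 1)
  fc <- pmin(pmax(cs - c0, 0), 1)
  A <- x[r0 + 1, c0 + 1, drop = FALSE]
  B <- x[r1 + 1, c0 + 1, drop = FALSE]
  C <- x[r0 + 1, c1 + 1, drop = FALSE]
  D <- x[r1 + 1, c1 + 1, drop = FALSE]
  wA <- outer(1 - fr, 1 - fc)
  wB <- outer(fr, 1 - fc)
  wC <- outer(1 - fr, fc)
  wD <- outer(fr, fc)
  A * wA + B * wB + C * wC + D * wD
}

#' Augment one patch (training mode only)
#'
#' Draws the augmentation sequence of the policy from the current RNG state:
#' rotation, horizontal flip, vertical flip, random resized crop. The output
#' has the same shape as the input with values in \[0, 1\]; the same RNG seed
#' and patch always reproduce the same output.
#'
#' @param patch square numeric matrix in \[0, 1\].
#' @param policy from [augmentationPolicy()].
#' @param training must be TRUE; augmenting validation/test data is a
#'   contract error.
#' @return augmented patch, same shape.
#' @export
augmentInstance <- function(patch, policy = augmentationPolicy(),
                            training = TRUE) {
  if (!isTRUE(training))
    stop("augmentInstance must only be called on training data")
  P <- nrow(patch)
  stopifnot(ncol(patch) == P)
  ang <- policy$rotationAngles[sample.int(length(policy$rotationAngles), 1L)]
  out <- .rot90(patch, ang)
  if (stats::runif(1) < policy$hflipProb)
    out <- out[, ncol(out):1L, drop = FALSE]
  if (stats::runif(1) < policy$vflipProb)
    out <- out[nrow(out):1L, , drop = FALSE]
  s <- stats::runif(1, policy$cropScale[1L], policy$cropScale[2L])
  side <- max(1L, min(P, as.integer(round(P * sqrt(s)))))
  r0 <- if (side < P) sample.int(P - side + 1L, 1L) else 1L
  c0 <- if (side < P) sample.int(P - side + 1L, 1L) else 1L
  out <- out[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
  .resizeBilinear(out, P)
}
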