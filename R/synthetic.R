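#' @include AllClasses.R
NULL

#' Construct a phantom dataset specification
#'
#' Defaults describe the desk-scale study conditions: 256 x 192 px paired
#' CC/MLO phantoms, half the patients cancerous, 1-3 bright radially decaying
#' lesion discs per cancer view, breast modelled as a half-ellipse flush with
#' the left (chest-wall) image edge over an exactly-zero background, and an
#' optional saturated full-height artifact band at the chest-wall edge whose
#' presence can be correlated with the label.
#'
#' @param nPatients number of patients.
#' @param imageShape integer (rows, cols).
#' @param cancerFraction fraction of patients with label cancer.
#' @param lesionRadiusRange lesion disc radius range, px.
#' @param lesionLiftRange peak intensity lift above the breast base.
#' @param lesionCountRange lesions per cancer view (inclusive range).
#' @param axisRowFrac,axisColFrac half-ellipse semi-axis ranges as fractions
#'   of image rows / cols.
#' @param baseIntensity mean breast tissue intensity.
#' @param noiseSd Gaussian texture noise standard deviation.
#' @param artifactProbCancer,artifactProbNonCancer class-conditional
#'   probabilities that an image carries the edge-artifact band.
#' @param artifactBandPx artifact band width in columns.
#' @param artifactIntensity artifact band intensity (near saturation).
#' @param seed RNG seed; the dataset is a pure function of the spec.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nPatients = 100L,
                        imageShape = c(256L, 192L),
                        cancerFraction = 0.5,
                        lesionRadiusRange = c(6, 12),
                        lesionLiftRange = c(0.30, 0.50),
                        lesionCountRange = c(1L, 3L),
                        axisRowFrac = c(0.35, 0.45),
                        axisColFrac = c(0.60, 0.80),
                        baseIntensity = 0.45,
                        noiseSd = 0.08,
                        artifactProbCancer = 0,
                        artifactProbNonCancer = 0,
                        artifactBandPx = 20L,
                        artifactIntensity = 0.98,
                        seed = 42L) {
  new("PhantomSpec",
      nPatients = as.integer(nPatients),
      imageShape = as.integer(imageShape),
      cancerFraction = cancerFraction,
      lesion = list(radiusRange = lesionRadiusRange,
                    liftRange = lesionLiftRange,
                    countRange = as.integer(lesionCountRange)),
      background = list(axisRowFrac = axisRowFrac,
                        axisColFrac = axisColFrac,
                        baseIntensity = baseIntensity,
                        noiseSd = noiseSd),
      artifact = list(probCancer = artifactProbCancer,
                      probNonCancer = artifactProbNonCancer,
                      bandPx = as.integer(artifactBandPx),
                      intensity = artifactIntensity),
      seed = as.integer(seed))
}

# Render one phantom view. Returns list(pixels, mask).
.renderView <- function(spec, cancer, withLesions = TRUE) {
  nr <- spec@imageShape[1L]
  nc <- spec@imageShape[2L]
  bg <- spec@background
  a <- stats::runif(1, bg$axisRowFrac[1L], bg$axisRowFrac[2L]) * nr
  b <- stats::runif(1, bg$axisColFrac[1L], bg$axisColFrac[2L]) * nc
  cy <- nr / 2 + stats::runif(1, -0.05, 0.05) * nr
  rr <- matrix(seq_len(nr) - 0.5, nr, nc)
  cc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  inside <- ((rr - cy) / a)^2 + (cc / b)^2 <= 1
  px <- matrix(0, nr, nc)
  n_in <- sum(inside)
  px[inside] <- pmin(1, pmax(
    0.02, bg$baseIntensity + stats::rnorm(n_in, 0, bg$noiseSd)))
  mask <- matrix(FALSE, nr, nc)
  if (cancer && withLesions) {
    nles <- sample(spec@lesion$countRange[1L]:spec@lesion$countRange[2L], 1L)
    for (l in seq_len(nles)) {
      rad <- stats::runif(1, spec@lesion$radiusRange[1L],
                          spec@lesion$radiusRange[2L])
      lift <- stats::runif(1, spec@lesion$liftRange[1L],
                           spec@lesion$liftRange[2L])
      # centre inside the breast with the whole disc inside breast and image
      for (try in 1:200) {
        lr <- stats::runif(1, rad, nr - rad)
        lc <- stats::runif(1, rad, nc - rad)
        shrunkR <- max(a - rad, 1)
        shrunkC <- max(b - rad, 1)
        if (((lr - cy) / shrunkR)^2 + (lc / shrunkC)^2 <= 1) break
      }
      d2 <- (rr - lr)^2 + (cc - lc)^2
      hit <- d2 <= rad^2
      px[hit] <- pmin(1, px[hit] + lift * (1 - d2[hit] / rad^2))
      mask <- mask | hit
    }
    mask <- mask & inside
  }
  list(pixels = px, mask = mask)
}

#' Generate a phantom dataset
#'
#' Per patient: a CC and an MLO view sharing the label but with independently
#' drawn breast geometry, texture noise and lesion positions (mirroring real
#' projections, which show the same lesion at different positions). The label
#' is cancer for exactly `round(cancerFraction * nPatients)` patients, in
#' shuffled order. Lesion masks record the lesion pixels per view (empty for
#' non-cancer). The artifact band, when drawn (class-conditional Bernoulli),
#' replaces the `bandPx` chest-wall-edge columns with a near-saturated
#' intensity. Fully reproducible from `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param lesions set FALSE to suppress lesion rendering entirely (labels
#'   keep their class-conditional artifact behaviour); the resulting null
#'   dataset has no pixel-level class signal and is useful for over-fitting
#'   detection.
#' @return list of per-patient cases; each case is a list with `patientId`,
#'   `label`, `cc`, `mlo` ([Mammogram-class]), `maskCC`, `maskMLO` (logical
#'   matrices), `artifactCC`, `artifactMLO` (logical flags).
#' @export
generateDataset <- function(spec, lesions = TRUE) {
  validObject(spec)
  withr_seed <- spec@seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(.restore_seed(old), add = TRUE)
  n <- spec@nPatients
  nCancer <- round(spec@cancerFraction * n)
  labs <- sample(c(rep("cancer", nCancer), rep("non_cancer", n - nCancer)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cancer <- labs[i] == "cancer"
    pArt <- if (cancer) spec@artifact$probCancer else
      spec@artifact$probNonCancer
    views <- lapply(1:2, function(v) .renderView(spec, cancer, lesions))
    art <- stats::runif(2) < pArt
    for (v in 1:2) {
      if (art[v]) {
        bp <- spec@artifact$bandPx
        nr <- spec@imageShape[1L]
        views[[v]]$pixels[, seq_len(bp)] <-
          pmin(1, pmax(0, spec@artifact$intensity +
                            stats::rnorm(nr * bp, 0, 0.005)))
      }
    }
    pid <- sprintf("P%04d", i)
    mk <- function(v, viewName) {
      Mammogram(views[[v]]$pixels, bitDepth = 12L, patientId = pid,
                laterality = "left", view = viewName, label = labs[i],
                pixelSpacing = 0.085, scaled = TRUE)
    }
    out[[i]] <- list(patientId = pid, label = labs[i],
                     cc = mk(1L, "CC"), mlo = mk(2L, "MLO"),
                     maskCC = views[[1L]]$mask, maskMLO = views[[2L]]$mask,
                     artifactCC = art[1L], artifactMLO = art[2L])
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Paired biased / de-biased phantom datasets
#'
#' Renders the same patient stream twice: once with the label-correlated
#' artifact band, and once with the artifact removed by cropping the band
#' columns via [removeEdgeArtifact()] (so the de-artifacted images are
#' `bandPx` columns narrower and cannot carry the shortcut feature). Labels,
#' breast geometry, noise and lesions are identical across the pair.
#'
#' @param spec a [PhantomSpec-class]; its artifact probabilities drive the
#'   biased member of the pair (defaults here: 0.9 given cancer, 0.1 given
#'   non-cancer).
#' @return list with elements `biased` and `clean`, each a dataset as
#'   returned by [generateDataset()] (masks are cropped alongside the
#'   images in `clean`).
#' @export
biasedPair <- function(spec = phantomSpec(artifactProbCancer = 0.9,
                                          artifactProbNonCancer = 0.1)) {
  biased <- generateDataset(spec)
  bp <- spec@artifact$bandPx
  clean <- lapply(biased, function(case) {
    case$cc <- removeEdgeArtifact(case$cc, bp)
    case$mlo <- removeEdgeArtifact(case$mlo, bp)
    case$maskCC <- case$maskCC[, -seq_len(bp), drop = FALSE]
    case$maskMLO <- case$maskMLO[, -seq_len(bp), drop = FALSE]
    case$artifactCC <- FALSE
    case$artifactMLO <- FALSE
    case
  })
  list(biased = biased, clean = clean)
}

#' Write a phantom dataset to disk
#'
#' Images as 16-bit grayscale PNGs, lesion masks as 8-bit PNGs, and a label
#' table `labels.csv` in the imaging module's input format
#' (`patient_id, laterality, view, label, path`).
#'
#' @param dataset from [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the label data.frame.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  rows <- list()
  for (case in dataset) {
    for (v in c("cc", "mlo")) {
      img <- case[[v]]
      fn <- sprintf("%s_%s.png", case$patientId, toupper(v))
      # 8-bit container: raw = round(intensity * 255), full scale maps to 1
      png::writePNG(round(img@pixels * 255) / 255, file.path(dir, fn))
      mask <- if (v == "cc") case$maskCC else case$maskMLO
      png::writePNG(mask * 1.0, file.path(dir, "masks", fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = case$patientId, laterality = img@laterality,
        view = img@view, label = case$label, path = fn,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(df)
}

#' Load a phantom dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing `labels.csv`.
#' @return dataset list in the [generateDataset()] layout (without artifact
#'   flags; masks are loaded when present).
#' @export
loadDataset <- function(dir) {
  df <- readLabelTable(file.path(dir, "labels.csv"))
  out <- list()
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, ]
    get <- function(viewName) {
      r <- sub[sub$view == viewName, ][1L, ]
      loadMammogram(file.path(dir, r$path), bitDepth = 8L,
                    patientId = r$patient_id, laterality = r$laterality,
                    view = r$view, label = r$label)
    }
    getMask <- function(viewName) {
      r <- sub[sub$view == viewName, ][1L, ]
      p <- file.path(dir, "masks", r$path)
      if (file.exists(p)) png::readPNG(p) > 0.5 else NULL
    }
    out[[length(out) + 1L]] <- list(
      patientId = pid, label = sub$label[1L],
      cc = get("CC"), mlo = get("MLO"),
      maskCC = getMask("CC"), maskMLO = getMask("MLO"))
  }
  out
}
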