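test_that("intensity scaling maps the bit-depth full scale onto [0, 1]", {
  m12 <- Mammogram(matrix(c(0, 4095), 1, 2), bitDepth = 12,
                   patientId = "a", laterality = "left", view = "CC",
                   label = "non_cancer")
  expect_identical(as.numeric(pixels(m12)), c(0, 1))
  m8 <- Mammogram(matrix(c(0, 255), 1, 2), bitDepth = 8,
                  patientId = "a", laterality = "left", view = "CC",
                  label = "non_cancer")
  expect_identical(as.numeric(pixels(m8)), c(0, 1))
  # linearity at mid scale
  expect_equal(pixels(Mammogram(matrix(819, 1, 1), 12, "a", "left", "CC",
                                "non_cancer"))[1], 819 / 4095)
  expect_error(
    Mammogram(matrix(4096, 1, 1), 12, "a", "left", "CC", "non_cancer"),
    "4096")
  # metadata copied verbatim
  expect_identical(patientId(m12), "a")
  expect_identical(laterality(m12), "left")
  expect_identical(imgLabel(m12), "non_cancer")
})

test_that("PNG round trip preserves intensities and flags range violations", {
  d <- withr::local_tempdir()
  px <- matrix(round(runif(30) * 255), 5, 6)
  png::writePNG(px / 255, file.path(d, "x.png"))
  m <- loadMammogram(file.path(d, "x.png"), bitDepth = 8, patientId = "p",
                     laterality = "left", view = "MLO", label = "cancer")
  expect_equal(pixels(m), px / 255)
  expect_identical(m@view, "MLO")
  expect_error(loadMammogram(file.path(d, "absent.png"), 8, "p", "left",
                             "CC", "cancer"), "absent.png")
})

test_that("channel expansion replicates the image exactly three times", {
  x <- matrix(0.5, 2, 2)
  a <- expandChannels(x)
  expect_identical(dim(a), c(2L, 2L, 3L))
  expect_true(all(a == 0.5))
  r <- matrix(runif(12), 3, 4)
  ar <- expandChannels(r)
  expect_identical(ar[, , 1], ar[, , 3])
  expect_identical(expandChannels(matrix(0, 1, 1)),
                   array(0, c(1, 1, 3)))
  expect_error(expandChannels(a), "multi-channel")
})

test_that("chest-wall orientation flips only when needed and is idempotent", {
  left <- cbind(matrix(0.8, 10, 4), matrix(0, 10, 6))
  right <- left[, 10:1]
  expect_identical(orientChestWall(left, "left"), left)
  expect_identical(orientChestWall(right, "left"), left)
  once <- orientChestWall(right, "left")
  expect_identical(orientChestWall(once, "left"), once)
  expect_warning(orientChestWall(matrix(0.5, 8, 8), "left"),
                 "equally bright")
})

test_that("edge-artifact removal crops the chest-wall band", {
  m <- makeMammogram(matrix(runif(100 * 100, 0.2, 0.8), 100, 100))
  out <- removeEdgeArtifact(m, 20)
  expect_identical(dim(pixels(out)), c(100L, 80L))
  expect_identical(pixels(out), pixels(m)[, 21:100])
  expect_identical(removeEdgeArtifact(m, 0), m)
  expect_error(removeEdgeArtifact(m, 100), "bandPx")
})

test_that("removing a bright chest-wall band lowers the peak column mean", {
  set.seed(3)
  ds <- generateDataset(phantomSpec(nPatients = 3L, imageShape = c(96L, 72L),
                                    artifactProbCancer = 1,
                                    artifactProbNonCancer = 1,
                                    cancerFraction = 0.5, seed = 9L))
  for (case in ds) {
    before <- pixels(case$cc)
    after <- pixels(removeEdgeArtifact(case$cc, 20))
    expect_lt(max(colMeans(after)), max(colMeans(before)))
  }
})

test_that("half-resizing floors dimensions, averages blocks, doubles spacing", {
  m <- makeMammogram(matrix(runif(2294 * 1914), 2294, 1914))
  h <- resizeHalf(m)
  expect_identical(dim(pixels(h)), c(1147L, 957L))
  expect_equal(pixelSpacing(h), 2 * pixelSpacing(m))
  # block means
  expect_equal(pixels(h)[1, 1], mean(pixels(m)[1:2, 1:2]))
  expect_equal(pixels(h)[5, 7], mean(pixels(m)[9:10, 13:14]))
  # constants are preserved
  expect_true(all(resizeHalf(matrix(0.37, 5, 9)) == 0.37))
  expect_identical(dim(resizeHalf(matrix(0, 5, 9))), c(2L, 4L))
  expect_error(resizeHalf(matrix(0, 1, 10)), "2 pixels")
})

test_that("view concatenation stacks CC on MLO and preserves pixels", {
  cc <- makeMammogram(matrix(runif(40 * 30), 40, 30), view = "CC")
  mlo <- makeMammogram(matrix(runif(40 * 30), 40, 30), view = "MLO")
  mm <- concatViews(cc, mlo)
  expect_identical(dim(pixels(mm)), c(80L, 30L))
  expect_identical(pixels(mm)[1:40, ], pixels(cc))
  expect_identical(pixels(mm)[41:80, ], pixels(mlo))
  expect_identical(imgLabel(mm), "non_cancer")
  # the reference acquisition geometry: 2294 x 1914 views
  cc2 <- makeMammogram(matrix(0.5, 2294, 1914), view = "CC")
  mlo2 <- makeMammogram(matrix(0.5, 2294, 1914), view = "MLO")
  both <- concatViews(cc2, mlo2)
  expect_identical(dim(pixels(both)), c(4588L, 1914L))
  expect_identical(dim(pixels(resizeHalf(both))), c(2294L, 957L))
})

test_that("width mismatches are zero-padded away from the chest wall", {
  cc <- makeMammogram(matrix(0.5, 20, 30), view = "CC")
  mloNarrow <- makeMammogram(matrix(0.5, 20, 24), view = "MLO")
  mm <- concatViews(cc, mloNarrow)
  expect_identical(dim(pixels(mm)), c(40L, 30L))
  expect_true(all(pixels(mm)[21:40, 25:30] == 0))
  expect_true(all(pixels(mm)[21:40, 1:24] == 0.5))
})

test_that("concatenating mismatched identities or labels is refused", {
  cc <- makeMammogram(matrix(0.5, 8, 8), view = "CC", patientId = "a")
  mloB <- makeMammogram(matrix(0.5, 8, 8), view = "MLO", patientId = "b")
  expect_error(concatViews(cc, mloB), "different patients")
  mloR <- makeMammogram(matrix(0.5, 8, 8), view = "MLO", patientId = "a",
                        laterality = "right")
  expect_error(concatViews(cc, mloR), "different patients")
  mloC <- makeMammogram(matrix(0.5, 8, 8), view = "MLO", patientId = "a",
                        label = "cancer")
  expect_error(concatViews(cc, mloC), "different image labels")
  expect_error(concatViews(mloB, mloB), "expects a CC view")
})

test_that("patch physical size follows the pixel spacing", {
  expect_equal(patchPhysicalSizeMm(224, 0.085), 19.04)
  expect_equal(patchPhysicalSizeMm(224, 0.17), 38.08)
})
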