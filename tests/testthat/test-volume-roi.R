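test_that("NIfTI round trip preserves data, voxel size and origin", {
  ph <- generatePhantom(phantomSpec(volumeShape = 32L, nVertebrae = 1L,
                                    bodyRadiusMm = c(6, 8),
                                    bodyHeightMm = c(6, 8)), seed = 3)
  vol <- ctVolume(imageValues(ph$ct), voxelSize = c(1, 1.25, 0.8),
                  origin = c(-4, 2.5, 10))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_identical(imageValues(back), imageValues(vol))
  expect_equal(voxelSizeMm(back), voxelSizeMm(vol))
  expect_equal(originMm(back), originMm(vol))
  # integer mask labels survive exactly
  fm <- tempfile(fileext = ".nii.gz")
  writeMask(ph$mask, fm)
  backm <- readMask(fm)
  expect_identical(imageValues(backm), imageValues(ph$mask))
})

test_that("reading bad inputs raises distinct errors", {
  expect_error(readVolume(tempfile()), "not found")
  f2d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:12, 3)), f2d)
  expect_error(readVolume(f2d), "3D")
  junk <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti header", junk)
  expect_error(readVolume(junk), "NIfTI|nifti|read")
})

test_that("mask bounding box is the tightest inclusive box", {
  m <- array(0L, c(8, 8, 8))
  m[3:6, 2:4, 1:8] <- 1L
  bb <- maskBoundingBox(segmentationMask(m))
  expect_identical(bb@minIndex, c(3L, 2L, 1L))
  expect_identical(bb@maxIndex, c(6L, 4L, 8L))
  # degenerate single-voxel box
  m1 <- array(0L, c(9, 9, 9)); m1[5, 5, 5] <- 2L
  bb1 <- maskBoundingBox(segmentationMask(m1))
  expect_identical(bb1@minIndex, bb1@maxIndex)
  expect_identical(bb1@minIndex, c(5L, 5L, 5L))
  expect_error(maskBoundingBox(segmentationMask(array(0L, c(4, 4, 4)))),
               "empty mask")
})

test_that("bounding box of random sparse masks matches an exhaustive scan", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- array(0L, c(10, 10, 10))
    m[sample(1000, 12)] <- 1L
    bb <- maskBoundingBox(segmentationMask(m))
    lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
    for (z in 1:10) for (y in 1:10) for (x in 1:10) if (m[z, y, x] > 0) {
      lo <- pmin(lo, c(z, y, x)); hi <- pmax(hi, c(z, y, x))
    }
    expect_identical(as.numeric(bb@minIndex), lo)
    expect_identical(as.numeric(bb@maxIndex), hi)
  }
})

test_that("cropping restricts both grids to the box and preserves world coordinates", {
  set.seed(11)
  vol <- ctVolume(array(runif(10 * 12 * 14, 0, 100), c(10, 12, 14)),
                  voxelSize = c(1, 2, 3), origin = c(5, 6, 7))
  m <- array(0L, c(10, 12, 14))
  m[3:6, 2:4, 1:8] <- 1L
  cr <- cropToMask(vol, segmentationMask(m, voxelSize = c(1, 2, 3),
                                         origin = c(5, 6, 7)))
  expect_identical(dim(imageValues(cr$ct)), c(4L, 3L, 8L))
  # world coordinate of the retained corner voxel is unchanged:
  # new origin = old origin + (minIndex - 1) * voxelSize
  expect_equal(originMm(cr$ct), c(5, 6, 7) + c(2, 1, 0) * c(1, 2, 3))
  expect_identical(imageValues(cr$ct), imageValues(vol)[3:6, 2:4, 1:8])
  # conservation: every labeled voxel survives
  expect_identical(sum(imageValues(cr$mask) > 0), sum(m > 0))
})

test_that("cropping is idempotent and the identity on full-extent masks", {
  ph <- generatePhantom(phantomSpec(), seed = 6)
  cr1 <- cropToMask(ph$ct, ph$mask)
  cr2 <- cropToMask(cr1$ct, cr1$mask)
  expect_identical(imageValues(cr2$ct), imageValues(cr1$ct))
  expect_equal(originMm(cr2$ct), originMm(cr1$ct))
  full <- segmentationMask(array(1L, c(5, 5, 5)))
  vol <- ctVolume(array(rnorm(125), c(5, 5, 5)))
  crf <- cropToMask(vol, full)
  expect_identical(imageValues(crf$ct), imageValues(vol))
  expect_error(cropToMask(vol, segmentationMask(array(1L, c(4, 4, 4)))),
               "shapes differ")
})
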