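test_that("transfer function evaluation interpolates, clamps, and validates", {
  pts <- cbind(c(0, 0.2, 0.4, 0.6, 0.8, 1), c(0, 0.1, 0.1, 0.5, 0.7, 1))
  tf <- opacityTransferFunction(pts)
  # exactly at knots
  expect_equal(evaluateTF(tf, pts[, 1]), pts[, 2])
  # midway between knots: arithmetic mean of the two opacities
  expect_equal(evaluateTF(tf, 0.5), (0.1 + 0.5) / 2)
  expect_equal(evaluateTF(tf, 0.7), (0.5 + 0.7) / 2)
  # clamped outside the covered range
  tf2 <- opacityTransferFunction(cbind(seq(0.2, 0.7, 0.1),
                                       c(0.3, 0, 0.1, 0.2, 0.4, 0.9)))
  expect_equal(evaluateTF(tf2, 0.05), 0.3)
  expect_equal(evaluateTF(tf2, 0.95), 0.9)
  expect_error(evaluateTF(tf, NaN), "finite")
  expect_error(opacityTransferFunction(cbind(c(0, 0.1, 0.1, 0.3, 0.5, 1),
                                             rep(0.5, 6))), "increasing")
})

test_that("a transfer function mapping everything to zero opacity yields a zero image", {
  vol <- ctVolume(array(runif(8^3, 0, 2500), c(8, 8, 8)))
  tf0 <- opacityTransferFunction(cbind(seq(0, 1, 0.2), rep(0, 6)))
  expect_warning(img <- projectDRR(vol, tf0, projectionGeometry(imageSize = 8L)),
                 "degenerate")
  expect_true(all(imageValues(img) == 0))
})

test_that("a single opaque voxel projects to exactly one pixel at (z0, x0)", {
  a <- array(0, c(8, 8, 8))
  z0 <- 3L; y0 <- 5L; x0 <- 2L
  a[z0, y0, x0] <- 2500
  tf <- opacityTransferFunction(cbind(c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                      c(0, 0, 0, 0, 1, 1)))
  img <- projectDRR(ctVolume(a), tf, projectionGeometry(viewAngleDeg = 0),
                    resize = FALSE)
  p <- imageValues(img)
  expect_identical(dim(p), c(8L, 8L))
  expect_identical(which(p > 0), (x0 - 1L) * 8L + z0)  # column-major index
  expect_equal(p[z0, x0], 1)
})

test_that("an axis-aligned box swaps its horizontal footprint between views", {
  a <- array(0, c(16, 16, 16))
  a[, 4:11, 6:9] <- 2500  # y-extent 8, x-extent 4
  vol <- ctVolume(a)
  width <- function(angle) {
    img <- imageValues(projectDRR(vol, defaultTF,
                                  projectionGeometry(viewAngleDeg = angle),
                                  resize = FALSE))
    sum(apply(img, 2, max) > 0.5)
  }
  expect_equal(width(0), 4)    # anterior sees the x footprint
  expect_equal(width(90), 8)   # lateral sees the y footprint
})

test_that("rotating the volume then projecting equals projecting at the angle", {
  ph <- generatePhantom(phantomSpec(volumeShape = 32L, nVertebrae = 2L,
                                    bodyRadiusMm = c(6, 8),
                                    bodyHeightMm = c(5, 7)), seed = 8)
  vol <- ph$ct
  for (theta in c(0, 90)) {
    rotated <- ctVolume(BiplanarCT:::rotateVolumeZ(imageValues(vol), theta),
                        voxelSizeMm(vol))
    i1 <- imageValues(projectDRR(rotated, defaultTF,
                                 projectionGeometry(0, imageSize = 64L)))
    i2 <- imageValues(projectDRR(vol, defaultTF,
                                 projectionGeometry(theta, imageSize = 64L)))
    expect_lt(max(abs(i1 - i2)), 1e-3)
  }
})

test_that("compositing matches a per-ray loop oracle and opacity accumulates monotonically", {
  set.seed(21)
  a <- array(runif(6 * 5 * 4, 0, 2500), c(6, 5, 4))
  vol <- ctVolume(a)
  geom <- projectionGeometry(viewAngleDeg = 0, intensityScale = 2500)
  img <- imageValues(projectDRR(vol, defaultTF, geom, rescale = FALSE,
                                resize = FALSE))
  v <- pmin(pmax(a / 2500, 0), 1)
  for (z in 1:6) for (x in 1:4) {
    C <- 0; A <- 0
    for (y in 1:5) {
      alpha <- evaluateTF(defaultTF, v[z, y, x])
      C <- C + (1 - A) * alpha * v[z, y, x]
      Anew <- A + (1 - A) * alpha
      expect_gte(Anew, A)     # monotone accumulation
      expect_lte(Anew, 1)     # never exceeds full opacity
      A <- Anew
    }
    expect_equal(img[z, x], C, tolerance = 1e-12)
  }
})

test_that("a quarter-turn biplanar pair of a circular cylinder is symmetric", {
  a <- array(0, c(12, 15, 15))
  cy <- 8; r <- 5
  for (y in 1:15) for (x in 1:15)
    if ((y - cy)^2 + (x - cy)^2 <= r^2) a[3:10, y, x] <- 1800
  bp <- makeBiplanar(ctVolume(a), defaultTF, lateralAngleDeg = 90,
                     geom = projectionGeometry(imageSize = 32L))
  expect_lt(max(abs(imageValues(bp$anterior) - imageValues(bp$lateral))),
            1e-6)
  expect_error(makeBiplanar(ctVolume(a), defaultTF, lateralAngleDeg = 0),
               "lateralAngleDeg")
})

test_that("the angle sweep set renders four equal-sized lateral views in range", {
  ph <- generatePhantom(phantomSpec(volumeShape = 32L, nVertebrae = 2L,
                                    bodyRadiusMm = c(6, 8),
                                    bodyHeightMm = c(5, 7)), seed = 12)
  for (ang in c(90, 85, 80, 75)) {
    bp <- makeBiplanar(ph$ct, defaultTF, lateralAngleDeg = ang)
    p <- imageValues(bp$lateral)
    expect_identical(dim(p), c(128L, 128L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(viewAngle(bp$lateral), ang)
  }
})
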