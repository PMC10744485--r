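test_that("preprocessing always lands on a normalized square of the requested size", {
  set.seed(3)
  # plain matrix, multi-channel array, XRayImage, and PNG path inputs
  m <- matrix(runif(60 * 90), 60, 90)
  arr <- array(runif(40 * 50 * 3), c(40, 50, 3))
  ximg <- xrayImage(matrix(runif(32 * 32), 32))
  f <- tempfile(fileext = ".png")
  writeXRay(ximg, f)
  for (input in list(m, arr, ximg, f)) {
    out <- preprocessXray(input)
    expect_s4_class(out, "XRayImage")
    expect_identical(dim(imageValues(out)), c(128L, 128L))
    expect_true(all(imageValues(out) >= 0 & imageValues(out) <= 1))
  }
  out64 <- preprocessXray(m, outSize = 64L)
  expect_identical(dim(imageValues(out64)), c(64L, 64L))
})

test_that("a uniform image degenerates to zeros and a lone bright pixel errors", {
  out <- preprocessXray(matrix(0.7, 40, 40))
  expect_true(all(imageValues(out) == 0))
  lone <- matrix(0, 64, 64)
  lone[20, 20] <- 1  # removed by the 3x3 opening
  expect_error(preprocessXray(lone), "empty X-ray")
})

test_that("a bright rectangle is cropped to its box, padded square, and resized", {
  img <- matrix(0, 100, 100)
  # 40 x 20 rectangle with an internal gradient so normalization is informative
  block <- outer(seq(0.6, 1, length.out = 40), seq(0.8, 1, length.out = 20))
  img[31:70, 41:60] <- block
  out <- imageValues(preprocessXray(img))
  # expected image derived by hand: crop the known box, min-max normalize,
  # pad columns 20 -> 40 symmetrically, resize to 128
  crop <- (block - min(block)) / (max(block) - min(block))
  padded <- matrix(0, 40, 40)
  padded[, 11:30] <- crop
  expected <- BiplanarCT:::resizeBilinear(padded, 128, 128)
  expect_lt(max(abs(out - expected)), 1e-12)
})

test_that("preprocessing its own output is stable", {
  ph <- generatePhantom(phantomSpec(), seed = 5)
  bp <- makeBiplanar(cropToMask(ph$ct, ph$mask)$ct, defaultTF, 90)
  once <- imageValues(preprocessXray(bp$anterior))
  twice <- imageValues(preprocessXray(once))
  expect_lt(mean(abs(twice - once)), 1e-2)
})

test_that("case packaging round trips exactly with the three canonical names", {
  s <- makeTrainingPair(1)
  f <- tempfile(fileext = ".rds")
  packageCase(ctVolume(s@ct * 2500), s@xray1, s@xray2, f)
  back <- readCase(f)
  expect_identical(names(back), c("ct", "xray1", "xray2"))
  expect_equal(back$ct, s@ct, tolerance = 1e-12)
  expect_identical(back$xray1, imageValues(s@xray1))
  expect_identical(back$xray2, imageValues(s@xray2))
  # missing inputs error before any file is created
  f2 <- tempfile(fileext = ".rds")
  expect_error(packageCase(ctVolume(s@ct), s@xray1, NULL, f2), "xray2")
  expect_false(file.exists(f2))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(ct = 1, other = 2), bad)
  expect_error(readCase(bad), "exactly")
})

test_that("splitting is seeded, conservative, and follows 80/20 arithmetic", {
  ids <- sprintf("case_%03d", 1:440)
  sp <- splitCases(ids, seed = 42)
  expect_length(trainIds(sp), 352L)
  expect_length(testIds(sp), 88L)
  expect_length(intersect(trainIds(sp), testIds(sp)), 0L)
  expect_setequal(c(trainIds(sp), testIds(sp)), ids)
  sp10 <- splitCases(as.character(1:10), seed = 1)
  expect_length(trainIds(sp10), 8L)
  expect_length(testIds(sp10), 2L)
  # determinism under the seed; different seeds reshuffle
  expect_identical(trainIds(splitCases(ids, seed = 42)), trainIds(sp))
  expect_false(identical(trainIds(splitCases(ids, seed = 43)), trainIds(sp)))
  # conservation across n and seeds
  for (n in c(2, 3, 7, 41)) for (seed in 1:3) {
    spn <- splitCases(as.character(seq_len(n)), seed = seed)
    expect_identical(length(trainIds(spn)) + length(testIds(spn)), as.integer(n))
  }
  expect_error(splitCases(ids, trainFrac = 1.2), "trainFrac")
  expect_error(splitCases("only_one"), "two cases")
})

test_that("the split manifest round trips through CSV", {
  sp <- splitCases(sprintf("c%02d", 1:10), seed = 3)
  f <- tempfile(fileext = ".csv")
  writeSplit(sp, f)
  back <- readSplit(f)
  expect_identical(trainIds(back), trainIds(sp))
  expect_identical(testIds(back), testIds(sp))
})

test_that("augmentation resizes through 150, crops both views together, deterministically", {
  s <- makeTrainingPair(2, N = 32L)  # pair with 128 x 128 x-rays
  r1 <- BiplanarCT:::resizeBilinear(imageValues(s@xray1), 150, 150)
  r2 <- BiplanarCT:::resizeBilinear(imageValues(s@xray2), 150, 150)
  # forced zero offset: the top-left 128-crop of the 150-resize
  a0 <- augmentSample(s, offset = c(0, 0))
  expect_identical(a0$xray1, r1[1:128, 1:128])
  expect_identical(a0$xray2, r2[1:128, 1:128])
  # the maximal offset reaches the opposite corner, proving the 150 stage
  aM <- augmentSample(s, offset = c(22, 22))
  expect_identical(aM$xray1, r1[23:150, 23:150])
  # random offsets are shared between the views and seeded
  aR <- augmentSample(s, seed = 5)
  aR2 <- augmentSample(s, seed = 5)
  expect_identical(aR$xray1, aR2$xray1)
  expect_identical(aR$xray2, aR2$xray2)
  # standardization with given statistics
  aS <- augmentSample(s, offset = c(4, 4), mean = 0.5, sd = 0.25)
  expect_equal(aS$xray1, (r1[5:132, 5:132] - 0.5) / 0.25)
  # the CT passes through untouched
  expect_identical(aS$ct, s@ct)
})
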