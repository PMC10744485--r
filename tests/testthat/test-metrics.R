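test_that("identity pairs score perfectly on every statistic", {
  set.seed(2)
  a <- array(runif(6^3), c(6, 6, 6))
  r <- metricReport(a, a, ssimWinSize = 3L)
  expect_equal(r@mae0, 0)
  expect_equal(r@mse0, 0)
  expect_equal(r@mae, 0)
  expect_equal(r@mse, 0)
  expect_equal(r@cosine, 1)
  expect_equal(r@ssim, 1, tolerance = 1e-9)
  for (f in c("psnr1", "psnr2", "psnr3", "psnrAvg", "psnr3d"))
    expect_equal(slot(r, f), 100)  # capped where the ideal is infinite
})

test_that("constant-difference pairs give hand-computable values", {
  n <- 4L
  one <- array(1, rep(n, 3)); half <- array(0.5, rep(n, 3))
  expect_equal(maeSlicewise(one, half), 0.5)
  expect_equal(mseSlicewise(one, half), 0.25)
  expect_equal(psnr(one, half), 10 * log10(1 / 0.25), tolerance = 1e-12)
  pt9 <- array(0.9, rep(n, 3))
  expect_equal(maeVolume(one, pt9, 2500), 250, tolerance = 1e-9)
  expect_equal(mseVolume(one, pt9, 2500), 62500, tolerance = 1e-6)
  # uniform error: every slice has the same MSE, so plane PSNRs equal PSNR-3D
  for (ax in 1:3)
    expect_equal(psnrPerPlane(one, half, ax), psnr3d(one, half))
})

test_that("denormalization identities hold exactly on cubic volumes", {
  for (seed in 1:3) {
    p <- randomVolumePair(5, seed)
    expect_equal(maeVolume(p$gt, p$pred, 2500),
                 2500 * maeSlicewise(p$gt, p$pred), tolerance = 1e-12)
    expect_equal(mseVolume(p$gt, p$pred, 2500),
                 2500^2 * mseSlicewise(p$gt, p$pred), tolerance = 1e-12)
    r <- metricReport(p$gt, p$pred, ssimWinSize = 3L)
    expect_identical(r@psnrAvg, mean(c(r@psnr1, r@psnr2, r@psnr3)))
  }
})

test_that("all eleven statistics agree with brute-force loop oracles", {
  for (n in c(4L, 6L, 8L)) {
    p <- randomVolumePair(n, seed = n)
    gt <- p$gt; pred <- p$pred
    tol <- 1e-10
    expect_equal(maeSlicewise(gt, pred), oracleSliceError(gt, pred, 1),
                 tolerance = tol)
    expect_equal(mseSlicewise(gt, pred),
                 oracleSliceError(gt, pred, 1, squared = TRUE),
                 tolerance = tol)
    expect_equal(maeVolume(gt, pred, 2500),
                 mean(abs(gt * 2500 - pred * 2500)), tolerance = tol)
    expect_equal(mseVolume(gt, pred, 2500),
                 mean((gt * 2500 - pred * 2500)^2), tolerance = tol)
    expect_equal(cosineSimilarity(gt, pred), oracleCosine(gt, pred),
                 tolerance = tol)
    expect_equal(psnr3d(gt, pred), oraclePSNR(gt, pred), tolerance = tol)
    for (ax in 1:3)
      expect_equal(psnrPerPlane(gt, pred, ax), oraclePSNRPlane(gt, pred, ax),
                   tolerance = tol)
    expect_equal(ssimVolume(gt, pred, winSize = 3L),
                 oracleSSIMVolume(gt, pred, winSize = 3L), tolerance = tol)
  }
})

test_that("cosine similarity is scale-invariant and orthogonal on disjoint supports", {
  set.seed(9)
  a <- array(runif(4^3), c(4, 4, 4))
  expect_equal(cosineSimilarity(a, a), 1, tolerance = 1e-12)
  expect_equal(cosineSimilarity(a, 3.7 * a), 1, tolerance = 1e-12)
  b <- array(0, c(4, 4, 4)); d <- array(0, c(4, 4, 4))
  b[1:2, , ] <- runif(32); d[3:4, , ] <- runif(32)
  expect_equal(cosineSimilarity(b, d), 0)
  expect_error(cosineSimilarity(a, array(0, c(4, 4, 4))), "zero-norm")
})

test_that("SSIM penalizes structural inversion and degrades with noise", {
  check <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  a <- array(rep(check, 16), c(16, 16, 16))
  a <- aperm(a, c(3, 1, 2))
  inv <- ssimVolume(a, 1 - a)
  expect_lt(inv, 0.5)
  sds <- c(0.02, 0.08, 0.2)
  mean_ssim <- vapply(sds, function(sd) {
    mean(vapply(1:10, function(s) {
      set.seed(s)
      noisy <- pmin(pmax(a + array(rnorm(length(a), sd = sd), dim(a)), 0), 1)
      ssimVolume(a, noisy)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ssim) < 0))
  expect_error(ssim2d(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("PSNR, SSIM and MAE degrade monotonically with noise level", {
  set.seed(31)
  gt <- imageValues(generatePhantom(phantomSpec(volumeShape = 24L,
                                                nVertebrae = 1L,
                                                bodyRadiusMm = c(6, 7),
                                                bodyHeightMm = c(6, 7),
                                                noiseSd = 0),
                                    seed = 2)$ct) / 2500
  sds <- c(0.01, 0.05, 0.15)
  stats <- sapply(sds, function(sd) {
    res <- sapply(1:8, function(s) {
      set.seed(s)
      noisy <- pmin(pmax(gt + array(rnorm(length(gt), sd = sd), dim(gt)), 0), 1)
      c(psnr3d(gt, noisy), ssimVolume(gt, noisy), maeSlicewise(gt, noisy))
    })
    rowMeans(res)
  })
  expect_true(all(diff(stats[1, ]) < 0))  # PSNR-3D falls
  expect_true(all(diff(stats[2, ]) < 0))  # SSIM falls
  expect_true(all(diff(stats[3, ]) > 0))  # MAE rises
})

test_that("evaluatePairs averages per-pair reports with a plain mean", {
  p1 <- randomVolumePair(6, 1); p2 <- randomVolumePair(6, 2)
  r1 <- metricReport(p1$gt, p1$pred, ssimWinSize = 3L)
  r2 <- metricReport(p2$gt, p2$pred, ssimWinSize = 3L)
  single <- evaluatePairs(list(p1), ssimWinSize = 3L)
  for (f in c("mae0", "mse0", "mae", "mse", "cosine", "psnr1", "psnr2",
              "psnr3", "psnrAvg", "psnr3d", "ssim"))
    expect_equal(slot(single, f), slot(r1, f))
  both <- evaluatePairs(list(p1, p2), ssimWinSize = 3L)
  for (f in c("mae0", "mse0", "mae", "mse", "cosine", "psnr1", "psnr2",
              "psnr3", "psnr3d", "ssim"))
    expect_equal(slot(both, f), mean(c(slot(r1, f), slot(r2, f))))
  expect_identical(both@n, 2L)
  expect_error(evaluatePairs(list()), "empty")
})

test_that("metric preconditions are enforced", {
  a <- array(0.5, c(4, 4, 4))
  expect_error(maeSlicewise(a, array(0.5, c(4, 4, 5))), "mismatch")
  expect_error(maeSlicewise(a, array(1.5, c(4, 4, 4))), "\\[0, 1\\]")
  expect_error(psnr(a, array(0, c(5, 4, 4))), "mismatch")
})

test_that("the report table follows the canonical row layout", {
  p <- randomVolumePair(6, 3)
  tb <- metricTable(metricReport(p$gt, p$pred, ssimWinSize = 3L))
  expect_identical(tb$Metrics,
                   c("MAE0", "MSE0", "MAE", "MSE", "Cosine Similarity",
                     "PSNR-3D", "PSNR-1", "PSNR-2", "PSNR-3", "PSNR-avg",
                     "SSIM"))
  expect_true(all(is.finite(tb$Value)))
})
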