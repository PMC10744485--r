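test_that("the generator emits a cube of the configured edge with values in [0, 1]", {
  cfg <- ganConfig(volumeSize = 32L, baseChannels = 2L, nEpochs = 1L, seed = 2L)
  gen <- buildGenerator(cfg)
  x1 <- matrix(runif(32 * 32), 32)
  v <- predictVolume(gen, x1, x1)  # identical views are fine
  expect_identical(dim(v), c(32L, 32L, 32L))
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0 & v <= 1))
  # inputs of other sizes are resampled to the network edge
  v2 <- predictVolume(gen, matrix(runif(128^2), 128), matrix(runif(64^2), 64))
  expect_identical(dim(v2), c(32L, 32L, 32L))
  expect_error(ganConfig(volumeSize = 8L), "power of two")
  expect_error(ganConfig(volumeSize = 48L), "power of two")
})

test_that("generator construction is seeded and serialization round trips", {
  cfg <- ganConfig(volumeSize = 32L, baseChannels = 2L, nEpochs = 1L, seed = 7L)
  g1 <- buildGenerator(cfg)
  g2 <- buildGenerator(cfg)
  x1 <- matrix(runif(32^2), 32); x2 <- matrix(runif(32^2), 32)
  expect_identical(predictVolume(g1, x1, x2), predictVolume(g2, x1, x2))
  ck <- serializeNet(g1)
  g3 <- restoreNet(buildGenerator(ganConfig(volumeSize = 32L,
                                            baseChannels = 2L, nEpochs = 1L,
                                            seed = 99L)), ck)
  expect_identical(predictVolume(g3, x1, x2), predictVolume(g1, x1, x2))
})

test_that("the discriminator is a deterministic conditional patch critic", {
  cfg <- ganConfig(volumeSize = 32L, baseChannels = 2L, nEpochs = 1L, seed = 3L)
  disc <- buildDiscriminator(cfg)
  vol <- array(runif(32^3), c(32, 32, 32))
  x1 <- matrix(runif(32^2), 32); x2 <- matrix(runif(32^2), 32)
  s <- predictScores(disc, vol, x1, x2)
  expect_gt(prod(dim(s)), 1)  # a grid of patch scores, not a single logit
  # no dropout: identical inputs score identically
  expect_identical(predictScores(disc, vol, x1, x2), s)
  # the condition matters: a different x-ray changes the scores
  expect_false(identical(predictScores(disc, vol, matrix(runif(32^2), 32), x2), s))
  expect_error(predictScores(disc, array(runif(16^3), c(16, 16, 16)), x1, x2),
               "volume")
})

test_that("least-squares GAN losses match their closed forms", {
  ones <- array(1, c(2, 2, 2)); zeros <- array(0, c(2, 2, 2))
  perfect <- lsganLoss(ones, zeros)
  expect_equal(perfect$lossD, 0)
  fooled <- lsganLoss(ones, ones)
  expect_equal(fooled$lossGAdv, 0)
  mid <- lsganLoss(ones * 0.5, zeros + 0.5)
  expect_equal(mid$lossD, 0.5 * 0.25 + 0.5 * 0.25)
  expect_equal(mid$lossGAdv, 0.25)
  expect_error(lsganLoss(ones * NA, zeros), "finite")
})

test_that("reconstruction loss is voxel MSE, zero only at identity", {
  set.seed(5)
  a <- array(runif(4^3), c(4, 4, 4)); b <- array(runif(4^3), c(4, 4, 4))
  expect_equal(reconstructionLoss(a, a), 0)
  expect_equal(reconstructionLoss(array(0, c(3, 3, 3)), array(1, c(3, 3, 3))), 1)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(reconstructionLoss(a, b), acc / length(a), tolerance = 1e-12)
  expect_error(reconstructionLoss(a, array(0, c(4, 4, 5))), "mismatch")
})

test_that("projection loss vanishes on projection-equivalent volumes", {
  set.seed(6)
  a <- array(0.5, c(4, 4, 4))
  # zero-line-sum perturbation: outer product of zero-sum vectors leaves all
  # three axis-mean projections untouched while changing voxels
  e <- c(0.1, -0.1, 0.1, -0.1)
  delta <- outer(outer(e, e), e)
  b <- a + delta
  expect_equal(projectionLoss(a, b), 0)
  expect_gt(reconstructionLoss(a, b), 0)
  # brute-force oracle on a random pair
  p <- randomVolumePair(4, 9)
  projMSE <- function(gt, pred, ax) {
    d <- dim(gt)[ax]
    pg <- apply(gt, setdiff(1:3, ax), mean)
    pp <- apply(pred, setdiff(1:3, ax), mean)
    mean((pg - pp)^2)
  }
  expect_equal(projectionLoss(p$gt, p$pred),
               mean(c(projMSE(p$gt, p$pred, 1), projMSE(p$gt, p$pred, 2),
                      projMSE(p$gt, p$pred, 3))), tolerance = 1e-12)
  expect_equal(projectionLoss(p$gt, p$gt), 0)
})

test_that("feature matching averages per-layer L1 distances", {
  set.seed(7)
  f1 <- list(array(runif(8), c(2, 2, 2)), array(runif(27), c(3, 3, 3)))
  expect_equal(featureMatchingLoss(f1, f1), 0)
  shifted <- list(f1[[1]] + 1, f1[[2]])
  expect_equal(featureMatchingLoss(f1, shifted), 1 / 2)
  g1 <- list(array(runif(8), c(2, 2, 2)), array(runif(27), c(3, 3, 3)))
  expect_equal(featureMatchingLoss(f1, g1),
               (mean(abs(f1[[1]] - g1[[1]])) + mean(abs(f1[[2]] - g1[[2]]))) / 2,
               tolerance = 1e-12)
  expect_error(featureMatchingLoss(f1, f1[1]), "lengths")
})

test_that("a single optimizer step moves the generator parameters", {
  ns <- asNamespace("BiplanarCT")
  cfg <- ganConfig(volumeSize = 16L, baseChannels = 2L, nEpochs = 1L,
                   seed = 13L)
  gen <- buildGenerator(cfg)
  params <- ns$flattenParams(gen$params)
  before <- ns$paramVectorNorm(params)
  x1 <- matrix(runif(16^2), 16); x2 <- matrix(runif(16^2), 16)
  target <- array(0.2, c(16, 16, 16, 1))
  loss <- ns$agMSE(ns$genForward(gen, x1, x2), target)
  ns$agBackward(loss)
  st <- ns$adamInit(params)
  ns$adamStep(params, st, 1e-3, 0.5, 0.99, 1)
  after <- ns$paramVectorNorm(params)
  expect_false(isTRUE(all.equal(before, after)))
})
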