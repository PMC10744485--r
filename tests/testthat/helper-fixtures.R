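# Shared fixtures and independent brute-force oracles. Everything is
# generated in code at test time; no binary fixtures are stored.

fixtureCache <- new.env(parent = emptyenv())

defaultTF <- opacityTransferFunction()

# a phantom cropped to its mask, plus its biplanar DRR pair, normalized CT
# resampled to N^3; mirrors the packaging pipeline at desk scale
makeTrainingPair <- function(i, N = 32L) {
  key <- paste0("pair_", i, "_", N)
  got <- fixtureCache[[key]]
  if (!is.null(got)) return(got)
  ph <- generatePhantom(phantomSpec(nVertebrae = 2L + (i %% 3L)), seed = i)
  cr <- cropToMask(ph$ct, ph$mask)
  bp <- makeBiplanar(cr$ct, defaultTF, 90)
  ctn <- BiplanarCT:::resizeVolume(imageValues(cr$ct) / 2500, rep(N, 3L))
  s <- pairedSample(pmin(pmax(ctn, 0), 1),
                    preprocessXray(bp$anterior), preprocessXray(bp$lateral),
                    sprintf("case_%03d", i))
  fixtureCache[[key]] <- s
  s
}

makeTrainingSet <- function(n = 4L, N = 32L)
  lapply(seq_len(n), makeTrainingPair, N = N)

randomVolumePair <- function(n, seed) {
  set.seed(seed)
  list(gt = array(stats::runif(n^3), rep(n, 3L)),
       pred = array(stats::runif(n^3), rep(n, 3L)))
}

# ---- independent loop oracles (deliberately naive) ------------------------

oracleSliceError <- function(gt, pred, axis, squared = FALSE) {
  n <- dim(gt)[axis]
  tot <- 0
  for (i in seq_len(n)) {
    s1 <- switch(axis, gt[i, , ], gt[, i, ], gt[, , i])
    s2 <- switch(axis, pred[i, , ], pred[, i, ], pred[, , i])
    d <- as.vector(s1) - as.vector(s2)
    tot <- tot + (if (squared) mean(d^2) else mean(abs(d)))
  }
  tot / n
}

oraclePSNR <- function(gt, pred, peak = 1) {
  mse <- 0
  v1 <- as.vector(gt); v2 <- as.vector(pred)
  for (i in seq_along(v1)) mse <- mse + (v1[i] - v2[i])^2
  mse <- mse / length(v1)
  if (mse == 0) 100 else min(10 * log10(peak^2 / mse), 100)
}

oraclePSNRPlane <- function(gt, pred, axis) {
  n <- dim(gt)[axis]
  vals <- numeric(n)
  for (i in seq_len(n)) {
    s1 <- switch(axis, gt[i, , ], gt[, i, ], gt[, , i])
    s2 <- switch(axis, pred[i, , ], pred[, i, ], pred[, , i])
    vals[i] <- oraclePSNR(s1, s2)
  }
  mean(vals)
}

oracleCosine <- function(gt, pred) {
  num <- sum(as.vector(gt) * as.vector(pred))
  num / (sqrt(sum(gt^2)) * sqrt(sum(pred^2)))
}

# reflect-101 index mapping used by the SSIM filter
reflectIdx <- function(j, n) {
  if (j < 1) j <- 2 - j
  if (j > n) j <- 2 * n - j
  min(max(j, 1), n)
}

oracleSSIM2d <- function(a, b, winSize = 3L, sigma = 1.5, L = 1) {
  half <- (winSize - 1) / 2
  k1 <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  nr <- nrow(a); nc <- ncol(a)
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    m1 <- m2 <- m11 <- m22 <- m12 <- 0
    for (u in seq_len(winSize)) for (v in seq_len(winSize)) {
      ii <- reflectIdx(i + u - 1 - half, nr)
      jj <- reflectIdx(j + v - 1 - half, nc)
      w <- k1[u] * k1[v]
      m1 <- m1 + w * a[ii, jj]; m2 <- m2 + w * b[ii, jj]
      m11 <- m11 + w * a[ii, jj]^2; m22 <- m22 + w * b[ii, jj]^2
      m12 <- m12 + w * a[ii, jj] * b[ii, jj]
    }
    s11 <- m11 - m1^2; s22 <- m22 - m2^2; s12 <- m12 - m1 * m2
    vals[i, j] <- ((2 * m1 * m2 + C1) * (2 * s12 + C2)) /
      ((m1^2 + m2^2 + C1) * (s11 + s22 + C2))
  }
  mean(vals)
}

oracleSSIMVolume <- function(gt, pred, winSize = 3L) {
  mean(vapply(seq_len(dim(gt)[1]), function(i)
    oracleSSIM2d(gt[i, , ], pred[i, , ], winSize), numeric(1)))
}

# numeric gradient of a scalar-valued function of a flat numeric vector
numericGradient <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
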