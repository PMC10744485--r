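#' @include AllClasses.R
NULL

PSNR_CAP_DB <- 100

checkPair <- function(gt, pred, normalized = TRUE) {
  if (!identical(dim(gt), dim(pred)))
    stop("shape mismatch: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(pred), collapse = "x"))
  if (normalized && (any(gt < 0 | gt > 1) || any(pred < 0 | pred > 1)))
    stop("values must lie within [0, 1]")
  invisible(TRUE)
}

sliceApply <- function(a, axis, f) {
  n <- dim(a)[axis]
  vapply(seq_len(n), function(i) {
    f(switch(axis, a[i, , ], a[, i, ], a[, , i]))
  }, numeric(1))
}

#' Slice-wise mean absolute / squared error (normalized scale)
#'
#' Mean over slices along `axis` of each slice's mean absolute (squared)
#' voxel difference, computed on the normalized [0, 1] scale. These are the
#' MAE0 and MSE0 statistics of the evaluation suite.
#'
#' @param gt,pred equal-shaped normalized volumes in [0, 1].
#' @param axis slicing axis (1 = axial/z, the default).
#' @return A scalar.
#' @export
maeSlicewise <- function(gt, pred, axis = 1L) {
  checkPair(gt, pred)
  mean(sliceApply(abs(gt - pred), axis, mean))
}

#' @rdname maeSlicewise
#' @export
mseSlicewise <- function(gt, pred, axis = 1L) {
  checkPair(gt, pred)
  mean(sliceApply((gt - pred)^2, axis, mean))
}

#' Whole-volume mean absolute / squared error (denormalized scale)
#'
#' Errors over all voxels after mapping the normalized volumes back to the
#' intensity scale (multiplication by `maxIntensity`). For cubic volumes the
#' identities `mae == maxIntensity * mae0` and
#' `mse == maxIntensity^2 * mse0` hold exactly, because equal-sized slices
#' partition the volume.
#'
#' @param gt,pred equal-shaped normalized volumes in [0, 1].
#' @param maxIntensity denormalization scale (default 2500).
#' @return A scalar on the denormalized scale.
#' @export
maeVolume <- function(gt, pred, maxIntensity = 2500) {
  checkPair(gt, pred)
  mean(abs(gt * maxIntensity - pred * maxIntensity))
}

#' @rdname maeVolume
#' @export
mseVolume <- function(gt, pred, maxIntensity = 2500) {
  checkPair(gt, pred)
  mean((gt * maxIntensity - pred * maxIntensity)^2)
}

#' Cosine similarity of two volumes
#'
#' Dot product of the flattened volumes over the product of their Euclidean
#' norms; invariant to positive rescaling of either input.
#'
#' @param gt,pred equal-shaped volumes; neither may have zero norm.
#' @return A scalar in [-1, 1].
#' @export
cosineSimilarity <- function(gt, pred) {
  checkPair(gt, pred, normalized = FALSE)
  ng <- sqrt(sum(gt^2)); np <- sqrt(sum(pred^2))
  if (ng == 0 || np == 0) stop("cosine similarity undefined for zero-norm input")
  sum(gt * pred) / (ng * np)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; a zero MSE (identical inputs) is capped
#' at 100 dB so reports stay finite.
#'
#' @param gt,pred equal-shaped arrays.
#' @param peak maximum possible signal value (1 for normalized volumes).
#' @return PSNR in dB.
#' @export
psnr <- function(gt, pred, peak = 1.0) {
  if (!identical(dim(gt), dim(pred))) stop("shape mismatch")
  mse <- mean((gt - pred)^2)
  if (mse == 0) return(PSNR_CAP_DB)
  min(10 * log10(peak^2 / mse), PSNR_CAP_DB)
}

#' Per-plane and volumetric PSNR
#'
#' `psnrPerPlane` averages per-slice PSNR (each slice capped at 100 dB)
#' over the slices along axis `axis`; the three axes 1/2/3 correspond to the
#' axial (z), coronal (y) and sagittal (x) slice stacks. `psnr3d` computes a
#' single PSNR over the whole volume in one go. Per-slice values are averaged
#' after the dB transform, not by pooling MSEs, which is why `psnrAvg` and
#' `psnr3d` differ in general.
#'
#' @param gt,pred equal-shaped normalized volumes.
#' @param axis slicing axis (1, 2 or 3).
#' @param peak signal peak (default 1).
#' @return PSNR in dB.
#' @export
psnrPerPlane <- function(gt, pred, axis = 1L, peak = 1.0) {
  if (!identical(dim(gt), dim(pred))) stop("shape mismatch")
  d <- abs(gt - pred)
  mean(sliceApply(d, axis, function(s) {
    mse <- mean(s^2)
    if (mse == 0) PSNR_CAP_DB else min(10 * log10(peak^2 / mse), PSNR_CAP_DB)
  }))
}

#' @rdname psnrPerPlane
#' @export
psnr3d <- function(gt, pred, peak = 1.0) psnr(gt, pred, peak)

# ---- SSIM ----------------------------------------------------------------

gaussianKernel1d <- function(winSize = 11L, sigma = 1.5) {
  half <- (winSize - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# band matrix applying a 1D kernel with reflective boundary handling,
# mapping a length-n signal to a filtered length-n signal
filterMatrix1d <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq_along(kernel)) {
      j <- i + t - 1L - half
      # reflect (symmetric, edge pixel not repeated beyond the border pair)
      if (j < 1L) j <- 1L - j + 1L
      if (j > n) j <- 2L * n - j
      j <- min(max(j, 1L), n)
      M[i, j] <- M[i, j] + kernel[t]
    }
  }
  M
}

ssimFilterCache <- new.env(parent = emptyenv())

gaussianFilter2d <- function(m, winSize, sigma) {
  key <- paste(nrow(m), ncol(m), winSize, sigma, sep = "_")
  f <- ssimFilterCache[[key]]
  if (is.null(f)) {
    k <- gaussianKernel1d(winSize, sigma)
    f <- list(R = filterMatrix1d(nrow(m), k), C = filterMatrix1d(ncol(m), k))
    ssimFilterCache[[key]] <- f
  }
  f$R %*% m %*% t(f$C)
}

#' 2D structural similarity of two image slices
#'
#' Gaussian-windowed SSIM (window `winSize`, sigma 1.5, stabilizers
#' K1 = 0.01, K2 = 0.03, dynamic range `L`), averaged over the full SSIM
#' map. Boundaries are handled by symmetric reflection.
#'
#' @param a,b equal-shaped matrices in [0, L].
#' @param winSize odd Gaussian window width (default 11); the slice must be
#'   at least this large in both dimensions.
#' @param sigma Gaussian window sd (default 1.5).
#' @param L dynamic range (default 1).
#' @return SSIM scalar in [-1, 1].
#' @export
ssim2d <- function(a, b, winSize = 11L, sigma = 1.5, L = 1.0) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (min(dim(a)) < winSize)
    stop("slice (", paste(dim(a), collapse = "x"),
         ") is smaller than the SSIM window (", winSize, ")")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu1 <- gaussianFilter2d(a, winSize, sigma)
  mu2 <- gaussianFilter2d(b, winSize, sigma)
  s11 <- gaussianFilter2d(a * a, winSize, sigma) - mu1^2
  s22 <- gaussianFilter2d(b * b, winSize, sigma) - mu2^2
  s12 <- gaussianFilter2d(a * b, winSize, sigma) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Slice-averaged volumetric SSIM
#'
#' Mean over axial (z) slices of the 2D Gaussian-windowed SSIM.
#'
#' @param gt,pred equal-shaped normalized volumes in [0, 1].
#' @param winSize odd window width (default 11); slices smaller than the
#'   window raise an error.
#' @param sigma window sd (default 1.5).
#' @return SSIM scalar in [-1, 1].
#' @export
ssimVolume <- function(gt, pred, winSize = 11L, sigma = 1.5) {
  checkPair(gt, pred)
  n <- dim(gt)[1]
  mean(vapply(seq_len(n), function(i)
    ssim2d(gt[i, , ], pred[i, , ], winSize = winSize, sigma = sigma),
    numeric(1)))
}

#' Compute all eleven evaluation statistics for one pair
#'
#' @param gt,pred equal-shaped normalized volumes in [0, 1].
#' @param maxIntensity denormalization scale for MAE/MSE (default 2500).
#' @param ssimWinSize SSIM window width (default 11).
#' @return A [MetricReport-class] with `n = 1`.
#' @export
metricReport <- function(gt, pred, maxIntensity = 2500, ssimWinSize = 11L) {
  checkPair(gt, pred)
  p1 <- psnrPerPlane(gt, pred, 1L)
  p2 <- psnrPerPlane(gt, pred, 2L)
  p3 <- psnrPerPlane(gt, pred, 3L)
  new("MetricReport",
      mae0 = maeSlicewise(gt, pred), mse0 = mseSlicewise(gt, pred),
      mae = maeVolume(gt, pred, maxIntensity),
      mse = mseVolume(gt, pred, maxIntensity),
      cosine = cosineSimilarity(gt, pred),
      psnr1 = p1, psnr2 = p2, psnr3 = p3, psnrAvg = mean(c(p1, p2, p3)),
      psnr3d = psnr3d(gt, pred),
      ssim = ssimVolume(gt, pred, winSize = ssimWinSize), n = 1L)
}

metricFields <- c("mae0", "mse0", "mae", "mse", "cosine", "psnr3d",
                  "psnr1", "psnr2", "psnr3", "psnrAvg", "ssim")
metricLabels <- c("MAE0", "MSE0", "MAE", "MSE", "Cosine Similarity",
                  "PSNR-3D", "PSNR-1", "PSNR-2", "PSNR-3", "PSNR-avg", "SSIM")

#' Average a list of MetricReports field-wise (plain mean)
#' @param reports a nonempty list of [MetricReport-class] objects.
#' @return A [MetricReport-class] with `n` = total pairs.
#' @export
averageReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  vals <- lapply(metricFields, function(f)
    mean(vapply(reports, function(r) slot(r, f), numeric(1))))
  names(vals) <- metricFields
  p <- do.call(new, c(list("MetricReport"), vals,
                      list(n = sum(vapply(reports, function(r) r@n,
                                          integer(1))))))
  # re-derive psnrAvg so the exact identity holds after averaging
  p@psnrAvg <- mean(c(p@psnr1, p@psnr2, p@psnr3))
  validObject(p)
  p
}

#' Evaluate reconstructions against ground truth over a set of pairs
#'
#' Computes all eleven statistics per pair and averages them (plain mean)
#' into a single report shaped like the evaluation table.
#'
#' @param pairs a nonempty list, each element a list with normalized volumes
#'   `gt` and `pred`.
#' @param maxIntensity denormalization scale (default 2500).
#' @param ssimWinSize SSIM window width (default 11).
#' @return A [MetricReport-class].
#' @export
evaluatePairs <- function(pairs, maxIntensity = 2500, ssimWinSize = 11L) {
  if (length(pairs) == 0L) stop("empty evaluation set")
  averageReports(lapply(pairs, function(p)
    metricReport(p$gt, p$pred, maxIntensity, ssimWinSize)))
}

#' Tabulate a MetricReport in the evaluation-table layout
#' @param report a [MetricReport-class].
#' @return A two-column data.frame (Metrics, Value).
#' @export
metricTable <- function(report) {
  data.frame(Metrics = metricLabels,
             Value = vapply(metricFields, function(f) slot(report, f),
                            numeric(1)),
             row.names = NULL)
}

#' Tabulate an AngleSweepReport (one metric column per angle)
#' @param sweep an [AngleSweepReport-class].
#' @return A data.frame with a Metrics column and one column per angle.
#' @export
sweepTable <- function(sweep) {
  df <- data.frame(Metrics = metricLabels)
  for (i in seq_along(sweep@angles)) {
    df[[paste0(sweep@angles[i], " Degree")]] <-
      vapply(metricFields, function(f) slot(sweep@reports[[i]], f), numeric(1))
  }
  df
}
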