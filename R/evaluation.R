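#' @include metrics.R drr.R generator.R
NULL

# normalize a model argument to function(x1, x2, caseIndex) -> 3D array
asReconModel <- function(model) {
  if (inherits(model, "ctGenerator"))
    return(function(x1, x2, i) predictVolume(model, x1, x2))
  if (is.function(model)) {
    if (length(formals(model)) >= 3L) return(model)
    return(function(x1, x2, i) model(x1, x2))
  }
  stop("model must be a ctGenerator or a function(xray1, xray2[, case])")
}

#' Biplanar angle-sensitivity sweep
#'
#' For each angle in `angles`, every test case's lateral X-ray is regenerated
#' at that angle (the anterior view stays at 0 degrees), both views are
#' preprocessed, the model reconstructs a volume, and the full metric suite
#' is computed against the ground truth CT resampled to the reconstruction
#' grid. The result is a report with one metric column per angle; 90 degrees
#' is the standard orthogonal setup.
#'
#' @param model a trained generator ([buildGenerator()]/[trainGan()]) or a
#'   function `(xray1, xray2[, caseIndex]) -> 3D array` (a stub model is
#'   useful for plumbing checks).
#' @param volumes list of ground-truth [CTVolume-class] objects (raw
#'   intensity scale).
#' @param angles lateral view angles in degrees (default 90, 85, 80, 75).
#' @param tf an [OpacityTransferFunction-class].
#' @param geom a [ProjectionGeometry-class] template.
#' @param outSize preprocessing output edge (default 128).
#' @param maxIntensity denormalization scale (default
#'   `geom@intensityScale`).
#' @param ssimWinSize SSIM window width.
#' @return An [AngleSweepReport-class].
#' @export
angleSweep <- function(model, volumes, angles = c(90, 85, 80, 75),
                       tf = opacityTransferFunction(),
                       geom = projectionGeometry(), outSize = 128L,
                       maxIntensity = geom@intensityScale,
                       ssimWinSize = 11L) {
  fn <- asReconModel(model)
  stopifnot(length(volumes) >= 1L)
  reports <- lapply(angles, function(ang) {
    pairs <- lapply(seq_along(volumes), function(i) {
      vol <- volumes[[i]]
      bp <- makeBiplanar(vol, tf, lateralAngleDeg = ang, geom = geom)
      x1 <- preprocessXray(bp$anterior, outSize = outSize)
      x2 <- preprocessXray(bp$lateral, outSize = outSize)
      pred <- fn(x1@pixels, x2@pixels, i)
      gt <- resizeVolume(pmin(pmax(vol@data / maxIntensity, 0), 1), dim(pred))
      list(gt = gt, pred = pmin(pmax(pred, 0), 1))
    })
    evaluatePairs(pairs, maxIntensity = maxIntensity,
                  ssimWinSize = ssimWinSize)
  })
  new("AngleSweepReport", angles = as.numeric(angles), reports = reports)
}
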