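#' @import methods
NULL

#' CTVolume: a 3D intensity grid with voxel spacing and origin
#'
#' The unit of reconstruction throughout the package. The array axis order is
#' fixed project-wide as (z = inferior to superior, y = posterior to anterior,
#' x = right to left); voxel sizes and origins are stored in the same order,
#' in millimetres.
#'
#' @slot data 3D numeric array of intensities (Hounsfield-like, finite).
#' @slot voxelSize numeric(3), voxel edge lengths in mm per axis (z, y, x).
#' @slot origin numeric(3), world coordinate of voxel (1,1,1) in mm.
#'
#' @seealso [ctVolume()], [readVolume()], [cropToMask()]
#' @exportClass CTVolume
setClass("CTVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must have exactly three axes (z, y, x)")
    if (any(dim(object@data) < 1L))
      msg <- c(msg, "every axis must have length >= 1")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "intensities must be finite")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive lengths")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be three finite coordinates")
    if (length(msg)) msg else TRUE
  })

#' Construct a CTVolume
#'
#' @param data 3D numeric array ordered (z, y, x).
#' @param voxelSize voxel edge lengths in mm, scalar or length 3.
#' @param origin world position of the first voxel in mm, length 3.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- ctVolume(array(0, c(4, 4, 4)))
#' @export
ctVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("CTVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' SegmentationMask: integer vertebra labels aligned to a CTVolume
#'
#' Label 0 is background; positive labels index vertebrae contiguously from 1
#' (inferior-most vertebra first).
#'
#' @slot labels 3D integer array, same shape as the companion CTVolume.
#' @slot voxelSize numeric(3), mm.
#' @slot origin numeric(3), mm.
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(labels = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must have exactly three axes")
    if (!is.integer(object@labels))
      msg <- c(msg, "labels must be stored as integers")
    else if (any(object@labels < 0L))
      msg <- c(msg, "labels must be nonnegative")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive lengths")
    if (length(msg)) msg else TRUE
  })

#' Construct a SegmentationMask
#'
#' @param labels 3D array of nonnegative integer labels, ordered (z, y, x).
#' @param voxelSize voxel edge lengths in mm, scalar or length 3.
#' @param origin world position of the first voxel in mm, length 3.
#' @return A [SegmentationMask-class] object.
#' @export
segmentationMask <- function(labels, voxelSize = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  storage.mode(labels) <- "integer"
  new("SegmentationMask", labels = labels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' BoundingBox: inclusive voxel-index box ordered (z, y, x)
#'
#' @slot minIndex integer(3), inclusive lower corner (1-based).
#' @slot maxIndex integer(3), inclusive upper corner (1-based).
#' @exportClass BoundingBox
setClass("BoundingBox",
  representation(minIndex = "integer", maxIndex = "integer"),
  validity = function(object) {
    if (length(object@minIndex) != 3L || length(object@maxIndex) != 3L)
      return("minIndex and maxIndex must each have length 3")
    if (any(object@minIndex < 1L))
      return("indices are 1-based and must be >= 1")
    if (any(object@minIndex > object@maxIndex))
      return("minIndex must be <= maxIndex componentwise")
    TRUE
  })

#' OpacityTransferFunction: six-point piecewise-linear opacity map
#'
#' Maps normalized intensity in [0, 1] to opacity in [0, 1]. Evaluation is
#' piecewise linear between the six control points and clamped to the end
#' opacities outside the covered intensity range.
#'
#' @slot points 6 x 2 numeric matrix; column 1 normalized intensity (strictly
#'   increasing, within [0, 1]), column 2 opacity (within [0, 1]).
#' @seealso [opacityTransferFunction()], [evaluateTF()]
#' @exportClass OpacityTransferFunction
setClass("OpacityTransferFunction",
  representation(points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || nrow(p) != 6L || ncol(p) != 2L)
      return("points must be a 6 x 2 numeric matrix")
    if (any(!is.finite(p))) return("control points must be finite")
    if (any(diff(p[, 1]) <= 0))
      return("control intensities must be strictly increasing")
    if (any(p[, 1] < 0 | p[, 1] > 1)) return("intensities must lie in [0, 1]")
    if (any(p[, 2] < 0 | p[, 2] > 1)) return("opacities must lie in [0, 1]")
    TRUE
  })

#' Construct an opacity transfer function
#'
#' The default control points emulate a bone-dominated X-ray preset: soft
#' tissue is faint and the cortical shell dominates the projection.
#'
#' @param points 6 x 2 matrix of (normalized intensity, opacity) pairs with
#'   strictly increasing intensities.
#' @return An [OpacityTransferFunction-class] object.
#' @examples
#' tf <- opacityTransferFunction()
#' evaluateTF(tf, c(0, 0.5, 1))
#' @export
opacityTransferFunction <- function(points = defaultTFPoints()) {
  new("OpacityTransferFunction", points = points)
}

#' Default six control points for the opacity transfer function
#' @return A 6 x 2 numeric matrix.
#' @export
defaultTFPoints <- function() {
  cbind(intensity = c(0.00, 0.10, 0.30, 0.55, 0.75, 1.00),
        opacity   = c(0.00, 0.00, 0.02, 0.10, 0.35, 0.85))
}

#' ProjectionGeometry: view angle and imaging parameters for a DRR
#'
#' @slot viewAngleDeg rotation about the z (inferior-superior) axis in
#'   degrees; 0 is the anterior view, 90 the lateral view. Within [0, 360).
#' @slot imageSize integer(2), output image size in pixels (rows, cols).
#' @slot intensityScale positive normalization divisor mapping raw intensity
#'   to [0, 1] (default 2500, the full Hounsfield-like phantom range).
#' @slot stepMm positive ray sampling distance in mm.
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
  representation(viewAngleDeg = "numeric", imageSize = "integer",
                 intensityScale = "numeric", stepMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@viewAngleDeg < 0 || object@viewAngleDeg >= 360)
      msg <- c(msg, "viewAngleDeg must lie in [0, 360)")
    if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
      msg <- c(msg, "imageSize must be two positive pixel counts")
    if (object@intensityScale <= 0)
      msg <- c(msg, "intensityScale must be positive")
    if (object@stepMm <= 0) msg <- c(msg, "stepMm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a ProjectionGeometry
#'
#' @param viewAngleDeg view angle in degrees about the z axis (0 = anterior).
#' @param imageSize output pixel size, scalar or length 2.
#' @param intensityScale normalization divisor (default 2500).
#' @param stepMm ray sampling step in mm (default 1).
#' @return A [ProjectionGeometry-class] object.
#' @export
projectionGeometry <- function(viewAngleDeg = 0, imageSize = c(128L, 128L),
                               intensityScale = 2500, stepMm = 1) {
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  new("ProjectionGeometry", viewAngleDeg = as.numeric(viewAngleDeg),
      imageSize = as.integer(imageSize),
      intensityScale = as.numeric(intensityScale), stepMm = as.numeric(stepMm))
}

#' XRayImage: a normalized 2D projection image
#'
#' Pixel rows run along z (inferior to superior) and columns along the
#' in-plane transverse axis of the view; all values lie in [0, 1].
#'
#' @slot pixels numeric matrix with values in [0, 1].
#' @slot viewAngleDeg the view angle the image was rendered at.
#' @exportClass XRayImage
setClass("XRayImage",
  representation(pixels = "matrix", viewAngleDeg = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p) || any(!is.finite(p)))
      return("pixels must be finite numeric")
    if (any(p < 0 | p > 1)) return("pixels must lie within [0, 1]")
    TRUE
  })

#' Construct an XRayImage
#' @param pixels numeric matrix in [0, 1], rows along z.
#' @param viewAngleDeg the view angle in degrees.
#' @return An [XRayImage-class] object.
#' @export
xrayImage <- function(pixels, viewAngleDeg = 0) {
  new("XRayImage", pixels = pixels, viewAngleDeg = as.numeric(viewAngleDeg))
}

#' PhantomSpec: parameters of the synthetic vertebral-column phantom
#'
#' Describes a stack of elliptic-cylinder vertebral bodies (optionally with a
#' posterior arch block) with a bright cortical shell, a medium trabecular
#' interior and a low-intensity surround. Radii and heights are ranges from
#' which per-vertebra values are drawn.
#'
#' @slot nVertebrae number of vertebral bodies (>= 1).
#' @slot bodyRadiusMm numeric(2), min/max right-left body semi-axis in mm
#'   (the posterior-anterior semi-axis is 0.75 of the drawn value, giving the
#'   anterior/lateral asymmetry the two-view model must learn).
#' @slot bodyHeightMm numeric(2), min/max body height in mm.
#' @slot discGapMm intervertebral gap in mm.
#' @slot archEnabled add a posterior arch block per vertebra.
#' @slot corticalIntensity,trabecularIntensity,backgroundIntensity intensities
#'   on a Hounsfield-like [0, 2500] scale; cortical > trabecular > background.
#' @slot noiseSd standard deviation of additive Gaussian noise (>= 0);
#'   intensities are clipped at 0 afterwards.
#' @slot volumeShape integer(3), voxel counts (z, y, x).
#' @slot voxelSizeMm numeric(3), voxel size in mm.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nVertebrae = "integer", bodyRadiusMm = "numeric",
                 bodyHeightMm = "numeric", discGapMm = "numeric",
                 archEnabled = "logical", corticalIntensity = "numeric",
                 trabecularIntensity = "numeric",
                 backgroundIntensity = "numeric", noiseSd = "numeric",
                 volumeShape = "integer", voxelSizeMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nVertebrae < 1L) msg <- c(msg, "nVertebrae must be >= 1")
    if (length(object@bodyRadiusMm) != 2L || any(object@bodyRadiusMm <= 0) ||
        object@bodyRadiusMm[1] > object@bodyRadiusMm[2])
      msg <- c(msg, "bodyRadiusMm must be a positive (min, max) range")
    if (length(object@bodyHeightMm) != 2L || any(object@bodyHeightMm <= 0) ||
        object@bodyHeightMm[1] > object@bodyHeightMm[2])
      msg <- c(msg, "bodyHeightMm must be a positive (min, max) range")
    if (object@discGapMm <= 0) msg <- c(msg, "discGapMm must be positive")
    if (!(object@corticalIntensity > object@trabecularIntensity &&
          object@trabecularIntensity > object@backgroundIntensity))
      msg <- c(msg, "need cortical > trabecular > background intensity")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
      msg <- c(msg, "volumeShape must be three positive voxel counts")
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      msg <- c(msg, "voxelSizeMm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults describe a three-vertebra column inside a 64 mm cube at 1 mm
#' voxels, with intensities on the package's Hounsfield-like [0, 2500] scale.
#'
#' @param nVertebrae number of vertebral bodies.
#' @param bodyRadiusMm (min, max) right-left semi-axis range in mm.
#' @param bodyHeightMm (min, max) body height range in mm.
#' @param discGapMm intervertebral gap in mm.
#' @param archEnabled add posterior arch blocks.
#' @param corticalIntensity,trabecularIntensity,backgroundIntensity phantom
#'   tissue intensities (cortical > trabecular > background).
#' @param noiseSd additive Gaussian noise sd (0 disables noise).
#' @param volumeShape voxel counts (z, y, x), scalar or length 3.
#' @param voxelSizeMm voxel size in mm, scalar or length 3.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(nVertebrae = 3, noiseSd = 0)
#' @export
phantomSpec <- function(nVertebrae = 3L, bodyRadiusMm = c(9, 13),
                        bodyHeightMm = c(8, 12), discGapMm = 4,
                        archEnabled = TRUE, corticalIntensity = 1500,
                        trabecularIntensity = 500, backgroundIntensity = 50,
                        noiseSd = 20, volumeShape = c(64L, 64L, 64L),
                        voxelSizeMm = c(1, 1, 1)) {
  if (length(volumeShape) == 1L) volumeShape <- rep(volumeShape, 3L)
  if (length(voxelSizeMm) == 1L) voxelSizeMm <- rep(voxelSizeMm, 3L)
  if (length(bodyRadiusMm) == 1L) bodyRadiusMm <- rep(bodyRadiusMm, 2L)
  if (length(bodyHeightMm) == 1L) bodyHeightMm <- rep(bodyHeightMm, 2L)
  new("PhantomSpec", nVertebrae = as.integer(nVertebrae),
      bodyRadiusMm = as.numeric(bodyRadiusMm),
      bodyHeightMm = as.numeric(bodyHeightMm), discGapMm = as.numeric(discGapMm),
      archEnabled = isTRUE(archEnabled),
      corticalIntensity = as.numeric(corticalIntensity),
      trabecularIntensity = as.numeric(trabecularIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSd = as.numeric(noiseSd), volumeShape = as.integer(volumeShape),
      voxelSizeMm = as.numeric(voxelSizeMm))
}

#' PairedSample: one training/evaluation record
#'
#' @slot ct normalized 3D grid in [0, 1].
#' @slot xray1 anterior [XRayImage-class].
#' @slot xray2 lateral [XRayImage-class].
#' @slot caseId case identifier.
#' @exportClass PairedSample
setClass("PairedSample",
  representation(ct = "array", xray1 = "XRayImage", xray2 = "XRayImage",
                 caseId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@ct)) != 3L) msg <- c(msg, "ct must be 3D")
    if (any(object@ct < 0 | object@ct > 1))
      msg <- c(msg, "ct values must lie in [0, 1]")
    d1 <- dim(object@xray1@pixels); d2 <- dim(object@xray2@pixels)
    if (d1[1] != d1[2] || !all(d1 == d2))
      msg <- c(msg, "the two X-rays must be square and equal-sized")
    if (length(msg)) msg else TRUE
  })

#' Construct a PairedSample
#' @param ct normalized 3D array in [0, 1].
#' @param xray1,xray2 anterior and lateral [XRayImage-class] objects (square,
#'   equal-sized).
#' @param caseId case identifier string.
#' @return A [PairedSample-class] object.
#' @export
pairedSample <- function(ct, xray1, xray2, caseId = "case") {
  new("PairedSample", ct = ct, xray1 = xray1, xray2 = xray2,
      caseId = as.character(caseId))
}

#' DatasetSplit: disjoint train/test case identifier lists
#'
#' @slot trainIds,testIds character vectors; disjoint, union = all ids.
#' @exportClass DatasetSplit
setClass("DatasetSplit",
  representation(trainIds = "character", testIds = "character"),
  validity = function(object) {
    if (length(intersect(object@trainIds, object@testIds)))
      return("train and test ids must be disjoint")
    TRUE
  })

#' LossWeights: weights of the generator objective terms
#'
#' @slot wGan,wRecon,wProj,wFm,wIdt nonnegative weights of the adversarial,
#'   voxel reconstruction (MSE), mean-projection, feature-matching and
#'   input-consistency (identity) losses. At least one must be positive.
#' @exportClass LossWeights
setClass("LossWeights",
  representation(wGan = "numeric", wRecon = "numeric", wProj = "numeric",
                 wFm = "numeric", wIdt = "numeric"),
  validity = function(object) {
    w <- c(object@wGan, object@wRecon, object@wProj, object@wFm, object@wIdt)
    if (any(w < 0)) return("all loss weights must be nonnegative")
    if (all(w == 0)) return("at least one loss weight must be positive")
    TRUE
  })

#' Construct LossWeights
#' @param wGan,wRecon,wProj,wFm,wIdt nonnegative term weights.
#' @return A [LossWeights-class] object.
#' @export
lossWeights <- function(wGan = 0.1, wRecon = 10, wProj = 10, wFm = 10,
                        wIdt = 5) {
  new("LossWeights", wGan = wGan, wRecon = wRecon, wProj = wProj, wFm = wFm,
      wIdt = wIdt)
}

#' GanConfig: hyper-parameters of the two-view reconstruction GAN
#'
#' @slot learningRate Adam learning rate (default 2e-4).
#' @slot beta1,beta2 Adam moment decay rates (defaults 0.5 and 0.99).
#' @slot batchSize training batch size (default 1).
#' @slot nEpochs number of training epochs.
#' @slot baseChannels channel width of the first encoder level; deeper levels
#'   scale multiples of it.
#' @slot volumeSize output edge length in voxels; a power of two >= 16
#'   (default 128; 32 is the desk-scale test size).
#' @slot lossWeights a [LossWeights-class] object.
#' @slot seed integer seed covering initialization, data order and
#'   augmentation.
#' @slot checkpointEvery save a checkpoint every this many epochs (0 = only
#'   at the end).
#' @exportClass GanConfig
setClass("GanConfig",
  representation(learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", batchSize = "integer",
                 nEpochs = "integer", baseChannels = "integer",
                 volumeSize = "integer", lossWeights = "LossWeights",
                 seed = "integer", checkpointEvery = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@beta1 < 0 || object@beta1 >= 1 ||
        object@beta2 < 0 || object@beta2 >= 1)
      msg <- c(msg, "beta1 and beta2 must lie in [0, 1)")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    v <- object@volumeSize
    if (v < 16L || bitwAnd(v, v - 1L) != 0L)
      msg <- c(msg, "volumeSize must be a power of two >= 16")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a GanConfig
#' @param learningRate Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batchSize training batch size.
#' @param nEpochs number of epochs.
#' @param baseChannels base channel width.
#' @param volumeSize output cube edge in voxels (power of two >= 16).
#' @param lossWeights a [LossWeights-class] object.
#' @param seed integer seed.
#' @param checkpointEvery checkpoint interval in epochs (0 = end only).
#' @return A [GanConfig-class] object.
#' @export
ganConfig <- function(learningRate = 2e-4, beta1 = 0.5, beta2 = 0.99,
                      batchSize = 1L, nEpochs = 10L, baseChannels = 16L,
                      volumeSize = 128L, lossWeights = NULL,
                      seed = 1L, checkpointEvery = 0L) {
  if (is.null(lossWeights)) lossWeights <- BiplanarCT::lossWeights()
  new("GanConfig", learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      batchSize = as.integer(batchSize), nEpochs = as.integer(nEpochs),
      baseChannels = as.integer(baseChannels),
      volumeSize = as.integer(volumeSize), lossWeights = lossWeights,
      seed = as.integer(seed), checkpointEvery = as.integer(checkpointEvery))
}

#' MetricReport: the eleven-statistic volumetric evaluation record
#'
#' Holds the full evaluation suite for one ground-truth/reconstruction pair,
#' or the plain mean over a set of pairs.
#'
#' @slot mae0,mse0 per-slice mean absolute/squared error on the normalized
#'   [0, 1] scale.
#' @slot mae,mse whole-volume errors on the denormalized intensity scale.
#' @slot cosine cosine similarity in [-1, 1].
#' @slot psnr1,psnr2,psnr3 slice-averaged PSNR (dB) along the axial, coronal
#'   and sagittal axes.
#' @slot psnrAvg mean of psnr1..psnr3 (exact).
#' @slot psnr3d PSNR of the whole volume in one computation (dB).
#' @slot ssim slice-averaged structural similarity in [-1, 1].
#' @slot n number of pairs averaged (1 for a single pair).
#' @exportClass MetricReport
setClass("MetricReport",
  representation(mae0 = "numeric", mse0 = "numeric", mae = "numeric",
                 mse = "numeric", cosine = "numeric", psnr1 = "numeric",
                 psnr2 = "numeric", psnr3 = "numeric", psnrAvg = "numeric",
                 psnr3d = "numeric", ssim = "numeric", n = "integer"),
  validity = function(object) {
    vals <- c(object@mae0, object@mse0, object@mae, object@mse, object@cosine,
              object@psnr1, object@psnr2, object@psnr3, object@psnrAvg,
              object@psnr3d, object@ssim)
    if (any(!is.finite(vals))) return("all metric fields must be finite")
    if (abs(object@psnrAvg - mean(c(object@psnr1, object@psnr2,
                                    object@psnr3))) > 1e-12 * max(1, abs(object@psnrAvg)))
      return("psnrAvg must equal the mean of psnr1..psnr3")
    TRUE
  })

#' AngleSweepReport: one MetricReport per biplanar angle
#'
#' @slot angles numeric vector of lateral view angles in degrees.
#' @slot reports list of [MetricReport-class], one per angle, same order.
#' @exportClass AngleSweepReport
setClass("AngleSweepReport",
  representation(angles = "numeric", reports = "list"),
  validity = function(object) {
    if (length(object@angles) != length(object@reports))
      return("one report per angle required")
    if (!all(vapply(object@reports, is, logical(1), class2 = "MetricReport")))
      return("reports must all be MetricReport objects")
    TRUE
  })
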