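#' @include AllClasses.R
NULL

#' Extract the voxel/pixel data of an image object
#' @param x a CTVolume, SegmentationMask or XRayImage.
#' @return The underlying numeric array or matrix.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' Voxel size in millimetres, ordered (z, y, x)
#' @param x a CTVolume or SegmentationMask.
#' @return numeric(3).
#' @export
setGeneric("voxelSizeMm", function(x) standardGeneric("voxelSizeMm"))

#' World origin in millimetres, ordered (z, y, x)
#' @param x a CTVolume or SegmentationMask.
#' @return numeric(3).
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' View angle of a projection image, in degrees
#' @param x an XRayImage.
#' @return numeric(1).
#' @export
setGeneric("viewAngle", function(x) standardGeneric("viewAngle"))

#' Train/test partitions of a DatasetSplit
#' @param x a DatasetSplit.
#' @return character vector of case ids.
#' @rdname splitAccessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname splitAccessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @describeIn imageValues voxel intensities of a CTVolume
#' @export
setMethod("imageValues", "CTVolume", function(x) x@data)

#' @describeIn imageValues integer labels of a SegmentationMask
#' @export
setMethod("imageValues", "SegmentationMask", function(x) x@labels)

#' @describeIn imageValues pixel matrix of an XRayImage
#' @export
setMethod("imageValues", "XRayImage", function(x) x@pixels)

#' @rdname voxelSizeMm
#' @export
setMethod("voxelSizeMm", "CTVolume", function(x) x@voxelSize)

#' @rdname voxelSizeMm
#' @export
setMethod("voxelSizeMm", "SegmentationMask", function(x) x@voxelSize)

#' @rdname originMm
#' @export
setMethod("originMm", "CTVolume", function(x) x@origin)

#' @rdname originMm
#' @export
setMethod("originMm", "SegmentationMask", function(x) x@origin)

#' @rdname viewAngle
#' @export
setMethod("viewAngle", "XRayImage", function(x) x@viewAngleDeg)

#' @rdname splitAccessors
#' @export
setMethod("trainIds", "DatasetSplit", function(x) x@trainIds)

#' @rdname splitAccessors
#' @export
setMethod("testIds", "DatasetSplit", function(x) x@testIds)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels (z, y, x)\n")
  cat("  voxel size:", paste(format(object@voxelSize), collapse = " x "),
      "mm; origin:", paste(format(object@origin), collapse = ", "), "mm\n")
  cat("  intensity range: [", format(min(object@data)), ",",
      format(max(object@data)), "]\n")
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  labs <- sort(unique(as.vector(object@labels)))
  cat("SegmentationMask:", paste(d, collapse = " x "), "voxels;",
      sum(labs > 0), "vertebra label(s)\n")
})

setMethod("show", "OpacityTransferFunction", function(object) {
  cat("OpacityTransferFunction with 6 control points:\n")
  p <- object@points
  cat(paste0("  (", format(p[, 1]), ", ", format(p[, 2]), ")", collapse = "\n"),
      "\n")
})

setMethod("show", "XRayImage", function(object) {
  d <- dim(object@pixels)
  cat("XRayImage:", d[1], "x", d[2], "pixels at",
      object@viewAngleDeg, "degrees\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nVertebrae, "vertebra(e) in a",
      paste(object@volumeShape, collapse = " x "), "volume\n")
  cat("  intensities (cortical/trabecular/background):",
      object@corticalIntensity, "/", object@trabecularIntensity, "/",
      object@backgroundIntensity, "; noise sd", object@noiseSd, "\n")
})

setMethod("show", "PairedSample", function(object) {
  cat("PairedSample", sQuote(object@caseId), ": ct",
      paste(dim(object@ct), collapse = "x"), "; x-rays",
      paste(dim(object@xray1@pixels), collapse = "x"), "\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat("DatasetSplit:", length(object@trainIds), "train /",
      length(object@testIds), "test cases\n")
})

setMethod("show", "GanConfig", function(object) {
  cat("GanConfig: output", object@volumeSize, "^3, base channels",
      object@baseChannels, ", lr", object@learningRate, ", epochs",
      object@nEpochs, "\n")
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport over", object@n, "pair(s):\n")
  print(metricTable(object), row.names = FALSE)
})

setMethod("show", "AngleSweepReport", function(object) {
  cat("AngleSweepReport over angles:",
      paste(object@angles, collapse = ", "), "degrees\n")
  print(sweepTable(object), row.names = FALSE)
})
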