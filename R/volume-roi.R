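#' @include AllClasses.R
NULL

niftiAffine <- function(voxelSize, origin) {
  aff <- diag(c(voxelSize, 1))
  aff[1:3, 4] <- origin
  aff
}

writeNiftiArray <- function(arr, voxelSize, origin, path, datatype) {
  d <- dim(arr)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(1, voxelSize, 1, 1, 1, 1)))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = datatype)
  img <- RNifti::`sform<-`(img,
    structure(niftiAffine(voxelSize, origin), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

readNiftiArray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable NIfTI header in ",
                                           sQuote(path), ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimension(s) in ",
         sQuote(path))
  aff <- RNifti::xform(img)
  list(data = array(as.vector(img), dim = d),
       voxelSize = as.numeric(RNifti::pixdim(img)),
       origin = as.numeric(aff[1:3, 4]))
}

#' Read and write CT volumes as NIfTI
#'
#' The round trip preserves voxel data, voxel size and origin exactly (within
#' the file format's numeric width). The affine stored in the header is
#' `diag(voxelSize)` plus the origin translation, with the NIfTI axes
#' following the package's (z, y, x) array order.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `readVolume` returns a [CTVolume-class]; `writeVolume` invisibly
#'   returns `path`.
#' @examples
#' ph <- generatePhantom(phantomSpec(volumeShape = 24L, nVertebrae = 1L,
#'                                   bodyRadiusMm = c(6, 6),
#'                                   bodyHeightMm = c(6, 6)), seed = 1)
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ph$ct, f)
#' vol <- readVolume(f)
#' stopifnot(identical(imageValues(vol), imageValues(ph$ct)))
#' @export
readVolume <- function(path) {
  r <- readNiftiArray(path)
  ctVolume(r$data, r$voxelSize, r$origin)
}

#' @rdname readVolume
#' @param vol a [CTVolume-class] to write.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  writeNiftiArray(vol@data, vol@voxelSize, vol@origin, path,
                  datatype = "double")
}

#' Read and write segmentation masks as NIfTI
#'
#' Integer labels are preserved exactly (stored as 32-bit integers).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `readMask` returns a [SegmentationMask-class]; `writeMask`
#'   invisibly returns `path`.
#' @export
readMask <- function(path) {
  r <- readNiftiArray(path)
  segmentationMask(r$data, r$voxelSize, r$origin)
}

#' @rdname readMask
#' @param mask a [SegmentationMask-class] to write.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  writeNiftiArray(mask@labels, mask@voxelSize, mask@origin, path,
                  datatype = "int32")
}

#' Tightest bounding box of the nonzero mask voxels
#'
#' Returns the inclusive voxel-index box, ordered (z, y, x), containing every
#' nonzero label. Errors on an all-zero mask, where the box is undefined.
#'
#' @param mask a [SegmentationMask-class] (or a plain 3D array of labels).
#' @return A [BoundingBox-class] with 1-based inclusive `minIndex` and
#'   `maxIndex`.
#' @export
maskBoundingBox <- function(mask) {
  labels <- if (is(mask, "SegmentationMask")) mask@labels else mask
  nz <- which(labels > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("empty mask: no nonzero voxels to bound")
  new("BoundingBox",
      minIndex = as.integer(apply(nz, 2L, min)),
      maxIndex = as.integer(apply(nz, 2L, max)))
}

#' Crop a CT volume and its mask to the mask's bounding box
#'
#' Both the volume and the mask are restricted to the tightest box containing
#' all nonzero labels; both ends are inclusive, so the output extent per axis
#' is `max - min + 1`. The origin is shifted by `(min - 1) * voxelSize` so
#' world coordinates of retained voxels are unchanged.
#'
#' @param vol a [CTVolume-class].
#' @param mask the aligned [SegmentationMask-class] (same shape).
#' @return A list with cropped `ct` and `mask`.
#' @export
cropToMask <- function(vol, mask) {
  stopifnot(is(vol, "CTVolume"), is(mask, "SegmentationMask"))
  if (!identical(dim(vol@data), dim(mask@labels)))
    stop("volume and mask shapes differ: ",
         paste(dim(vol@data), collapse = "x"), " vs ",
         paste(dim(mask@labels), collapse = "x"))
  bb <- maskBoundingBox(mask)
  zi <- bb@minIndex[1]:bb@maxIndex[1]
  yi <- bb@minIndex[2]:bb@maxIndex[2]
  xi <- bb@minIndex[3]:bb@maxIndex[3]
  shift <- (bb@minIndex - 1L) * vol@voxelSize
  list(ct = ctVolume(vol@data[zi, yi, xi, drop = FALSE], vol@voxelSize,
                     vol@origin + shift),
       mask = segmentationMask(mask@labels[zi, yi, xi, drop = FALSE],
                               mask@voxelSize, mask@origin + shift))
}
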