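#' @include AllClasses.R utils-interp.R
NULL

#' Evaluate an opacity transfer function
#'
#' Piecewise-linear interpolation between the six control points, clamped to
#' the first/last control opacity outside the covered intensity range.
#'
#' @param tf an [OpacityTransferFunction-class].
#' @param v normalized intensities (any numeric vector/array; must be finite).
#' @return Opacities with the same shape as `v`.
#' @examples
#' tf <- opacityTransferFunction()
#' evaluateTF(tf, c(0, 0.875, 2))  # knot, midway, clamped
#' @export
evaluateTF <- function(tf, v) {
  stopifnot(is(tf, "OpacityTransferFunction"))
  if (any(!is.finite(v))) stop("non-finite intensity passed to evaluateTF")
  p <- tf@points
  out <- stats::approx(p[, 1], p[, 2], xout = as.vector(v), rule = 2)$y
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

#' Synthesize a digitally reconstructed radiograph (DRR)
#'
#' Projects a CT volume to a 2D X-ray-like image: the volume is rotated by
#' `viewAngleDeg` about the z axis (trilinear interpolation, which for a pure
#' z-rotation reduces to bilinear in each transverse plane; background filled
#' with the minimum intensity), intensities are normalized
#' by `intensityScale` and clipped to [0, 1], and parallel rays are cast
#' along the y axis (posterior to anterior) compositing front to back with
#' the emission-absorption rule: with per-sample opacity
#' \eqn{\alpha_i = tf(v_i)} and emission \eqn{c_i = v_i},
#' \eqn{C \leftarrow C + (1-A)\alpha_i c_i} and
#' \eqn{A \leftarrow A + (1-A)\alpha_i}, at sample spacing `stepMm`. The
#' image is then min-max rescaled to [0, 1] and resampled to
#' `imageSize`. Deterministic.
#'
#' An all-constant projection (nothing absorbs or emits) degenerates the
#' rescale; an all-zeros image is returned with a warning.
#'
#' @param vol a [CTVolume-class].
#' @param tf an [OpacityTransferFunction-class].
#' @param geom a [ProjectionGeometry-class] (angle, image size, intensity
#'   scale, ray step).
#' @param mode `"composite"` (default, emission-absorption) or
#'   `"attenuation"` (Beer-Lambert: pixel = 1 - exp(-optical depth)).
#' @param rescale min-max rescale the raw accumulation to [0, 1].
#' @param resize resample the native (nz x nx) image to `geom@imageSize`.
#' @return An [XRayImage-class]; rows run along z, columns along the
#'   in-plane transverse axis.
#' @export
projectDRR <- function(vol, tf, geom = projectionGeometry(),
                       mode = c("composite", "attenuation"),
                       rescale = TRUE, resize = TRUE) {
  stopifnot(is(vol, "CTVolume"), is(tf, "OpacityTransferFunction"),
            is(geom, "ProjectionGeometry"))
  mode <- match.arg(mode)
  a <- vol@data
  if (length(a) == 0L) stop("empty volume")
  rot <- rotateVolumeZ(a, geom@viewAngleDeg, fill = min(a))
  v <- pmin(pmax(rot / geom@intensityScale, 0), 1)
  d <- dim(v)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  stepVox <- geom@stepMm / vol@voxelSize[2]
  tpos <- seq(1, ny, by = stepVox)
  C <- matrix(0, nz, nx)
  A <- matrix(0, nz, nx)
  for (t in tpos) {
    f <- min(floor(t), ny - 1L)
    if (ny == 1L) { slice <- v[, 1, ]; dim(slice) <- c(nz, nx) }
    else {
      w <- t - f
      slice <- v[, f, ] * (1 - w) + v[, f + 1, ] * w
      dim(slice) <- c(nz, nx)
    }
    alpha <- evaluateTF(tf, slice)
    if (mode == "composite") {
      C <- C + (1 - A) * alpha * slice
      A <- A + (1 - A) * alpha
    } else {
      A <- A + alpha  # optical depth accumulation
    }
  }
  img <- if (mode == "composite") C else 1 - exp(-A)
  if (rescale) img <- rescale01(img, warnDegenerate = TRUE)
  else img <- pmin(pmax(img, 0), 1)
  if (resize) img <- resizeBilinear(img, geom@imageSize[1], geom@imageSize[2])
  xrayImage(pmin(pmax(img, 0), 1), geom@viewAngleDeg)
}

#' Render a biplanar X-ray pair
#'
#' The anterior view is projected at 0 degrees and the lateral view at
#' `lateralAngleDeg` (90 for the standard orthogonal setup; 85/80/75 for the
#' angle-sensitivity sweep).
#'
#' @param vol a [CTVolume-class].
#' @param tf an [OpacityTransferFunction-class].
#' @param lateralAngleDeg lateral view angle in degrees, within (0, 180).
#' @param geom a [ProjectionGeometry-class] template (its angle is
#'   overridden per view).
#' @param ... passed on to [projectDRR()].
#' @return A list with [XRayImage-class] elements `anterior` and `lateral`.
#' @export
makeBiplanar <- function(vol, tf, lateralAngleDeg = 90,
                         geom = projectionGeometry(), ...) {
  if (lateralAngleDeg <= 0 || lateralAngleDeg >= 180)
    stop("lateralAngleDeg must lie in (0, 180)")
  gA <- geom; gA@viewAngleDeg <- 0
  gL <- geom; gL@viewAngleDeg <- as.numeric(lateralAngleDeg)
  list(anterior = projectDRR(vol, tf, gA, ...),
       lateral = projectDRR(vol, tf, gL, ...))
}

#' Read and write X-ray images as 8-bit grayscale PNG
#'
#' @param img an [XRayImage-class].
#' @param path output `.png` path.
#' @return `writeXRay` invisibly returns `path`; `readXRay` returns a numeric
#'   matrix in [0, 1] (multi-channel files are averaged to luminance).
#' @export
writeXRay <- function(img, path) {
  stopifnot(is(img, "XRayImage"))
  png::writePNG(img@pixels, target = path)
  invisible(path)
}

#' @rdname writeXRay
#' @export
readXRay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
  p
}
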