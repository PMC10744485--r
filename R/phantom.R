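#' @include AllClasses.R
NULL

# derive a reproducible per-case RNG seed from a master seed; kept below
# 2^31 so it is a valid R integer
caseSeed <- function(masterSeed, caseIndex) {
  as.integer((as.numeric(masterSeed) * 7919 + caseIndex * 104729) %% 2147483647)
}

#' Generate a synthetic vertebral-column CT phantom
#'
#' Builds a stack of `nVertebrae` elliptic-cylinder vertebral bodies centred
#' on the z axis, each with a thin cortical shell at `corticalIntensity`, a
#' trabecular interior, and (optionally) a posterior arch block; everything
#' else is `backgroundIntensity`. Zero-mean Gaussian noise of sd `noiseSd` is
#' added and intensities clipped at 0. The aligned segmentation mask labels
#' the i-th vertebra (body plus arch) with label i, voxel-exactly.
#'
#' The generator is deterministic given `(spec, seed)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed.
#' @return A list with elements `ct` ([CTVolume-class]) and `mask`
#'   ([SegmentationMask-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0), seed = 1)
#' table(imageValues(ph$mask) > 0)
#' @export
generatePhantom <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  shp <- spec@volumeShape
  vz <- spec@voxelSizeMm[1]; vy <- spec@voxelSizeMm[2]; vx <- spec@voxelSizeMm[3]
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]

  n <- spec@nVertebrae
  radii <- stats::runif(n, spec@bodyRadiusMm[1], spec@bodyRadiusMm[2])
  heights <- stats::runif(n, spec@bodyHeightMm[1], spec@bodyHeightMm[2])

  # column extent along z (mm): bodies plus gaps, centred in the volume
  totalH <- sum(heights) + (n - 1) * spec@discGapMm
  if (totalH >= nz * vz)
    stop("phantom exceeds volume_shape along z (needs ", format(totalH),
         " mm, volume is ", nz * vz, " mm)")
  maxR <- max(radii)
  archDepth <- if (spec@archEnabled) 6 else 0
  if (2 * maxR >= nx * vx)
    stop("phantom exceeds volume_shape along x (body diameter ",
         format(2 * maxR), " mm, volume is ", nx * vx, " mm)")
  if (2 * 0.75 * maxR + archDepth >= ny * vy)
    stop("phantom exceeds volume_shape along y (body depth ",
         format(2 * 0.75 * maxR + archDepth), " mm, volume is ",
         ny * vy, " mm)")

  # world coordinates of voxel centres (origin at volume corner)
  zc <- (seq_len(nz) - 0.5) * vz
  yc <- (seq_len(ny) - 0.5) * vy
  xc <- (seq_len(nx) - 0.5) * vx
  cy <- ny * vy / 2; cx <- nx * vx / 2

  data <- array(spec@backgroundIntensity, dim = shp)
  labels <- array(0L, dim = shp)

  shellMm <- 1.5 * max(vx, vy)  # 1-2 voxel cortical shell
  z0 <- (nz * vz - totalH) / 2
  for (i in seq_len(n)) {
    rx <- radii[i]; ry <- 0.75 * radii[i]; h <- heights[i]
    zlo <- z0; zhi <- z0 + h
    z0 <- zhi + spec@discGapMm
    zidx <- which(zc >= zlo & zc < zhi)
    if (!length(zidx)) next
    # normalized elliptic radius on the (y, x) plane
    ry2 <- outer((yc - cy) / ry, rep(1, nx))^2
    rx2 <- outer(rep(1, ny), (xc - cx) / rx)^2
    rr <- sqrt(ry2 + rx2)
    inner <- 1 - shellMm / min(rx, ry)
    body <- rr <= 1
    core <- rr <= inner
    plane <- array(spec@backgroundIntensity, c(ny, nx))
    plane[body] <- spec@corticalIntensity
    plane[core] <- spec@trabecularIntensity
    inBody <- body
    if (spec@archEnabled) {
      # posterior arch: a block behind the body with a trabecular core,
      # spanning the central half of the body width
      yB <- yc >= (cy - ry - archDepth) & yc < (cy - ry)
      xB <- abs(xc - cx) <= rx / 2
      archSel <- outer(yB, xB, "&")
      plane[archSel] <- spec@corticalIntensity
      archCore <- outer(yc >= (cy - ry - archDepth + shellMm) &
                          yc < (cy - ry - shellMm),
                        abs(xc - cx) <= rx / 2 - shellMm, "&")
      plane[archCore] <- spec@trabecularIntensity
      inBody <- inBody | archSel
    }
    for (zi in zidx) {
      data[zi, , ] <- plane
      sl <- labels[zi, , ]
      sl[inBody] <- i
      labels[zi, , ] <- sl
    }
  }

  if (spec@noiseSd > 0) {
    data <- data + stats::rnorm(length(data), sd = spec@noiseSd)
    data[data < 0] <- 0
  }

  list(ct = ctVolume(data, spec@voxelSizeMm),
       mask = segmentationMask(labels, spec@voxelSizeMm))
}

#' Generate a cohort of phantom cases on disk
#'
#' Draws per-case phantom parameters from `specRanges` under a seeded
#' generator (one independent pseudo-random stream per case, derived from the
#' master seed and case index so cohorts are reproducible), writes each case's
#' CT and mask as NIfTI files in its own directory, and returns the directory
#' paths in creation order.
#'
#' @param nCases number of cases (>= 1).
#' @param seed master integer seed.
#' @param outDir output directory (created if missing).
#' @param specRanges a [PhantomSpec-class] serving as the per-case parameter
#'   template; `nVertebraeRange` additionally varies the vertebra count.
#' @param nVertebraeRange integer (min, max) number of vertebrae per case.
#' @return Character vector of case directory paths, in creation order.
#' @export
generateCohort <- function(nCases, seed = 1L, outDir,
                           specRanges = phantomSpec(),
                           nVertebraeRange = c(2L, 4L)) {
  stopifnot(nCases >= 1)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", sQuote(outDir))
  dirs <- character(nCases)
  for (i in seq_len(nCases)) {
    si <- caseSeed(seed, i)
    set.seed(si)
    nv <- sample(seq(nVertebraeRange[1], nVertebraeRange[2]), 1L)
    spec <- specRanges
    spec@nVertebrae <- as.integer(nv)
    ph <- generatePhantom(spec, seed = caseSeed(si, 1L))
    caseDir <- file.path(outDir, sprintf("case_%03d", i))
    dir.create(caseDir, showWarnings = FALSE)
    writeVolume(ph$ct, file.path(caseDir, "ct.nii.gz"))
    writeMask(ph$mask, file.path(caseDir, "mask.nii.gz"))
    dirs[i] <- caseDir
  }
  dirs
}
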