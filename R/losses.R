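#' @include autograd.R
NULL

#' Least-squares GAN losses
#'
#' `lossD = mean((dReal - 1)^2)/2 + mean(dFake^2)/2` and
#' `lossGAdv = mean((dFake - 1)^2)`: squared distances to the real/fake
#' target labels rather than log-likelihoods.
#'
#' @param dReal,dFake discriminator score grids (numeric arrays) for real
#'   and generated volumes; must be finite.
#' @return A list with `lossD` and `lossGAdv`.
#' @export
lsganLoss <- function(dReal, dFake) {
  if (any(!is.finite(dReal)) || any(!is.finite(dFake)))
    stop("non-finite discriminator scores")
  list(lossD = 0.5 * mean((dReal - 1)^2) + 0.5 * mean(dFake^2),
       lossGAdv = mean((dFake - 1)^2))
}

#' Voxel-wise reconstruction loss (MSE)
#'
#' @param genVol,gtVol equal-shaped volumes with values in [0, 1].
#' @return Mean squared error over all voxels.
#' @export
reconstructionLoss <- function(genVol, gtVol) {
  if (!identical(dim(genVol), dim(gtVol))) stop("shape mismatch")
  mean((genVol - gtVol)^2)
}

meanProjection <- function(vol, axis) apply(vol, setdiff(1:3, axis), mean)

#' Mean-projection consistency loss
#'
#' Mean over the three orthogonal axes of the MSE between the axis-mean
#' projections (2D maps) of the generated and ground-truth volumes. Volumes
#' that differ only by permutations of values within projection rays share
#' all three projections and score zero here while still having a positive
#' reconstruction loss.
#'
#' @param genVol,gtVol equal-shaped 3D volumes.
#' @return A nonnegative scalar.
#' @export
projectionLoss <- function(genVol, gtVol) {
  if (!identical(dim(genVol), dim(gtVol))) stop("shape mismatch")
  mean(vapply(1:3, function(ax)
    mean((meanProjection(genVol, ax) - meanProjection(gtVol, ax))^2),
    numeric(1)))
}

#' Feature-matching loss
#'
#' Mean absolute difference between the discriminator's intermediate-layer
#' activations for real versus generated inputs, averaged over layers.
#'
#' @param featsReal,featsFake equal-length lists of equal-shaped numeric
#'   arrays.
#' @return A nonnegative scalar.
#' @export
featureMatchingLoss <- function(featsReal, featsFake) {
  if (length(featsReal) != length(featsFake))
    stop("feature list lengths differ")
  vals <- mapply(function(a, b) {
    if (!identical(dim(a), dim(b))) stop("feature shape mismatch")
    mean(abs(a - b))
  }, featsReal, featsFake)
  mean(vals)
}
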