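#' @include nn-ops.R
NULL

# replicate the anterior X-ray along its projection axis (y) and the lateral
# X-ray along its own projection axis (x) to volume-shaped condition channels
conditionChannels <- function(x1, x2, N) {
  c1 <- aperm(array(x1, c(N, N, N)), c(1, 3, 2))  # c1[z,y,x] = x1[z,x]
  c2 <- array(x2, c(N, N, N))                     # c2[z,y,x] = x2[z,y]
  list(c1 = c1, c2 = c2)
}

#' Build the conditional 3D patch discriminator
#'
#' A 3D convolutional stack with instance normalization and no dropout.
#' Conditioning concatenates each input X-ray, replicated along its own
#' projection axis, to the candidate volume as extra channels. The output is
#' a grid of real/fake scores over (volumeSize/4)^3 patches.
#'
#' @param cfg a [GanConfig-class].
#' @return A discriminator object (list with `params`, `cfg`), class
#'   `"ctDiscriminator"`.
#' @export
buildDiscriminator <- function(cfg) {
  stopifnot(is(cfg, "GanConfig"))
  set.seed(cfg@seed + 1L)
  C <- cfg@baseChannels
  params <- list(
    c1 = convParam(27L, 3L, C),
    in1 = list(gamma = newParam(rep(1, C)), beta = newParam(numeric(C))),
    c2 = convParam(27L, C, 2L * C),
    in2 = list(gamma = newParam(rep(1, 2L * C)),
               beta = newParam(numeric(2L * C))),
    c3 = convParam(27L, 2L * C, 2L * C),
    score = convParam(1L, 2L * C, 1L))
  structure(list(params = params, cfg = cfg), class = "ctDiscriminator")
}

# forward pass; vol is a tensor or array shaped (N, N, N, 1); x1/x2 are
# N x N condition matrices (constants, no gradient flows into them).
# Returns the patch score tensor and the intermediate feature tensors used
# by the feature-matching loss.
discForward <- function(disc, vol, x1, x2) {
  p <- disc$params
  N <- disc$cfg@volumeSize
  vol <- agConst(vol)
  dv <- dim(vol$val)
  if (length(dv) != 4L || !all(dv == c(N, N, N, 1L)))
    stop("discriminator input must be a ", N, "^3 single-channel volume")
  cond <- conditionChannels(x1, x2, N)
  xin <- agConcatC(vol, agConst(array(c(cond$c1, cond$c2), c(N, N, N, 2L))))
  f1 <- agRelu(agConv(xin, p$c1$W, p$c1$b))
  x <- agInstNorm(agPool(f1), p$in1$gamma, p$in1$beta)
  f2 <- agRelu(agConv(x, p$c2$W, p$c2$b))
  x <- agInstNorm(agPool(f2), p$in2$gamma, p$in2$beta)
  f3 <- agRelu(agConv(x, p$c3$W, p$c3$b))
  scores <- agConv(f3, p$score$W, p$score$b, k = 1L)
  list(scores = scores, features = list(f1, f2, f3))
}

#' Score a candidate volume with the discriminator
#'
#' Inference-mode forward pass (deterministic; the network has no dropout).
#'
#' @param disc a discriminator from [buildDiscriminator()].
#' @param vol a `volumeSize`^3 array in [0, 1] (an optional trailing
#'   singleton channel axis is accepted).
#' @param xray1,xray2 condition images, matrices or [XRayImage-class].
#' @return A 3D array of patch scores.
#' @export
predictScores <- function(disc, vol, xray1, xray2) {
  stopifnot(inherits(disc, "ctDiscriminator"))
  N <- disc$cfg@volumeSize
  m1 <- if (is(xray1, "XRayImage")) xray1@pixels else xray1
  m2 <- if (is(xray2, "XRayImage")) xray2@pixels else xray2
  m1 <- resizeBilinear(m1, N, N)
  m2 <- resizeBilinear(m2, N, N)
  if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
  out <- agNoGrad(discForward(disc, vol, m1, m2))
  s <- out$scores$val
  dim(s) <- dim(s)[1:3]
  s
}
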