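#' @include nn-ops.R
NULL

# ---------------------------------------------------------------------------
# Two-view fusion generator.
#
# Each X-ray view feeds a 2D encoder with dense (concatenative) connections
# at four scales (N .. N/8). At the two coarsest scales the 2D feature maps
# are channel-matched by 1x1 2D convolutions, expanded along the view's own
# projection axis into pseudo-3D grids, and refined by 3D convolutions. Each
# view then runs its own 3D decoder (kernel-2 stride-2 transposed
# convolutions with skip connections); the lateral decoder's grids are
# rotated 90 degrees about z into the anterior frame (exact lattice rotation)
# and averaged element-wise with the anterior grids, feeding a third decoding
# stream that emits the final volume through a sigmoid. ReLU activations
# throughout.
# ---------------------------------------------------------------------------

convParam <- function(K, cin, cout, norm = FALSE) {
  p <- list(W = newParam(heInit(K * cin, cout, fanin = K * cin)),
            b = newParam(numeric(cout)))
  if (norm) {
    p$gamma <- newParam(rep(1, cout))
    p$beta <- newParam(numeric(cout))
  }
  p
}

convTParam <- function(cin, cout) {
  list(W = newParam(heInit(cin, 8L * cout, fanin = cin)),
       b = newParam(numeric(cout)))
}

encoderParams <- function(C) {
  n <- TRUE  # Basic2d/Basic3d blocks are Conv + InstanceNorm + ReLU
  list(e0a = convParam(9L, 1L, C, n),       e0b = convParam(9L, 1L + C, C, n),
       e1a = convParam(9L, C, 2L * C, n),   e1b = convParam(9L, 3L * C, 2L * C, n),
       e2a = convParam(9L, 2L * C, 4L * C, n), e2b = convParam(9L, 6L * C, 4L * C, n),
       e3a = convParam(9L, 4L * C, 4L * C, n), e3b = convParam(9L, 8L * C, 4L * C, n),
       m3 = convParam(1L, 4L * C, 2L * C), r3 = convParam(27L, 2L * C, 2L * C, n),
       m2 = convParam(1L, 4L * C, C),      r2 = convParam(27L, C, C, n),
       m1 = convParam(1L, 2L * C, C),      r1 = convParam(27L, C, C, n),
       u2 = convTParam(2L * C, C),         d2 = convParam(27L, 2L * C, C, n),
       u1 = convTParam(C, C),              d1 = convParam(27L, 2L * C, C, n))
}

#' Build the two-view fusion generator
#'
#' Parameter initialization is seeded from `cfg@seed`; channel widths scale
#' with `cfg@baseChannels` and the output is a `cfg@volumeSize`^3 grid in
#' [0, 1]. The network depth (three 2x down/up-samplings) requires
#' `volumeSize >= 16`.
#'
#' @param cfg a [GanConfig-class].
#' @return A generator object (list with `params`, `cfg`), class
#'   `"ctGenerator"`.
#' @export
buildGenerator <- function(cfg) {
  stopifnot(is(cfg, "GanConfig"))
  validObject(cfg)
  if (cfg@volumeSize %/% 8L < 2L)
    stop("volumeSize ", cfg@volumeSize,
         " is incompatible with the network depth (needs >= 16)")
  set.seed(cfg@seed)
  C <- cfg@baseChannels
  params <- list(
    view1 = encoderParams(C),
    view2 = encoderParams(C),
    h2 = convParam(27L, C, C, TRUE),
    fu1 = convTParam(C, C),
    h1 = convParam(27L, 2L * C, C, TRUE),
    fu0 = convTParam(C, C),
    outc = convParam(1L, C, 1L))
  # calm start for the output head: small weights and a dark bias keep the
  # sigmoid out of saturation (CT volumes are mostly low-intensity surround)
  params$outc$W$val <- params$outc$W$val * 0.02
  params$outc$b$val <- params$outc$b$val - 2
  structure(list(params = params, cfg = cfg), class = "ctGenerator")
}

convBlock <- function(x, p, k = 3L) {
  y <- agConv(x, p$W, p$b, k = k)
  if (!is.null(p$gamma)) y <- agInstNorm(y, p$gamma, p$beta)
  agRelu(y)
}

# dense 2D encoder stage: conv, concat input, conv
denseStage <- function(x, pa, pb) {
  a <- convBlock(x, pa)
  convBlock(agConcatC(x, a), pb)
}

# one view's encoder + pseudo-3D bridge + view-specific decoder.
# Returns the decoder grids at scales N/4 and N/2 (in the view's own frame).
viewStream <- function(img, p) {
  x0 <- agConst(array(img, c(dim(img), 1L)))
  e0 <- denseStage(x0, p$e0a, p$e0b)
  e1 <- denseStage(agPool(e0), p$e1a, p$e1b)          # N/2
  e2 <- denseStage(agPool(e1), p$e2a, p$e2b)          # N/4
  e3 <- denseStage(agPool(e2), p$e3a, p$e3b)          # N/8
  s3 <- dim(e3$val)[1]; s2 <- dim(e2$val)[1]; s1 <- dim(e1$val)[1]
  f3 <- convBlock(agExpandY(agConv(e3, p$m3$W, p$m3$b, k = 1L), s3), p$r3)
  f2 <- convBlock(agExpandY(agConv(e2, p$m2$W, p$m2$b, k = 1L), s2), p$r2)
  f1 <- convBlock(agExpandY(agConv(e1, p$m1$W, p$m1$b, k = 1L), s1), p$r1)
  u2 <- agConvT3d(f3, p$u2$W, p$u2$b)                 # N/8 -> N/4
  d2 <- convBlock(agConcatC(u2, f2), p$d2)            # N/4
  u1 <- agConvT3d(d2, p$u1$W, p$u1$b)                 # N/4 -> N/2
  d1 <- convBlock(agConcatC(u1, f1), p$d1)            # N/2
  list(d2 = d2, d1 = d1)
}

# full generator forward pass; x1, x2 are N x N matrices in [0, 1].
genForward <- function(gen, x1, x2) {
  p <- gen$params
  N <- gen$cfg@volumeSize
  stopifnot(all(dim(x1) == N), all(dim(x2) == N))
  v1 <- viewStream(x1, p$view1)
  v2 <- viewStream(x2, p$view2)
  g2 <- agAvg(v1$d2, agRotZ90(v2$d2))                 # fuse at N/4
  h2 <- convBlock(g2, p$h2)
  g1 <- agAvg(v1$d1, agRotZ90(v2$d1))                 # fuse at N/2
  h1 <- convBlock(agConcatC(agConvT3d(h2, p$fu1$W, p$fu1$b), g1), p$h1)
  h0 <- agConvT3d(h1, p$fu0$W, p$fu0$b)               # N
  agSigmoid(agConv(h0, p$outc$W, p$outc$b, k = 1L))
}

#' Reconstruct a CT volume from a biplanar X-ray pair
#'
#' Runs the generator in inference mode (no gradient graph is retained).
#' Inputs are resized to the generator's input edge if needed.
#'
#' @param gen a generator built by [buildGenerator()] (possibly trained).
#' @param xray1,xray2 anterior and lateral images: [XRayImage-class] objects
#'   or numeric matrices in [0, 1].
#' @return A `volumeSize`^3 numeric array in [0, 1].
#' @export
predictVolume <- function(gen, xray1, xray2) {
  stopifnot(inherits(gen, "ctGenerator"))
  N <- gen$cfg@volumeSize
  m1 <- if (is(xray1, "XRayImage")) xray1@pixels else xray1
  m2 <- if (is(xray2, "XRayImage")) xray2@pixels else xray2
  m1 <- resizeBilinear(m1, N, N)
  m2 <- resizeBilinear(m2, N, N)
  out <- agNoGrad(genForward(gen, m1, m2))
  v <- out$val
  dim(v) <- rep(N, 3L)
  v
}

#' Serialize / restore network parameters
#'
#' Checkpoints hold plain numeric parameter values (no environments), so
#' they are stable across sessions.
#'
#' @param net a generator or discriminator object.
#' @return `serializeNet` returns a plain list; `restoreNet` a network with
#'   the checkpointed values in place.
#' @export
serializeNet <- function(net) {
  mapTensors <- function(x)
    if (agIsTensor(x)) x$val else lapply(x, mapTensors)
  list(values = mapTensors(net$params), cfg = net$cfg, cls = class(net))
}

#' @rdname serializeNet
#' @param checkpoint a list produced by `serializeNet`.
#' @export
restoreNet <- function(net, checkpoint) {
  flat <- flattenParams(net$params)
  ckFlat <- flattenCheckpoint(checkpoint$values)
  stopifnot(length(flat) == length(ckFlat))
  for (i in seq_along(flat)) flat[[i]]$val <- ckFlat[[i]]
  net
}

flattenCheckpoint <- function(x) {
  if (is.numeric(x)) return(list(x))
  unlist(lapply(x, flattenCheckpoint), recursive = FALSE, use.names = FALSE)
}
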